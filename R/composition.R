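#' Codon and amino-acid compositional statistics
#'
#' Frequencies are always `Freq(X) = Count(X) / s` with `s` the number of
#' codons in the unit (peak or gene). Peak-level biases are tested against
#' 10 000 matched control peak sets (same peak number, same per-peak codon
#' lengths, placed uniformly in expressed CDS); gene-set contrasts use a
#' zero-inflated beta regression on per-gene frequencies.
#'
#' @name composition
NULL

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                    c("T", "C", "A", "G"), paste0),
                              c("T", "C", "A", "G"), paste0))
AA_LEVELS <- sort(unique(unname(Biostrings::GENETIC_CODE)))

# integer codon codes 1..64 for a gene_model (or codon character vector)
codon_codes <- function(x) {
  codons <- if (inherits(x, "gene_model")) x$codons else x
  match(codons, ALL_CODONS)
}

feature_levels <- function(family) {
  switch(family, codon = ALL_CODONS, amino_acid = AA_LEVELS,
         stop("unknown feature family: ", family))
}

# map codon codes to feature codes for a family
feature_codes <- function(codes, family) {
  if (family == "codon") return(codes)
  match(unname(Biostrings::GENETIC_CODE[ALL_CODONS]), AA_LEVELS)[codes]
}

#' Codons overlapped by nucleotide-interval peaks
#'
#' Any codon with at least one overlapped nucleotide belongs to the peak;
#' codons spanning a CDS-segment junction can be excluded.
#'
#' @param peaks data.frame with gene_id, start, end (0-based half-open CDS
#'   nt coordinates).
#' @param models named list of `gene_model` (or a `gene_model_set`).
#' @param exclude_boundary drop junction-spanning codons (default TRUE).
#' @return list of character codon vectors, one per peak row.
#' @export
peak_codons <- function(peaks, models, exclude_boundary = TRUE) {
  if (inherits(models, "gene_model_set")) models <- models$models
  lapply(seq_len(nrow(peaks)), function(i) {
    g <- models[[peaks$gene_id[i]]]
    if (is.null(g)) stop("peak unit outside any CDS: ", peaks$gene_id[i])
    first <- peaks$start[i] %/% 3L + 1L
    last <- (peaks$end[i] - 1L) %/% 3L + 1L
    ord <- seq(first, min(last, length(g$codons)))
    if (exclude_boundary) {
      ci <- codon_index(g)
      ord <- ord[!ci$codon_table$boundary[ord]]
    }
    g$codons[ord]
  })
}

#' Per-unit feature frequency table
#'
#' @param units list of codon character vectors (one per unit: a peak or a
#'   whole CDS), optionally named.
#' @param family `"codon"` or `"amino_acid"`.
#' @return data.frame: unit_id, feature, count, n_codons, freq. Absent
#'   features get frequency 0.
#' @export
feature_frequencies <- function(units, family = c("codon", "amino_acid")) {
  family <- match.arg(family)
  lev <- feature_levels(family)
  ids <- names(units)
  if (is.null(ids)) ids <- paste0("unit", seq_along(units))
  rows <- lapply(seq_along(units), function(i) {
    codes <- feature_codes(codon_codes(units[[i]]), family)
    s <- length(codes)
    cnt <- tabulate(codes, nbins = length(lev))
    data.frame(unit_id = ids[i], feature = lev, count = cnt, n_codons = s,
               freq = if (s > 0) cnt / s else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# mean per-unit frequency vector over a list of codon vectors
mean_unit_freq <- function(units, family) {
  lev <- feature_levels(family)
  fr <- vapply(units, function(u) {
    codes <- feature_codes(codon_codes(u), family)
    tabulate(codes, nbins = length(lev)) / length(codes)
  }, numeric(length(lev)))
  rowMeans(matrix(fr, nrow = length(lev)))
}

#' Matched-control randomization test of peak compositional bias
#'
#' Draws `n_controls` control peak sets, each with the same number of peaks
#' and identical per-peak codon lengths, placed uniformly at random over
#' codon start positions of the expressed-gene CDS (genes weighted by their
#' number of eligible positions). For each feature, the observed mean
#' per-peak frequency is compared with the control distribution:
#' `k` controls are >= and `l` controls <= the observed value (ties in
#' both), `p_emp = min(k, l) / n_controls`, floored at `1 / n_controls`,
#' then BH-adjusted across features.
#'
#' @param peak_units list of codon vectors for the observed peaks (e.g.
#'   from [peak_codons()]).
#' @param models expressed-gene models (list or `gene_model_set`) the
#'   controls are placed in.
#' @param family `"codon"` or `"amino_acid"`.
#' @param n_controls number of control sets (default 10000).
#' @param seed integer seed for the placement draw.
#' @return data.frame per feature: mean_obs, k, l, n_controls, p_emp,
#'   p_adj, sign (+1 if k > l else -1), refreq vs the pooled control mean.
#'   The control-set count actually drawn is attached as attribute
#'   `n_controls_drawn`.
#' @export
peak_randomization_test <- function(peak_units, models,
                                    family = c("codon", "amino_acid"),
                                    n_controls = 10000L, seed = 1L) {
  family <- match.arg(family)
  if (inherits(models, "gene_model_set")) models <- models$models
  lens <- vapply(peak_units, length, integer(1L))
  if (any(lens < 1L)) stop("every peak must cover at least one codon")
  lev <- feature_levels(family)
  obs <- mean_unit_freq(peak_units, family)

  gene_codes <- lapply(models, codon_codes)
  gene_len <- vapply(gene_codes, length, integer(1L))
  big <- unlist(gene_codes, use.names = FALSE)
  big <- feature_codes(big, family)
  offset <- cumsum(c(0L, gene_len[-length(gene_len)]))
  n_peaks <- length(peak_units)

  set.seed(seed)
  sums <- matrix(0, n_controls, length(lev))
  for (l in sort(unique(lens))) {
    m <- sum(lens == l)
    eligible <- which(gene_len >= l)
    if (!length(eligible))
      stop("a control peak of ", l, " codons is longer than every CDS")
    w <- gene_len[eligible] - l + 1L
    M <- n_controls * m
    gpick <- eligible[sample.int(length(eligible), M, replace = TRUE,
                                 prob = w)]
    start <- floor(stats::runif(M) * (gene_len[gpick] - l + 1L))  # 0-based
    base <- offset[gpick] + start
    # sum of per-peak frequencies per control set: within a length group the
    # peak length is constant, so sum(freq) = sum(counts) / l and no
    # per-placement matrix is needed
    set_id <- rep(seq_len(n_controls), each = m)
    cnt_set <- numeric(n_controls * length(lev))
    for (j in seq_len(l)) {
      code <- big[base + j]
      cnt_set <- cnt_set + tabulate((code - 1L) * n_controls + set_id,
                                    nbins = n_controls * length(lev))
    }
    sums <- sums + matrix(cnt_set, n_controls, length(lev)) / l
  }
  ctrl_means <- sums / n_peaks
  k <- colSums(ctrl_means >= matrix(obs, n_controls, length(lev),
                                    byrow = TRUE))
  low <- colSums(ctrl_means <= matrix(obs, n_controls, length(lev),
                                      byrow = TRUE))
  p_emp <- pmax(pmin(k, low) / n_controls, 1 / n_controls)
  ctrl_overall <- colMeans(ctrl_means)
  out <- data.frame(feature = lev, mean_obs = obs, k = k, l = low,
                    n_controls = n_controls, p_emp = p_emp,
                    p_adj = stats::p.adjust(p_emp, "BH"),
                    sign = ifelse(k > low, 1L, -1L),
                    refreq = ifelse(ctrl_overall > 0,
                                    (obs - ctrl_overall) / ctrl_overall,
                                    NA_real_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_controls_drawn") <- nrow(ctrl_means)
  out
}

#' Relative frequency of a feature between a test and a control set
#'
#' @param freq_t,freq_c average feature frequencies in the test and control
#'   sets.
#' @return `(freq_t - freq_c) / freq_c` (multiply by 100 for percent);
#'   `NA` when `freq_c` is 0.
#' @export
relative_frequency <- function(freq_t, freq_c) {
  out <- (freq_t - freq_c) / freq_c
  out[freq_c == 0] <- NA_real_
  out
}

# ---- zero-inflated beta regression -----------------------------------------

# ML beta regression: logit(mu) ~ X, common log(phi); returns coef, vcov
fit_beta_reg <- function(y, X) {
  nll <- function(par) {
    beta <- par[-length(par)]
    phi <- exp(par[length(par)])
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(stats::qlogis(mean(y)), rep(0, ncol(X) - 1L), log(10))
  fit <- try(stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                          control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) return(NULL)
  V <- try(solve(fit$hessian), silent = TRUE)
  if (inherits(V, "try-error")) return(NULL)
  list(coef = fit$par[-length(fit$par)],
       vcov = V[-nrow(V), -ncol(V), drop = FALSE])
}

#' Zero-inflated beta comparison of feature frequencies across gene sets
#'
#' Per feature, frequencies are modeled in two parts: a logistic zero part
#' (`freq == 0 ~ set`) and a beta positive part with
#' `logit(mu) ~ set + size` and common precision, fit by maximum
#' likelihood. All pairwise set contrasts are Wald tests; within each
#' feature the contrast p-values are family-wise adjusted (Holm), then
#' BH-corrected across features.
#'
#' @param freq_table data.frame: unit_id, feature, freq, size (unit length
#'   in codons), set (factor of set labels; include the control set as its
#'   own level).
#' @return data.frame per feature x contrast: estimate_pos (logit-scale
#'   positive-part difference), p_pos, p_zero, p_value (positive part when
#'   defined, else zero part), p_fw (Holm within feature), p_adj (BH across
#'   features), converged.
#' @export
zib_set_comparison <- function(freq_table) {
  stopifnot(all(c("feature", "freq", "size", "set") %in% names(freq_table)))
  freq_table$set <- factor(freq_table$set)
  sets <- levels(freq_table$set)
  if (length(sets) < 2L) stop("need at least two sets")
  pairs <- utils::combn(sets, 2L, simplify = FALSE)
  rows <- list()
  for (f in unique(freq_table$feature)) {
    d <- freq_table[freq_table$feature == f, , drop = FALSE]
    n <- nrow(d)
    y <- d$freq
    y[y == 1] <- (y[y == 1] * (n - 1) + 0.5) / n  # boundary shrink
    pos <- y > 0
    # positive part: beta regression on positive units
    dp <- d[pos, , drop = FALSE]
    bfit <- NULL
    if (nrow(dp) > length(sets) + 2L && length(unique(dp$set)) == length(sets)) {
      Xp <- stats::model.matrix(~ set + scale(size), data = dp)
      bfit <- fit_beta_reg(y[pos], Xp)
    }
    for (pr in pairs) {
      cvec_for <- function(names_vec) {
        cv <- numeric(length(names_vec)); names(cv) <- names_vec
        na <- paste0("set", pr[1L]); nb <- paste0("set", pr[2L])
        if (na %in% names_vec) cv[na] <- 1
        if (nb %in% names_vec) cv[nb] <- -1
        cv
      }
      est_p <- p_pos <- NA_real_
      if (!is.null(bfit)) {
        cn <- colnames(stats::model.matrix(~ set + scale(size), data = dp))
        cv <- cvec_for(cn)
        est_p <- sum(cv * bfit$coef)
        se <- sqrt(drop(t(cv) %*% bfit$vcov %*% cv))
        if (is.finite(se) && se > 0)
          p_pos <- 2 * stats::pnorm(abs(est_p / se), lower.tail = FALSE)
      }
      # zero part: likelihood-ratio test on the pair subset (robust to the
      # quasi-separation of an all-zero set, where Wald degenerates)
      p_zero <- NA_real_
      sel2 <- d$set %in% pr
      z2 <- !pos[sel2]
      if (any(z2) && any(!z2)) {
        fit1 <- stats::glm(z2 ~ factor(d$set[sel2]),
                           family = stats::binomial())
        p_zero <- stats::anova(fit1, test = "Chisq")[2L, "Pr(>Chi)"]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, set_a = pr[1L], set_b = pr[2L], estimate_pos = est_p,
        p_pos = p_pos, p_zero = p_zero,
        p_value = ifelse(is.na(p_pos), p_zero, p_pos),
        converged = !is.null(bfit), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fw <- NA_real_
  for (f in unique(out$feature)) {
    sel <- out$feature == f
    out$p_fw[sel] <- stats::p.adjust(out$p_value[sel], "holm")
  }
  conv <- !is.na(out$p_fw)
  out$p_adj <- NA_real_
  out$p_adj[conv] <- stats::p.adjust(out$p_fw[conv], "BH")
  rownames(out) <- NULL
  out
}

#' Codon frequency profile in sliding windows around peak centers
#'
#' The center codon is `start + ceiling((end - start) / 2)` in codon
#' coordinates. Offset 0 reports the within-peak frequency; offsets
#' -n_windows..-1 and 1..n_windows report `window`-codon windows stepped by
#' `step` codons from the center, truncated at the CDS ends. Boundary
#' codons are excluded.
#'
#' @param peaks data.frame gene_id, start, end (0-based half-open nt).
#' @param models gene models the peaks live in.
#' @param family feature family.
#' @param window window width in codons (default 10).
#' @param n_windows maximum windows each side (default 50).
#' @param step step between window anchors in codons (default 1).
#' @return list: `freq` (feature x offset mean-frequency matrix) and `n`
#'   (number of peaks contributing per offset).
#' @export
codon_window_profile <- function(peaks, models,
                                 family = c("codon", "amino_acid"),
                                 window = 10L, n_windows = 50L, step = 1L) {
  family <- match.arg(family)
  if (inherits(models, "gene_model_set")) models <- models$models
  lev <- feature_levels(family)
  offsets <- seq(-n_windows, n_windows)
  acc <- matrix(0, length(lev), length(offsets),
                dimnames = list(lev, offsets))
  nmat <- matrix(0L, length(lev), length(offsets),
                 dimnames = list(lev, offsets))
  for (i in seq_len(nrow(peaks))) {
    g <- models[[peaks$gene_id[i]]]
    ci <- codon_index(g)
    usable <- !ci$codon_table$boundary
    codes <- feature_codes(codon_codes(g), family)
    n_cod <- length(codes)
    first <- peaks$start[i] %/% 3L + 1L
    last <- min((peaks$end[i] - 1L) %/% 3L + 1L, n_cod)
    center <- first + as.integer(ceiling((last - first) / 2))
    win_freq <- function(lo, hi) {
      lo <- max(1L, lo); hi <- min(n_cod, hi)
      if (hi < lo) return(NULL)
      sel <- seq(lo, hi)
      sel <- sel[usable[sel]]
      if (!length(sel)) return(NULL)
      tabulate(codes[sel], nbins = length(lev)) / length(sel)
    }
    for (o in seq_along(offsets)) {
      k <- offsets[o]
      fr <- if (k == 0L) win_freq(first, last)
            else if (k > 0L) win_freq(center + (k - 1L) * step + 1L,
                                      center + (k - 1L) * step + window)
            else win_freq(center + (k + 1L) * step - window,
                          center + (k + 1L) * step - 1L)
      if (!is.null(fr)) {
        acc[, o] <- acc[, o] + fr
        nmat[, o] <- nmat[, o] + 1L
      }
    }
  }
  freq <- acc / ifelse(nmat > 0, nmat, NA)
  list(freq = freq, n = nmat)
}

KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Kyte-Doolittle GRAVY index of a protein sequence
#'
#' @param protein amino-acid string (one-letter); stop (`*`) and unknown
#'   residues are excluded from the mean.
#' @return mean residue hydropathy.
#' @export
gravy_index <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1L]]
  h <- KYTE_DOOLITTLE[aa]
  mean(h, na.rm = TRUE)
}
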
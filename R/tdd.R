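#' Translation-dependent decay (TDD) index from inhibitor time courses
#'
#' The TDD index of an mRNA is the gap its abundance keeps when translation
#' is blocked alongside transcription:
#' `index = (R_TciTli - R_Tci) / R0`, where R0 is the normalized abundance
#' at t = 0, R_Tci after t hours of transcription inhibitor only, and
#' R_TciTli after t hours of transcription + translation inhibitors.
#' Normalization anchors on "stable genes" — genes whose relative (CPM)
#' abundance satisfies three criteria through the time course — via
#' median-of-ratios size factors restricted to those genes.
#'
#' @name tdd
NULL

#' Counts-per-million normalization
#'
#' @param counts numeric gene x sample matrix of raw counts.
#' @return matrix of the same shape; each column sums to 1e6. Zeros are
#'   preserved (no pseudo-count).
#' @export
compute_cpm <- function(counts) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    bad <- colnames(counts)[libs <= 0]
    if (is.null(bad)) bad <- which(libs <= 0)
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2L, libs, "/") * 1e6
}

#' Detect stable normalization genes from the CPM time course
#'
#' A gene is stable when, in every condition x replicate: (i) its CPM at the
#' initial (t = 0) sample exceeds `cpm0_min`; and at the required
#' transcription-inhibitor times t, (ii) CPM_t is at least 10% greater than
#' CPM0 (`literal` mode) or within a 10-fold window below (`ratio` mode),
#' and (iii) CPM0 exceeds 10% of CPM_t. Under transcription shutoff CPM is
#' compositional, so the relative abundance of non-decaying genes rises —
#' hence criterion (ii)'s direction.
#'
#' @param cpm CPM matrix (genes x samples).
#' @param design sample sheet with columns sample, condition, regime,
#'   time_h, replicate; must contain t = 0 and Tci samples.
#' @param mode `"literal"`: CPM_t >= 1.1 * CPM0. `"ratio"`: CPM_t >= 0.1 *
#'   CPM0 (symmetric 10-fold reading).
#' @param times `"both"`: criteria must hold at every Tci time; `"any"`: at
#'   least one time suffices.
#' @param cpm0_min threshold for criterion (i).
#' @return character vector of stable gene ids.
#' @export
detect_stable_genes <- function(cpm, design, mode = c("literal", "ratio"),
                                times = c("both", "any"), cpm0_min = 0.2) {
  mode <- match.arg(mode)
  times <- match.arg(times)
  if (!any(design$time_h == 0))
    stop("design lacks a t = 0 initial sample")
  tci_times <- sort(unique(design$time_h[design$regime == "Tci" &
                                         design$time_h > 0]))
  if (!length(tci_times)) stop("design lacks Tci samples at t > 0")
  ok <- rep(TRUE, nrow(cpm))
  for (cond in unique(design$condition)) {
    for (r in unique(design$replicate[design$condition == cond])) {
      s0 <- design$sample[design$condition == cond & design$replicate == r &
                          design$time_h == 0]
      if (length(s0) != 1L)
        stop("expected one t = 0 sample for ", cond, " replicate ", r)
      cpm0 <- cpm[, s0]
      ok <- ok & (cpm0 > cpm0_min)
      per_time <- sapply(tci_times, function(t) {
        st <- design$sample[design$condition == cond &
                            design$replicate == r &
                            design$regime == "Tci" & design$time_h == t]
        cpmt <- cpm[, st]
        crit2 <- if (mode == "literal") cpmt >= 1.1 * cpm0
                 else cpmt >= 0.1 * cpm0
        crit3 <- cpm0 > 0.1 * cpmt
        crit2 & crit3
      })
      ok <- ok & if (times == "both") apply(per_time, 1L, all)
                 else apply(per_time, 1L, any)
    }
  }
  rownames(cpm)[ok]
}

#' Median-of-ratios size factors over a stable-gene set
#'
#' Each sample's factor is the median, over stable genes, of the ratio of
#' its count to the gene's geometric-mean pseudo-reference across samples.
#' With every gene declared stable this is the standard all-gene
#' median-of-ratios estimator.
#'
#' @param counts raw count matrix (genes x samples).
#' @param stable_set character vector of stable gene ids (rownames).
#' @return named numeric vector of per-sample size factors.
#' @export
stable_size_factors <- function(counts, stable_set) {
  stopifnot(length(stable_set) >= 1L)
  sub <- as.matrix(counts[rownames(counts) %in% stable_set, , drop = FALSE])
  if (nrow(sub) == 0L) stop("no stable genes found in the count matrix")
  logs <- log(sub)
  log_ref <- rowMeans(logs)
  usable <- is.finite(log_ref)
  if (!any(usable))
    stop("no stable gene is nonzero across all samples")
  sf <- apply(logs[usable, , drop = FALSE], 2L, function(col)
    exp(stats::median(col - log_ref[usable])))
  if (any(!is.finite(sf) | sf <= 0)) {
    bad <- colnames(sub)[!is.finite(sf) | sf <= 0]
    stop("degenerate size factor for sample(s): ", paste(bad, collapse = ", "))
  }
  sf
}

#' The TDD index of one observation
#'
#' @param R0 normalized abundance at t = 0 (must be > 0).
#' @param R_tci normalized abundance after t h of transcription inhibitor.
#' @param R_tcitli normalized abundance after t h of transcription +
#'   translation inhibitors.
#' @return `(R_tcitli - R_tci) / R0`, vectorized; `NA` with reason
#'   attribute when R0 is not positive.
#' @export
compute_tdd_index <- function(R0, R_tci, R_tcitli) {
  idx <- (R_tcitli - R_tci) / R0
  bad <- !(R0 > 0)
  if (any(bad, na.rm = TRUE)) {
    idx[bad] <- NA_real_
    attr(idx, "excluded") <- which(bad)
    attr(idx, "reason") <- "R0_not_positive"
  }
  idx
}

#' Per-gene TDD index table for a full design
#'
#' Normalizes counts by stable-gene size factors and evaluates the index
#' for every gene x condition x time x replicate cell.
#'
#' @param counts raw counts (genes x samples).
#' @param design sample sheet (see [detect_stable_genes()]).
#' @param stable_set stable genes; computed from the data when `NULL`. When
#'   detection returns no gene, all genes are used as normalization anchors
#'   (plain median-of-ratios) with a warning.
#' @param ... passed to [detect_stable_genes()].
#' @return list: `indices` (long data.frame gene_id, condition, time_h,
#'   replicate, index), `size_factors`, `stable_genes`, `excluded`
#'   (gene ids dropped for non-positive R0).
#' @export
tdd_index_table <- function(counts, design, stable_set = NULL, ...) {
  counts <- as.matrix(counts)
  cpm <- compute_cpm(counts)
  if (is.null(stable_set)) {
    stable_set <- detect_stable_genes(cpm, design, ...)
    if (length(stable_set) == 0L) {
      warning("no gene passed the stable criteria in every replicate; ",
              "falling back to all-gene median-of-ratios normalization",
              call. = FALSE)
      stable_set <- rownames(counts)
    }
  }
  sf <- stable_size_factors(counts, stable_set)
  norm <- sweep(counts, 2L, sf[colnames(counts)], "/")
  cells <- unique(design[design$time_h > 0,
                         c("condition", "time_h", "replicate")])
  rows <- vector("list", nrow(cells))
  excluded <- character(0)
  for (i in seq_len(nrow(cells))) {
    cond <- cells$condition[i]; t <- cells$time_h[i]; r <- cells$replicate[i]
    pick <- function(regime, time) {
      s <- design$sample[design$condition == cond &
                         design$replicate == r &
                         design$regime == regime & design$time_h == time]
      if (length(s) != 1L)
        stop("need exactly one sample for ", cond, "/", regime, "/t", time,
             "/r", r)
      norm[, s]
    }
    R0 <- pick("none", 0)
    idx <- compute_tdd_index(R0, pick("Tci", t), pick("Tci+Tli", t))
    excluded <- union(excluded, rownames(norm)[!(R0 > 0)])
    rows[[i]] <- data.frame(gene_id = rownames(norm), condition = cond,
                            time_h = t, replicate = r, index = as.numeric(idx),
                            stringsAsFactors = FALSE)
  }
  list(indices = do.call(rbind, rows), size_factors = sf,
       stable_genes = stable_set, excluded = excluded)
}

#' Test per-mRNA TDD shifts between conditions
#'
#' Fits, per gene, `index ~ condition + time + replicate` by least squares
#' (time and replicate as factors, main effects only) and performs a
#' two-sided Student's t-test on the condition coefficient. Significant
#' genes are classified `increased`/`decreased` by the sign of the
#' unweighted mean difference (treated - control) of indices across
#' replicates and times.
#'
#' @param indices long data.frame from [tdd_index_table()] (`$indices`), or
#'   any data.frame with gene_id, condition, time_h, replicate, index.
#' @param treated level of `condition` regarded as treated; default the
#'   last level alphabetically ("TRT" in the simulated design).
#' @param alpha significance level on the raw p-value.
#' @return data.frame per gene: mean_treated, mean_control, estimate
#'   (condition coefficient), p_value, p_adj (BH, informational), class.
#' @export
test_tdd_shift <- function(indices, treated = NULL, alpha = 0.05) {
  df <- indices[!is.na(indices$index), , drop = FALSE]
  conds <- sort(unique(df$condition))
  if (length(conds) != 2L) stop("need exactly two conditions")
  if (is.null(treated)) treated <- conds[2L]
  control <- setdiff(conds, treated)
  # one shared design matrix; genes fitted jointly by matrix least squares
  wide <- split(df, df$gene_id)
  n_obs <- vapply(wide, nrow, integer(1L))
  layout <- df[df$gene_id == names(wide)[which.max(n_obs)],
               c("condition", "time_h", "replicate")]
  key <- function(d) paste(d$condition, d$time_h, d$replicate, sep = "|")
  full_keys <- key(layout)
  terms <- c("condition",
             if (length(unique(layout$time_h)) > 1L) "factor(time_h)",
             if (length(unique(layout$replicate)) > 1L) "factor(replicate)")
  form <- stats::reformulate(terms)
  X <- stats::model.matrix(form, data = layout)
  cond_col <- grep("^condition", colnames(X))
  stopifnot(length(cond_col) == 1L)
  # genes with a complete layout go through the fast path
  complete <- names(wide)[vapply(wide, function(d)
    setequal(key(d), full_keys) && nrow(d) == length(full_keys), logical(1L))]
  res <- list()
  if (length(complete)) {
    Y <- vapply(wide[complete], function(d)
      d$index[match(full_keys, key(d))], numeric(length(full_keys)))
    XtXi <- solve(crossprod(X))
    B <- XtXi %*% crossprod(X, Y)
    resid <- Y - X %*% B
    dfres <- nrow(X) - ncol(X)
    if (dfres > 0) {
      s2 <- colSums(resid^2) / dfres
      se <- sqrt(s2 * XtXi[cond_col, cond_col])
      tval <- B[cond_col, ] / se
      p <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
    } else {
      tval <- rep(NA_real_, length(complete))
      p <- rep(NA_real_, length(complete))
    }
    mt <- vapply(wide[complete], function(d)
      mean(d$index[d$condition == treated]), numeric(1L))
    mc <- vapply(wide[complete], function(d)
      mean(d$index[d$condition == control]), numeric(1L))
    res[[1L]] <- data.frame(gene_id = complete, mean_treated = mt,
                            mean_control = mc, estimate = B[cond_col, ],
                            p_value = p, stringsAsFactors = FALSE)
  }
  partial <- setdiff(names(wide), complete)
  for (g in partial) {
    d <- wide[[g]]
    mt <- mean(d$index[d$condition == treated])
    mc <- mean(d$index[d$condition == control])
    p <- NA_real_; est <- NA_real_
    if (length(unique(d$condition)) == 2L) {
      tg <- c("condition",
              if (length(unique(d$time_h)) > 1L) "factor(time_h)",
              if (length(unique(d$replicate)) > 1L) "factor(replicate)")
      fit <- stats::lm(stats::reformulate(tg, response = "index"), data = d)
      co <- summary(fit)$coefficients
      row <- grep("^condition", rownames(co))
      if (length(row) == 1L && fit$df.residual > 0) {
        est <- co[row, "Estimate"]
        p <- co[row, "Pr(>|t|)"]
      }
    }
    res[[length(res) + 1L]] <- data.frame(gene_id = g, mean_treated = mt,
                                          mean_control = mc, estimate = est,
                                          p_value = p,
                                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$class <- ifelse(is.na(out$p_value) | out$p_value > alpha, "unchanged",
                      ifelse(out$mean_treated > out$mean_control,
                             "increased", "decreased"))
  out$reason <- ifelse(is.na(out$p_value), "insufficient_df_or_design", "")
  out
}
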
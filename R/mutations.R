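#' Transcriptional-mutation tallies from nucleotide pileups
#'
#' Low-frequency mismatches in RNA-seq pileups are read as transcriptional
#' mutations: after depth-matching the libraries, only sites with adequate
#' quality and depth are kept, sites with any alternative allele fraction
#' at or above 5% are removed as genomic variants, and the proportion of
#' REF sites carrying each SNP REF>ALT is compared between conditions by
#' logistic regression.
#'
#' @name mutations
NULL

PILEUP_BASES <- c("A", "C", "G", "T")

check_pileup <- function(sites) {
  need <- c("site_id", "ref", "depth", PILEUP_BASES, "qual")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("pileup table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(sites$ref %in% PILEUP_BASES))
    stop("ref base not in {A,C,G,T}")
  tot <- rowSums(as.matrix(sites[, PILEUP_BASES]))
  if (!isTRUE(all.equal(tot, as.numeric(sites$depth))))
    stop("per-base counts do not sum to depth")
  invisible(sites)
}

#' Thin pileup tables to the smallest library's read total
#'
#' Per-base counts are binomially thinned with probability
#' `target / total`, where `total` is the table's summed base counts and
#' `target` the smallest total across conditions; depth is recomputed from
#' the thinned counts.
#'
#' @param tables named list of pileup data.frames (site_id, ref, depth, A,
#'   C, G, T, qual).
#' @param seed integer seed.
#' @return the list with thinned counts.
#' @export
subsample_depth <- function(tables, seed = 1L) {
  for (tb in tables) check_pileup(tb)
  totals <- vapply(tables, function(tb)
    sum(as.matrix(tb[, PILEUP_BASES])), numeric(1L))
  target <- min(totals)
  set.seed(seed)
  out <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    p <- target / totals[i]
    if (p >= 1) return(tb)
    for (b in PILEUP_BASES)
      tb[[b]] <- stats::rbinom(nrow(tb), tb[[b]], p)
    tb$depth <- rowSums(as.matrix(tb[, PILEUP_BASES]))
    tb
  })
  names(out) <- names(tables)
  out
}

#' Filter pileup sites and flag transcriptional SNPs
#'
#' A site is eligible when `qual >= min_qual` (skipped with
#' `use_qual = FALSE`) and `depth` passes the depth rule. Sites with any
#' alternative allele fraction at or above `max_alt_frac` are excluded
#' entirely as genomic variants. An eligible site carries a SNP REF>ALT for
#' every non-REF base with a positive count.
#'
#' @param sites pileup data.frame.
#' @param min_qual site quality threshold (default 10).
#' @param min_depth depth threshold (default 700).
#' @param max_alt_frac genomic-variant allele-fraction cutoff (default
#'   0.05, strict: alt fractions must be < this).
#' @param depth_cmp `">="` (default) or `">"` for the depth rule.
#' @param use_qual apply the quality criterion (default TRUE).
#' @return eligible sites with logical columns `snp_A` .. `snp_T` and
#'   `alt_frac_max`.
#' @export
filter_sites <- function(sites, min_qual = 10, min_depth = 700,
                         max_alt_frac = 0.05, depth_cmp = c(">=", ">"),
                         use_qual = TRUE) {
  check_pileup(sites)
  depth_cmp <- match.arg(depth_cmp)
  cnt <- as.matrix(sites[, PILEUP_BASES])
  ref_idx <- match(sites$ref, PILEUP_BASES)
  alt <- cnt
  alt[cbind(seq_len(nrow(cnt)), ref_idx)] <- 0
  frac <- alt / ifelse(sites$depth > 0, sites$depth, NA)
  ok <- (!use_qual | sites$qual >= min_qual) &
        (if (depth_cmp == ">=") sites$depth >= min_depth
         else sites$depth > min_depth) &
        apply(frac, 1L, max) < max_alt_frac
  ok[is.na(ok)] <- FALSE
  out <- sites[ok, , drop = FALSE]
  af <- frac[ok, , drop = FALSE]
  for (b in PILEUP_BASES)
    out[[paste0("snp_", b)]] <- alt[ok, b] > 0
  out$alt_frac_max <- apply(af, 1L, max)
  out
}

#' SNP proportions per REF>ALT and per REF>* over eligible sites
#'
#' @param eligible filtered sites from [filter_sites()].
#' @return data.frame: ref, alt (`"*"` rows aggregate any SNP on that REF),
#'   n_snp, n_ref (eligible REF sites), proportion.
#' @export
snp_proportions <- function(eligible) {
  rows <- list()
  for (r in PILEUP_BASES) {
    sel <- eligible$ref == r
    n_ref <- sum(sel)
    any_snp <- rep(FALSE, n_ref)
    for (a in setdiff(PILEUP_BASES, r)) {
      snp <- eligible[[paste0("snp_", a)]][sel]
      any_snp <- any_snp | snp
      rows[[length(rows) + 1L]] <- data.frame(
        ref = r, alt = a, n_snp = sum(snp), n_ref = n_ref,
        proportion = if (n_ref > 0) sum(snp) / n_ref else NA_real_,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      ref = r, alt = "*", n_snp = sum(any_snp), n_ref = n_ref,
      proportion = if (n_ref > 0) sum(any_snp) / n_ref else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare SNP proportions between two conditions
#'
#' Per REF>ALT (and REF>*), a logistic regression of the site-level SNP
#' indicator on condition over eligible REF sites of both conditions
#' (replicates pooled); the Wald p-value of the condition term is reported
#' with the relative frequency `(prop_test - prop_ctrl) / prop_ctrl`.
#'
#' @param test,ctrl filtered site tables from [filter_sites()] for the test
#'   and control condition.
#' @param include_any include REF>* aggregate rows and an overall `*>*` row
#'   pooling all eligible sites (default TRUE).
#' @return data.frame: ref, alt, prop_test, prop_ctrl, refreq (fraction;
#'   multiply by 100 for percent), refreq_pct, p_value, reason.
#' @export
compare_conditions <- function(test, ctrl, include_any = TRUE) {
  combos <- expand.grid(ref = PILEUP_BASES, alt = PILEUP_BASES,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  if (include_any)
    combos <- rbind(combos, data.frame(ref = c(PILEUP_BASES, "*"), alt = "*"))
  count_y <- function(d, r, a) {
    sel <- if (r == "*") rep(TRUE, nrow(d)) else d$ref == r
    if (a == "*") {
      y <- rep(FALSE, sum(sel))
      for (b in PILEUP_BASES) {
        hit <- if (r == "*") d$ref[sel] != b else r != b
        y <- y | (d[[paste0("snp_", b)]][sel] & hit)
      }
    } else y <- d[[paste0("snp_", a)]][sel]
    c(k = sum(y), n = length(y))
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    r <- combos$ref[i]; a <- combos$alt[i]
    ct <- count_y(test, r, a); cc <- count_y(ctrl, r, a)
    reason <- ""
    p <- NA_real_; refreq <- NA_real_
    pt <- if (ct["n"] > 0) ct[["k"]] / ct[["n"]] else NA_real_
    pc <- if (cc["n"] > 0) cc[["k"]] / cc[["n"]] else NA_real_
    if (ct["n"] == 0 || cc["n"] == 0) {
      reason <- "zero_denominator"
    } else {
      if (pc == 0) reason <- "zero_control_proportion"
      else refreq <- (pt - pc) / pc
      if (ct["k"] + cc["k"] > 0 && ct["k"] + cc["k"] < ct["n"] + cc["n"]) {
        # logistic regression of the SNP indicator on condition; the
        # aggregated binomial fit is identical to the site-level one
        cond <- factor(c("test", "ctrl"), levels = c("ctrl", "test"))
        fit <- suppressWarnings(
          stats::glm(cbind(c(ct[["k"]], cc[["k"]]),
                           c(ct[["n"]] - ct[["k"]],
                             cc[["n"]] - cc[["k"]])) ~ cond,
                     family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 50L)))
        if (fit$converged) {
          co <- summary(fit)$coefficients
          if ("condtest" %in% rownames(co))
            p <- co["condtest", "Pr(>|z|)"]
        } else if (reason == "") reason <- "glm_not_converged"
      } else {
        p <- 1
        if (reason == "") reason <- "no_variation"
      }
    }
    rows[[i]] <- data.frame(ref = r, alt = a, prop_test = pt, prop_ctrl = pc,
                            refreq = refreq, refreq_pct = 100 * refreq,
                            p_value = p, reason = reason,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
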
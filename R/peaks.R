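#' Differential ribosome-pause peak calling
#'
#' For each gene and replicate i the Ribo-seq coverage is normalized by the
#' paired RNA-seq coverage (`cNorm = ribo/rna`; positions with zero RNA
#' coverage are masked). The per-position test-minus-control difference
#' `cDiff_i` is averaged over replicates into `cMean`, and a gene-level
#' threshold `T = MeanCov + 3 * StdMean` is set from the mean and population
#' standard deviation of `cMean` over defined CDS positions. Maximal runs of
#' positions with `cMean > T` are peaks; each peak is scored
#' `(sum(c) / ((e - s) * T) - 1) * 100` and kept when the peak's mean RNA
#' coverage is at least 3 and its per-replicate score exceeds 3 in at least
#' two replicates. The whole procedure is run in both directions
#' (test>control: TC; control>test: CC).
#'
#' @name peak-calling
NULL

#' A per-gene, per-condition coverage bundle
#'
#' @param gene_id gene identifier.
#' @param ribo numeric L x N matrix of per-nucleotide Ribo-seq coverage
#'   (CDS coordinates, one column per replicate).
#' @param rna matching RNA-seq coverage matrix.
#' @return a `coverage_bundle`.
#' @export
coverage_bundle <- function(gene_id, ribo, rna) {
  ribo <- as.matrix(ribo); rna <- as.matrix(rna)
  if (!all(dim(ribo) == dim(rna)))
    stop("ribo and rna coverage differ in shape for gene ", gene_id)
  if (any(ribo < 0) || any(rna < 0)) stop("negative coverage")
  structure(list(gene_id = gene_id, ribo = ribo, rna = rna,
                 L = nrow(ribo), N = ncol(ribo)),
            class = "coverage_bundle")
}

#' RNA-normalized Ribo coverage per replicate, with zero-RNA mask
#'
#' @param bundle a [coverage_bundle()].
#' @return L x N matrix of `ribo / rna`; positions with zero RNA coverage
#'   are `NA` (masked), never infinite.
#' @export
normalize_coverage <- function(bundle) {
  stopifnot(inherits(bundle, "coverage_bundle"))
  out <- bundle$ribo / bundle$rna
  out[bundle$rna == 0] <- NA_real_
  out
}

#' Differential coverage track between two conditions
#'
#' @param test,ctrl [coverage_bundle()]s for the same gene with equal
#'   replicate counts (replicate i is paired with replicate i).
#' @return list of class `diff_track`: `cdiff` (L x N matrix), `cmean`,
#'   `meancov`, `stdmean` (population SD), `threshold`, `defined` (logical
#'   mask), `gene_id`. Positions masked in any replicate of either
#'   condition are masked throughout.
#' @export
diff_track <- function(test, ctrl) {
  stopifnot(inherits(test, "coverage_bundle"),
            inherits(ctrl, "coverage_bundle"))
  if (test$L != ctrl$L) stop("test and ctrl coverage lengths differ")
  if (test$N != ctrl$N) stop("unequal replicate counts; provide a pairing")
  cn_t <- normalize_coverage(test)
  cn_c <- normalize_coverage(ctrl)
  cdiff <- cn_t - cn_c
  defined <- rowSums(is.na(cdiff)) == 0L
  cdiff[!defined, ] <- NA_real_
  if (!any(defined))
    return(structure(list(gene_id = test$gene_id, cdiff = cdiff,
                          cmean = rep(NA_real_, test$L), meancov = NA_real_,
                          stdmean = NA_real_, threshold = NA_real_,
                          defined = defined, skipped = "all_positions_masked"),
                     class = "diff_track"))
  cmean <- rowMeans(cdiff)
  vals <- cmean[defined]
  meancov <- mean(vals)
  stdmean <- sqrt(mean((vals - meancov)^2))  # population SD over defined L
  structure(list(gene_id = test$gene_id, cdiff = cdiff, cmean = cmean,
                 meancov = meancov, stdmean = stdmean,
                 threshold = meancov + 3 * stdmean, defined = defined,
                 skipped = NULL),
            class = "diff_track")
}

#' Maximal runs of positions with cMean strictly above the threshold
#'
#' @param track a [diff_track()].
#' @return data.frame with 0-based half-open `start`, `end` per peak;
#'   masked positions break runs.
#' @export
call_peaks <- function(track) {
  stopifnot(inherits(track, "diff_track"))
  if (!is.null(track$skipped))
    return(data.frame(start = integer(0), end = integer(0)))
  above <- !is.na(track$cmean) & track$cmean > track$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Score peaks and apply the coverage and replicate filters
#'
#' The reported score uses `cmean`; the two-replicate rule recomputes the
#' score on each replicate's `cdiff` against the shared threshold. Peaks
#' whose mean RNA coverage over the interval (across all provided RNA
#' replicates) is below `min_rna` are discarded; the rest are kept when the
#' per-replicate score strictly exceeds `min_score` in at least
#' `min_replicates` replicates. A non-positive threshold makes the score
#' undefined; such peaks are kept on the coverage rule alone and flagged.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param track the [diff_track()] the peaks came from.
#' @param rna L x M matrix of RNA coverage columns used for the coverage
#'   rule (typically both conditions' replicates, column-bound).
#' @param min_rna,min_score,min_replicates filter constants (defaults 3, 3,
#'   2).
#' @param score_rule `"per-replicate"` (default) or `"mean-only"`, which
#'   applies the score rule to the cmean score.
#' @return the peaks with `score_mean`, per-replicate scores,
#'   `rna_mean_coverage`, `kept`, `reason`, `threshold_flag`.
#' @export
score_and_filter <- function(peaks, track, rna, min_rna = 3,
                             min_score = 3, min_replicates = 2L,
                             score_rule = c("per-replicate", "mean-only")) {
  score_rule <- match.arg(score_rule)
  n <- nrow(peaks)
  rna <- as.matrix(rna)
  N <- ncol(track$cdiff)
  score_of <- function(vals, s, e, T) {
    v <- vals[(s + 1L):e]
    (sum(v, na.rm = TRUE) / ((e - s) * T) - 1) * 100
  }
  out <- peaks
  out$score_mean <- NA_real_
  rep_scores <- matrix(NA_real_, n, N,
                       dimnames = list(NULL, paste0("score_rep", seq_len(N))))
  out$rna_mean_coverage <- NA_real_
  out$kept <- logical(n)
  out$reason <- character(n)
  out$threshold_flag <- FALSE
  T <- track$threshold
  for (i in seq_len(n)) {
    s <- peaks$start[i]; e <- peaks$end[i]
    if (e <= s) stop("invalid peak interval [", s, ", ", e, ")")
    out$rna_mean_coverage[i] <- mean(rna[(s + 1L):e, , drop = FALSE])
    if (!is.na(T) && T > 0) {
      out$score_mean[i] <- score_of(track$cmean, s, e, T)
      rep_scores[i, ] <- vapply(seq_len(N), function(j)
        score_of(track$cdiff[, j], s, e, T), numeric(1L))
    } else {
      out$threshold_flag[i] <- TRUE
    }
    if (out$rna_mean_coverage[i] < min_rna) {
      out$reason[i] <- "rna_coverage_below_min"
    } else if (out$threshold_flag[i]) {
      out$kept[i] <- TRUE
      out$reason[i] <- "kept_threshold_nonpositive"
    } else {
      n_pass <- if (score_rule == "per-replicate")
        sum(rep_scores[i, ] > min_score) else
        as.integer(out$score_mean[i] > min_score) * min_replicates
      if (n_pass >= min_replicates) {
        out$kept[i] <- TRUE
        out$reason[i] <- "kept"
      } else out$reason[i] <- "score_rule_failed"
    }
  }
  cbind(out, rep_scores)
}

#' Full per-gene peak call in one direction
#'
#' @param test,ctrl [coverage_bundle()]s.
#' @param ... passed to [score_and_filter()].
#' @return list: `track`, `peaks` (scored, with `kept`), `kept` subset.
#' @export
call_gene_peaks <- function(test, ctrl, ...) {
  track <- diff_track(test, ctrl)
  raw <- call_peaks(track)
  rna <- cbind(test$rna, ctrl$rna)
  scored <- if (nrow(raw)) score_and_filter(raw, track, rna, ...)
            else cbind(raw, score_mean = numeric(0),
                       rna_mean_coverage = numeric(0), kept = logical(0),
                       reason = character(0), threshold_flag = logical(0))
  list(track = track, peaks = scored,
       kept = scored[scored$kept %in% TRUE, , drop = FALSE])
}

#' Bidirectional peak calling over a set of genes
#'
#' Runs the full procedure test-vs-control (direction `TC`) and with the
#' roles reversed (`CC`) for every gene.
#'
#' @param bundles named list; each element a list with `test` and `ctrl`
#'   [coverage_bundle()]s (as produced by [simulate_ribo_rna_coverage()]).
#' @param ... passed to [score_and_filter()].
#' @return data.frame of all scored peaks across genes with `gene_id` and
#'   `direction` columns.
#' @export
bidirectional_call <- function(bundles, ...) {
  rows <- list()
  for (g in names(bundles)) {
    b <- bundles[[g]]
    for (dir in c("TC", "CC")) {
      res <- if (dir == "TC") call_gene_peaks(b$test, b$ctrl, ...)
             else call_gene_peaks(b$ctrl, b$test, ...)
      if (nrow(res$peaks)) {
        pk <- res$peaks
        pk$gene_id <- g
        pk$direction <- dir
        rows[[length(rows) + 1L]] <- pk
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      score_mean = numeric(0), rna_mean_coverage = numeric(0),
                      kept = logical(0), reason = character(0),
                      threshold_flag = logical(0), gene_id = character(0),
                      direction = character(0)))
  lead <- c("gene_id", "direction", "start", "end", "score_mean",
            "rna_mean_coverage", "kept", "reason", "threshold_flag")
  out <- do.call(rbind, lapply(rows, function(d)
    d[, c(lead, grep("^score_rep", names(d), value = TRUE))]))
  rownames(out) <- NULL
  out
}

#' Write kept peaks as BED6
#'
#' @param peaks output of [bidirectional_call()] (kept rows are written).
#' @param path output BED path; name = gene:direction, score = score_mean.
#' @export
write_peaks_bed <- function(peaks, path) {
  kept <- peaks[peaks$kept %in% TRUE, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t%.4g\t+", kept$gene_id, kept$start,
                   kept$end, kept$gene_id, kept$direction,
                   ifelse(is.na(kept$score_mean), 0, kept$score_mean))
  writeLines(lines, path)
  invisible(path)
}
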
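#' Empirical amino-acid enrichment of protein lists
#'
#' A labeled protein list (e.g. a GO term with its descendants, or a
#' curated keyword) is compared against 10 000 size-matched control sets
#' sampled from the proteome. Per amino acid, the list's mean frequency sits
#' somewhere in the control distribution: with `k` controls at or above and
#' `l` at or below it, `P_emp = (min(k, l) + 1) / (n_controls + 1)`,
#' BH-adjusted within the list, and transformed for display as
#' `T = 1 - P_adj * s` with `s = +1` if `k > l`, else `-1` (so depleted
#' amino acids land above 1, enriched ones below).
#'
#' @name enrichment
NULL

# minimal OBO parser: term ids plus is_a / part_of edges
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
  }
  in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { flush(); cur <- list(parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || is.null(cur)) next
    if (startsWith(ln, "id: ")) cur$id <- sub("^id: ", "", ln)
    else if (startsWith(ln, "is_a: "))
      cur$parents <- c(cur$parents, sub("^is_a: (\\S+).*", "\\1", ln))
    else if (startsWith(ln, "relationship: part_of "))
      cur$parents <- c(cur$parents,
                       sub("^relationship: part_of (\\S+).*", "\\1", ln))
    else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
  }
  flush()
  terms
}

# all descendants of a root (inclusive) through is_a/part_of edges
obo_descendants <- function(terms, root) {
  if (!root %in% names(terms)) stop("unknown term id: ", root)
  children <- split(
    rep(names(terms), vapply(terms, function(t) length(t$parents), integer(1L))),
    unlist(lapply(terms, `[[`, "parents")))
  seen <- character(0)
  queue <- root
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, children[[t]])
  }
  seen
}

#' Collect proteins annotated to GO root terms or their descendants
#'
#' Descendants are reached through `is_a` and `part_of` edges. Association
#' lines with a `NOT` qualifier are excluded; only the accepted qualifiers
#' are kept.
#'
#' @param gaf_file GO association file (GAF 2.x: tab-separated, `!`
#'   comments; column 2 = protein id, 4 = qualifier, 5 = GO id).
#' @param obo_file ontology OBO file.
#' @param root_terms character vector of GO ids.
#' @param qualifiers accepted association qualifiers.
#' @return list of `ProteinList`s (one per root term): `list_id`,
#'   `proteins`, `provenance`.
#' @export
collect_go_proteins <- function(gaf_file, obo_file, root_terms,
                                qualifiers = c("involved_in", "located_in",
                                               "is_active_in", "part_of")) {
  terms <- parse_obo(obo_file)
  gaf <- utils::read.delim(gaf_file, header = FALSE, comment.char = "!",
                           stringsAsFactors = FALSE)
  prot <- gaf[[2L]]
  qual <- gaf[[4L]]
  go <- gaf[[5L]]
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual) & qual %in% qualifiers
  lapply(root_terms, function(root) {
    fam <- obo_descendants(terms, root)
    ids <- sort(unique(prot[keep & go %in% fam]))
    structure(list(list_id = root, proteins = ids, provenance = "GO"),
              class = "protein_list")
  })
}

# per-protein amino-acid frequency matrix (proteins x 20), stop excluded
proteome_aa_freq <- function(proteome) {
  aa20 <- names(KYTE_DOOLITTLE)
  seqs <- stats::setNames(as.character(proteome), names(proteome))
  mat <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    ch <- ch[ch %in% aa20]
    tabulate(match(ch, aa20), nbins = 20L) / length(ch)
  }, numeric(20L)))
  colnames(mat) <- aa20
  rownames(mat) <- names(seqs)
  mat
}

#' Empirical amino-acid enrichment of a protein list
#'
#' @param proteins character vector of protein ids in the list.
#' @param proteome named `AAStringSet` (or named character vector) of the
#'   whole proteome; list ids must resolve into it.
#' @param n_controls number of size-matched control sets (default 10000),
#'   each drawn without replacement from the proteome.
#' @param seed integer seed.
#' @return data.frame per amino acid: mean_obs, k, l, p_emp, p_adj, sign,
#'   t_signed.
#' @export
empirical_aa_enrichment <- function(proteins, proteome,
                                    n_controls = 10000L, seed = 1L) {
  freq <- proteome_aa_freq(proteome)
  if (!all(proteins %in% rownames(freq)))
    stop("protein ids missing from the proteome: ",
         paste(utils::head(setdiff(proteins, rownames(freq))), collapse = ", "))
  m <- length(proteins)
  if (m >= nrow(freq)) stop("list is not smaller than the proteome")
  obs <- colMeans(freq[proteins, , drop = FALSE])
  set.seed(seed)
  ctrl <- matrix(0, n_controls, 20L)
  for (i in seq_len(n_controls)) {
    ctrl[i, ] <- colMeans(freq[sample.int(nrow(freq), m), , drop = FALSE])
  }
  k <- colSums(ctrl >= matrix(obs, n_controls, 20L, byrow = TRUE))
  low <- colSums(ctrl <= matrix(obs, n_controls, 20L, byrow = TRUE))
  p_emp <- empirical_p(k, low, n_controls)
  p_adj <- stats::p.adjust(p_emp, "BH")
  s <- ifelse(k > low, 1L, -1L)
  data.frame(aa = colnames(freq), mean_obs = obs, k = k, l = low,
             n_controls = n_controls, p_emp = p_emp, p_adj = p_adj,
             sign = s, t_signed = signed_heatmap_transform(p_adj, k, low),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pseudocount empirical p-value
#'
#' @param k controls at or above the observed statistic.
#' @param l controls at or below it.
#' @param n_controls number of control sets.
#' @return `(min(k, l) + 1) / (n_controls + 1)`.
#' @export
empirical_p <- function(k, l, n_controls) {
  (pmin(k, l) + 1) / (n_controls + 1)
}

#' Signed transform of adjusted empirical p-values for heatmap display
#'
#' @param p_adj BH-adjusted empirical p-value.
#' @param k,l control counts (see [empirical_p()]); ties (`k == l`) take
#'   the `s = -1` branch.
#' @return `1 - p_adj * s` with `s = +1` when `k > l`, else `-1`.
#' @export
signed_heatmap_transform <- function(p_adj, k, l) {
  s <- ifelse(k > l, 1, -1)
  1 - p_adj * s
}
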
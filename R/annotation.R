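#' Gene models: filtered, frame-consistent concatenated CDS per gene
#'
#' A `GeneModel` is the coordinate backbone of every downstream stage: one
#' retained mRNA per gene, its CDS segments concatenated 5'->3' in
#' transcription order, and the resulting codon array. Coordinates are
#' 0-based half-open internally; GTF/GFF input (1-based closed) is converted
#' at the boundary.
#'
#' @name gene-models
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

new_gene_model <- function(gene_id, chrom, strand, cds_segments, cds_seq) {
  length_nt <- nchar(cds_seq)
  stopifnot(length_nt %% 3L == 0L,
            length_nt == sum(cds_segments[, 2L] - cds_segments[, 1L]))
  codons <- substring(cds_seq, seq(1L, length_nt, by = 3L),
                      seq(3L, length_nt, by = 3L))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds_segments = cds_segments, cds_seq = cds_seq,
                 codons = codons, length_nt = length_nt),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%s  %d nt (%d codons), %d CDS segment(s)\n",
              x$gene_id, x$chrom, x$strand, x$length_nt,
              length(x$codons), nrow(x$cds_segments)))
  invisible(x)
}

# Extract, strand-resolve and concatenate CDS segments given 0-based
# half-open genomic intervals sorted in transcription order.
concat_cds_seq <- function(chrom_seq, segments, strand) {
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    s <- Biostrings::subseq(chrom_seq, start = segments[i, 1L] + 1L,
                            end = segments[i, 2L])
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1L))
  paste(parts, collapse = "")
}

#' Load, filter and index gene models from a GTF/GFF3 annotation
#'
#' Builds one concatenated-CDS mRNA per gene and applies the retention
#' filters: a gene must have at least one CDS, begin with a start codon
#' (ATG), end with a stop codon, have total CDS length divisible by 3, carry
#' no internal stop codon, have a consistent reading frame across its CDS
#' segments, and not overlap another gene's CDS on the same strand ("merged"
#' genes are dropped pairwise). When a gene has several transcripts, the
#' union of their CDS is used if it is frame-consistent; otherwise the
#' longest frame-consistent transcript is taken.
#'
#' @param annotation_file path to a GTF or GFF3 file with CDS features.
#' @param genome path to the genome FASTA the annotation refers to.
#' @param check_phase if `TRUE` (default), a `phase`/frame attribute that
#'   contradicts the cumulative CDS length drops the gene as
#'   frame-ambiguous.
#' @return a list of class `gene_model_set`: `models` (named list of
#'   `gene_model`), and `report` (a data.frame counting genes dropped per
#'   rule).
#' @export
load_gene_models <- function(annotation_file, genome, check_phase = TRUE) {
  gr <- tryCatch(rtracklayer::import(annotation_file),
                 error = function(e) stop("malformed annotation '",
                                          annotation_file, "': ",
                                          conditionMessage(e), call. = FALSE))
  seqs <- Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(cds) == 0L) stop("annotation contains no CDS features")
  meta <- S4Vectors::mcols(cds)
  gene_id <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
             else as.character(meta$Parent)
  tx_id <- if ("transcript_id" %in% names(meta)) as.character(meta$transcript_id)
           else if ("Parent" %in% names(meta)) as.character(unlist(meta$Parent))
           else gene_id
  if (anyNA(gene_id)) stop("CDS records without a gene identifier")
  phase <- if ("phase" %in% names(meta)) suppressWarnings(as.integer(meta$phase))
           else rep(NA_integer_, length(cds))

  df <- data.frame(
    gene_id = gene_id, tx_id = tx_id,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(BiocGenerics::strand(cds)),
    start = GenomicRanges::start(cds) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(cds),
    phase = phase, stringsAsFactors = FALSE)

  drop <- c(no_cds = 0L, out_of_bounds = 0L, ambiguous_frame = 0L,
            bad_frame_length = 0L, no_start = 0L, no_stop = 0L,
            internal_stop = 0L, merged_overlap = 0L,
            unknown_sequence = 0L)
  models <- list()

  for (g in unique(df$gene_id)) {
    gd <- df[df$gene_id == g, , drop = FALSE]
    if (!all(gd$chrom %in% names(seqs))) {
      drop["unknown_sequence"] <- drop["unknown_sequence"] + 1L
      next
    }
    chrom <- gd$chrom[1L]
    if (any(gd$end > length(seqs[[chrom]]))) {
      warning("gene ", g, " has CDS past end of sequence ", chrom,
              "; dropped", call. = FALSE)
      drop["out_of_bounds"] <- drop["out_of_bounds"] + 1L
      next
    }
    strand <- gd$strand[1L]
    built <- build_gene_cds(gd, strand, check_phase)
    if (is.character(built)) {  # a drop reason
      drop[built] <- drop[built] + 1L
      next
    }
    seq <- concat_cds_seq(seqs[[chrom]], built, strand)
    reason <- check_cds_seq(seq)
    if (!is.null(reason)) { drop[reason] <- drop[reason] + 1L; next }
    models[[g]] <- new_gene_model(g, chrom, strand, built, seq)
  }

  # merged genes: CDS overlapping another gene's CDS on the same strand;
  # both members of an overlapping pair are dropped
  if (length(models) > 1L) {
    seg <- do.call(rbind, lapply(models, function(m)
      data.frame(gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
                 start = m$cds_segments[, 1L], end = m$cds_segments[, 2L])))
    gr_seg <- GenomicRanges::GRanges(seg$chrom,
                                     IRanges::IRanges(seg$start + 1L, seg$end),
                                     strand = seg$strand)
    ov <- GenomicRanges::findOverlaps(gr_seg, drop.self = TRUE)
    hit <- seg$gene_id[S4Vectors::queryHits(ov)] !=
           seg$gene_id[S4Vectors::subjectHits(ov)]
    merged <- unique(seg$gene_id[S4Vectors::queryHits(ov)[hit]])
    drop["merged_overlap"] <- length(merged)
    models[merged] <- NULL
  }

  report <- data.frame(rule = names(drop), dropped = unname(drop))
  structure(list(models = models, report = report), class = "gene_model_set")
}

# Resolve a gene's transcripts to one ordered 0-based half-open segment
# matrix, or return a drop-reason string.
build_gene_cds <- function(gd, strand, check_phase) {
  order_tx <- function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    seg
  }
  frame_ok <- function(seg) {
    lens <- seg$end - seg$start
    if (sum(lens) %% 3L != 0L) return(FALSE)
    if (check_phase && !all(is.na(seg$phase))) {
      expected <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
      obs <- seg$phase
      if (any(!is.na(obs) & obs != expected)) return(FALSE)
    }
    TRUE
  }
  as_mat <- function(seg) cbind(start = seg$start, end = seg$end)

  txs <- split(gd, gd$tx_id)
  txs <- lapply(txs, order_tx)
  # union of CDS across transcripts, if frame-consistent
  union_seg <- unique(gd[, c("start", "end", "phase")])
  ir <- IRanges::reduce(IRanges::IRanges(union_seg$start + 1L, union_seg$end))
  us <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
                   phase = NA_integer_)
  us <- order_tx(us)
  if (length(txs) == 1L) {
    tx <- txs[[1L]]
    if (!frame_ok(tx)) {
      return(if ((sum(tx$end - tx$start) %% 3L) == 0L) "ambiguous_frame"
             else "bad_frame_length")
    }
    return(as_mat(tx))
  }
  if (frame_ok(us)) return(as_mat(us))
  ok <- Filter(frame_ok, txs)
  if (length(ok) == 0L) return("ambiguous_frame")
  lens <- vapply(ok, function(s) sum(s$end - s$start), numeric(1L))
  as_mat(ok[[which.max(lens)]])
}

# NULL when the concatenated sequence is a valid ORF, else a drop reason.
check_cds_seq <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L || n < 6L) return("bad_frame_length")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[1L] != "ATG") return("no_start")
  if (!codons[length(codons)] %in% STOP_CODONS) return("no_stop")
  if (any(codons[-length(codons)] %in% STOP_CODONS)) return("internal_stop")
  NULL
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d retained gene model(s)\n",
              length(x$models)))
  dropped <- x$report[x$report$dropped > 0L, ]
  if (nrow(dropped)) {
    cat("dropped:\n")
    for (i in seq_len(nrow(dropped)))
      cat(sprintf("  %-18s %d\n", dropped$rule[i], dropped$dropped[i]))
  }
  invisible(x)
}

#' Map CDS nucleotide positions to codon ordinals and label codons
#'
#' Positions `3k..3k+2` (0-based) map to codon `k + 1`. Codons that span a
#' CDS-segment junction are flagged `boundary = TRUE` so window analyses can
#' exclude them; the terminal stop codon translates to `"*"`.
#'
#' @param gene a `gene_model`.
#' @return list with `nt_to_codon` (integer vector of length `length_nt`,
#'   1-based codon ordinals) and `codon_table` (data.frame: `ordinal`,
#'   `codon`, `aa`, `boundary`).
#' @export
codon_index <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  if (gene$length_nt %% 3L != 0L)
    stop("gene ", gene$gene_id, " length not divisible by 3")
  n_cod <- gene$length_nt %/% 3L
  nt_to_codon <- rep(seq_len(n_cod), each = 3L)
  aa <- translate_codons(gene$codons)
  seg_lens <- gene$cds_segments[, 2L] - gene$cds_segments[, 1L]
  junctions <- cumsum(seg_lens)
  junctions <- junctions[-length(junctions)]  # internal boundaries, 0-based
  boundary <- rep(FALSE, n_cod)
  if (length(junctions)) {
    # codon k (0-based) spans a junction j iff 3k < j < 3k+3
    k <- unique(junctions[junctions %% 3L != 0L] %/% 3L)
    boundary[k + 1L] <- TRUE
  }
  list(nt_to_codon = nt_to_codon,
       codon_table = data.frame(ordinal = seq_len(n_cod),
                                codon = gene$codons, aa = aa,
                                boundary = boundary,
                                stringsAsFactors = FALSE))
}

#' Translate a codon vector to one-letter amino acids (stop = "*")
#' @param codons character vector of 3-mers.
#' @return character vector of single letters.
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Write retained gene models back to GFF3 and concatenated-CDS FASTA
#'
#' @param set a `gene_model_set` (or plain list of `gene_model`).
#' @param gff3 output GFF3 path (CDS segments, 1-based).
#' @param fasta output FASTA path of concatenated CDS sequences; `NULL` to
#'   skip.
#' @export
write_gene_models <- function(set, gff3, fasta = NULL) {
  models <- if (inherits(set, "gene_model_set")) set$models else set
  rows <- lapply(models, function(m) {
    seg <- m$cds_segments
    lens <- seg[, 2L] - seg[, 1L]
    phase <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
    data.frame(chrom = m$chrom, start = seg[, 1L] + 1L, end = seg[, 2L],
               strand = m$strand, gene_id = m$gene_id, phase = phase,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- paste0("cds-", df$gene_id)
  S4Vectors::mcols(gr)$Parent <- df$gene_id
  rtracklayer::export(gr, gff3, format = "gff3")
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(vapply(models, `[[`, character(1L),
                                          "cds_seq"))
    names(ss) <- vapply(models, `[[`, character(1L), "gene_id")
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(NULL)
}
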
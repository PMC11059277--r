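# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files these helpers write to
# tempdirs.

# Write a toy genome + GTF for single-exon plus-strand ORFs.
# orfs: named character vector of ORF sequences (one contig per gene).
write_toy_genome <- function(orfs, pad = 5L, dir = tempfile("toygenome_")) {
  dir.create(dir)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "genes.gtf")
  fa_lines <- character(0)
  gtf_lines <- character(0)
  for (g in names(orfs)) {
    flank1 <- strrep("C", pad)
    flank2 <- strrep("G", pad)
    fa_lines <- c(fa_lines, paste0(">", g), paste0(flank1, orfs[[g]], flank2))
    gtf_lines <- c(gtf_lines, sprintf(
      "%s\ttoy\tCDS\t%d\t%d\t.\t+\t0\tgene_id \"%s\"; transcript_id \"%s.1\";",
      g, pad + 1L, pad + nchar(orfs[[g]]), g, g))
  }
  writeLines(fa_lines, fa)
  writeLines(gtf_lines, gtf)
  list(fasta = fa, gtf = gtf, dir = dir)
}

# Append raw GTF lines (e.g. multi-exon or minus-strand genes) and contigs.
append_toy_gene <- function(toy, contig_name, contig_seq, gtf_lines) {
  cat(paste0(">", contig_name, "\n", contig_seq, "\n"),
      file = toy$fasta, append = TRUE)
  cat(paste0(paste(gtf_lines, collapse = "\n"), "\n"),
      file = toy$gtf, append = TRUE)
  toy
}

# A random ORF: ATG + n internal sense codons + stop.
random_orf <- function(n_codons, codons = ribopause:::SENSE_CODONS) {
  paste0("ATG", paste(sample(codons, n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

# Coverage bundle with given per-replicate ribo/rna vectors (recycled).
make_bundle <- function(gene_id, ribo, rna, n_rep = 1L) {
  L <- length(ribo)
  coverage_bundle(gene_id,
                  ribo = matrix(rep(ribo, n_rep), nrow = L),
                  rna = matrix(rep(rna, n_rep), nrow = L))
}

# A minimal pileup row builder.
pileup_row <- function(site_id, ref, depth, alt = NULL, alt_n = 0L,
                       qual = 30) {
  cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (!is.null(alt)) cnt[alt] <- as.integer(alt_n)
  cnt[ref] <- as.integer(depth) - sum(cnt)
  data.frame(site_id = site_id, ref = ref, depth = depth,
             A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
             qual = qual, stringsAsFactors = FALSE)
}

# Independent naive peak-calling oracle used by equivalence tests: literal
# transcription of the published formulas with plain loops.
naive_peak_oracle <- function(ribo_t, rna_t, ribo_c, rna_c) {
  L <- nrow(ribo_t); N <- ncol(ribo_t)
  cdiff <- matrix(NA_real_, L, N)
  for (i in seq_len(N)) {
    for (p in seq_len(L)) {
      if (rna_t[p, i] > 0 && rna_c[p, i] > 0)
        cdiff[p, i] <- ribo_t[p, i] / rna_t[p, i] - ribo_c[p, i] / rna_c[p, i]
    }
  }
  defined <- apply(cdiff, 1L, function(r) !any(is.na(r)))
  cmean <- rep(NA_real_, L)
  for (p in seq_len(L)) if (defined[p]) cmean[p] <- mean(cdiff[p, ])
  vals <- cmean[defined]
  meancov <- mean(vals)
  stdmean <- sqrt(sum((vals - meancov)^2) / length(vals))
  T <- meancov + 3 * stdmean
  peaks <- list()
  run_start <- NA
  for (p in seq_len(L)) {
    above <- defined[p] && cmean[p] > T
    if (above && is.na(run_start)) run_start <- p
    if ((!above || p == L) && !is.na(run_start)) {
      run_end <- if (above) p else p - 1L
      peaks[[length(peaks) + 1L]] <- c(run_start - 1L, run_end)  # 0-based
      run_start <- NA
    }
  }
  score <- function(vals, s, e) {
    (sum(vals[(s + 1L):e]) / ((e - s) * T) - 1) * 100
  }
  pk <- if (length(peaks)) do.call(rbind, peaks) else
    matrix(integer(0), 0, 2)
  list(meancov = meancov, stdmean = stdmean, threshold = T,
       peaks = pk,
       scores = if (nrow(pk)) vapply(seq_len(nrow(pk)), function(i)
         score(cmean, pk[i, 1L], pk[i, 2L]), numeric(1L)) else numeric(0))
}
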
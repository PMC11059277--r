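#' Synthetic fixtures with the statistical structure of each pipeline stage
#'
#' The generator writes/returns annotation + sequence (FASTA/GTF), TDD
#' time-course count tables, paired Ribo/RNA per-nucleotide coverage, and
#' nucleotide pileups, each with a truth table of the planted signal. Counts
#' are negative binomial (bulk RNA-seq convention); coverage is Poisson.
#' Library size follows total mRNA abundance, so the compositional effect of
#' transcription inhibition (relative abundance of stable genes rises) is
#' reproduced.
#'
#' @name synthetic-data
NULL

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"), paste0),
                  c("T", "C", "A", "G"), paste0)),
  c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param gene_length_codons integer range (min, max) of internal codons per
#'   gene (excludes the start and stop codon).
#' @param biased_gene_fraction fraction of genes with a planted codon bias.
#' @param bias_codons codons enriched in biased genes.
#' @param bias_multiplier fold-enrichment of `bias_codons` in biased genes;
#'   must keep their total frequency below 1.
#' @param k_base basal decay rate (/h).
#' @param k_tdd extra translation-dependent decay rate (/h) for TDD genes.
#' @param k_tdd_treated `k_tdd` under the treated condition for genes with
#'   treatment-induced TDD.
#' @param tdd_gene_fraction fraction of genes with basal TDD.
#' @param induced_tdd_fraction fraction of genes whose TDD is larger when
#'   treated.
#' @param stable_gene_fraction fraction of near-zero-decay spike genes
#'   recoverable as normalization anchors.
#' @param dispersion negative-binomial dispersion of counts (size = 1/disp).
#' @param lib_size mean library size (reads) per count-table sample.
#' @param pause_intensity multiplicative Ribo coverage elevation at planted
#'   pause codons (treated condition).
#' @param pause_codon codon at which pauses are planted.
#' @param pause_gene_fraction fraction of genes given one planted pause.
#' @param mean_coverage mean per-nucleotide RNA coverage.
#' @param n_replicates replicates per condition for coverage/counts.
#' @param error_rate_control,error_rate_treated per-base transcriptional
#'   mismatch probabilities. Defaults sit in the unsaturated regime at
#'   pileup depths of a few thousand, so site-level SNP proportions track
#'   the underlying rate ratio.
#' @param variant_fraction fraction of pileup sites carrying a genomic
#'   variant (alt fraction ~ 0.5), to be removed by the allele-fraction
#'   filter.
#' @param qual_pass_fraction fraction of pileup sites with QUAL at or above
#'   the default quality threshold.
#' @param depth mean pileup depth.
#' @param seed integer seed; a fixed seed gives identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L,
                       gene_length_codons = c(100L, 300L),
                       biased_gene_fraction = 0.3,
                       bias_codons = c("GAA", "GAT", "AAT", "AAA"),
                       bias_multiplier = 2,
                       k_base = 0.1,
                       k_tdd = 0.2,
                       k_tdd_treated = 0.4,
                       tdd_gene_fraction = 0.3,
                       induced_tdd_fraction = 0.15,
                       stable_gene_fraction = 0.1,
                       dispersion = 0.05,
                       lib_size = 1e6,
                       pause_intensity = 8,
                       pause_codon = "GAA",
                       pause_gene_fraction = 0.5,
                       mean_coverage = 50,
                       n_replicates = 3L,
                       error_rate_control = 1e-4,
                       error_rate_treated = 1.2e-4,
                       variant_fraction = 0.01,
                       qual_pass_fraction = 0.98,
                       depth = 2000,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 0, length(gene_length_codons) == 2L,
            gene_length_codons[1L] >= 2L,
            k_base >= 0, k_tdd >= 0, k_tdd_treated >= 0,
            bias_multiplier >= 1, dispersion >= 0,
            pause_intensity >= 0, mean_coverage > 0, n_replicates >= 1L,
            error_rate_control >= 0, error_rate_treated >= 0)
  for (p in c("biased_gene_fraction", "tdd_gene_fraction",
              "induced_tdd_fraction", "stable_gene_fraction",
              "pause_gene_fraction", "variant_fraction",
              "qual_pass_fraction"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must be in [0, 1]")
  if (bias_multiplier * length(bias_codons) / length(SENSE_CODONS) >= 1)
    stop("infeasible bias: multiplier forces bias-codon frequency >= 1")
  if (depth <= 0) stop("depth must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# exact bias: bias codons get m * p0, the rest rescaled
codon_probs <- function(cfg, biased) {
  p0 <- rep(1 / length(SENSE_CODONS), length(SENSE_CODONS))
  names(p0) <- SENSE_CODONS
  if (!biased) return(p0)
  idx <- SENSE_CODONS %in% cfg$bias_codons
  p <- p0
  p[idx] <- cfg$bias_multiplier * p0[idx]
  p[!idx] <- p0[!idx] * (1 - sum(p[idx])) / (1 - sum(p0[idx]))
  p
}

#' Simulate a transcriptome: FASTA + GTF + truth table of biased genes
#'
#' Every gene is a single-CDS ORF (ATG ... stop, no internal stop) on its
#' own contig, padded by 10 nt of random flank on each side so CDS
#' coordinates are non-trivial. Biased genes draw their internal codons from
#' a distribution in which `bias_codons` are exactly
#' `bias_multiplier`-fold enriched.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, `genome.fa` and
#'   `annotation.gtf` and `truth_genes.tsv` are written there.
#' @return list: `seqs` (named character, contig sequences), `gtf`
#'   (data.frame of CDS features, 1-based), `truth` (data.frame gene_id,
#'   biased, length_codons), and file paths when `dir` is given.
#' @export
simulate_transcriptome <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  empty <- list(seqs = setNames(character(0), character(0)),
                gtf = data.frame(), truth = data.frame(gene_id = character(0),
                                                       biased = logical(0)))
  if (n == 0L) {
    if (!is.null(dir)) empty <- write_transcriptome(empty, dir)
    return(empty)
  }
  ids <- sprintf("gene%04d", seq_len(n))
  biased <- seq_len(n) <= round(cfg$biased_gene_fraction * n)
  biased <- sample(biased)  # decouple label from id order
  len_cod <- sample(seq(cfg$gene_length_codons[1L],
                        cfg$gene_length_codons[2L]), n, replace = TRUE)
  pb <- codon_probs(cfg, TRUE)
  p0 <- codon_probs(cfg, FALSE)
  pad <- 10L
  seqs <- character(n)
  gtf <- vector("list", n)
  for (i in seq_len(n)) {
    internal <- sample(SENSE_CODONS, len_cod[i], replace = TRUE,
                       prob = if (biased[i]) pb else p0)
    orf <- paste0("ATG", paste(internal, collapse = ""),
                  sample(STOP_CODONS, 1L))
    flank1 <- paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), pad, TRUE), collapse = "")
    seqs[i] <- paste0(flank1, orf, flank2)
    gtf[[i]] <- data.frame(chrom = ids[i], source = "sim", type = "CDS",
                           start = pad + 1L, end = pad + nchar(orf),
                           score = ".", strand = "+", frame = 0L,
                           gene_id = ids[i], transcript_id = paste0(ids[i], ".1"),
                           stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  out <- list(seqs = seqs, gtf = do.call(rbind, gtf),
              truth = data.frame(gene_id = ids, biased = biased,
                                 length_codons = len_cod,
                                 stringsAsFactors = FALSE))
  if (!is.null(dir)) out <- write_transcriptome(out, dir)
  out
}

write_transcriptome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  truth <- file.path(dir, "truth_genes.tsv")
  ss <- Biostrings::DNAStringSet(sim$seqs)
  Biostrings::writeXStringSet(ss, fa)
  if (nrow(sim$gtf)) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     sim$gtf$gene_id, sim$gtf$transcript_id)
    lines <- paste(sim$gtf$chrom, sim$gtf$source, sim$gtf$type,
                   sim$gtf$start, sim$gtf$end, sim$gtf$score,
                   sim$gtf$strand, sim$gtf$frame, attrs, sep = "\t")
    writeLines(lines, gtf)
  } else writeLines(character(0), gtf)
  utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(sim, list(fasta_path = fa, gtf_path = gtf, truth_path = truth))
}

#' Default TDD time-course design
#'
#' Two conditions (CTRL, TRT), an initial sample (t = 0, no inhibitor) and
#' transcription-inhibitor (Tci) and transcription+translation-inhibitor
#' (Tci+Tli) regimes at 3 and 5 h, for `n_replicates` replicates.
#'
#' @param n_replicates replicates per condition.
#' @param times post-treatment sampling times in hours.
#' @return a sample sheet data.frame: sample, condition, regime, time_h,
#'   replicate.
#' @export
tdd_design <- function(n_replicates = 3L, times = c(3, 5)) {
  rows <- expand.grid(condition = c("CTRL", "TRT"),
                      replicate = seq_len(n_replicates),
                      regime = c("Tci", "Tci+Tli"), time_h = times,
                      stringsAsFactors = FALSE)
  init <- expand.grid(condition = c("CTRL", "TRT"),
                      replicate = seq_len(n_replicates),
                      regime = "none", time_h = 0,
                      stringsAsFactors = FALSE)
  d <- rbind(init, rows)
  d$sample <- sprintf("%s_%s_t%g_r%d", d$condition,
                      gsub("[+]", "", d$regime), d$time_h, d$replicate)
  d[, c("sample", "condition", "regime", "time_h", "replicate")]
}

#' Simulate the TDD time-course count table
#'
#' Expected abundance decays as
#' `A(t) = A0 * exp(-(k_base + k_tdd * active) * t)` where translation is
#' active unless the regime includes the translation inhibitor. Counts are
#' NB around library-size-scaled relative abundances; the per-sample library
#' is fixed, so CPM follows the compositional mixture (stable genes rise as
#' bulk mRNA decays).
#'
#' @param cfg a [sim_config()].
#' @param genes data.frame with `gene_id` (e.g. the transcriptome truth
#'   table), or an integer number of genes.
#' @param design a sample sheet as from [tdd_design()]; must contain t = 0.
#' @param noise `"nb"` (default) or `"none"` for the noiseless expected
#'   counts (non-integer), used to verify closed-form recovery.
#' @return list: `counts` (genes x samples matrix), `design`, `truth`
#'   (gene_id, k_base, k_tdd_ctrl, k_tdd_trt, stable, A0).
#' @export
simulate_tdd_counts <- function(cfg, genes = cfg$n_genes,
                                design = tdd_design(cfg$n_replicates),
                                noise = c("nb", "none")) {
  stopifnot(inherits(cfg, "sim_config"))
  noise <- match.arg(noise)
  if (!any(design$time_h == 0))
    stop("design lacks a t = 0 initial sample; TDD index undefined without R0")
  set.seed(cfg$seed + 1L)
  ids <- if (is.data.frame(genes)) genes$gene_id
         else sprintf("gene%04d", seq_len(genes))
  n <- length(ids)
  n_stable <- round(cfg$stable_gene_fraction * n)
  n_tdd <- round(cfg$tdd_gene_fraction * n)
  n_ind <- round(cfg$induced_tdd_fraction * n)
  role <- rep("plain", n)
  role[seq_len(n_stable)] <- "stable"
  role[n_stable + seq_len(n_tdd)] <- "tdd"
  role[n_stable + n_tdd + seq_len(n_ind)] <- "induced"
  role <- sample(role)
  k_base <- ifelse(role == "stable", 0, cfg$k_base)
  k_tdd_ctrl <- ifelse(role %in% c("tdd", "induced"), cfg$k_tdd, 0)
  k_tdd_trt <- ifelse(role == "induced", cfg$k_tdd_treated, k_tdd_ctrl)
  A0 <- exp(stats::rnorm(n, mean = log(100), sd = 1))
  A0[role == "stable"] <- pmax(A0[role == "stable"], 50)

  counts <- matrix(0, n, nrow(design),
                   dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    active <- design$regime[j] != "Tci+Tli"
    k_tdd <- if (design$condition[j] == "TRT") k_tdd_trt else k_tdd_ctrl
    A <- A0 * exp(-(k_base + k_tdd * active) * design$time_h[j])
    mu <- cfg$lib_size * A / sum(A)
    counts[, j] <- if (noise == "none") mu
                   else stats::rnbinom(n, mu = mu, size = 1 / max(cfg$dispersion, 1e-8))
  }
  list(counts = counts, design = design,
       truth = data.frame(gene_id = ids, role = role, k_base = k_base,
                          k_tdd_ctrl = k_tdd_ctrl, k_tdd_trt = k_tdd_trt,
                          stable = role == "stable", A0 = A0,
                          stringsAsFactors = FALSE))
}

#' Simulate paired Ribo/RNA coverage with planted pause sites
#'
#' RNA coverage is flat Poisson per gene; Ribo coverage matches it except at
#' one planted pause codon per designated gene, where the treated-condition
#' Ribo rate is multiplied by `pause_intensity` over the codon's
#' `footprint_nt` nucleotides.
#'
#' @param cfg a [sim_config()].
#' @param transcriptome output of [simulate_transcriptome()] (codon content
#'   is needed to locate `pause_codon` occurrences); pause genes lacking the
#'   codon are skipped with a warning.
#' @param footprint_nt width of the elevated window, default one codon.
#' @return list: `bundles` — per gene a list with `test`/`ctrl`
#'   [coverage_bundle()]s — and `truth` (gene_id, codon_ordinal, start_nt,
#'   end_nt of each planted pause, 0-based half-open CDS coords).
#' @export
simulate_ribo_rna_coverage <- function(cfg, transcriptome,
                                       footprint_nt = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  ids <- transcriptome$truth$gene_id
  n <- length(ids)
  n_pause <- round(cfg$pause_gene_fraction * n)
  pause_gene <- sample(ids, n_pause)
  truth <- list()
  bundles <- vector("list", n)
  names(bundles) <- ids
  pad <- 10L
  for (g in ids) {
    seq_full <- transcriptome$seqs[[g]]
    orf_len <- nchar(seq_full) - 2L * pad
    L <- orf_len
    cod <- substring(substr(seq_full, pad + 1L, pad + orf_len),
                     seq(1L, L, 3L), seq(3L, L, 3L))
    rate_rna <- rep(cfg$mean_coverage, L)
    rate_ribo_test <- rate_rna
    rate_ribo_ctrl <- rate_rna
    if (g %in% pause_gene) {
      hits <- which(cod == cfg$pause_codon)
      hits <- hits[hits > 1L & hits < length(cod)]  # not start/stop-adjacent ends
      if (!length(hits)) {
        warning("pause codon ", cfg$pause_codon, " absent from gene ", g,
                "; skipped in truth table", call. = FALSE)
      } else {
        k <- hits[sample.int(length(hits), 1L)]
        s <- (k - 1L) * 3L            # 0-based start of codon
        w <- seq(s + 1L, min(L, s + footprint_nt))
        rate_ribo_test[w] <- rate_ribo_test[w] * cfg$pause_intensity
        truth[[g]] <- data.frame(gene_id = g, codon_ordinal = k,
                                 start_nt = s, end_nt = s + footprint_nt,
                                 stringsAsFactors = FALSE)
      }
    }
    draw <- function(rate) matrix(stats::rpois(L * cfg$n_replicates,
                                               rep(rate, cfg$n_replicates)),
                                  nrow = L)
    bundles[[g]] <- list(
      test = coverage_bundle(g, ribo = draw(rate_ribo_test),
                             rna = draw(rate_rna)),
      ctrl = coverage_bundle(g, ribo = draw(rate_ribo_ctrl),
                             rna = draw(rate_rna)))
  }
  list(bundles = bundles,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(gene_id = character(0),
                               codon_ordinal = integer(0),
                               start_nt = integer(0), end_nt = integer(0)))
}

#' Simulate per-condition nucleotide pileup tables
#'
#' Each site takes its REF base from the gene sequence; mismatch reads are
#' binomial at the condition's error rate, spread uniformly over the three
#' non-REF bases. A `variant_fraction` of sites carries a genomic variant
#' (alt fraction ~ 0.5) that the allele-fraction filter must remove, and a
#' `1 - qual_pass_fraction` share of sites gets QUAL below 10.
#'
#' @param cfg a [sim_config()].
#' @param transcriptome output of [simulate_transcriptome()]; sites are
#'   sampled from its CDS sequence, recycled if `n_sites` exceeds it.
#' @param n_sites sites per condition table.
#' @return list: `pileups` — named list (`ctrl`, `trt`) of data.frames with
#'   site_id, ref, depth, A, C, G, T, qual — and `truth` (site_id,
#'   is_variant).
#' @export
simulate_pileup <- function(cfg, transcriptome, n_sites = 5000L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$depth <= 0) stop("depth must be > 0")
  set.seed(cfg$seed + 3L)
  bases <- c("A", "C", "G", "T")
  pool <- unlist(strsplit(paste(transcriptome$seqs, collapse = ""), ""))
  pool <- pool[pool %in% bases]
  ref <- sample(pool, n_sites, replace = n_sites > length(pool))
  is_variant <- stats::runif(n_sites) < cfg$variant_fraction
  qual_low <- stats::runif(n_sites) > cfg$qual_pass_fraction
  qual <- ifelse(qual_low, stats::runif(n_sites, 0, 9.99),
                 stats::runif(n_sites, 10, 60))
  site_id <- sprintf("site%06d", seq_len(n_sites))

  one_condition <- function(err) {
    depth <- stats::rpois(n_sites, cfg$depth)
    n_err <- stats::rbinom(n_sites, depth, err)
    # variant sites: one fixed alt at ~50% allele fraction
    n_var <- ifelse(is_variant,
                    stats::rbinom(n_sites, pmax(depth - n_err, 0L), 0.5), 0L)
    # the three non-ref bases per site, and one variant alt among them
    alt_lookup <- t(vapply(bases, function(r) setdiff(bases, r),
                           character(3L)))
    alt_bases <- alt_lookup[match(ref, bases), , drop = FALSE]
    var_alt <- alt_bases[cbind(seq_len(n_sites),
                               sample.int(3L, n_sites, replace = TRUE))]
    # exact multinomial split of errors over the three non-ref bases
    a1 <- stats::rbinom(n_sites, n_err, 1 / 3)
    a2 <- stats::rbinom(n_sites, n_err - a1, 1 / 2)
    a3 <- n_err - a1 - a2
    cnt <- matrix(0L, n_sites, 4L, dimnames = list(NULL, bases))
    idx <- cbind(seq_len(n_sites), match(alt_bases[, 1L], bases))
    cnt[idx] <- a1
    cnt[cbind(seq_len(n_sites), match(alt_bases[, 2L], bases))] <- a2
    cnt[cbind(seq_len(n_sites), match(alt_bases[, 3L], bases))] <- a3
    vsel <- which(n_var > 0L)
    vidx <- cbind(vsel, match(var_alt[vsel], bases))
    cnt[vidx] <- cnt[vidx] + n_var[vsel]
    cnt[cbind(seq_len(n_sites), match(ref, bases))] <- depth - n_err - n_var
    data.frame(site_id = site_id, ref = ref, depth = depth,
               A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"],
               T = cnt[, "T"], qual = qual, stringsAsFactors = FALSE)
  }
  list(pileups = list(ctrl = one_condition(cfg$error_rate_control),
                      trt = one_condition(cfg$error_rate_treated)),
       truth = data.frame(site_id = site_id, is_variant = is_variant,
                          stringsAsFactors = FALSE))
}
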
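#' End-to-end pipeline orchestration
#'
#' One configuration (JSON file or R list) drives simulate -> annotate ->
#' tdd -> peaks -> composition -> enrichment -> mutations -> report. Every
#' stage writes its result tables plus a manifest (inputs, parameters,
#' seed, output md5 hashes) so reruns are checkable; per-stage seeds are
#' derived deterministically from the global seed.
#'
#' @name pipeline
NULL

PIPELINE_STAGES <- c("simulate", "annotate", "tdd", "peaks", "composition",
                     "enrichment", "mutations", "report")

#' Build / validate a pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed global integer seed.
#' @param sim named list of [sim_config()] overrides.
#' @param tdd named list: alpha, stable_mode, stable_times.
#' @param peaks named list: min_rna, min_score, min_replicates.
#' @param composition named list: n_controls.
#' @param enrichment named list: n_controls.
#' @param mutations named list: min_qual, min_depth, max_alt_frac.
#' @param n_pileup_sites pileup sites per condition.
#' @return validated `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("ribopause_run_"), seed = 1L,
                       sim = list(), tdd = list(), peaks = list(),
                       composition = list(), enrichment = list(),
                       mutations = list(), n_pileup_sites = 2000L) {
  defaults <- list(
    tdd = list(alpha = 0.05, stable_mode = "literal", stable_times = "both"),
    peaks = list(min_rna = 3, min_score = 3, min_replicates = 2L),
    composition = list(n_controls = 10000L),
    enrichment = list(n_controls = 10000L),
    mutations = list(min_qual = 10, min_depth = 700, max_alt_frac = 0.05))
  merge1 <- function(d, o) { d[names(o)] <- o; d }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              tdd = merge1(defaults$tdd, tdd),
              peaks = merge1(defaults$peaks, peaks),
              composition = merge1(defaults$composition, composition),
              enrichment = merge1(defaults$enrichment, enrichment),
              mutations = merge1(defaults$mutations, mutations),
              n_pileup_sites = as.integer(n_pileup_sites))
  bad <- character(0)
  if (!is.finite(cfg$seed)) bad <- c(bad, "seed")
  if (!is.character(cfg$out_dir)) bad <- c(bad, "out_dir")
  if (cfg$tdd$alpha <= 0 || cfg$tdd$alpha >= 1) bad <- c(bad, "tdd$alpha")
  if (length(bad)) stop("invalid config field(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

stage_seed <- function(cfg, stage) {
  # deterministic per-stage sub-seed, kept within 32-bit integer range
  i <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(cfg$seed) * 97L + i * 1009L) %% 2147483647)
}

write_manifest <- function(cfg, stage, params, outputs) {
  manifest <- list(stage = stage, seed = stage_seed(cfg, stage),
                   params = params,
                   outputs = as.list(tools::md5sum(unlist(outputs))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(cfg$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the pipeline
#'
#' Stages run in dependency order; asking for a stage whose upstream
#' outputs are absent (and not scheduled) is a dependency error. All
#' intermediate state is returned invisibly and written under
#' `cfg$out_dir`.
#'
#' @param cfg a [run_config()] or path to a JSON config.
#' @param stages ordered subset of
#'   simulate/annotate/tdd/peaks/composition/enrichment/mutations/report.
#' @return (invisibly) list of per-stage results and manifest paths.
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(manifests = list())
  need <- function(what, from) {
    if (is.null(state[[what]]))
      stop("stage '", from, "' needs output of an earlier stage ('", what,
           "' missing); schedule it first", call. = FALSE)
    state[[what]]
  }
  for (stage in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    if (stage == "simulate") {
      sim_args <- c(cfg$sim, list(seed = stage_seed(cfg, stage)))
      scfg <- do.call(sim_config, sim_args)
      state$sim_cfg <- scfg
      state$transcriptome <- simulate_transcriptome(scfg, dir = cfg$out_dir)
      state$tdd_sim <- simulate_tdd_counts(scfg, state$transcriptome$truth)
      state$coverage <- simulate_ribo_rna_coverage(scfg, state$transcriptome)
      state$pileup <- simulate_pileup(scfg, state$transcriptome,
                                      n_sites = cfg$n_pileup_sites)
      counts_path <- file.path(cfg$out_dir, "tdd_counts.tsv")
      utils::write.table(state$tdd_sim$counts, counts_path, sep = "\t",
                         quote = FALSE, col.names = NA)
      state$manifests$simulate <- write_manifest(
        cfg, stage, unclass(scfg)[setdiff(names(scfg), "bias_codons")],
        list(counts = counts_path, fasta = state$transcriptome$fasta_path,
             gtf = state$transcriptome$gtf_path))
    } else if (stage == "annotate") {
      tr <- need("transcriptome", stage)
      state$models <- load_gene_models(tr$gtf_path, tr$fasta_path)
      gff <- file.path(cfg$out_dir, "gene_models.gff3")
      write_gene_models(state$models, gff,
                        file.path(cfg$out_dir, "cds.fa"))
      state$manifests$annotate <- write_manifest(
        cfg, stage, list(n_retained = length(state$models$models)),
        list(gff = gff))
    } else if (stage == "tdd") {
      ts <- need("tdd_sim", stage)
      tab <- tdd_index_table(ts$counts, ts$design,
                             mode = cfg$tdd$stable_mode,
                             times = cfg$tdd$stable_times)
      res <- test_tdd_shift(tab$indices, alpha = cfg$tdd$alpha)
      state$tdd_result <- list(table = tab, shifts = res)
      path <- file.path(cfg$out_dir, "tdd_results.tsv")
      utils::write.table(res, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      stable_path <- file.path(cfg$out_dir, "stable_genes.tsv")
      utils::write.table(data.frame(gene_id = tab$stable_genes), stable_path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      state$manifests$tdd <- write_manifest(cfg, stage, cfg$tdd,
                                            list(results = path,
                                                 stable = stable_path))
    } else if (stage == "peaks") {
      cov <- need("coverage", stage)
      pk <- bidirectional_call(cov$bundles,
                               min_rna = cfg$peaks$min_rna,
                               min_score = cfg$peaks$min_score,
                               min_replicates = cfg$peaks$min_replicates)
      state$peaks <- pk
      tsv <- file.path(cfg$out_dir, "peaks.tsv")
      utils::write.table(pk, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
      bed <- file.path(cfg$out_dir, "peaks_kept.bed")
      write_peaks_bed(pk, bed)
      state$manifests$peaks <- write_manifest(cfg, stage, cfg$peaks,
                                              list(tsv = tsv, bed = bed))
    } else if (stage == "composition") {
      pk <- need("peaks", stage)
      models <- need("models", stage)
      kept <- pk[pk$kept & pk$direction == "TC", , drop = FALSE]
      state$composition <- NULL
      if (nrow(kept)) {
        units <- peak_codons(kept, models)
        units <- units[lengths(units) > 0L]
        state$composition <- peak_randomization_test(
          units, models, family = "codon",
          n_controls = cfg$composition$n_controls,
          seed = stage_seed(cfg, stage))
        path <- file.path(cfg$out_dir, "composition_codon.tsv")
        utils::write.table(state$composition, path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        state$manifests$composition <- write_manifest(
          cfg, stage, cfg$composition, list(codon = path))
      }
    } else if (stage == "enrichment") {
      models <- need("models", stage)
      tr <- need("transcriptome", stage)
      proteome <- vapply(models$models, function(m)
        paste(translate_codons(m$codons), collapse = ""), character(1L))
      biased <- tr$truth$gene_id[tr$truth$biased]
      biased <- intersect(biased, names(proteome))
      state$enrichment <- NULL
      if (length(biased) >= 2L && length(biased) < length(proteome)) {
        state$enrichment <- empirical_aa_enrichment(
          biased, proteome, n_controls = cfg$enrichment$n_controls,
          seed = stage_seed(cfg, stage))
        path <- file.path(cfg$out_dir, "enrichment_aa.tsv")
        utils::write.table(state$enrichment, path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        state$manifests$enrichment <- write_manifest(
          cfg, stage, cfg$enrichment, list(aa = path))
      }
    } else if (stage == "mutations") {
      pu <- need("pileup", stage)
      thin <- subsample_depth(pu$pileups, seed = stage_seed(cfg, stage))
      elig <- lapply(thin, filter_sites,
                     min_qual = cfg$mutations$min_qual,
                     min_depth = cfg$mutations$min_depth,
                     max_alt_frac = cfg$mutations$max_alt_frac)
      cmp <- compare_conditions(elig$trt, elig$ctrl)
      state$mutations <- list(eligible = elig, comparison = cmp)
      path <- file.path(cfg$out_dir, "mutation_rates.tsv")
      utils::write.table(cmp, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      state$manifests$mutations <- write_manifest(cfg, stage,
                                                  cfg$mutations,
                                                  list(rates = path))
    } else if (stage == "report") {
      path <- file.path(cfg$out_dir, "report.md")
      writeLines(render_report(state), path)
      state$manifests$report <- write_manifest(cfg, stage, list(),
                                               list(report = path))
    }
  }
  invisible(state)
}

render_report <- function(state) {
  lines <- c("# ribopause pipeline report", "")
  if (!is.null(state$tdd_result)) {
    cls <- table(state$tdd_result$shifts$class)
    lines <- c(lines, "## TDD classes",
               sprintf("- %s: %d", names(cls), as.integer(cls)), "")
  } else lines <- c(lines, "## TDD classes", "- no findings", "")
  if (!is.null(state$peaks) && nrow(state$peaks)) {
    kept <- state$peaks[state$peaks$kept, ]
    cnt <- table(factor(kept$direction, levels = c("TC", "CC")))
    lines <- c(lines, "## Kept peaks per direction",
               sprintf("- %s: %d", names(cnt), as.integer(cnt)), "")
  } else lines <- c(lines, "## Kept peaks per direction", "- no findings", "")
  if (!is.null(state$composition)) {
    top <- state$composition[order(state$composition$p_adj,
                                   -state$composition$mean_obs), ]
    # enriched features sit above the controls: k small, sign = -1
    top <- utils::head(top[top$sign < 0 & top$mean_obs > 0, ], 5L)
    lines <- c(lines, "## Top enriched codons in TC peaks",
               if (nrow(top)) sprintf("- %s (p_adj = %.3g)", top$feature,
                                      top$p_adj) else "- no findings", "")
  } else lines <- c(lines, "## Top enriched codons in TC peaks",
                    "- no findings", "")
  if (!is.null(state$mutations)) {
    any_rows <- state$mutations$comparison
    any_rows <- any_rows[any_rows$alt == "*", ]
    lines <- c(lines, "## Mutation relative frequencies (REF>*)",
               sprintf("- %s>*: Refreq = %.1f%% (p = %.3g)", any_rows$ref,
                       any_rows$refreq_pct, any_rows$p_value), "")
  } else lines <- c(lines, "## Mutation relative frequencies (REF>*)",
                    "- no findings", "")
  if (!is.null(state$coverage) && !is.null(state$peaks)) {
    truth <- state$coverage$truth
    if (nrow(truth)) {
      kept <- state$peaks[state$peaks$kept & state$peaks$direction == "TC", ]
      hit <- vapply(seq_len(nrow(truth)), function(i) {
        sel <- kept$gene_id == truth$gene_id[i]
        any(kept$start[sel] < truth$end_nt[i] &
            kept$end[sel] > truth$start_nt[i])
      }, logical(1L))
      lines <- c(lines, "## Planted-pause recovery",
                 sprintf("- %d/%d planted sites overlapped by kept TC peaks (%.1f%%)",
                         sum(hit), nrow(truth), 100 * mean(hit)), "")
    }
  }
  lines
}
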
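# cli_config: pipeline configuration handling and the end-to-end run that
# chains simulate -> demux -> call -> curate -> stats. The exec/amphap454
# script exposes the same stages as shell subcommands.

#' Default pipeline configuration
#'
#' Per-stage tunables with the package defaults; see [sim_config()],
#' [demultiplex()] and [genotype_bin()] for the meaning of each knob.
#'
#' @param seed RNG seed for the whole run.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    sim = list(),
    demux = list(min_len = 150, min_mean_q = 30, trim_cutoff = 0.05),
    call = list(het_threshold = 0.75, min_coverage = 1, min_majority_cov = 10)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or within a stage) are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML file with optional sections `seed`, `sim`,
#'   `demux`, `call`.
#' @return Merged configuration list.
#' @export
load_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  for (stage in c("demux", "call")) {
    bad <- setdiff(names(user[[stage]]), names(base[[stage]]))
    if (length(bad)) stop("unknown ", stage, " key(s): ",
                          paste(bad, collapse = ", "))
    base[[stage]][names(user[[stage]])] <- user[[stage]]
  }
  bad <- setdiff(names(user$sim), names(formals(sim_config)))
  if (length(bad)) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
  base$sim <- user$sim
  if (!is.null(user$seed)) base$seed <- as.integer(user$seed)
  base
}

#' Run the whole pipeline end to end
#'
#' Simulates a library, demultiplexes each population file, genotypes
#' every bin, curates alleles within populations, and writes the summary
#' statistics. All outputs land in `out_dir` together with the resolved
#' configuration; identical configuration and seed give identical outputs.
#'
#' @param config A configuration list from [pipeline_config()] /
#'   [load_pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results (`sim`, `demux`,
#'   `genotypes`, `curated`, `summary`) and `paths` to the artifacts.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  truth <- simulate_genotypes(scfg)
  sim <- simulate_reads(truth, scfg)
  paths <- write_simulated_library(sim, out_dir)
  yaml::write_yaml(list(seed = config$seed, sim = unclass(scfg),
                        demux = config$demux, call = config$call),
                   file.path(out_dir, "resolved_config.yaml"))

  ledgers <- list()
  reports <- list()
  for (p in unique(sim$samples$population)) {
    reads <- read_fastq(file.path(out_dir, sprintf("reads_%s.fastq", p)))
    sheet <- sim$samples[sim$samples$population == p, , drop = FALSE]
    dm <- demultiplex(reads, sheet, sim$loci,
                      min_len = config$demux$min_len,
                      min_mean_q = config$demux$min_mean_q,
                      trim_cutoff = config$demux$trim_cutoff)
    ledgers[[p]] <- dm$assignments
    reports[[p]] <- dm$report
  }
  ledger <- do.call(rbind, ledgers)
  rownames(ledger) <- NULL
  ledger_out <- ledger[setdiff(names(ledger), c("bases", "quals"))]
  utils::write.table(ledger_out, file.path(out_dir, "demux_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genotypes <- genotype_all(ledger, sim$samples, sim$loci,
                            het_threshold = config$call$het_threshold,
                            min_coverage = config$call$min_coverage,
                            min_majority_cov = config$call$min_majority_cov)
  utils::write.table(genotypes, file.path(out_dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  table0 <- population_allele_table(genotypes, sim$samples)
  cur <- singleton_correction(table0)
  utils::write.table(cur$table, file.path(out_dir, "curated_alleles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cur$edits, file.path(out_dir, "singleton_edits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  called <- genotypes[genotypes$status == "called", , drop = FALSE]
  if (nrow(called)) {
    pop <- sim$samples$population[match(called$individual,
                                        sim$samples$individual)]
    recs <- data.frame(
      locus = rep(called$locus, 2L), population = rep(pop, 2L),
      individual = rep(called$individual, 2L),
      allele_index = rep(1:2, each = nrow(called)),
      support = c(called$support1, called$support2),
      seq = c(called$allele1, called$allele2), stringsAsFactors = FALSE
    )
    write_alleles(recs, file.path(out_dir, "alleles.fasta"))
  }

  summ <- diversity_summary(genotypes, cur$table)
  summary_json <- list(
    schema_version = "1.0",
    seed = config$seed,
    libraries = lapply(reports, function(r) {
      list(total_reads = r$total_reads, kept_reads = r$kept_reads,
           discarded_by_reason = as.list(r$discarded_by_reason))
    }),
    per_locus = summ$per_locus,
    overall = summ$overall
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(sim = sim, ledger = ledger, reports = reports,
                 genotypes = genotypes, curated = cur, summary = summ,
                 paths = paths, out_dir = out_dir))
}
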
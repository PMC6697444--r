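#' Default pipeline configuration
#'
#' Parameters for [run_full_pipeline()]. The selection stage defaults to
#' the study design: a 20-nt random-core library, five rounds of
#' affinity-driven enrichment with measured class affinities, and
#' pattern counting on the final round. The EMSA and enrichment stages
#' are optional.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param n_library_reads Reads in the round-0 library.
#' @param model A [selection_model()].
#' @param patterns Pattern tibble.
#' @param count_round Which round to count (default the final round).
#' @param emsa Optional list of [simulate_titration()] argument lists, one
#'   per RNA, e.g. `list(cFBE = list(true_kd = 10.3))`; `NULL` disables
#'   the stage.
#' @param enrichment Optional list of [generate_gene_fixtures()]
#'   arguments (minus `seed`); `NULL` disables the stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_library_reads = 1e5L,
                            model = selection_model(),
                            patterns = puf_patterns(),
                            count_round = model$rounds,
                            emsa = NULL,
                            enrichment = NULL) {
  stopifnot(count_round >= 1, count_round <= model$rounds)
  structure(
    list(seed = as.integer(seed), n_library_reads = as.integer(n_library_reads),
         model = model, patterns = patterns,
         count_round = as.integer(count_round),
         emsa = emsa, enrichment = enrichment),
    class = "pipeline_config"
  )
}

# stage seeds derived deterministically from the master seed
.stage_seed <- function(seed, offset) (seed * 1000L + offset) %% .Machine$integer.max

#' Run the full selection-to-report pipeline
#'
#' Executes library simulation, selection rounds, pattern counting, ratio
#' computation and the position-frequency-matrix summary, plus the
#' optional EMSA-fitting and enrichment stages, writing all outputs and a
#' run manifest to `out_dir`. Two runs with the same configuration
#' produce byte-identical outputs.
#'
#' Outputs: `round_<k>.fasta` per round, `pattern_counts.tsv`,
#' `ratios.tsv`, `pfm.tsv` + `pfm.json`, optionally `emsa_fits.tsv`,
#' `genes.fasta`/`annotations.tsv`/`enrichment.tsv`, and
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main result tables (`counts`,
#'   `ratios`, `pfm`, and present stages' results) and `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }

  say("library", "simulating ", config$n_library_reads, " reads")
  library0 <- simulate_library(config$n_library_reads,
                               seed = .stage_seed(config$seed, 1L))

  say("selection", config$model$rounds, " rounds")
  sel_patterns <- config$patterns[
    config$patterns$name %in% names(config$model$class_kd), , drop = FALSE]
  rounds <- simulate_selection(library0, config$model, sel_patterns,
                               seed = .stage_seed(config$seed, 2L))
  for (k in seq_along(rounds)) {
    write_reads(rounds[[k]], file.path(out_dir, sprintf("round_%d.fasta", k)))
  }

  say("count", "round ", config$count_round)
  counted <- rounds[[config$count_round]]
  counts <- count_patterns(counted, config$patterns,
                           dataset_label = sprintf("round_%d",
                                                   config$count_round))
  write_count_table(counts, file.path(out_dir, "pattern_counts.tsv"))
  ratios <- ratio_table(counts)
  readr::write_tsv(ratios, file.path(out_dir, "ratios.tsv"))

  say("pfm", "anchoring on generic compact element")
  pfm <- tryCatch(build_pfm(counted), error = function(e) NULL)
  if (!is.null(pfm)) {
    utils::write.table(pfm$prob, file.path(out_dir, "pfm.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    jsonlite::write_json(
      list(n_sites = pfm$n_sites, window = pfm$window, ic = pfm$ic),
      file.path(out_dir, "pfm.json"), auto_unbox = TRUE, digits = NA
    )
  }

  emsa_fits <- NULL
  if (!is.null(config$emsa)) {
    say("emsa", length(config$emsa), " titration set(s)")
    emsa_fits <- purrr::imap_dfr(config$emsa, function(args, label) {
      args$seed <- .stage_seed(config$seed, 3L + match(label, names(config$emsa)))
      tt <- do.call(simulate_titration, args)
      agg <- aggregate_replicates(fit_titrations(tt))
      dplyr::mutate(agg, rna = label, .before = 1)
    })
    readr::write_tsv(emsa_fits, file.path(out_dir, "emsa_fits.tsv"))
  }

  enrichment <- NULL
  if (!is.null(config$enrichment)) {
    say("enrich", "building gene fixtures and testing terms")
    args <- config$enrichment
    args$seed <- .stage_seed(config$seed, 99L)
    fx <- do.call(generate_gene_fixtures, args)
    write_gene_fixtures(fx$genes, fx$annotations,
                        file.path(out_dir, "genes.fasta"),
                        file.path(out_dir, "annotations.tsv"))
    enrichment <- enrich_by_element(fx$genes, fx$annotations,
                                    stratum = "compact_only",
                                    patterns = config$patterns)
    readr::write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  }

  manifest <- list(
    package = "pufselect",
    version = as.character(utils::packageVersion("pufselect")),
    seed = config$seed,
    n_library_reads = config$n_library_reads,
    model = config$model[c("protein_concentration", "class_kd",
                           "background_retention", "rounds",
                           "reads_per_round")],
    patterns = as.list(stats::setNames(config$patterns$pattern,
                                       config$patterns$name)),
    count_round = config$count_round,
    stages = c("library", "selection", "count", "pfm",
               if (!is.null(config$emsa)) "emsa",
               if (!is.null(config$enrichment)) "enrichment")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(counts = counts, ratios = ratios, pfm = pfm,
                 emsa_fits = emsa_fits, enrichment = enrichment,
                 manifest = manifest))
}
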
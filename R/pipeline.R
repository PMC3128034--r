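# End-to-end pipeline: simulate -> build gold standard -> evaluate.

#' Run the simulate / build-gold / evaluate pipeline
#'
#' Drives the full benchmark from one configuration: simulate reads from a
#' reference (or use provided reads), build the gold standard (oracle or
#' seeded from the origin SAM), and evaluate a SAM file -- by default the
#' origin SAM itself, i.e. a perfect "biological" mapper -- in one or more
#' categories. Configuration can be given as a YAML file path or an
#' equivalent nested list with blocks `reference`, `simulate`, `gold`,
#' `evaluate` and `output`.
#'
#' @param config YAML file path or list. Recognized fields:
#'   `reference$fasta` (path) or `reference$random_length` + optional
#'   `reference$seed`; `simulate` (arguments for [sim_config()]);
#'   `gold$model`, `gold$max_error_rate`, `gold$mode`;
#'   `evaluate$sam` (defaults to the origin SAM), `evaluate$categories`,
#'   `evaluate$rate`, `evaluate$cap`, `evaluate$cap_seed`;
#'   `output$dir` (artifact directory, default `tempdir()`).
#' @return A list with `summary` (one [glance.mapbench_eval()] row per
#'   category), `results` (the `mapbench_eval` objects), `gold`, and the
#'   artifact `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output$dir %||% tempfile("mapbench_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  refs <- if (!is.null(config$reference$fasta)) {
    read_fasta(config$reference$fasta)
  } else if (!is.null(config$reference$random_length)) {
    withr::with_seed(config$reference$seed %||% 1L,
                     tibble(id = "sim_ref",
                            seq = random_dna(config$reference$random_length)))
  } else abort("config$reference needs 'fasta' or 'random_length'")

  sc <- do.call(sim_config, config$simulate %||% list())
  sim <- simulate_reads(refs, sc)
  paths <- list(
    ref = file.path(out_dir, "reference.fa"),
    reads = file.path(out_dir, "reads.fq"),
    origins = file.path(out_dir, "origins.sam"),
    gold = file.path(out_dir, "gold.gsi")
  )
  write_fasta(refs, paths$ref)
  write_fastq(sim$reads, paths$reads)
  write_origin_sam(sim$origins, sim$reads, refs, paths$origins)

  model <- config$gold$model %||% "edit"
  rate <- config$gold$max_error_rate %||% 0
  mode <- config$gold$mode %||% "seeded"
  gs <- build_gold(refs, sim$reads, model = model, max_error_rate = rate,
                   mode = mode,
                   seed_sam = if (mode == "seeded") paths$origins else NULL)
  write_gsi(gs, paths$gold)

  sam <- config$evaluate$sam %||% paths$origins
  eval_rate <- config$evaluate$rate %||% rate
  cats <- config$evaluate$categories %||% c("all", "all_best", "any_best")
  records <- parse_sam(sam, reads = sim$reads)
  if (!is.null(config$evaluate$cap)) {
    records <- cap_matches(records, config$evaluate$cap, sim$reads, refs,
                           model, seed = config$evaluate$cap_seed %||% 1L)
  }
  results <- lapply(cats, function(cat) {
    evaluate_mapping(gs, records, sim$reads, refs, category = cat,
                     rate = eval_rate)
  })
  names(results) <- cats
  summary <- bind_rows(lapply(results, glance))
  jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  list(summary = summary, results = results, gold = gs, paths = paths)
}
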
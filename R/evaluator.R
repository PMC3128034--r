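# Scoring a mapper's records against a gold standard.

#' Evaluate read-mapper output against a gold standard
#'
#' Scores SAM records in one of three categories at error rate `rate`
#' (percent of read length): `"all"` (every feasible equivalence class
#' counts), `"all_best"` (only classes whose minimal distance equals the
#' read's best), `"any_best"` (one best class suffices). For each read the
#' error budget is `c = rate_to_k(rate, length)` and the relevant gold
#' intervals are those built at `k == c` (restricted to `min_k == best` for
#' the best categories). A record hits an interval iff read, contig and
#' strand agree, `first <= end <= last`, and the recomputed distance at the
#' record's end position is `<= c` -- interval spans may contain absorbed
#' separating positions, so feasibility is always re-checked. With the
#' normalized found intervals metric each read gives at most one point:
#' hitting one of its `n` relevant intervals earns `1/n` point (`all` /
#' `all_best`), or the full point for any best interval (`any_best`);
#' the final score is `100 * points / reads scored`.
#'
#' @param gs A `gold_standard` built at a rate `>= rate`.
#' @param records Record tibble from [parse_sam()] (optionally capped with
#'   [cap_matches()]).
#' @param reads,refs Sequence tables; needed to recompute distances.
#' @param category `"all"`, `"all_best"` or `"any_best"`.
#' @param rate Evaluation error rate in percent.
#' @param scored_reads Denominator convention: `"with_intervals"` counts
#'   only reads that have at least one relevant interval (default),
#'   `"all"` counts every read in `reads`.
#' @return A `mapbench_eval` object; see [tidy.mapbench_eval()] and
#'   [glance.mapbench_eval()].
#' @export
evaluate_mapping <- function(gs, records, reads, refs,
                             category = c("all", "all_best", "any_best"),
                             rate = 0,
                             scored_reads = c("with_intervals", "all")) {
  category <- match.arg(category)
  scored_reads <- match.arg(scored_reads)
  if (rate > gs$max_error_rate) {
    abort(sprintf(
      "evaluation rate %g%% exceeds the gold standard's rate %g%%",
      rate, gs$max_error_rate))
  }
  refs <- load_seqs(refs)
  reads <- load_seqs(reads)
  budget <- setNames(rate_to_k(rate, nchar(reads$seq)), reads$id)

  iv <- gs$intervals |>
    filter(.data$read_id %in% reads$id) |>
    mutate(c_k = budget[.data$read_id]) |>
    filter(.data$k == .data$c_k)
  if (category != "all" && nrow(iv)) {
    iv <- iv |>
      group_by(.data$read_id) |>
      filter(.data$min_k == min(.data$min_k)) |>
      ungroup()
  }
  iv$interval_id <- seq_len(nrow(iv))

  recs <- records
  recs$record_id <- seq_len(nrow(recs))
  recs$dist <- if (nrow(recs)) record_distances(recs, reads, refs, gs$model)
    else integer()
  recs$feasible <- nrow(recs) > 0 &
    recs$dist <= budget[recs$read_id] & !is.na(budget[recs$read_id])

  hits <- dplyr::inner_join(
    recs, select(iv, "read_id", "contig_id", "strand", "interval_id",
                 "first", "last"),
    by = c("read_id", "contig_id", "strand"),
    relationship = "many-to-many") |>
    filter(.data$first <= .data$end, .data$end <= .data$last)
  absorbed <- filter(hits, !.data$feasible)
  hits <- filter(hits, .data$feasible)

  unexpected <- recs |>
    filter(!(.data$record_id %in%
               c(hits$record_id, absorbed$record_id))) |>
    mutate(reason = ifelse(.data$feasible,
                           "feasible but not in gold standard",
                           "infeasible at evaluation rate"))

  hit_counts <- hits |>
    distinct(.data$read_id, .data$interval_id) |>
    dplyr::count(.data$read_id, name = "n_hit")
  per_read <- iv |>
    dplyr::count(.data$read_id, name = "n_relevant") |>
    left_join(hit_counts, by = "read_id") |>
    mutate(n_hit = dplyr::coalesce(.data$n_hit, 0L),
           points = if (category == "any_best") as.numeric(.data$n_hit > 0)
           else .data$n_hit / .data$n_relevant)

  n_scored <- if (scored_reads == "with_intervals") nrow(per_read)
    else nrow(reads)
  nfi <- if (n_scored > 0) 100 * sum(per_read$points) / n_scored else NA_real_

  missed <- iv |>
    filter(!(.data$interval_id %in% hits$interval_id)) |>
    select("read_id", "contig_id", "strand", "k", "min_k", "first",
           "last") |>
    arrange(.data$read_id, .data$contig_id, .data$first)

  structure(
    list(category = category, rate = rate,
         points = sum(per_read$points), n_reads_scored = n_scored,
         normalized_found_intervals = nfi,
         per_read = per_read, missed = missed,
         unexpected = select(unexpected, "read_id", "contig_id", "strand",
                             "end", "dist", "line_no", "reason"),
         absorbed = select(absorbed, "read_id", "contig_id", "strand",
                           "end", "dist", "line_no"),
         invalid = attr(records, "invalid") %||%
           tibble(line_no = integer(), read_id = character(),
                  reason = character())),
    class = "mapbench_eval"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mapbench_eval <- function(x, ...) {
  cat(sprintf("<mapbench_eval> category %s at error rate %g%%\n",
              x$category, x$rate))
  cat(sprintf("  normalized found intervals: %.1f%% (%.3g points over %d reads)\n",
              x$normalized_found_intervals, x$points, x$n_reads_scored))
  cat(sprintf("  missed intervals: %d; unexpected records: %d; invalid records: %d\n",
              nrow(x$missed), nrow(x$unexpected), nrow(x$invalid)))
  invisible(x)
}

#' Per-read scores of an evaluation
#'
#' @param x A `mapbench_eval`.
#' @param ... Unused.
#' @return Tibble with `read_id`, `n_relevant`, `n_hit`, `points`.
#' @export
tidy.mapbench_eval <- function(x, ...) x$per_read

#' One-row summary of an evaluation
#'
#' @param x A `mapbench_eval`.
#' @param ... Unused.
#' @return One-row tibble with the category, rate, points, reads scored,
#'   normalized found intervals and the sizes of the missed / unexpected /
#'   invalid sets.
#' @export
glance.mapbench_eval <- function(x, ...) {
  tibble(category = x$category, rate = x$rate, points = x$points,
         n_reads_scored = x$n_reads_scored,
         normalized_found_intervals = x$normalized_found_intervals,
         n_missed = nrow(x$missed), n_unexpected = nrow(x$unexpected),
         n_invalid = nrow(x$invalid))
}

#' Write the missed-interval report
#'
#' One GSI-syntax line per missed equivalence class, preceded by a header
#' naming the category and rate; useful for analysing why a mapper misses
#' matches.
#'
#' @param result A `mapbench_eval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
report_missed <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@MISSED\tCATEGORY:%s\tRATE:%g",
                     result$category, result$rate), con)
  m <- result$missed
  if (nrow(m)) {
    writeLines(paste(m$read_id, m$contig_id, m$strand, m$k, m$min_k,
                     m$first, m$last, sep = "\t"), con)
  }
  invisible(path)
}

#' Plot evaluation summaries
#'
#' Bar chart of normalized found intervals for one or more evaluations
#' (e.g. the three categories side by side).
#'
#' @param object A `mapbench_eval` or a list of them.
#' @param ... Further `mapbench_eval` objects.
#' @return A ggplot object.
#' @export
autoplot.mapbench_eval <- function(object, ...) {
  objs <- c(list(object), Filter(function(o) inherits(o, "mapbench_eval"),
                                 list(...)))
  df <- bind_rows(lapply(objs, glance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$normalized_found_intervals)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "normalized found intervals (%)",
                  title = sprintf("Mapper evaluation at error rate %g%%",
                                  df$rate[1]))
}
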
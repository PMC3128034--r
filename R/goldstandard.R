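# Gold standard construction, annotation and serialization.

#' Convert an error rate to an absolute error count
#'
#' Error budgets are expressed relative to read length so that read sets of
#' mixed length can share one rate; the absolute count for a read is
#' `floor(rate * length / 100)` (conservative: never admits more errors
#' than the rate).
#'
#' @param rate Error rate in percent (0-100).
#' @param read_length Read length in bases.
#' @return Integer error count `k`.
#' @export
#' @examples
#' rate_to_k(8, 36) # 2
rate_to_k <- function(rate, read_length) {
  if (any(rate < 0)) abort("error rate must be non-negative")
  as.integer(floor(rate * read_length / 100))
}

new_gold_standard <- function(intervals, model, max_error_rate, build_mode) {
  intervals <- arrange(intervals, .data$read_id, .data$contig_id,
                       .data$strand, .data$k, .data$first)
  structure(
    list(model = model, max_error_rate = max_error_rate, rate_mode = TRUE,
         build_mode = build_mode, intervals = intervals),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf(
    "<gold_standard> %s distance, max error rate %g%%, built in %s mode\n",
    x$model, x$max_error_rate, x$build_mode))
  cat(sprintf("  %d intervals for %d reads on %d contigs\n",
              nrow(x$intervals), length(unique(x$intervals$read_id)),
              length(unique(x$intervals$contig_id))))
  invisible(x)
}

#' Tidy a gold standard into its interval table
#'
#' @param x A `gold_standard`.
#' @param ... Unused.
#' @return The interval tibble (`read_id`, `contig_id`, `strand`, `k`,
#'   `min_k`, `first`, `last`).
#' @export
tidy.gold_standard <- function(x, ...) x$intervals

#' Build a gold standard for a read set
#'
#' In `"oracle"` mode, full error landscapes are computed on both strands
#' of every contig for every read and the equivalence classes are extracted
#' for every `0 <= k <= k_max(read)` -- exact but only practical for small
#' references. In `"seeded"` mode, the matches of a fully sensitive mapper
#' (one SAM record per equivalence class suffices) seed localized interval
#' extensions, so only a fraction of the reference is inspected; with
#' complete seeds the result is identical to oracle mode.
#'
#' @param refs Reference tibble (`id`, `seq`), named character vector, or a
#'   FASTA path.
#' @param reads Read tibble (`id`, `seq`), named character vector, or a
#'   FASTA/FASTQ path.
#' @param model Distance model, `"edit"` or `"hamming"`.
#' @param max_error_rate Maximal error rate in percent; each read's error
#'   budget is [rate_to_k()] of its length.
#' @param mode `"oracle"` or `"seeded"`.
#' @param seed_sam For seeded mode: SAM file path or a record tibble from
#'   [parse_sam()] giving at least one match per equivalence class.
#' @return A `gold_standard` object.
#' @export
build_gold <- function(refs, reads, model = c("edit", "hamming"),
                       max_error_rate = 0, mode = c("oracle", "seeded"),
                       seed_sam = NULL) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  refs <- load_seqs(refs)
  reads <- load_seqs(reads)
  if (nrow(reads) == 0L) abort("empty read set")
  if (anyDuplicated(refs$id)) abort("duplicate contig ids in reference")
  if (mode == "oracle") {
    iv <- purrr::map2(reads$id, reads$seq, function(id, seq) {
      intervals_for_read(seq, refs, model,
                         k_max = rate_to_k(max_error_rate, nchar(seq)),
                         read_id = id)
    })
    gs <- new_gold_standard(bind_rows(c(list(empty_intervals()), iv)),
                            model, max_error_rate, "oracle")
  } else {
    if (is.null(seed_sam)) abort("seeded mode requires seed_sam")
    gs <- build_seeded(refs, reads, seed_sam, model, max_error_rate)
  }
  gs
}

build_seeded <- function(refs, reads, seed_sam, model, max_error_rate) {
  recs <- if (is.character(seed_sam)) parse_sam(seed_sam) else seed_sam
  bad_contig <- !(recs$contig_id %in% refs$id)
  if (any(bad_contig)) {
    abort(sprintf("seed SAM line %d references unknown contig '%s'",
                  recs$line_no[which(bad_contig)[1]],
                  recs$contig_id[which(bad_contig)[1]]))
  }
  bad_read <- !(recs$read_id %in% reads$id)
  if (any(bad_read)) {
    abort(sprintf("seed SAM line %d references unknown read '%s'",
                  recs$line_no[which(bad_read)[1]],
                  recs$read_id[which(bad_read)[1]]))
  }
  seeds <- distinct(recs, .data$read_id, .data$contig_id, .data$strand,
                    .data$end)
  read_seq <- setNames(reads$seq, reads$id)
  rc_seq <- setNames(reverse_complement(reads$seq), reads$id)
  ref_seq <- setNames(refs$seq, refs$id)
  ns <- nrow(seeds)
  rows <- vector("list", ns)
  touched <- 0L
  for (si in seq_len(ns)) {
    rid <- seeds$read_id[si]
    rd <- if (seeds$strand[si] == "-") rc_seq[[rid]] else read_seq[[rid]]
    ctg <- ref_seq[[seeds$contig_id[si]]]
    k_max <- rate_to_k(max_error_rate, nchar(rd))
    d <- distance_at(rd, ctg, model, seeds$end[si])
    if (d > k_max) next                      # unexpected seed, not an error
    ks <- d:k_max
    mink <- first <- last <- integer(length(ks))
    for (t in seq_along(ks)) {
      iv <- extend_interval(seeds$end[si], rd, ctg, model, ks[t])
      touched <- touched + attr(iv, "positions_touched")
      mink[t] <- iv$min_k; first[t] <- iv$first; last[t] <- iv$last
    }
    rows[[si]] <- list(rid = rid, contig = seeds$contig_id[si],
                       strand = seeds$strand[si], k = as.integer(ks),
                       mink = mink, first = first, last = last)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    gs <- new_gold_standard(empty_intervals(), model, max_error_rate, "seeded")
    attr(gs, "positions_touched") <- touched
    return(gs)
  }
  nk <- vapply(rows, function(r) length(r$k), integer(1))
  iv <- distinct(tibble(
    read_id = rep(vapply(rows, `[[`, character(1), "rid"), nk),
    contig_id = rep(vapply(rows, `[[`, character(1), "contig"), nk),
    strand = rep(vapply(rows, `[[`, character(1), "strand"), nk),
    k = unlist(lapply(rows, `[[`, "k")),
    min_k = unlist(lapply(rows, `[[`, "mink")),
    first = unlist(lapply(rows, `[[`, "first")),
    last = unlist(lapply(rows, `[[`, "last"))))
  gs <- new_gold_standard(iv, model, max_error_rate, "seeded")
  attr(gs, "positions_touched") <- touched
  gs
}

#' Reconstruct the equivalence class around one seed match
#'
#' Grows a window around a feasible seed end position until it is bounded
#' on both sides by a stretch of `read length + k` consecutive infeasible
#' positions (or a contig border) -- no trace-equivalence link can span such
#' a stretch, so the class computed inside the window equals the class in
#' the full landscape. Only `O(interval length + read length + k)`
#' reference positions are inspected.
#'
#' @param end Seed end position (0-based); its recomputed distance must be
#'   `<= k`.
#' @param read Read sequence, already reverse-complemented for
#'   reverse-strand seeds.
#' @param ref Contig sequence.
#' @param model Distance model.
#' @param k Error threshold.
#' @return One-row tibble (`k`, `first`, `last`, `min_k`) with attribute
#'   `positions_touched` (number of reference positions evaluated).
#' @export
extend_interval <- function(end, read, ref, model = c("edit", "hamming"), k) {
  model <- match.arg(model)
  end <- as.integer(end); k <- as.integer(k)
  m <- nchar(read); n <- nchar(ref)
  g <- m + k                                  # no link can span g infeasibles
  chunk <- 2L * g
  lo <- max(0L, end - chunk); hi <- min(n - 1L, end + chunk)
  w <- landscape_window(read, ref, model, lo, hi, slack = k)
  touched <- hi - lo + 1L

  gap_ok <- function(d, side) {
    if (length(d) < g) return(FALSE)
    tail_inf <- if (side == "right") rev(d) else d
    all(tail_inf[seq_len(g)] > k)
  }
  while (!(hi == n - 1L || gap_ok(w$delta, "right"))) {
    hi <- min(n - 1L, hi + chunk)
    w <- landscape_window(read, ref, model, lo, hi, slack = k)
    touched <- touched + chunk
  }
  while (!(lo == 0L || gap_ok(w$delta, "left"))) {
    lo <- max(0L, lo - chunk)
    w <- landscape_window(read, ref, model, lo, hi, slack = k)
    touched <- touched + chunk
  }

  mc <- merge_core(w$delta, w$cstart, lake_runs(w$delta, k), k)
  # window coordinates -> contig coordinates
  first <- mc$first + lo; last <- mc$last + lo
  hit <- which(first <= end & end <= last)
  if (!length(hit)) abort(sprintf("seed end %d infeasible at k = %d", end, k))
  res <- tibble(k = as.integer(k), first = first[hit], last = last[hit],
                min_k = mc$min_k[hit])
  attr(res, "positions_touched") <- touched
  res
}

#' Annotate intervals with the minimal k of contained intervals
#'
#' For the all-best and any-best categories, each interval is labelled with
#' the smallest `k` of any gold interval contained in it (its own `k`
#' included), which equals the depth of its deepest lake when all levels
#' `0..k_max` were built.
#'
#' @param gs A `gold_standard` with intervals for all `k <= k_max`.
#' @return The `gold_standard` with the `min_k` column recomputed.
#' @export
annotate_min_k <- function(gs) {
  iv <- gs$intervals
  if (nrow(iv) == 0L) return(gs)
  key <- paste(iv$read_id, iv$contig_id, iv$strand, sep = "\r")
  min_k <- iv$min_k
  for (g in split(seq_len(nrow(iv)), key)) {
    f <- iv$first[g]; l <- iv$last[g]; kk <- iv$k[g]
    for (i in seq_along(g)) {
      min_k[g[i]] <- min(kk[f >= f[i] & l <= l[i]])
    }
  }
  gs$intervals$min_k <- min_k
  gs
}

# canonical-start windows for cstart are not needed here: merge_lakes does
# the work inside extend_interval and intervals_for_read.

#' Write a gold standard to a GSI file
#'
#' The GSI format is a small TSV: header lines `@MAPBENCH-GSI  VERSION:1`,
#' `@MODEL:<hamming|edit>`, `@RATE:<percent>`, then one line per interval
#' with columns read_id, contig_id, strand, k, min_k, first, last
#' (0-based closed coordinates).
#'
#' @param gs A `gold_standard`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gsi <- function(gs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@MAPBENCH-GSI\tVERSION:1",
               paste0("@MODEL:", gs$model),
               paste0("@RATE:", format(gs$max_error_rate))), con)
  iv <- gs$intervals
  if (nrow(iv)) {
    writeLines(paste(iv$read_id, iv$contig_id, iv$strand, iv$k, iv$min_k,
                     iv$first, iv$last, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gold standard from a GSI file
#'
#' @param path Path to a file written by [write_gsi()].
#' @return A `gold_standard`.
#' @export
read_gsi <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !identical(lines[1], "@MAPBENCH-GSI\tVERSION:1"))
    abort(sprintf("'%s' is not a version-1 GSI file", path))
  model <- sub("^@MODEL:", "", lines[2])
  if (!model %in% c("hamming", "edit"))
    abort(sprintf("GSI line 2: unknown distance model '%s'", model))
  rate <- suppressWarnings(as.numeric(sub("^@RATE:", "", lines[3])))
  if (is.na(rate)) abort("GSI line 3: malformed @RATE header")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(new_gold_standard(empty_intervals(), model, rate, "oracle"))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L)) {
    abort(sprintf("GSI line %d: expected 7 tab-separated fields, found %d",
                  which(nf != 7L)[1] + 3L, nf[nf != 7L][1]))
  }
  mat <- do.call(rbind, parts)
  num <- suppressWarnings(apply(mat[, 4:7, drop = FALSE], 2, as.integer))
  num <- matrix(num, ncol = 4L)
  if (anyNA(num)) {
    abort(sprintf("GSI line %d: non-integer coordinate field",
                  which(apply(is.na(num), 1, any))[1] + 3L))
  }
  iv <- tibble(read_id = mat[, 1], contig_id = mat[, 2], strand = mat[, 3],
               k = num[, 1], min_k = num[, 2], first = num[, 3],
               last = num[, 4])
  new_gold_standard(iv, model, rate, "oracle")
}

# Accept a tibble, a named character vector, or a FASTA/FASTQ path.
load_seqs <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.(fa|fasta|fq|fastq)$", x, ignore.case = TRUE)) {
    if (grepl("\\.(fq|fastq)$", x, ignore.case = TRUE)) return(read_fastq(x))
    return(read_fasta(x))
  }
  as_ref_tbl(x)
}
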
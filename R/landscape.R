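#' Compute the error landscape of a read against one reference strand
#'
#' The error landscape assigns to every 0-based reference position `i` the
#' minimal distance `delta[i]` of a semi-global alignment of the full read
#' that ends with the read's last base on position `i`. Alignments are
#' end-anchored: the first and last read base must align to reference
#' characters (never to a gap), and the alignment must lie fully inside the
#' reference. Alongside `delta`, the leftmost start position among
#' minimal-distance alignments ending at `i` is recorded as the canonical
#' start; under Hamming distance this is always the diagonal `i - m + 1`.
#'
#' Positions where no valid alignment ends carry the sentinel `m + 1`
#' (one more than the read length, i.e. infeasible at every meaningful `k`)
#' and `NA` as canonical start. `N` bases mismatch everything, including `N`.
#'
#' @param read A single read sequence (string over A,C,G,T,N).
#' @param ref A single reference sequence.
#' @param model Distance model, `"edit"` (Levenshtein) or `"hamming"`.
#' @param read_id,contig_id,strand Identifiers stored on the result.
#' @return An object of class `error_landscape`: a list with `delta` and
#'   `canonical_start` integer vectors (length = reference length, 0-based
#'   index), the distance `model`, `read_length`, and the identifiers.
#' @seealso [landscape_bruteforce()] for the independent reference
#'   implementation, [find_lakes()] and [merge_lakes()] for the equivalence
#'   classes built on top.
#' @export
#' @examples
#' ls <- error_landscape("ACG", "ACGACG", model = "hamming")
#' ls$delta  # 4 4 0 3 3 0
error_landscape <- function(read, ref, model = c("edit", "hamming"),
                            read_id = "read", contig_id = "ref",
                            strand = "+") {
  model <- match.arg(model)
  check_sequence(read, "read")
  check_sequence(ref, "reference")
  raw <- if (model == "hamming") .ls_hamming(read, ref) else .ls_edit(read, ref)
  structure(
    list(read_id = read_id, contig_id = contig_id, strand = strand,
         model = model, read_length = nchar(read),
         delta = raw$delta, canonical_start = raw$cstart),
    class = "error_landscape"
  )
}

#' @export
print.error_landscape <- function(x, ...) {
  feas <- sum(x$delta <= x$read_length)
  cat(sprintf(
    "<error_landscape> read '%s' (%d bp) vs contig '%s' (%s strand, %s distance)\n",
    x$read_id, x$read_length, x$contig_id, x$strand, x$model))
  cat(sprintf("  %d reference positions, %d with a valid alignment end; min delta %s\n",
              length(x$delta), feas,
              if (feas) min(x$delta) else "none"))
  invisible(x)
}

#' Tidy an error landscape into a position table
#'
#' @param x An `error_landscape`.
#' @param ... Unused.
#' @return A tibble with 0-based `pos`, `delta` (`NA` where infeasible) and
#'   `canonical_start`.
#' @export
tidy.error_landscape <- function(x, ...) {
  d <- x$delta
  d[d > x$read_length] <- NA_integer_
  tibble(pos = seq_along(x$delta) - 1L, delta = d,
         canonical_start = x$canonical_start)
}

# Exact landscape restricted to reference positions lo..hi (0-based).
# A left margin of read_length + slack reference characters is prepended so
# that every alignment with distance <= slack ending inside the window is
# fully contained; reported values <= slack are exact, larger values are
# valid lower-bound-exceeding sentinels (still > slack).
landscape_window <- function(read, ref, model, lo, hi, slack = nchar(read)) {
  m <- nchar(read)
  n <- nchar(ref)
  lo <- as.integer(lo); hi <- as.integer(hi); slack <- as.integer(slack)
  a <- max(0L, lo - (m + slack))
  sub <- substr(ref, a + 1L, hi + 1L)
  raw <- if (model == "hamming") .ls_hamming(read, sub) else .ls_edit(read, sub)
  idx <- (lo - a + 1L):(hi - a + 1L)
  cs <- raw$cstart[idx]
  list(pos = lo:hi, delta = raw$delta[idx],
       cstart = ifelse(is.na(cs), NA_integer_, cs + a))
}

#' Alignment distance of a read at one end position
#'
#' Point query into the error landscape: the minimal distance of an
#' end-anchored semi-global alignment of `read` ending at reference
#' position `end` (0-based).
#'
#' @inheritParams error_landscape
#' @param end 0-based reference position.
#' @return Integer distance; `nchar(read) + 1` if no valid alignment ends
#'   at `end`.
#' @export
distance_at <- function(read, ref, model = c("edit", "hamming"), end) {
  model <- match.arg(model)
  check_sequence(read, "read")
  if (end < 0L || end >= nchar(ref))
    abort(sprintf("end position %d outside reference [0, %d]", end, nchar(ref) - 1L))
  landscape_window(read, ref, model, end, end)$delta[1L]
}

#' Canonical start position of a read at one end position
#'
#' The leftmost start position among minimal-distance end-anchored
#' alignments of `read` ending at `end`. Under Hamming distance every match
#' occupies exactly one diagonal, so the canonical start is `end - m + 1`.
#'
#' @inheritParams distance_at
#' @return 0-based start position.
#' @export
canonical_start_at <- function(read, ref, model = c("edit", "hamming"), end) {
  model <- match.arg(model)
  check_sequence(read, "read")
  if (end < 0L || end >= nchar(ref))
    abort(sprintf("end position %d outside reference [0, %d]", end, nchar(ref) - 1L))
  w <- landscape_window(read, ref, model, end, end)
  if (w$delta[1L] > nchar(read))
    abort(sprintf("no valid alignment ends at position %d", end))
  w$cstart[1L]
}

#' Plot an error landscape with its water level
#'
#' Draws the per-position distances as a landscape profile and floods it to
#' the water level `k + 0.5`; runs of positions below the water line are the
#' lakes that become match equivalence classes.
#'
#' @param object An `error_landscape`.
#' @param k Error threshold used for the water level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_landscape <- function(object, k = 0, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$delta), ],
                  ggplot2::aes(x = .data$pos, y = .data$delta)) +
    ggplot2::geom_area(fill = "grey80") +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = k + 0.5, colour = "steelblue") +
    ggplot2::labs(
      x = "reference end position", y = expression(delta(i)),
      title = sprintf("Error landscape: %s vs %s (%s strand, %s)",
                      object$read_id, object$contig_id, object$strand,
                      object$model),
      subtitle = sprintf("water level k + 0.5 = %.1f", k + 0.5)
    )
}
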
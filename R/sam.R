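# Plain-text SAM ingestion and per-read match capping.

#' Parse a SAM file into a mapper record table
#'
#' Reads the 11 mandatory columns of a plain-text SAM file. Unmapped
#' records are dropped; records with soft/hard clipping or (when `reads`
#' is supplied) with unknown read ids are routed to the `invalid`
#' attribute with a reason rather than kept, because the benchmark is
#' defined for full-read semi-global alignment. The 0-based rightmost
#' reference position covered by each alignment (`end`) is derived from
#' POS and the reference-consuming CIGAR operations; a record carrying the
#' reverse flag already corresponds to the reverse-strand convention used
#' by the gold standard (reverse-complemented read aligned on forward
#' coordinates), so no coordinate flipping is needed.
#'
#' @param path SAM file path.
#' @param reads Optional read table (`id`, `seq`); records naming unknown
#'   reads become invalid.
#' @return Tibble with columns `read_id`, `flag`, `contig_id`, `strand`,
#'   `pos` (0-based leftmost), `end` (0-based rightmost), `cigar`,
#'   `line_no`; attribute `invalid` holds a tibble of rejected records with
#'   a `reason` column.
#' @export
parse_sam <- function(path, reads = NULL) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@") & nzchar(lines))
  empty <- tibble(read_id = character(), flag = integer(),
                  contig_id = character(), strand = character(),
                  pos = integer(), end = integer(), cigar = character(),
                  line_no = integer())
  invalid <- tibble(line_no = integer(), read_id = character(),
                    reason = character())
  if (!length(body_idx)) {
    attr(empty, "invalid") <- invalid
    return(empty)
  }
  parts <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  short <- lengths(parts) < 11L
  if (any(short)) {
    abort(sprintf("SAM line %d: fewer than 11 fields",
                  body_idx[which(short)[1]]))
  }
  rec <- tibble(
    read_id = vapply(parts, `[`, character(1), 1L),
    flag = as.integer(vapply(parts, `[`, character(1), 2L)),
    contig_id = vapply(parts, `[`, character(1), 3L),
    pos1 = as.integer(vapply(parts, `[`, character(1), 4L)),
    cigar = vapply(parts, `[`, character(1), 6L),
    line_no = body_idx
  )
  rec <- filter(rec, bitwAnd(.data$flag, 4L) == 0L, .data$contig_id != "*")
  clipped <- grepl("[SH]", rec$cigar)
  no_cigar <- rec$cigar == "*"
  unknown <- if (!is.null(reads)) !(rec$read_id %in% reads$id) else
    rep(FALSE, nrow(rec))
  bad <- clipped | no_cigar | unknown
  if (any(bad)) {
    invalid <- tibble(
      line_no = rec$line_no[bad], read_id = rec$read_id[bad],
      reason = dplyr::case_when(
        no_cigar[bad] ~ "missing CIGAR",
        clipped[bad] ~ "clipped",
        TRUE ~ "unknown read"
      ))
    rec <- rec[!bad, ]
  }
  out <- if (nrow(rec)) {
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
    tibble(
      read_id = rec$read_id, flag = rec$flag, contig_id = rec$contig_id,
      strand = ifelse(bitwAnd(rec$flag, 16L) > 0L, "-", "+"),
      pos = rec$pos1 - 1L, end = rec$pos1 - 1L + width - 1L,
      cigar = rec$cigar, line_no = rec$line_no
    )
  } else empty
  attr(out, "invalid") <- invalid
  out
}

#' Write mapper records to a SAM file
#'
#' Minimal SAM writer used by the simulator (origin alignments) and by
#' synthetic mappers in tests.
#'
#' @param records Tibble with `read_id`, `contig_id`, `strand`, `pos`
#'   (0-based), `cigar`, and optionally `seq`, `qual`, `flag`.
#' @param refs Reference table (`id`, `seq`) for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, refs, path) {
  refs <- as_ref_tbl(refs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", refs$id, nchar(refs$seq))), con)
  if (nrow(records)) {
    flag <- if ("flag" %in% names(records)) records$flag else
      ifelse(records$strand == "-", 16L, 0L)
    seq <- if ("seq" %in% names(records)) records$seq else "*"
    qual <- if ("qual" %in% names(records)) records$qual else "*"
    writeLines(paste(records$read_id, flag, records$contig_id,
                     records$pos + 1L, 255L, records$cigar, "*", 0L, 0L,
                     seq, qual, sep = "\t"), con)
  }
  invisible(path)
}

# Recompute the alignment distance of each record at its reported end
# position (the mapper's own NM/CIGAR is never trusted).
record_distances <- function(records, reads, refs, model) {
  read_seq <- setNames(reads$seq, reads$id)
  rc_seq <- setNames(reverse_complement(reads$seq), reads$id)
  ref_seq <- setNames(refs$seq, refs$id)
  ref_len <- setNames(nchar(refs$seq), refs$id)
  vapply(seq_len(nrow(records)), function(i) {
    rd <- if (records$strand[i] == "-") rc_seq[[records$read_id[i]]] else
      read_seq[[records$read_id[i]]]
    if (records$end[i] < 0L ||
        records$end[i] >= ref_len[[records$contig_id[i]]])
      return(nchar(rd) + 1L)
    m <- nchar(rd)
    landscape_window(rd, ref_seq[[records$contig_id[i]]], model,
                     records$end[i], records$end[i])$delta[1L]
  }, integer(1))
}

#' Cap mapper output at the best n matches per read
#'
#' Keeps, per read, at most `limit` records ranked by recomputed alignment
#' distance, breaking ties randomly but reproducibly under `seed`
#' (mirrors capping mapper output at its best 100 matches before
#' evaluation).
#'
#' @param records Record tibble from [parse_sam()].
#' @param limit Maximal records per read (>= 1).
#' @param reads,refs Sequence tables used to recompute distances.
#' @param model Distance model.
#' @param seed Integer seed for the tie-breaking RNG.
#' @return Filtered record tibble (original order not preserved).
#' @export
cap_matches <- function(records, limit = 100L, reads, refs,
                        model = c("edit", "hamming"), seed = 1L) {
  model <- match.arg(model)
  stopifnot(limit >= 1L)
  if (nrow(records) <= 0L) return(records)
  d <- record_distances(records, reads, refs, model)
  withr::with_seed(seed, {
    tie <- runif(nrow(records))
    records |>
      mutate(.dist = d, .tie = tie) |>
      group_by(.data$read_id) |>
      arrange(.data$.dist, .data$.tie, .by_group = TRUE) |>
      slice(seq_len(min(limit, n()))) |>
      ungroup() |>
      select(-".dist", -".tie")
  })
}
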
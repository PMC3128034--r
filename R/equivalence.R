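# Match equivalence classes: lakes and their trace-equivalence merging.
#
# The hot path (seeded gold-standard construction calls this once per seed
# and per k) works on plain integer vectors; the exported functions wrap
# the same core in the tibble interface.

# maximal runs of positions with delta <= k; 0-based closed intervals
lake_runs <- function(delta, k) {
  wet <- delta <= k
  if (!any(wet)) return(list(first = integer(0), last = integer(0)))
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(first = starts[keep] - 1L, last = ends[keep] - 1L)
}

uf_new <- function(n) seq_len(n)

# Merge lakes into equivalence classes. Two lakes join when feasible
# positions in them share a canonical start (trace equivalence across the
# separating positions between them); every lake lying inside the span of
# a merged class is absorbed as well (a match between two trace-equivalent
# matches belongs to their class); transitive closure throughout.
# Returns list(first, last, min_k), sorted by first.
merge_core <- function(delta, cstart, lakes, k) {
  nl <- length(lakes$first)
  if (nl == 0L) return(list(first = integer(0), last = integer(0),
                            min_k = integer(0)))
  pos <- which(delta <= k) - 1L
  lake_of <- findInterval(pos, lakes$first)
  parent <- uf_new(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }

  cs <- cstart[pos + 1L]
  for (g in split(lake_of, cs)) {
    u <- unique(g)
    if (length(u) > 1L) for (j in u[-1L]) union(u[1L], j)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  span_first <- tapply(lakes$first, root, min)
  span_last <- tapply(lakes$last, root, max)
  ord <- order(span_first)
  roots <- as.integer(names(span_first))[ord]
  sf <- as.integer(span_first)[ord]; sl <- as.integer(span_last)[ord]
  cur <- 1L
  for (i in seq_along(roots)[-1L]) {
    if (sf[i] <= sl[cur]) {                 # lake inside a wider class span
      union(roots[cur], roots[i])
      sl[cur] <- max(sl[cur], sl[i])
    } else cur <- i
  }

  root <- vapply(seq_len(nl), find, integer(1))
  first <- as.integer(tapply(lakes$first, root, min))
  last <- as.integer(tapply(lakes$last, root, max))
  o <- order(first)
  first <- first[o]; last <- last[o]
  min_k <- vapply(seq_along(first), function(i) {
    min(delta[pos[pos >= first[i] & pos <= last[i]] + 1L])
  }, integer(1))
  list(first = first, last = last, min_k = min_k)
}

#' Find lakes of an error landscape at water level k + 0.5
#'
#' A lake is a maximal run of consecutive end positions with
#' `delta <= k` -- the neighbour-equivalence classes of feasible matches.
#'
#' @param landscape An `error_landscape`.
#' @param k Error threshold (non-negative integer).
#' @return Tibble with 0-based closed interval columns `first`, `last`,
#'   sorted, disjoint and non-adjacent.
#' @export
find_lakes <- function(landscape, k) {
  stopifnot(k >= 0)
  as_tibble(lake_runs(landscape$delta, k))
}

#' Merge lakes into match equivalence classes
#'
#' Two lakes belong to the same class when they contain trace-equivalent
#' feasible positions, i.e. positions sharing the same canonical start
#' (the infeasible positions between distinct lakes are separating matches,
#' so trace equivalence across them merges the classes). Every lake lying
#' between two trace-equivalent positions is absorbed into their class as
#' well, and the transitive closure is taken. Each resulting class is
#' reported as one closed interval from its leftmost to its rightmost
#' feasible position; interior separating positions (with `delta > k`) may
#' exist inside the interval, which is why hit-checking downstream
#' re-verifies feasibility at the reported position.
#'
#' @param landscape An `error_landscape`.
#' @param lakes Output of [find_lakes()] on the same landscape and `k`.
#' @param k Error threshold the lakes were computed at.
#' @return Tibble with columns `k`, `first`, `last`, `min_k` where `min_k`
#'   is the minimal `delta` over the feasible positions of the class (the
#'   depth of its deepest lake).
#' @export
merge_lakes <- function(landscape, lakes, k) {
  mc <- merge_core(landscape$delta, landscape$canonical_start,
                   list(first = lakes$first, last = lakes$last), k)
  tibble(k = rep(as.integer(k), length(mc$first)),
         first = mc$first, last = mc$last, min_k = mc$min_k)
}

#' Gold intervals of one read against a reference set
#'
#' For every contig, both strands (the reverse strand is represented by the
#' reverse-complemented read aligned left-to-right on forward coordinates)
#' and every `k` in `0..k_max`, extracts lakes and merges them into match
#' equivalence classes.
#'
#' @param read Read sequence.
#' @param refs Reference tibble (`id`, `seq`) or named/unnamed character
#'   vector.
#' @param model Distance model, `"edit"` or `"hamming"`.
#' @param k_max Maximal error count.
#' @param read_id Identifier recorded in the output.
#' @return Interval tibble (`read_id`, `contig_id`, `strand`, `k`, `min_k`,
#'   `first`, `last`), sorted.
#' @export
#' @examples
#' intervals_for_read("ACG", c(chr = "ACGTACG"), model = "hamming", k_max = 0)
intervals_for_read <- function(read, refs, model = c("edit", "hamming"),
                               k_max = 0L, read_id = "read") {
  model <- match.arg(model)
  stopifnot(k_max >= 0)
  refs <- as_ref_tbl(refs)
  out <- list()
  for (ci in seq_len(nrow(refs))) {
    for (std in c("+", "-")) {
      rd <- if (std == "+") read else reverse_complement(read)
      ls <- error_landscape(rd, refs$seq[ci], model,
                            read_id = read_id, contig_id = refs$id[ci],
                            strand = std)
      for (k in 0:k_max) {
        mc <- merge_core(ls$delta, ls$canonical_start,
                         lake_runs(ls$delta, k), k)
        if (length(mc$first)) {
          out[[length(out) + 1L]] <-
            list(contig = refs$id[ci], strand = std, k = as.integer(k),
                 first = mc$first, last = mc$last, min_k = mc$min_k)
        }
      }
    }
  }
  if (!length(out)) return(empty_intervals())
  nn <- vapply(out, function(o) length(o$first), integer(1))
  iv <- tibble(
    read_id = rep(read_id, sum(nn)),
    contig_id = rep(vapply(out, `[[`, character(1), "contig"), nn),
    strand = rep(vapply(out, `[[`, character(1), "strand"), nn),
    k = rep(vapply(out, `[[`, integer(1), "k"), nn),
    min_k = unlist(lapply(out, `[[`, "min_k")),
    first = unlist(lapply(out, `[[`, "first")),
    last = unlist(lapply(out, `[[`, "last")))
  arrange(iv, .data$read_id, .data$contig_id, .data$strand, .data$k,
          .data$first)
}
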
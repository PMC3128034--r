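# Brute-force reference implementations.
#
# These re-derive landscapes and match equivalence classes from first
# principles -- explicit enumeration of anchored start positions with
# utils::adist() for the interior alignment, and an explicit closure of the
# neighbour/trace/k-trace equivalence definitions via igraph components.
# They share no code with the optimized C++ landscape or the union-find
# merger and exist to pin down correctness on desk-scale inputs.

# mismatch under the package's N convention (N never matches, even N vs N)
.neq <- function(a, b) (a != b) | a == "N" | b == "N"

#' Brute-force error landscape (reference implementation)
#'
#' Enumerates, for every end position, all anchored start positions and
#' scores the alignment as: first-base column + interior global edit
#' distance (via [utils::adist()]) + last-base column. Exact but quadratic;
#' intended for validating [error_landscape()] on small inputs.
#'
#' @inheritParams error_landscape
#' @return An `error_landscape` object (same contract as
#'   [error_landscape()]).
#' @export
landscape_bruteforce <- function(read, ref, model = c("edit", "hamming"),
                                 read_id = "read", contig_id = "ref",
                                 strand = "+") {
  model <- match.arg(model)
  check_sequence(read, "read")
  check_sequence(ref, "reference")
  m <- nchar(read); n <- nchar(ref)
  INF <- m + 1L
  rv <- strsplit(read, "")[[1]]
  sv <- strsplit(ref, "")[[1]]
  delta <- rep(INF, n)
  cstart <- rep(NA_integer_, n)

  if (model == "hamming") {
    if (n >= m) {
      for (i in (m - 1L):(n - 1L)) {          # 0-based end position
        s <- i - m + 2L                        # 1-based window start
        d <- sum(.neq(rv, sv[s:(i + 1L)]))
        if (d <= m) { delta[i + 1L] <- d; cstart[i + 1L] <- i - m + 1L }
      }
    }
  } else if (m == 1L) {
    delta <- as.integer(.neq(rv[1L], sv))
    cstart <- seq_len(n) - 1L
  } else {
    # interior alignment is unconstrained; map N to distinct off-alphabet
    # letters on the two sides so adist never matches it
    interior_read <- chartr("N", "X", substr(read, 2L, m - 1L))
    ref_x <- chartr("N", "Z", ref)
    for (i in 1L:(n - 1L)) {                  # 0-based end position i
      smin <- max(0L, i - 2L * m + 1L)        # farther starts cost > m
      ss <- smin:(i - 1L)                     # 0-based candidate starts
      interiors <- substr(rep(ref_x, length(ss)), ss + 2L, i)
      costs <- .neq(rv[1L], sv[ss + 1L]) +
        as.vector(adist(interior_read, interiors)) +
        .neq(rv[m], sv[i + 1L])
      d <- min(costs)
      if (d <= m) {
        delta[i + 1L] <- as.integer(d)
        cstart[i + 1L] <- ss[which(costs == d)[1L]]
      }
    }
  }
  structure(
    list(read_id = read_id, contig_id = contig_id, strand = strand,
         model = model, read_length = m,
         delta = as.integer(delta), canonical_start = cstart),
    class = "error_landscape"
  )
}

# Equivalence classes at level k from a landscape, by explicit closure of
# the definitions: feasible positions are vertices; neighbour equivalence
# links adjacent feasible positions; trace equivalence links positions with
# equal canonical start, and any feasible position lying between two
# trace-equivalent positions joins their class (separating positions are
# bridged). Connected components of this graph are the classes.
bf_intervals_one <- function(ls, k) {
  feas <- which(ls$delta <= k)                 # 1-based indices
  if (length(feas) == 0L) {
    return(tibble(k = integer(), first = integer(), last = integer(),
                  min_k = integer()))
  }
  pos <- feas - 1L
  edges <- list()
  adj <- which(diff(pos) == 1L)
  if (length(adj)) edges[[1L]] <- cbind(pos[adj], pos[adj + 1L])
  grp <- split(pos, ls$canonical_start[feas])
  bridge <- lapply(grp, function(g) {
    a <- min(g); b <- max(g)
    if (b == a) return(NULL)
    inside <- pos[pos >= a & pos <= b]
    cbind(rep(b, length(inside)), inside)
  })
  edges <- c(edges, Filter(Negate(is.null), bridge))
  g <- igraph::graph_from_data_frame(
    d = if (length(edges)) {
      em <- do.call(rbind, edges)
      data.frame(from = as.character(em[, 1L]), to = as.character(em[, 2L]))
    } else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = as.character(pos))
  )
  comp <- igraph::components(g)$membership
  cls <- split(as.integer(names(comp)), comp)
  out <- lapply(cls, function(p) {
    tibble(k = as.integer(k), first = min(p), last = max(p),
           min_k = min(ls$delta[p + 1L]))
  })
  arrange(bind_rows(out), .data$first)
}

#' Brute-force gold intervals for one read (reference implementation)
#'
#' Computes landscapes with [landscape_bruteforce()] on both strands of
#' every contig and derives the match equivalence classes for every
#' `0 <= k <= k_max` by explicit closure of the neighbour- and
#' trace-equivalence definitions (graph components). The optimized
#' counterpart is [intervals_for_read()].
#'
#' @param read Read sequence.
#' @param refs Reference table (tibble with `id`, `seq`) or a single string.
#' @param model Distance model.
#' @param k_max Maximal error count.
#' @param read_id Identifier recorded in the output.
#' @return Tibble with columns `read_id`, `contig_id`, `strand`, `k`,
#'   `min_k`, `first`, `last`.
#' @export
gold_intervals_bruteforce <- function(read, refs, model = c("edit", "hamming"),
                                      k_max = 0L, read_id = "read") {
  model <- match.arg(model)
  refs <- as_ref_tbl(refs)
  out <- list()
  for (ci in seq_len(nrow(refs))) {
    for (std in c("+", "-")) {
      rd <- if (std == "+") read else reverse_complement(read)
      ls <- landscape_bruteforce(rd, refs$seq[ci], model)
      for (k in 0:k_max) {
        iv <- bf_intervals_one(ls, k)
        if (nrow(iv)) {
          iv$read_id <- read_id; iv$contig_id <- refs$id[ci]; iv$strand <- std
          out[[length(out) + 1L]] <- iv
        }
      }
    }
  }
  if (!length(out)) return(empty_intervals())
  arrange(select(bind_rows(out), "read_id", "contig_id", "strand",
                 "k", "min_k", "first", "last"),
          .data$read_id, .data$contig_id, .data$strand, .data$k, .data$first)
}

empty_intervals <- function() {
  tibble(read_id = character(), contig_id = character(), strand = character(),
         k = integer(), min_k = integer(), first = integer(), last = integer())
}

as_ref_tbl <- function(refs) {
  if (is.character(refs)) {
    ids <- if (!is.null(names(refs))) names(refs) else
      paste0("ref", seq_along(refs))
    refs <- tibble(id = ids, seq = unname(refs))
  }
  stopifnot(all(c("id", "seq") %in% names(refs)))
  if (anyDuplicated(refs$id)) abort("duplicate contig ids in reference")
  refs
}
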
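# Deterministic repeat-structure fixtures exercising the phenomena the
# match definition is built around: unique matches, tandem repeats of long
# and short period, near-duplicate copies, and contig-border placement.

#' Random DNA sequence
#'
#' Uniform i.i.d. bases using the current RNG state.
#'
#' @param n Length in bases.
#' @return A single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sequence over a restricted alphabet; fixtures use disjoint alphabets for
# repeat and spacer so spacer-only windows mismatch at every column
random_over <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a named benchmark fixture
#'
#' Builds a small reference/read pair reproducing a named repeat
#' phenomenon, together with a manifest stating the interval counts the
#' construction forces:
#'
#' * `unique_match`: read embedded once in random sequence; one interval
#'   with `first == last` at `k = 0`.
#' * `long_period_tandem`: `copies` exact copies of a unit longer than the
#'   read, in tandem; the copies stay separate classes (one per copy).
#' * `short_period_tandem`: read spans several periods of a short-period
#'   repeat; at `k >= 2` (edit; the cost of the indel pair that shifts the
#'   alignment by one period) the per-period matches merge into a single
#'   class.
#' * `near_duplicate_pair`: two copies of a segment differing by one
#'   substitution, separated by a random spacer; two classes.
#' * `border_case`: read occurring flush at the first and last position of
#'   the contig; two classes, exercising contig-boundary handling.
#'
#' @param kind Fixture kind (see above).
#' @param rng_seed Integer seed; output is deterministic given it.
#' @param period Repeat period (tandem kinds).
#' @param copies Number of repeat copies.
#' @param read_length Read length (non-tandem kinds).
#' @param k Error threshold recorded in the manifest.
#' @param model Distance model recorded in the manifest.
#' @return A list with `refs`, `reads` (tibbles) and `manifest` (tibble
#'   with `kind`, `model`, `k`, `strand`, `expected_n_intervals`).
#' @export
make_fixture <- function(kind = c("unique_match", "long_period_tandem",
                                  "short_period_tandem",
                                  "near_duplicate_pair", "border_case"),
                         rng_seed = 42L, period = 2L, copies = 10L,
                         read_length = 20L, k = NULL,
                         model = c("edit", "hamming")) {
  kind <- match.arg(kind)
  model <- match.arg(model)
  withr::with_seed(rng_seed, {
    switch(kind,
      unique_match = {
        k <- k %||% 0L
        repeat {
          ref <- random_dna(200L)
          start <- 90L
          read <- substr(ref, start + 1L, start + read_length)
          occ <- gregexpr(read, ref, fixed = TRUE)[[1]]
          if (length(occ) == 1L && occ[1] == start + 1L) break
        }
        list(refs = tibble(id = "fix", seq = ref),
             reads = tibble(id = "r1", seq = read),
             manifest = tibble(kind = kind, model = model, k = k,
                               strand = "+", expected_n_intervals = 1L))
      },
      long_period_tandem = {
        k <- k %||% 0L
        unit_len <- max(2L * read_length, read_length + 10L)
        repeat {
          unit <- random_dna(unit_len)
          read <- substr(unit, 1L, read_length)
          ref <- paste0(random_dna(50L), strrep(unit, copies),
                        random_dna(50L))
          if (length(gregexpr(read, ref, fixed = TRUE)[[1]]) == copies)
            break
        }
        list(refs = tibble(id = "fix", seq = ref),
             reads = tibble(id = "r1", seq = read),
             manifest = tibble(kind = kind, model = model, k = k,
                               strand = "+",
                               expected_n_intervals = as.integer(copies)))
      },
      short_period_tandem = {
        # shifting a periodic alignment by one period costs an indel pair,
        # so per-period matches merge into one class from k = 2 upward;
        # {A,C} repeat inside {G,T} spacers keeps the background dry
        k <- k %||% 2L
        unit <- random_over(period, c("A", "C"))
        read <- strrep(unit, 3L)
        ref <- paste0(random_over(40L, c("G", "T")), strrep(unit, copies),
                      random_over(40L, c("G", "T")))
        list(refs = tibble(id = "fix", seq = ref),
             reads = tibble(id = "r1", seq = read),
             manifest = tibble(kind = kind, model = model, k = k,
                               strand = "+", expected_n_intervals = 1L))
      },
      near_duplicate_pair = {
        k <- k %||% 1L
        seg <- random_over(read_length, c("A", "C"))
        mid <- read_length %/% 2L
        seg2 <- paste0(substr(seg, 1L, mid - 1L),
                       chartr("AC", "CA", substr(seg, mid, mid)),
                       substr(seg, mid + 1L, read_length))
        ref <- paste0(random_over(40L, c("G", "T")), seg,
                      random_over(60L, c("G", "T")), seg2,
                      random_over(40L, c("G", "T")))
        list(refs = tibble(id = "fix", seq = ref),
             reads = tibble(id = "r1", seq = seg),
             manifest = tibble(kind = kind, model = model, k = k,
                               strand = "+", expected_n_intervals = 2L))
      },
      border_case = {
        k <- k %||% 0L
        repeat {
          read <- random_dna(read_length)
          middle <- random_dna(80L)
          ref <- paste0(read, middle, read)
          if (length(gregexpr(read, ref, fixed = TRUE)[[1]]) == 2L) break
        }
        list(refs = tibble(id = "fix", seq = ref),
             reads = tibble(id = "r1", seq = read),
             manifest = tibble(kind = kind, model = model, k = k,
                               strand = "+", expected_n_intervals = 2L))
      }
    )
  })
}
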
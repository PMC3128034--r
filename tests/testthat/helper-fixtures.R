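# Shared helpers: in-code fixture construction for the test suite.

# a landscape object with prescribed delta/canonical_start, for tests that
# probe lake extraction and merging in isolation
fake_landscape <- function(delta, cstart = NULL, m = 3L) {
  structure(
    list(read_id = "read", contig_id = "ref", strand = "+", model = "edit",
         read_length = m, delta = as.integer(delta),
         canonical_start = if (is.null(cstart)) rep(NA_integer_, length(delta))
         else as.integer(cstart)),
    class = "error_landscape")
}

# an error rate whose floor()ed budget is exactly k_max for length m
rate_for_k <- function(k_max, m) 100 * (k_max + 0.5) / m

# random read/reference instance
random_instance <- function(m_range = 8:40, n_range = 50:500) {
  list(read = random_dna(sample(m_range, 1)),
       ref = random_dna(sample(n_range, 1)))
}

# SAM file with one record per gold interval (end = first), i.e. the
# output of a mapper that finds every equivalence class
perfect_mapper_sam <- function(gs, refs, path = tempfile(fileext = ".sam")) {
  iv <- dplyr::distinct(tidy(gs), read_id, contig_id, strand, first)
  write_sam(tibble::tibble(read_id = iv$read_id, contig_id = iv$contig_id,
                           strand = iv$strand, pos = iv$first,
                           cigar = "1M"),
            refs, path)
  path
}

# reference with four exact copies of read "one" and a unique site for
# read "two"; the two-read scoring example (0.5 + 1 points over 2 reads)
worked_example <- function() {
  withr::with_seed(101, {
    repeat {
      unit <- random_dna(30)
      r1 <- substr(unit, 1, 10)
      r2 <- random_dna(10)
      ref <- paste0(strrep(unit, 4), random_dna(25), r2, random_dna(20))
      occ1 <- gregexpr(r1, ref, fixed = TRUE)[[1]]
      occ2 <- gregexpr(r2, ref, fixed = TRUE)[[1]]
      occ1r <- gregexpr(reverse_complement(r1), ref, fixed = TRUE)[[1]]
      occ2r <- gregexpr(reverse_complement(r2), ref, fixed = TRUE)[[1]]
      if (length(occ1) == 4L && occ1[1] > 0 &&
          length(occ2) == 1L && occ2[1] > 0 &&
          occ1r[1] < 0 && occ2r[1] < 0) break
    }
  })
  refs <- tibble::tibble(id = "chr", seq = ref)
  reads <- tibble::tibble(id = c("one", "two"), seq = c(r1, r2))
  gs <- build_gold(refs, reads, model = "edit", max_error_rate = 0)
  list(refs = refs, reads = reads, gs = gs)
}

# instance frozen from a randomized search: the k = 2 gold interval
# [49, 51] contains position 50 with delta = 3 (an absorbed separating
# position bridged by trace equivalence)
absorbed_instance <- function() {
  list(read = "GAGGTA",
       ref = "CGTTCTACCATGGGCACTTCATGGTTTACTGTGCACGCGAGCAAGGAGTGTAG",
       k = 2L, first = 49L, last = 51L, separating = 50L)
}
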
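# Gold standard construction (oracle and seeded), annotation, GSI I/O.

test_that("error rates convert to budgets by flooring", {
  expect_identical(rate_to_k(8, 36), 2L)
  expect_identical(rate_to_k(8, 100), 8L)
  expect_identical(rate_to_k(0, 50), 0L)
  expect_error(rate_to_k(-1, 36), "non-negative")
})

test_that("oracle mode recovers exact occurrences and drops unmatched reads", {
  refs <- tibble::tibble(id = "chr", seq = "TTGACGTTTTACGTTT")
  reads <- tibble::tibble(id = c("hit", "miss"), seq = c("ACGT", "GGGG"))
  gs <- build_gold(refs, reads, model = "hamming", max_error_rate = 0)
  iv <- tidy(gs)
  hit_fwd <- iv[iv$read_id == "hit" & iv$strand == "+", ]
  expect_identical(hit_fwd$first, c(6L, 13L))
  expect_identical(hit_fwd$last, c(6L, 13L))
  expect_identical(nrow(iv[iv$read_id == "miss", ]), 0L)
  expect_error(build_gold(refs, reads[0, ], model = "hamming"), "empty")
  expect_error(
    build_gold(tibble::tibble(id = c("a", "a"), seq = c("ACGT", "ACGT")),
               reads, model = "hamming"),
    "duplicate")
})

test_that("interval extension reproduces the oracle class around a seed", {
  # unique exact match
  withr::with_seed(3, {
    ref <- random_dna(400)
  })
  read <- substr(ref, 101, 120)
  iv <- extend_interval(119L, read, ref, "edit", 0)
  expect_identical(iv$first, 119L)
  expect_identical(iv$last, 119L)
  expect_identical(iv$min_k, 0L)

  # short-period tandem: one wide class spanning the repeat
  tref <- paste0("TGGTT", strrep("AC", 10), "GGTTG")
  oracle <- gold_intervals_bruteforce("ACACAC", c(fix = tref), "edit", 2)
  oracle2 <- oracle[oracle$k == 2 & oracle$strand == "+", ]
  seeded <- extend_interval(10L, "ACACAC", tref, "edit", 2)
  expect_identical(seeded$first, oracle2$first)
  expect_identical(seeded$last, oracle2$last)
  expect_identical(seeded$min_k, oracle2$min_k)
  # two seeds in the same class return the identical interval
  seeded2 <- extend_interval(24L, "ACACAC", tref, "edit", 2)
  strip <- function(x) { attr(x, "positions_touched") <- NULL; as.data.frame(x) }
  expect_identical(strip(seeded), strip(seeded2))
  # infeasible seed is rejected
  expect_error(extend_interval(2L, "ACACAC", tref, "edit", 0), "infeasible")
})

test_that("interval extension touches only a window around the class", {
  withr::with_seed(17, {
    ref <- random_dna(5000)
  })
  read <- substr(ref, 2001, 2030)
  m <- nchar(read)
  for (k in 0:2) {
    iv <- extend_interval(2029L, read, ref, "edit", k)
    touched <- attr(iv, "positions_touched")
    width <- iv$last - iv$first + 1L
    expect_lte(touched, width + 12L * (m + k))
  }
})

test_that("seeded building equals oracle building when seeds are complete", {
  withr::with_seed(29, {
    for (i in 1:6) {
      refs <- tibble::tibble(id = "c1", seq = random_dna(600))
      reads <- tibble::tibble(
        id = paste0("r", 1:5),
        seq = vapply(1:5, function(j) {
          s <- sample(1:580, 1)
          substr(refs$seq, s, s + sample(12:20, 1))
        }, character(1)))
      rate <- rate_for_k(2, min(nchar(reads$seq)))
      gs_o <- build_gold(refs, reads, model = "edit", max_error_rate = rate,
                         mode = "oracle")
      sam <- perfect_mapper_sam(gs_o, refs)
      gs_s <- build_gold(refs, reads, model = "edit", max_error_rate = rate,
                         mode = "seeded", seed_sam = sam)
      expect_identical(as.data.frame(tidy(gs_o)), as.data.frame(tidy(gs_s)))
      unlink(sam)
    }
  })
})

test_that("seeded building is idempotent under duplicate seeds and faithful to missing ones", {
  refs <- tibble::tibble(id = "chr", seq = "TTGACGTTTTACGTTT")
  reads <- tibble::tibble(id = "r1", seq = "ACGT")
  gs_o <- build_gold(refs, reads, model = "hamming", max_error_rate = 0)
  iv <- tidy(gs_o)
  fwd <- iv[iv$strand == "+", ]
  sam_dup <- tempfile(fileext = ".sam")
  dup <- fwd[c(1, 1, 2, 2, 2), ]
  write_sam(tibble::tibble(read_id = dup$read_id, contig_id = dup$contig_id,
                           strand = dup$strand, pos = dup$first,
                           cigar = "1M"), refs, sam_dup)
  sam_missing <- tempfile(fileext = ".sam")
  write_sam(tibble::tibble(read_id = fwd$read_id[1],
                           contig_id = fwd$contig_id[1],
                           strand = fwd$strand[1], pos = fwd$first[1],
                           cigar = "1M"), refs, sam_missing)
  gs_dup <- build_gold(refs, reads, model = "hamming", max_error_rate = 0,
                       mode = "seeded", seed_sam = sam_dup)
  gs_miss <- build_gold(refs, reads, model = "hamming", max_error_rate = 0,
                        mode = "seeded", seed_sam = sam_missing)
  expect_identical(as.data.frame(tidy(gs_dup)), as.data.frame(fwd))
  expect_identical(as.data.frame(tidy(gs_miss)), as.data.frame(fwd[1, ]))

  bad_contig <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "r1\t0\tnope\t6\t255\t1M\t*\t0\t0\t*\t*"),
             bad_contig)
  expect_error(build_gold(refs, reads, model = "hamming",
                          max_error_rate = 0, mode = "seeded",
                          seed_sam = bad_contig), "unknown contig")
  bad_read <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "zz\t0\tchr\t6\t255\t1M\t*\t0\t0\t*\t*"),
             bad_read)
  expect_error(build_gold(refs, reads, model = "hamming",
                          max_error_rate = 0, mode = "seeded",
                          seed_sam = bad_read), "unknown read")
})

test_that("min-k annotation equals the containment rule and the landscape depth", {
  withr::with_seed(37, {
    inst <- random_instance(8:16, 100:300)
    refs <- tibble::tibble(id = "c", seq = inst$ref)
    reads <- tibble::tibble(id = "r", seq = inst$read)
    rate <- rate_for_k(3, nchar(inst$read))
    gs <- build_gold(refs, reads, model = "edit", max_error_rate = rate)
    ann <- annotate_min_k(gs)
    expect_identical(ann$intervals$min_k, gs$intervals$min_k)
  })
})

test_that("GSI files round-trip losslessly and reject foreign content", {
  refs <- tibble::tibble(id = "chr", seq = "TTGACGTTTTACGTTT")
  reads <- tibble::tibble(id = "r1", seq = "ACGT")
  gs <- build_gold(refs, reads, model = "hamming",
                   max_error_rate = rate_for_k(1, 4))
  p <- tempfile(fileext = ".gsi")
  write_gsi(gs, p)
  back <- read_gsi(p)
  expect_identical(as.data.frame(tidy(back)), as.data.frame(tidy(gs)))
  expect_identical(back$model, gs$model)
  expect_equal(back$max_error_rate, gs$max_error_rate)

  # empty standard: header-only file
  gs0 <- build_gold(refs, tibble::tibble(id = "m", seq = "GGGG"),
                    model = "hamming", max_error_rate = 0)
  p0 <- tempfile(fileext = ".gsi")
  write_gsi(gs0, p0)
  expect_identical(length(readLines(p0)), 3L)
  expect_identical(nrow(tidy(read_gsi(p0))), 0L)

  # version / format rejection with a line number for body errors
  bad <- tempfile()
  writeLines(c("@SOMETHING-ELSE\tVERSION:9", "@MODEL:edit", "@RATE:0"), bad)
  expect_error(read_gsi(bad), "not a version-1 GSI")
  bad2 <- tempfile()
  writeLines(c("@MAPBENCH-GSI\tVERSION:1", "@MODEL:edit", "@RATE:0",
               "r1\tchr\t+\t0\t0\t5"), bad2)
  expect_error(read_gsi(bad2), "line 4")
})
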
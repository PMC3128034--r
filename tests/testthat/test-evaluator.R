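# Scoring in the all / all-best / any-best categories.
# (worked_example() lives in helper-fixtures.R)

test_that("a mapper reporting every class scores 100 in every category", {
  withr::with_seed(53, {
    refs <- tibble::tibble(id = "g", seq = paste0(random_dna(150),
                                                  strrep(random_dna(40), 3),
                                                  random_dna(150)))
    reads <- tibble::tibble(
      id = paste0("r", 1:4),
      seq = vapply(c(10, 120, 200, 300), function(s)
        substr(refs$seq, s, s + 14), character(1)))
  })
  rate <- rate_for_k(1, 15)
  gs <- build_gold(refs, reads, model = "edit", max_error_rate = rate)
  sam <- perfect_mapper_sam(gs, refs)
  rec <- parse_sam(sam, reads = reads)
  for (cat in c("all", "all_best", "any_best")) {
    res <- evaluate_mapping(gs, rec, reads, refs, category = cat,
                            rate = rate)
    expect_equal(res$normalized_found_intervals, 100)
    expect_identical(nrow(res$missed), 0L)
    expect_identical(nrow(res$unexpected), 0L)
  }
})

test_that("partial discovery scores by the 1/n-per-interval rule", {
  w <- worked_example()
  iv <- tidy(w$gs)
  one <- iv[iv$read_id == "one" & iv$strand == "+", ]
  two <- iv[iv$read_id == "two" & iv$strand == "+", ]
  expect_identical(nrow(one), 4L)
  expect_identical(nrow(two), 1L)
  # read one finds 2 of its 4 classes, read two finds its single class:
  # (0.5 + 1) / 2 reads = 75.0
  sam <- tempfile(fileext = ".sam")
  write_sam(tibble::tibble(
    read_id = c("one", "one", "two"),
    contig_id = "chr", strand = "+",
    pos = c(one$first[1:2], two$first[1]) - 9L,
    cigar = "10M"), w$refs, sam)
  rec <- parse_sam(sam, reads = w$reads)
  res <- evaluate_mapping(w$gs, rec, w$reads, w$refs, category = "all",
                          rate = 0)
  expect_equal(res$normalized_found_intervals, 75)
  expect_equal(res$points, 1.5)
  expect_identical(res$n_reads_scored, 2L)
  expect_identical(nrow(res$missed), 2L)
})

test_that("an empty SAM scores zero and misses every class", {
  w <- worked_example()
  sam <- tempfile(fileext = ".sam")
  write_sam(tibble::tibble(read_id = character(), contig_id = character(),
                           strand = character(), pos = integer(),
                           cigar = character()), w$refs, sam)
  rec <- parse_sam(sam, reads = w$reads)
  res <- evaluate_mapping(w$gs, rec, w$reads, w$refs, category = "all",
                          rate = 0)
  expect_equal(res$normalized_found_intervals, 0)
  expect_identical(nrow(res$missed), nrow(tidy(w$gs)))
  # report lists every missed class under a category header
  rp <- tempfile()
  report_missed(res, rp)
  lines <- readLines(rp)
  expect_match(lines[1], "CATEGORY:all")
  expect_identical(length(lines) - 1L, nrow(res$missed))
})

test_that("adding records never lowers the score, and any-best dominates all-best", {
  w <- worked_example()
  iv <- tidy(w$gs)
  full_sam <- perfect_mapper_sam(w$gs, w$refs)
  full <- parse_sam(full_sam, reads = w$reads)
  withr::with_seed(71, {
    for (trial in 1:5) {
      keep <- sort(sample(nrow(full), sample(0:nrow(full), 1)))
      sub <- full[keep, ]
      more <- full[sort(unique(c(keep, sample(nrow(full), 2)))), ]
      for (cat in c("all", "all_best", "any_best")) {
        a <- evaluate_mapping(w$gs, sub, w$reads, w$refs, cat, 0)
        b <- evaluate_mapping(w$gs, more, w$reads, w$refs, cat, 0)
        expect_gte(b$normalized_found_intervals,
                   a$normalized_found_intervals)
      }
      ab <- evaluate_mapping(w$gs, sub, w$reads, w$refs, "all_best", 0)
      an <- evaluate_mapping(w$gs, sub, w$reads, w$refs, "any_best", 0)
      expect_gte(an$normalized_found_intervals,
                 ab$normalized_found_intervals)
    }
  })
})

test_that("records at absorbed separating positions are neither hits nor unexpected", {
  inst <- absorbed_instance()
  refs <- tibble::tibble(id = "c", seq = inst$ref)
  reads <- tibble::tibble(id = "r", seq = inst$read)
  rate <- rate_for_k(inst$k, nchar(inst$read))
  gs <- build_gold(refs, reads, model = "edit", max_error_rate = rate)
  iv <- tidy(gs)
  target <- iv[iv$k == inst$k & iv$strand == "+" &
                 iv$first == inst$first, ]
  expect_identical(target$last, inst$last)
  expect_gt(distance_at(inst$read, inst$ref, "edit", inst$separating),
            inst$k)
  sam <- tempfile(fileext = ".sam")
  write_sam(tibble::tibble(read_id = "r", contig_id = "c", strand = "+",
                           pos = inst$separating, cigar = "1M"),
            refs, sam)
  rec <- parse_sam(sam, reads = reads)
  res <- evaluate_mapping(gs, rec, reads, refs, "all", rate)
  expect_identical(nrow(res$absorbed), 1L)
  expect_identical(nrow(res$unexpected), 0L)
  expect_identical(sum(res$per_read$n_hit), 0L)
})

test_that("infeasible stray records are reported as unexpected", {
  w <- worked_example()
  sam <- tempfile(fileext = ".sam")
  write_sam(tibble::tibble(read_id = "two", contig_id = "chr", strand = "+",
                           pos = 0L, cigar = "10M"), w$refs, sam)
  rec <- parse_sam(sam, reads = w$reads)
  res <- evaluate_mapping(w$gs, rec, w$reads, w$refs, "all", 0)
  expect_identical(nrow(res$unexpected), 1L)
  expect_match(res$unexpected$reason, "infeasible")
})

test_that("evaluating beyond the gold standard's rate is an error", {
  w <- worked_example()
  sam <- perfect_mapper_sam(w$gs, w$refs)
  rec <- parse_sam(sam, reads = w$reads)
  expect_error(
    evaluate_mapping(w$gs, rec, w$reads, w$refs, "all", rate = 50),
    "exceeds")
})

test_that("evaluation results tidy, glance and plot", {
  w <- worked_example()
  sam <- perfect_mapper_sam(w$gs, w$refs)
  rec <- parse_sam(sam, reads = w$reads)
  res <- evaluate_mapping(w$gs, rec, w$reads, w$refs, "all", 0)
  td <- tidy(res)
  expect_identical(nrow(td), 2L)
  g <- glance(res)
  expect_identical(g$category, "all")
  expect_equal(g$normalized_found_intervals, 100)
  expect_s3_class(autoplot(res), "ggplot")
})
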
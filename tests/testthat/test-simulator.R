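# Haplotype simulation, read sampling, origin SAM.

test_that("zero rates reproduce the reference and exact reads", {
  withr::with_seed(2, {
    ref <- random_dna(3000)
  })
  cfg <- sim_config(n_reads = 50, read_length = 30, snp_rate = 0,
                    indel_rate = 0, mismatch_rate_begin = 0,
                    mismatch_rate_end = 0, rng_seed = 4)
  withr::with_seed(4, {
    hap <- simulate_haplotype(ref, cfg)
  })
  expect_identical(hap$seq, ref)
  expect_identical(nrow(hap$log), 0L)
  expect_identical(hap$map, 0:(nchar(ref) - 1L))

  sim <- simulate_reads(c(chr = ref), cfg)
  expect_identical(sum(sim$origins$n_errors), 0L)
  expect_true(all(sim$origins$cigar == "30M"))
  for (i in seq_len(10)) {
    o <- sim$origins[i, ]
    rd <- sim$reads$seq[sim$reads$id == o$read_id]
    if (o$strand == "-") rd <- reverse_complement(rd)
    expect_identical(substr(ref, o$ref_begin + 1, o$ref_end + 1), rd)
  }
})

test_that("saturating SNP rate changes every base", {
  withr::with_seed(6, {
    ref <- random_dna(500)
    cfg <- sim_config(snp_rate = 1, indel_rate = 0)
    hap <- simulate_haplotype(ref, cfg)
  })
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(hap$seq, "")[[1]]
  expect_identical(length(b), length(a))
  expect_true(all(a != b))
})

test_that("realized rates match configured rates within binomial noise", {
  n <- 100000L
  withr::with_seed(8, {
    ref <- random_dna(n)
    cfg <- sim_config(snp_rate = 0.01, indel_rate = 0)
    hap <- simulate_haplotype(ref, cfg)
  })
  snps <- sum(hap$log$type == "snp")
  expect_lt(abs(snps - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))

  # sequencing mismatch ramp: mean errors per read = mean(ramp) * length
  cfg2 <- sim_config(n_reads = 4000, read_length = 36, snp_rate = 0,
                     indel_rate = 0, mismatch_rate_begin = 0.01,
                     mismatch_rate_end = 0.05, rng_seed = 12)
  sim <- simulate_reads(c(chr = withr::with_seed(9, random_dna(5000))),
                        cfg2)
  expected <- 4000 * 36 * mean(c(0.01, 0.05))
  observed <- sum(sim$origins$n_errors)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("simulation is byte-reproducible under a fixed seed", {
  refs <- tibble::tibble(id = "chr",
                         seq = withr::with_seed(14, random_dna(4000)))
  cfg <- sim_config(n_reads = 200, read_length = 25, rng_seed = 77)
  a <- simulate_reads(refs, cfg)
  b <- simulate_reads(refs, cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$origins, b$origins)
  fa <- tempfile(); fb <- tempfile()
  write_fastq(a$reads, fa); write_fastq(b$reads, fb)
  sa <- tempfile(); sb <- tempfile()
  write_origin_sam(a$origins, a$reads, refs, sa)
  write_origin_sam(b$origins, b$reads, refs, sb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(readLines(sa), readLines(sb))
})

test_that("origin SAM round-trips end positions on both strands", {
  refs <- tibble::tibble(id = "chr",
                         seq = withr::with_seed(16, random_dna(4000)))
  cfg <- sim_config(n_reads = 100, read_length = 30, snp_rate = 0.002,
                    indel_rate = 5e-4, rng_seed = 21)
  sim <- simulate_reads(refs, cfg)
  sam <- tempfile(fileext = ".sam")
  write_origin_sam(sim$origins, sim$reads, refs, sam)
  rec <- parse_sam(sam, reads = sim$reads)
  merged <- merge(rec, sim$origins, by = "read_id")
  expect_identical(nrow(merged), nrow(sim$origins))
  expect_identical(merged$end, merged$ref_end)
  expect_identical(merged$pos, merged$ref_begin)
  expect_identical(merged$strand.x, merged$strand.y)
  expect_true(any(sim$origins$strand == "-"))
})

test_that("origin end positions are feasible at the sequencing error count", {
  refs <- tibble::tibble(id = "chr",
                         seq = withr::with_seed(18, random_dna(6000)))
  cfg <- sim_config(n_reads = 120, read_length = 36, snp_rate = 0,
                    indel_rate = 0, mismatch_rate_begin = 0.02,
                    mismatch_rate_end = 0.08, rng_seed = 31)
  sim <- simulate_reads(refs, cfg)
  for (i in seq_len(nrow(sim$origins))) {
    o <- sim$origins[i, ]
    rd <- sim$reads$seq[sim$reads$id == o$read_id]
    if (o$strand == "-") rd <- reverse_complement(rd)
    d <- distance_at(rd, refs$seq, "edit", o$ref_end)
    expect_lte(d, o$n_errors)
  }
})

test_that("the longread profile emits indel CIGARs consistent with coordinates", {
  refs <- tibble::tibble(id = "chr",
                         seq = withr::with_seed(19, random_dna(8000)))
  cfg <- sim_config(profile = "longread", n_reads = 40, length_mean = 300,
                    length_sd = 30, snp_rate = 0, indel_rate = 0,
                    mismatch_rate_begin = 0.005,
                    indel_error_rate = 0.01, rng_seed = 41)
  sim <- simulate_reads(refs, cfg)
  expect_true(any(grepl("[ID]", sim$origins$cigar)))
  sam <- tempfile(fileext = ".sam")
  write_origin_sam(sim$origins, sim$reads, refs, sam)
  rec <- parse_sam(sam, reads = sim$reads)
  merged <- merge(rec, sim$origins, by = "read_id")
  expect_identical(merged$end, merged$ref_end)
  # read length equals the query-consuming CIGAR width
  w <- GenomicAlignments::cigarWidthAlongQuerySpace(merged$cigar.x)
  expect_identical(nchar(sim$reads$seq[match(merged$read_id,
                                             sim$reads$id)]), w)
  # origins remain feasible at the logged error count under edit distance
  for (i in seq_len(20)) {
    o <- sim$origins[i, ]
    rd <- sim$reads$seq[sim$reads$id == o$read_id]
    if (o$strand == "-") rd <- reverse_complement(rd)
    d <- distance_at(rd, refs$seq, "edit", o$ref_end)
    expect_lte(d, o$n_errors)
  }
})
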
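# Haplotype and read simulation for the biological benchmark problem.
#
# A deliberately small error model: haplotypes are derived from the
# reference by independent per-base SNPs and indels; reads are sampled
# uniformly from the haplotypes on both strands. The "illumina" profile
# applies a linear substitution-rate ramp along the read and no indels; the
# "longread" profile draws Gaussian read lengths and applies flat
# substitution and indel error rates. This is not a calibrated model of any
# instrument -- it provides controllable error structure so that simulated
# origins can be tied to the mathematical gold standard.

#' Simulation configuration
#'
#' @param profile `"illumina"` (fixed-length reads, substitution-only
#'   errors with a linear rate ramp along the read) or `"longread"`
#'   (Gaussian length distribution, flat substitution + indel error rates).
#' @param n_reads Number of reads to sample.
#' @param read_length Read length for the illumina profile.
#' @param length_mean,length_sd Length distribution for the longread
#'   profile.
#' @param n_haplotypes Haplotypes simulated per contig.
#' @param snp_rate Per-base haplotype SNP probability.
#' @param indel_rate Per-base haplotype indel probability.
#' @param indel_size_range Inclusive range of haplotype indel sizes.
#' @param mismatch_rate_begin,mismatch_rate_end Sequencing substitution
#'   probability at the first/last base (illumina ramp; the longread
#'   profile uses `mismatch_rate_begin` flat).
#' @param indel_error_rate Per-base sequencing indel probability (longread
#'   only).
#' @param rng_seed Integer seed; [simulate_reads()] is byte-reproducible
#'   under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(profile = c("illumina", "longread"),
                       n_reads = 10000L, read_length = 36L,
                       length_mean = 400, length_sd = 40,
                       n_haplotypes = 1L,
                       snp_rate = 0.001, indel_rate = 1e-4,
                       indel_size_range = c(1L, 6L),
                       mismatch_rate_begin = 0.002,
                       mismatch_rate_end = 0.02,
                       indel_error_rate = 0.005,
                       rng_seed = 1L) {
  profile <- match.arg(profile)
  probs <- c(snp_rate, indel_rate, mismatch_rate_begin, mismatch_rate_end,
             indel_error_rate)
  if (any(probs < 0 | probs > 1)) abort("rates must be probabilities in [0, 1]")
  if (n_reads < 1L) abort("n_reads must be >= 1")
  structure(list(profile = profile, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 length_mean = length_mean, length_sd = length_sd,
                 n_haplotypes = as.integer(n_haplotypes),
                 snp_rate = snp_rate, indel_rate = indel_rate,
                 indel_size_range = as.integer(indel_size_range),
                 mismatch_rate_begin = mismatch_rate_begin,
                 mismatch_rate_end = mismatch_rate_end,
                 indel_error_rate = indel_error_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

# substitute each base by a uniformly chosen different base (N -> random)
.mutate_bases <- function(chars) {
  idx <- match(chars, .BASES)
  idx[is.na(idx)] <- sample.int(4L, sum(is.na(idx)), replace = TRUE)
  .BASES[1L + (idx - 1L + sample.int(3L, length(chars), replace = TRUE)) %% 4L]
}

#' Simulate one haplotype from a reference contig
#'
#' Applies independent per-base SNPs (uniform over the three alternative
#' bases) and indels (size uniform in the configured range, insertion bases
#' uniform) to the contig. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param ref A single contig sequence.
#' @param config A [sim_config()].
#' @return A list with `seq` (haplotype sequence), `map` (0-based reference
#'   coordinate of every haplotype base, `NA` for inserted bases), and
#'   `log` (variant tibble with `type`, `ref_pos`, `size`, `alt`).
#' @export
simulate_haplotype <- function(ref, config) {
  chars <- strsplit(ref, "")[[1]]
  n <- length(chars)
  log <- list()

  snp_pos <- which(runif(n) < config$snp_rate)
  if (length(snp_pos)) {
    alt <- .mutate_bases(chars[snp_pos])
    chars[snp_pos] <- alt
    log[[1L]] <- tibble(type = "snp", ref_pos = snp_pos - 1L, size = 1L,
                        alt = alt)
  }

  ev_pos <- which(runif(n) < config$indel_rate)
  del_mask <- rep(FALSE, n)
  ins_at <- integer(); ins_seq <- character()
  if (length(ev_pos)) {
    is_ins <- runif(length(ev_pos)) < 0.5
    sizes <- sample(config$indel_size_range[1]:config$indel_size_range[2],
                    length(ev_pos), replace = TRUE)
    last_del_end <- -1L
    for (i in seq_along(ev_pos)) {
      p <- ev_pos[i]
      if (p <= last_del_end) next           # inside an earlier deletion
      if (is_ins[i]) {
        s <- paste(sample(.BASES, sizes[i], replace = TRUE), collapse = "")
        ins_at <- c(ins_at, p); ins_seq <- c(ins_seq, s)
        log[[length(log) + 1L]] <-
          tibble(type = "ins", ref_pos = p - 1L, size = sizes[i], alt = s)
      } else {
        to <- min(n, p + sizes[i] - 1L)
        del_mask[p:to] <- TRUE
        last_del_end <- to
        log[[length(log) + 1L]] <-
          tibble(type = "del", ref_pos = p - 1L, size = to - p + 1L,
                 alt = NA_character_)
      }
    }
  }

  keep <- !del_mask
  hap_chars <- chars[keep]
  map <- (seq_len(n) - 1L)[keep]
  if (length(ins_at)) {
    # insert before reference position p (1-based), i.e. after the kept
    # bases with reference coordinate < p - 1
    ord <- order(ins_at, decreasing = TRUE)
    for (i in ord) {
      at <- sum(map < ins_at[i] - 1L, na.rm = TRUE)
      piece <- strsplit(ins_seq[i], "")[[1]]
      hap_chars <- append(hap_chars, piece, after = at)
      map <- append(map, rep(NA_integer_, length(piece)), after = at)
    }
  }
  list(seq = paste(hap_chars, collapse = ""), map = map,
       log = if (length(log)) bind_rows(log) else
         tibble(type = character(), ref_pos = integer(), size = integer(),
                alt = character()))
}

# per-read-position substitution probability
.ramp <- function(config, len) {
  if (config$profile == "illumina") {
    if (len == 1L) return(config$mismatch_rate_begin)
    config$mismatch_rate_begin +
      (config$mismatch_rate_end - config$mismatch_rate_begin) *
      (seq_len(len) - 1L) / (len - 1L)
  } else rep(config$mismatch_rate_begin, len)
}

.phred_chars <- function(p) {
  q <- pmin(41L, pmax(2L, as.integer(round(-10 * log10(pmax(p, 1e-5))))))
  paste(intToUtf8(q + 33L, multiple = TRUE), collapse = "")
}

#' Sample reads from simulated haplotypes
#'
#' Start positions and strands are uniform; reads lie fully inside the
#' haplotype. Sequencing errors follow the configured profile; per-base
#' qualities are the Phred encoding of the per-position error probability.
#' Origins are projected back to reference coordinates through the
#' haplotype variant map (`ref_end` is the rightmost reference base the
#' alignment consumes).
#'
#' @param haps List of haplotypes as returned by [simulate_haplotype()],
#'   each additionally carrying `contig_id` and `hap_id` fields (see
#'   [simulate_reads()]).
#' @param config A [sim_config()].
#' @return A list with `reads` (tibble `id`, `seq`, `qual`) and `origins`
#'   (tibble `read_id`, `haplotype_id`, `contig_id`, `strand`, `ref_begin`,
#'   `ref_end`, `n_errors`, `cigar`).
#' @export
sample_reads <- function(haps, config) {
  nh <- length(haps)
  hap_len <- vapply(haps, function(h) nchar(h$seq), integer(1))
  nr <- config$n_reads
  out_seq <- character(nr); out_qual <- character(nr)
  org <- vector("list", nr)

  hap_idx <- sample.int(nh, nr, replace = TRUE)
  strand <- ifelse(runif(nr) < 0.5, "+", "-")
  lens <- if (config$profile == "illumina") rep(config$read_length, nr) else
    pmax(10L, as.integer(round(rnorm(nr, config$length_mean,
                                     config$length_sd))))
  lens <- pmin(lens, hap_len[hap_idx])
  hb <- vapply(seq_len(nr), function(i) {
    as.integer(floor(runif(1, 0, hap_len[hap_idx[i]] - lens[i] + 1)))
  }, integer(1))

  for (i in seq_len(nr)) {
    h <- haps[[hap_idx[i]]]
    res <- .simulate_one_read(h, hb[i], lens[i], strand[i], config)
    out_seq[i] <- res$seq; out_qual[i] <- res$qual
    org[[i]] <- tibble(
      haplotype_id = h$hap_id, contig_id = h$contig_id, strand = strand[i],
      ref_begin = res$ref_begin, ref_end = res$ref_end,
      n_errors = res$n_errors, cigar = res$cigar)
  }
  ids <- sprintf("sim_%06d", seq_len(nr))
  origins <- bind_rows(org)
  origins$read_id <- ids
  list(
    reads = tibble(id = ids, seq = out_seq, qual = out_qual),
    origins = select(origins, "read_id", "haplotype_id", "contig_id",
                     "strand", "ref_begin", "ref_end", "n_errors", "cigar")
  )
}

# one read sampled at haplotype span [hb, hb+len-1] (0-based)
.simulate_one_read <- function(h, hb, len, strand, config) {
  he <- hb + len - 1L
  span_map <- h$map[(hb + 1L):(he + 1L)]
  p_read <- .ramp(config, len)
  # error probabilities in haplotype orientation
  p_hap <- if (strand == "-") rev(p_read) else p_read
  chars <- strsplit(substr(h$seq, hb + 1L, he + 1L), "")[[1]]

  use_indels <- config$profile == "longread" && config$indel_error_rate > 0
  sub_mask <- runif(len) < p_hap
  n_err <- sum(sub_mask)
  if (any(sub_mask)) chars[sub_mask] <- .mutate_bases(chars[sub_mask])

  contiguous <- !anyNA(span_map) &&
    span_map[len] - span_map[1L] == len - 1L

  if (!use_indels && contiguous) {
    cigar <- sprintf("%dM", len)
    ref_begin <- span_map[1L]; ref_end <- span_map[len]
    emitted <- chars; p_emit <- p_hap
  } else {
    # column walk: ops over haplotype positions, then projection to the
    # reference through the variant map
    ops <- character(0); bases <- character(0); refc <- integer(0)
    p_emit <- numeric(0)
    for (j in seq_len(len)) {
      if (use_indels && runif(1) < config$indel_error_rate) {
        if (runif(1) < 0.5) {                       # read insertion
          ops <- c(ops, "I"); bases <- c(bases, sample(.BASES, 1L))
          refc <- c(refc, NA_integer_); p_emit <- c(p_emit, p_hap[j])
          n_err <- n_err + 1L
        } else {                                    # haplotype base dropped
          ops <- c(ops, "D"); bases <- c(bases, NA_character_)
          refc <- c(refc, span_map[j])
          n_err <- n_err + 1L
          next
        }
      }
      ops <- c(ops, "M"); bases <- c(bases, chars[j])
      refc <- c(refc, span_map[j]); p_emit <- c(p_emit, p_hap[j])
    }
    # project: M/D on inserted haplotype bases (NA map) become I / vanish
    proj_ops <- character(0); proj_bases <- character(0)
    proj_ref <- integer(0); proj_p <- numeric(0)
    last_ref <- NA_integer_
    for (t in seq_along(ops)) {
      op <- ops[t]; rc <- refc[t]
      if (op == "M" && is.na(rc)) op <- "I"
      if (op == "D" && is.na(rc)) next
      if (op != "I" && !is.na(last_ref) && rc > last_ref + 1L) {
        gap <- (last_ref + 1L):(rc - 1L)            # reference bases deleted
        proj_ops <- c(proj_ops, rep("D", length(gap)))
        proj_bases <- c(proj_bases, rep(NA_character_, length(gap)))
        proj_ref <- c(proj_ref, gap); proj_p <- c(proj_p, rep(NA_real_, length(gap)))
      }
      proj_ops <- c(proj_ops, op); proj_bases <- c(proj_bases, bases[t])
      proj_ref <- c(proj_ref, rc)
      proj_p <- c(proj_p, if (op == "D") NA_real_ else p_emit[t])
      if (op != "I") last_ref <- rc
    }
    mpos <- which(proj_ops == "M")
    if (!length(mpos)) {
      # read fell entirely into inserted sequence; emit a degenerate,
      # reference-less record anchored at the nearest mapped base
      anchor <- span_map[which(!is.na(span_map))[1L]]
      if (length(anchor) == 0L || is.na(anchor)) anchor <- 0L
      seq_hap <- paste(chars, collapse = "")
      sq <- if (strand == "-") reverse_complement(seq_hap) else seq_hap
      ql <- .phred_chars(if (strand == "-") rev(p_hap) else p_hap)
      return(list(seq = sq, qual = ql, ref_begin = anchor, ref_end = anchor,
                  n_errors = n_err, cigar = sprintf("%dI", length(chars))))
    }
    keep <- seq(min(mpos), max(mpos))               # trim flanking I/D
    proj_ops <- proj_ops[keep]; proj_bases <- proj_bases[keep]
    proj_ref <- proj_ref[keep]; proj_p <- proj_p[keep]
    ref_begin <- min(proj_ref[proj_ops != "I"], na.rm = TRUE)
    ref_end <- max(proj_ref[proj_ops != "I"], na.rm = TRUE)
    r <- rle(proj_ops)
    cigar <- paste0(r$lengths, r$values, collapse = "")
    emit_sel <- proj_ops != "D"
    emitted <- proj_bases[emit_sel]; p_emit <- proj_p[emit_sel]
  }

  seq_hap <- paste(emitted, collapse = "")
  if (strand == "-") {
    list(seq = reverse_complement(seq_hap),
         qual = .phred_chars(rev(p_emit)),
         ref_begin = ref_begin, ref_end = ref_end, n_errors = n_err,
         cigar = cigar)
  } else {
    list(seq = seq_hap, qual = .phred_chars(p_emit),
         ref_begin = ref_begin, ref_end = ref_end, n_errors = n_err,
         cigar = cigar)
  }
}

#' Simulate haplotypes and reads from a reference
#'
#' End-to-end driver: simulates `n_haplotypes` per contig, samples reads,
#' and returns reads, origins and haplotypes. Byte-reproducible for a given
#' `config$rng_seed`.
#'
#' @param refs Reference tibble (`id`, `seq`), named character vector or
#'   FASTA path.
#' @param config A [sim_config()].
#' @return List with `reads`, `origins` (see [sample_reads()]) and
#'   `haplotypes`.
#' @export
simulate_reads <- function(refs, config) {
  refs <- load_seqs(refs)
  withr::with_seed(config$rng_seed, {
    haps <- list()
    for (ci in seq_len(nrow(refs))) {
      for (hi in seq_len(config$n_haplotypes)) {
        h <- simulate_haplotype(refs$seq[ci], config)
        h$contig_id <- refs$id[ci]
        h$hap_id <- sprintf("%s_hap%d", refs$id[ci], hi)
        haps[[length(haps) + 1L]] <- h
      }
    }
    res <- sample_reads(haps, config)
    res$haplotypes <- haps
    res
  })
}

#' Write simulated read origins as a SAM file
#'
#' One record per read; POS/CIGAR encode the origin alignment projected to
#' reference coordinates. The file doubles as the biological-problem gold
#' standard: parsed back with [parse_sam()] it recovers each origin's end
#' position, usable both as seeds for [build_gold()] and as the output of a
#' perfect "biological" mapper for [evaluate_mapping()].
#'
#' @param origins,reads Tables from [simulate_reads()].
#' @param refs Reference table for the SAM header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origin_sam <- function(origins, reads, refs, path) {
  refs <- load_seqs(refs)
  seqs <- setNames(reads$seq, reads$id)[origins$read_id]
  quals <- if ("qual" %in% names(reads))
    setNames(reads$qual, reads$id)[origins$read_id] else
      rep("*", nrow(origins))
  rev <- origins$strand == "-"
  seqs[rev] <- reverse_complement(seqs[rev])
  quals[rev] <- vapply(quals[rev], function(q)
    paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
  write_sam(tibble(read_id = origins$read_id, contig_id = origins$contig_id,
                   strand = origins$strand, pos = origins$ref_begin,
                   cigar = origins$cigar, seq = unname(seqs),
                   qual = unname(quals)),
            refs, path)
}
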
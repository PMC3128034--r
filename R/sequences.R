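#' Read a (multi-)FASTA file into a sequence table
#'
#' Sequences are uppercased on input; ids are the first whitespace-delimited
#' token of each header line.
#'
#' @param path Path to a FASTA file (line-wrapped and multi-contig allowed).
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    id  = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L),
    seq = toupper(as.character(x))
  )
}

#' Read a FASTQ file into a sequence table
#'
#' Base qualities are parsed but not used by any distance computation; they
#' are retained for round-tripping only.
#'
#' @param path Path to a FASTQ file (Sanger/Phred+33 qualities).
#' @return A tibble with columns `id`, `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    id   = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L),
    seq  = toupper(as.character(x)),
    qual = as.character(Biostrings::quality(x))
  )
}

#' Write a sequence table to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a sequence table to FASTQ
#'
#' If no `qual` column is present, a constant high quality is emitted.
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  qual <- if ("qual" %in% names(seqs)) seqs$qual else
    vapply(nchar(seqs$seq), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", seqs$id, "\n", seqs$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' `N` is self-complementary; characters outside `A`, `C`, `G`, `T`, `N`
#' are rejected.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AACG") # "CGTT"
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    abort(sprintf("sequence contains characters outside {A,C,G,T,N}: %s",
                  seq[which(bad)[1]]))
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
         USE.NAMES = FALSE)
}

check_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    abort(sprintf("%s must be a single non-empty string", what))
  if (grepl("[^ACGTN]", seq))
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", what))
  invisible(seq)
}
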
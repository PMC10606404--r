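#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased on read (soft-masking is ignored throughout the
#' pipeline) and record names are truncated to the first whitespace-delimited
#' word of the header, which is the identifier every other component keys on.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_io("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort_format("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  names(x) <- sub("\\s.*$", "", names(x))
  bad <- !nzchar(names(x))
  if (any(bad)) abort_format("FASTA '", path, "' has a record with an empty id")
  x
}

#' Write sequences to a FASTA file
#'
#' @param x A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param line_width Bases per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 60) {
  assert_that(line_width >= 1, "line_width must be >= 1")
  x <- as_dna(x)
  Biostrings::writeXStringSet(x, path, width = line_width)
  invisible(path)
}

#' Read a FASTQ file, discarding quality strings
#'
#' The pipeline is sequence-only: qualities are never consumed, so reads are
#' returned as a plain [Biostrings::DNAStringSet]. Records must be strict
#' 4-line FASTQ; a truncated trailing record is a format error.
#'
#' @param path Path to a FASTQ file.
#' @return A [Biostrings::DNAStringSet] named by read id.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort_io("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(Biostrings::DNAStringSet())
  if (length(lines) %% 4 != 0)
    abort_format("FASTQ '", path, "': truncated record (line count ", length(lines),
                 " is not a multiple of 4)")
  hdr <- lines[seq(1, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  if (!all(startsWith(hdr, "@")) || !all(startsWith(plus, "+")))
    abort_format("FASTQ '", path, "': record header or separator line malformed")
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as 4-line FASTQ with uniform placeholder qualities
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  x <- as_dna(x)
  seqs <- as.character(x)
  lines <- as.vector(rbind(paste0("@", names(x)), seqs, "+",
                           vapply(nchar(seqs), function(n) strrep("I", n), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of DNA sequences over {A,C,G,T,N}
#'
#' An involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param x A character vector or [Biostrings::DNAStringSet].
#' @return Same type as the input.
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    bad <- grepl("[^ACGTN]", x)
    if (any(bad)) abort("reverse_complement: sequence contains characters outside {A,C,G,T,N}")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    Biostrings::reverseComplement(x)
  }
}

#' Coerce a named character vector (or DNAStringSet) to DNAStringSet
#' @noRd
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    names(out) <- names(x)
    return(out)
  }
  abort("cannot coerce object of class ", paste(class(x), collapse = "/"),
        " to DNAStringSet")
}
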
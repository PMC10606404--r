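#' Alignment tables
#'
#' Alignments are kept as plain data frames with one row per PAF record and
#' columns `query_id`, `query_len`, `query_start`, `query_end`, `strand`,
#' `target_id`, `target_len`, `target_start`, `target_end`,
#' `residue_matches`, `block_len`, `mapq`, `tp` (the `tp:A` primary/secondary
#' flag, `NA` when absent) and `tags` (a list column of named character
#' vectors holding any further SAM-style tags). All coordinates are 0-based
#' half-open, the native PAF convention, which is also the convention used
#' everywhere inside this package.
#'
#' @param query_id,target_id Sequence identifiers.
#' @param query_len,target_len Full sequence lengths in bp.
#' @param query_start,query_end,target_start,target_end 0-based half-open
#'   intervals. For strand `-` the query interval is still expressed on the
#'   forward query strand, as in PAF.
#' @param strand `"+"` or `"-"`.
#' @param residue_matches Number of matching bases in the alignment.
#' @param block_len Alignment block length (>= residue_matches).
#' @param mapq Mapping quality, 0-255.
#' @param tp `tp:A` flag value (`"P"`, `"S"`, ...) or `NA`.
#' @param tags List of named character vectors of extra tags.
#' @return A data frame of alignment records.
#' @export
alignment_table <- function(query_id = character(), query_len = integer(),
                            query_start = integer(), query_end = integer(),
                            strand = character(), target_id = character(),
                            target_len = integer(), target_start = integer(),
                            target_end = integer(), residue_matches = integer(),
                            block_len = integer(), mapq = integer(),
                            tp = NA_character_, tags = NULL) {
  n <- length(query_id)
  df <- data.frame(
    query_id = as.character(query_id), query_len = as.integer(query_len),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    strand = as.character(strand), target_id = as.character(target_id),
    target_len = as.integer(target_len), target_start = as.integer(target_start),
    target_end = as.integer(target_end),
    residue_matches = as.integer(residue_matches),
    block_len = as.integer(block_len), mapq = as.integer(mapq),
    tp = rep_len(as.character(tp), n),
    stringsAsFactors = FALSE
  )
  df$tags <- if (is.null(tags)) rep(list(character()), n) else tags
  bad <- alignment_invariant_violations(df)
  if (any(bad)) abort("alignment records violate coordinate invariants at rows: ",
                      paste(which(bad), collapse = ", "))
  df
}

#' Which rows of an alignment table violate the record invariants
#' @noRd
alignment_invariant_violations <- function(df) {
  !(df$query_start >= 0 & df$query_start < df$query_end &
      df$query_end <= df$query_len &
      df$target_start >= 0 & df$target_start < df$target_end &
      df$target_end <= df$target_len &
      df$residue_matches <= df$block_len &
      df$strand %in% c("+", "-") &
      df$mapq >= 0 & df$mapq <= 255)
}

#' Parse a PAF alignment file
#'
#' Reads the 12 mandatory tab-separated PAF columns plus any trailing
#' `TAG:TYPE:VALUE` fields (the minimap2 dialect; the `tp:A` flag is lifted
#' into its own column). Rows violating the coordinate invariants (empty
#' intervals, out-of-bounds coordinates, `residue_matches > block_len`) are
#' dropped with a warning naming their line numbers.
#'
#' @param path Path to a PAF file.
#' @return An alignment data frame (see [alignment_table()]).
#' @export
parse_paf <- function(path) {
  if (!file.exists(path)) abort_io("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(alignment_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12))
    abort_format("PAF '", path, "': line ", which(nf < 12)[1],
                 " has fewer than 12 columns")
  col <- function(i) vapply(fields, `[[`, "", i)
  int_col <- function(i, what) {
    v <- col(i)
    iv <- suppressWarnings(as.integer(v))
    if (anyNA(iv))
      abort_format("PAF '", path, "': non-integer ", what, " at line ",
                   which(is.na(iv))[1])
    iv
  }
  tags <- lapply(fields, function(f) {
    if (length(f) <= 12) return(character())
    extra <- f[-(1:12)]
    m <- regmatches(extra, regexec("^([A-Za-z][A-Za-z0-9]):([AifZHB]):(.*)$", extra))
    ok <- lengths(m) == 4
    vals <- vapply(m[ok], `[[`, "", 4)
    names(vals) <- vapply(m[ok], `[[`, "", 2)
    vals
  })
  tp <- vapply(tags, function(t) if ("tp" %in% names(t)) t[["tp"]] else NA_character_, "")
  df <- data.frame(
    query_id = col(1), query_len = int_col(2, "query length"),
    query_start = int_col(3, "query start"), query_end = int_col(4, "query end"),
    strand = col(5), target_id = col(6), target_len = int_col(7, "target length"),
    target_start = int_col(8, "target start"), target_end = int_col(9, "target end"),
    residue_matches = int_col(10, "residue matches"),
    block_len = int_col(11, "block length"), mapq = int_col(12, "mapping quality"),
    tp = tp, stringsAsFactors = FALSE
  )
  df$tags <- tags
  bad <- alignment_invariant_violations(df)
  if (any(bad)) {
    warning("PAF '", path, "': dropped ", sum(bad),
            " record(s) violating coordinate invariants at line(s): ",
            paste(which(bad), collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write an alignment table as PAF
#'
#' @param aln An alignment data frame (see [alignment_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(aln, path) {
  tag_strs <- vapply(seq_len(nrow(aln)), function(i) {
    t <- aln$tags[[i]]
    if (!is.na(aln$tp[i]) && !("tp" %in% names(t))) t <- c(t, tp = aln$tp[i])
    if (length(t) == 0) return("")
    typed <- vapply(names(t), function(nm) {
      ty <- if (nm == "tp") "A" else if (grepl("^-?[0-9]+$", t[[nm]])) "i" else "Z"
      paste(nm, ty, t[[nm]], sep = ":")
    }, "")
    paste0("\t", paste(typed, collapse = "\t"))
  }, "")
  core <- aln[, c("query_id", "query_len", "query_start", "query_end", "strand",
                  "target_id", "target_len", "target_start", "target_end",
                  "residue_matches", "block_len", "mapq")]
  lines <- paste0(do.call(paste, c(unname(as.list(core)), sep = "\t")), tag_strs)
  writeLines(lines, path)
  invisible(path)
}
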
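BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Build a gene status table from per-hit columns
#'
#' A gene status table is the internal form of a completeness-assessor
#' report: one row per hit with columns `gene_id`, `status` (Complete,
#' Duplicated, Fragmented or Missing), `sequence_id`, `start`, `end`
#' (0-based half-open), `strand`, `score` and `length`. Location columns are
#' `NA` exactly for Missing rows. A gene reported Complete on several rows
#' is reclassified Duplicated so that Complete always means a unique
#' placement.
#'
#' @param gene_id,status,sequence_id,start,end,strand,score,length Per-hit
#'   columns, recycled to a common length.
#' @return A data frame of class `gene_status_table`.
#' @export
gene_status_table <- function(gene_id, status, sequence_id = NA_character_,
                              start = NA_integer_, end = NA_integer_,
                              strand = NA_character_, score = NA_real_,
                              length = NA_integer_) {
  n <- base::length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    status = as.character(status),
    sequence_id = rep_len(as.character(sequence_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    score = rep_len(as.numeric(score), n),
    length = rep_len(as.integer(length), n),
    stringsAsFactors = FALSE
  )
  bad_status <- setdiff(unique(df$status), BUSCO_STATUSES)
  if (base::length(bad_status) > 0)
    abort_format("unknown gene status word(s): ", paste(bad_status, collapse = ", "))
  # a gene reported Complete more than once is by definition Duplicated
  if (n > 0) {
    comp <- df$status == "Complete"
    multi <- names(which(table(df$gene_id[comp]) > 1))
    df$status[comp & df$gene_id %in% multi] <- "Duplicated"
  }
  miss <- df$status == "Missing"
  df$sequence_id[miss] <- NA_character_
  df$start[miss] <- NA_integer_
  df$end[miss] <- NA_integer_
  df$strand[miss] <- NA_character_
  loc_missing <- !miss & (is.na(df$sequence_id) | is.na(df$start) | is.na(df$end))
  if (any(loc_missing))
    abort_format("non-Missing hit(s) lack coordinates for gene(s): ",
                 paste(unique(df$gene_id[loc_missing]), collapse = ", "))
  if (any(!miss & df$start >= df$end))
    abort_format("empty or inverted gene interval for gene(s): ",
                 paste(unique(df$gene_id[!miss & df$start >= df$end]), collapse = ", "))
  class(df) <- c("gene_status_table", "data.frame")
  df
}

#' All hits for one gene
#'
#' @param table A [gene_status_table()].
#' @param gene_id Gene identifier.
#' @return The subset of rows for that gene.
#' @export
gene_hits <- function(table, gene_id) {
  table[table$gene_id == gene_id, , drop = FALSE]
}

#' Consensus status of each gene in a table
#'
#' @param table A [gene_status_table()].
#' @return Named character vector, gene_id -> status.
#' @export
gene_statuses <- function(table) {
  vapply(split(table$status, table$gene_id), `[[`, "", 1)
}

#' Parse a completeness-assessor full table (BUSCO TSV dialect)
#'
#' Expects `#`-prefixed comment lines followed by tab-separated rows with
#' columns gene id, status, sequence, gene start, gene end, strand, score
#' and length; Missing rows may carry only the first two columns. Extra
#' trailing columns (some assessor versions append descriptions and URLs)
#' are ignored. Table coordinates are 1-based inclusive and are converted to
#' 0-based half-open on read.
#'
#' @param path Path to the TSV file.
#' @return A [gene_status_table()].
#' @export
parse_busco_full_table <- function(path) {
  if (!file.exists(path)) abort_io("full table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (base::length(lines) == 0)
    return(gene_status_table(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(f, i) if (base::length(f) >= i && nzchar(f[[i]])) f[[i]] else NA_character_
  gene_id <- vapply(fields, `[[`, "", 1)
  status <- vapply(fields, get, "", 2)
  if (anyNA(status)) abort_format("full table '", path, "': row without a status")
  seq_id <- vapply(fields, get, "", 3)
  start1 <- suppressWarnings(as.integer(vapply(fields, get, "", 4)))
  end1 <- suppressWarnings(as.integer(vapply(fields, get, "", 5)))
  strand <- vapply(fields, get, "", 6)
  score <- suppressWarnings(as.numeric(vapply(fields, get, "", 7)))
  len <- suppressWarnings(as.integer(vapply(fields, get, "", 8)))
  gene_status_table(gene_id, status, seq_id,
                    start = start1 - 1L, end = end1,
                    strand = strand, score = score, length = len)
}

#' Write a gene status table in the assessor's TSV dialect
#'
#' The inverse of [parse_busco_full_table()]: internal 0-based half-open
#' coordinates are serialized back as 1-based inclusive.
#'
#' @param table A [gene_status_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_busco_full_table <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  lines <- c("# gene status table",
             paste(table$gene_id, table$status, fmt(table$sequence_id),
                   fmt(table$start + 1L), fmt(table$end), fmt(table$strand),
                   fmt(table$score), fmt(table$length), sep = "\t"))
  # Missing rows carry only the first two columns
  miss <- c(FALSE, table$status == "Missing")
  lines[miss] <- sub("\t+$", "", lines[miss])
  writeLines(lines, path)
  invisible(path)
}
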
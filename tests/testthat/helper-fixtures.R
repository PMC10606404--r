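# Shared fixtures and brute-force oracles, built in code at test time.

# Reduced-size truth-tracked fixture for unit tests (cached across files).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture(seed = 42, n_chrom = 2, chrom_len = 40000,
                             n_markers = 4, marker_len = 500, n_drop = 2,
                             contig_margin_bp = 1000, depth = 12,
                             read_len_mean = 4000, read_len_sd = 300)
    }
    cache
  }
})

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random but invariant-respecting alignment records.
random_alignment_table <- function(n, n_queries = 8, n_targets = 3,
                                   with_tp = FALSE) {
  qid <- sprintf("q%02d", sample.int(n_queries, n, replace = TRUE))
  tid <- sprintf("t%02d", sample.int(n_targets, n, replace = TRUE))
  qlen <- sample(1000:20000, n, replace = TRUE)
  tlen <- sample(50000:100000, n, replace = TRUE)
  qs <- vapply(qlen, function(l) sample.int(l - 1L, 1L) - 1L, integer(1))
  qe <- vapply(seq_len(n), function(i) qs[i] + sample.int(qlen[i] - qs[i], 1L),
               integer(1))
  ts <- vapply(tlen, function(l) sample.int(l - 1L, 1L) - 1L, integer(1))
  te <- vapply(seq_len(n), function(i) ts[i] + sample.int(tlen[i] - ts[i], 1L),
               integer(1))
  bl <- pmax(qe - qs, te - ts)
  rm <- vapply(bl, function(b) sample.int(b, 1L), integer(1))
  alignment_table(qid, qlen, qs, qe, sample(c("+", "-"), n, TRUE), tid, tlen,
                  ts, te, rm, bl, mapq = sample(0:60, n, TRUE),
                  tp = if (with_tp) sample(c("P", "S"), n, TRUE) else NA)
}

# Brute-force oracle: ids of reads overlapping an interval, by row scan.
brute_overlapping_reads <- function(aln, target_id, interval, min_overlap = 1) {
  out <- character(0)
  for (i in seq_len(nrow(aln))) {
    if (aln$target_id[i] != target_id) next
    ov <- min(aln$target_end[i], interval[2]) - max(aln$target_start[i], interval[1])
    if (ov >= min_overlap) out <- c(out, aln$query_id[i])
  }
  sort(unique(out))
}

# Brute-force oracle: anchor choice by explicit enumeration of the sort key.
brute_anchor <- function(contig_id, aln, min_matches = 500) {
  best <- NULL
  for (i in seq_len(nrow(aln))) {
    if (aln$query_id[i] != contig_id) next
    if (any(!is.na(aln$tp[aln$query_id == contig_id])) &&
        (is.na(aln$tp[i]) || aln$tp[i] != "P")) next
    if (aln$residue_matches[i] < min_matches) next
    key <- list(-aln$residue_matches[i], -aln$block_len[i], aln$target_id[i],
                aln$target_start[i])
    if (is.null(best) || key_less(key, best$key)) best <- list(key = key, row = i)
  }
  if (is.null(best)) NULL else aln[best$row, , drop = FALSE]
}

key_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[[k]] < b[[k]]) return(TRUE)
    if (a[[k]] > b[[k]]) return(FALSE)
  }
  FALSE
}

# Brute-force oracle: splice via independent full-string rebuild.
brute_splice <- function(seq, events) {
  evs <- Filter(function(e) e$status == "applied", events)
  if (length(evs) == 0) return(seq)
  starts <- vapply(evs, `[[`, integer(1), "start")
  evs <- evs[order(starts)]
  out <- ""
  cursor <- 0L
  for (e in evs) {
    out <- paste0(out, substr(seq, cursor + 1L, e$start), e$new_bases)
    cursor <- e$end
  }
  paste0(out, substring(seq, cursor + 1L))
}
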
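#' Deterministic k-mer chain aligner
#'
#' A desk-scale stand-in for a whole-genome/long-read aligner, intended for
#' the low-error regime the pipeline's fixtures operate in. Exact k-mers
#' sampled along each query (every `stride` bases, plus the final position)
#' are matched against an index of all target k-mers, grouped into
#' same-diagonal runs, and chained colinearly (query and target offsets both
#' increasing, gaps up to `max_gap`) per (query, target, strand). Chains
#' whose query span reaches `min_chain_bp` are emitted as PAF-style records
#' with `residue_matches` equal to the number of query bases covered by
#' chained anchors; for an exact substring match this equals the full match
#' length. The best record per query is flagged `tp = "P"` (primary).
#'
#' Repetitive k-mers are matched at every target occurrence; chaining picks
#' the colinear subset. Output is deterministic for fixed inputs.
#'
#' @param queries,targets [Biostrings::DNAStringSet] or named character
#'   vectors.
#' @param k K-mer size (>= 11).
#' @param min_chain_bp Minimum query span of an emitted chain.
#' @param stride Distance between sampled query k-mer start positions;
#'   values <= k make anchor coverage contiguous on exact matches.
#' @param max_gap Maximum query or target gap bridged within one chain;
#'   bounds the size of insertions/deletions an alignment can span.
#' @param max_chains_per_pair Maximum records per (query, target, strand).
#' @return An alignment data frame (see [alignment_table()]).
#' @export
toy_align <- function(queries, targets, k = 31, min_chain_bp = 500,
                      stride = 20, max_gap = 20000, max_chains_per_pair = 4) {
  assert_that(k >= 11, "k must be >= 11")
  queries <- as_dna(queries)
  targets <- as_dna(targets)
  assert_that(!anyDuplicated(names(queries)), "query ids must be unique")
  assert_that(!anyDuplicated(names(targets)), "target ids must be unique")
  qlens <- stats::setNames(Biostrings::width(queries), names(queries))
  tlens <- stats::setNames(Biostrings::width(targets), names(targets))

  tindex <- kmer_index(targets, k)
  if (nrow(tindex) == 0 || length(queries) == 0) return(alignment_table())

  recs <- list()
  for (strand in c("+", "-")) {
    qset <- if (strand == "+") queries else Biostrings::reverseComplement(queries)
    qk <- sampled_kmers(qset, k, stride)
    if (nrow(qk) == 0) next
    anchors <- tindex[qk, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(anchors) == 0) next
    chains <- anchors[, chain_anchor_group(qpos, tpos, k, max_gap, min_chain_bp,
                                           max_chains_per_pair),
                      by = c("qid", "tid")]
    if (nrow(chains) == 0) next
    # convert 1-based inclusive chain coords to 0-based half-open records;
    # '-' strand query coords are mapped back to the forward query strand
    ql <- qlens[chains$qid]
    qs0 <- chains$qs - 1L
    qe0 <- chains$qe
    if (strand == "-") {
      tmp <- ql - qe0
      qe0 <- ql - qs0
      qs0 <- tmp
    }
    recs[[strand]] <- data.frame(
      query_id = chains$qid, query_len = as.integer(ql),
      query_start = as.integer(qs0), query_end = as.integer(qe0),
      strand = strand, target_id = chains$tid,
      target_len = as.integer(tlens[chains$tid]),
      target_start = chains$ts - 1L, target_end = chains$te,
      residue_matches = chains$cov,
      block_len = pmax(qe0 - qs0, chains$te - chains$ts + 1L),
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) return(alignment_table())
  df <- do.call(rbind, c(recs, list(make.row.names = FALSE)))

  # primary flag: best record per query by (matches, block_len, target, pos)
  ord <- order(df$query_id, -df$residue_matches, -df$block_len,
               df$target_id, df$target_start, df$strand)
  df <- df[ord, , drop = FALSE]
  primary <- !duplicated(df$query_id)
  rownames(df) <- NULL
  alignment_table(df$query_id, df$query_len, df$query_start, df$query_end,
                  df$strand, df$target_id, df$target_len, df$target_start,
                  df$target_end, df$residue_matches, df$block_len,
                  mapq = ifelse(primary, 60L, 0L),
                  tp = ifelse(primary, "P", "S"))
}

#' All k-mer start positions of a sequence set, as a keyed data.table
#' @noRd
kmer_index <- function(seqs, k) {
  chars <- as.character(seqs)
  parts <- lapply(seq_along(chars), function(j) {
    L <- nchar(chars[[j]])
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(chars[[j]], pos, pos + k - 1L),
                           tid = names(chars)[j], tpos = pos)
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0) return(data.table::data.table(kmer = character(),
                                                    tid = character(),
                                                    tpos = integer()))
  data.table::setkey(out, kmer)
  out
}

#' Query k-mers sampled every `stride` positions plus the final position
#' @noRd
sampled_kmers <- function(seqs, k, stride) {
  chars <- as.character(seqs)
  parts <- lapply(seq_along(chars), function(j) {
    L <- nchar(chars[[j]])
    if (L < k) return(NULL)
    pos <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
    data.table::data.table(kmer = substring(chars[[j]], pos, pos + k - 1L),
                           qid = names(chars)[j], qpos = as.integer(pos))
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0) return(data.table::data.table(kmer = character(),
                                                    qid = character(),
                                                    qpos = integer()))
  out
}

#' Chain the anchors of one (query, target, strand) group
#'
#' Anchors are first merged into same-diagonal segments (splitting runs with
#' internal gaps over `max_gap`), then segments are chained by dynamic
#' programming maximizing total anchor coverage subject to colinearity and
#' the gap bound. Chains are extracted greedily best-first; segments whose
#' query interval was consumed are excluded from later chains.
#'
#' @return data.table with one row per emitted chain: qs, qe, ts, te
#'   (1-based inclusive) and cov (covered query bases).
#' @noRd
chain_anchor_group <- function(qpos, tpos, k, max_gap, min_chain_bp, max_chains) {
  dg <- tpos - qpos
  o <- order(dg, qpos)
  qpos <- qpos[o]; tpos <- tpos[o]; dg <- dg[o]
  # segment breaks: new diagonal, or same-diagonal gap beyond max_gap
  newseg <- c(TRUE, diff(dg) != 0L | diff(qpos) > max_gap)
  segid <- cumsum(newseg)
  qs <- tapply(qpos, segid, min)
  qe <- tapply(qpos, segid, max) + k - 1L
  ts <- tapply(tpos, segid, min)
  te <- tapply(tpos, segid, max) + k - 1L
  cov <- as.integer(tapply(qpos, segid, function(p) {
    if (length(p) == 1L) k else sum(pmin(diff(p), k)) + k
  }))
  seg <- data.frame(qs = as.integer(qs), qe = as.integer(qe),
                    ts = as.integer(ts), te = as.integer(te), cov = cov)
  seg <- seg[order(seg$qs, seg$ts), , drop = FALSE]
  out <- list()
  alive <- rep(TRUE, nrow(seg))
  while (sum(alive) > 0 && length(out) < max_chains) {
    ch <- best_chain(seg[alive, , drop = FALSE], max_gap, k)
    qs1 <- min(ch$qs); qe1 <- max(ch$qe)
    used <- alive & seg$qs <= qe1 & seg$qe >= qs1
    alive <- alive & !used
    if (qe1 - qs1 + 1L < min_chain_bp) next
    out[[length(out) + 1L]] <- data.frame(
      qs = qs1, qe = qe1, ts = min(ch$ts), te = max(ch$te),
      cov = min(sum(ch$cov), qe1 - qs1 + 1L))
  }
  if (length(out) == 0) {
    return(data.table::data.table(qs = integer(), qe = integer(),
                                  ts = integer(), te = integer(),
                                  cov = integer()))
  }
  data.table::rbindlist(out)
}

#' Highest-coverage colinear chain over a segment set (DP, vectorized inner loop)
#' @noRd
best_chain <- function(seg, max_gap, k) {
  n <- nrow(seg)
  score <- seg$cov
  prev <- rep(0L, n)
  if (n > 1) {
    for (i in 2:n) {
      j <- seq_len(i - 1L)
      gapq <- seg$qs[i] - seg$qe[j] - 1L
      gapt <- seg$ts[i] - seg$te[j] - 1L
      ok <- seg$qs[j] < seg$qs[i] & seg$ts[j] < seg$ts[i] &
        gapq <= max_gap & gapt <= max_gap & gapq >= -k & gapt >= -k
      if (any(ok)) {
        cand <- score[j]
        cand[!ok] <- -Inf
        b <- which.max(cand)
        if (cand[b] > 0) {
          score[i] <- seg$cov[i] + cand[b]
          prev[i] <- b
        }
      }
    }
  }
  end <- which.max(score)
  idx <- integer()
  while (end != 0L) {
    idx <- c(end, idx)
    end <- prev[end]
  }
  seg[idx, , drop = FALSE]
}
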
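#' Generate a random truth genome with planted single-copy markers
#'
#' Backgrounds are uniform random DNA; markers are random unique sequences
#' planted at non-overlapping loci (kept `min_spacing` bp apart and
#' `end_margin` bp away from chromosome ends so that later excisions stay
#' internal), each verified to occur exactly once genome-wide on either
#' strand and regenerated on the (vanishingly rare) collision. Deterministic
#' for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param n_markers Number of marker genes to plant.
#' @param marker_len Marker length in bp.
#' @param seed Integer seed.
#' @param min_spacing Minimum distance between planted marker intervals.
#' @param end_margin Minimum distance of a marker from a chromosome end.
#' @return A list of class `fixture_truth` with elements `truth_genome`
#'   ([Biostrings::DNAStringSet]), `catalog` ([marker_catalog()]),
#'   `marker_loci` (data frame gene_id/chrom_id/start/end, 0-based
#'   half-open) and `seed`.
#' @export
generate_genome <- function(n_chrom = 2, chrom_len = 100000, n_markers = 6,
                            marker_len = 1000, seed = 1,
                            min_spacing = 10000, end_margin = 6000) {
  assert_that(n_markers * (marker_len + min_spacing) < n_chrom * chrom_len,
              "markers do not fit: reduce n_markers, marker_len or min_spacing")
  with_seed(seed, {
    chroms <- stats::setNames(
      vapply(seq_len(n_chrom), function(i) random_dna(chrom_len), ""),
      sprintf("chr%02d", seq_len(n_chrom)))
    loci <- place_marker_loci(n_chrom, chrom_len, n_markers, marker_len,
                              min_spacing, end_margin)
    gene_ids <- sprintf("gene%03d", seq_len(n_markers))
    markers <- character(n_markers)
    for (i in seq_len(n_markers)) {
      for (attempt in 1:25) {
        cand <- random_dna(marker_len)
        planted <- chroms
        ch <- loci$chrom[i]
        substr(planted[[ch]], loci$start[i] + 1L, loci$end[i]) <- cand
        n_occ <- count_occurrences(planted, cand)
        if (n_occ == 1L && !(cand %in% markers)) {
          markers[i] <- cand
          chroms <- planted
          break
        }
        if (attempt == 25) abort("could not plant a unique marker sequence")
      }
    }
    out <- list(
      truth_genome = as_dna(chroms),
      catalog = marker_catalog(gene_ids, markers),
      marker_loci = data.frame(gene_id = gene_ids,
                               chrom_id = names(chroms)[loci$chrom],
                               start = loci$start, end = loci$end,
                               stringsAsFactors = FALSE),
      seed = seed)
    class(out) <- "fixture_truth"
    out
  })
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
count_occurrences <- function(seqs, pattern) {
  seqs <- as_dna(seqs)
  p <- Biostrings::DNAString(pattern)
  sum(vapply(seq_along(seqs), function(j) {
    Biostrings::countPattern(p, seqs[[j]]) +
      Biostrings::countPattern(Biostrings::reverseComplement(p), seqs[[j]])
  }, integer(1)))
}

#' Uniformly place non-overlapping marker loci (0-based half-open)
#'
#' Per chromosome, sorted uniform draws plus fixed spacing offsets give a
#' uniform sample of positions at pairwise distance >= marker_len +
#' min_spacing, which is feasible whenever the window arithmetic allows it.
#' @noRd
place_marker_loci <- function(n_chrom, chrom_len, n_markers, marker_len,
                              min_spacing, end_margin) {
  chrom <- rep(seq_len(n_chrom), length.out = n_markers)
  start <- integer(n_markers)
  d <- marker_len + min_spacing
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    if (m == 0) next
    avail <- (chrom_len - marker_len - end_margin) - end_margin - (m - 1L) * d
    if (avail < 0)
      abort("cannot place markers without overlap; loosen spacing")
    u <- sort(sample.int(avail + 1L, m, replace = TRUE)) - 1L
    start[idx] <- end_margin + u + (seq_len(m) - 1L) * d
  }
  list(chrom = chrom, start = start, end = start + marker_len)
}

#' Degrade a truth genome into a chromosome assembly plus lost contigs
#'
#' Emulates sequence loss during assembly and scaffolding: each dropped
#' gene's planted locus, widened by `contig_margin_bp` on both sides, is
#' removed from the chromosomes (`excise`) or overwritten with N
#' (`n_fill`). The removed segments, widened by a further jittered margin so
#' that each lost contig shares flanking sequence with the remaining
#' chromosomes, are emitted as `n_contig_sets` contig sets with different
#' jitters, emulating multiple assemblers recovering the same region with
#' slightly different boundaries.
#'
#' @param truth A `fixture_truth` from [generate_genome()].
#' @param genes_to_drop Character vector of planted gene ids to remove.
#' @param gap_char_policy `"excise"` (remove bases) or `"n_fill"`
#'   (replace with N, preserving coordinates).
#' @param contig_margin_bp Margin around the gene locus that is removed, and
#'   again the margin by which lost contigs extend beyond the removed
#'   segment.
#' @param n_contig_sets Number of jittered contig sets to emit (>= 2 mirrors
#'   a merged multi-assembler contig collection).
#' @param jitter_bp Maximum +/- jitter on contig boundaries.
#' @param seed Integer seed for the jitter.
#' @return The input `fixture_truth` augmented with `chrom_assembly`
#'   ([Biostrings::DNAStringSet]), `contig_sets` (list of DNAStringSet),
#'   `deletions` (data frame chrom_id/start/end/gene_ids, truth
#'   coordinates) and `lost_contigs` (data frame contig_id/set/chrom_id/
#'   start/end, truth coordinates).
#' @export
degrade_assembly <- function(truth, genes_to_drop,
                             gap_char_policy = c("excise", "n_fill"),
                             contig_margin_bp = 2000, n_contig_sets = 2,
                             jitter_bp = 500, seed = truth$seed + 1L) {
  gap_char_policy <- match.arg(gap_char_policy)
  loci <- truth$marker_loci
  assert_that(all(genes_to_drop %in% loci$gene_id),
              "genes_to_drop contains gene ids not planted in the truth genome")
  drop <- loci[match(genes_to_drop, loci$gene_id), , drop = FALSE]
  chrom_chars <- as.character(truth$truth_genome)

  removed <- data.frame(chrom_id = drop$chrom_id,
                        start = pmax(0L, drop$start - contig_margin_bp),
                        end = pmin(nchar(chrom_chars)[match(drop$chrom_id, names(chrom_chars))],
                                   drop$end + contig_margin_bp),
                        gene_id = drop$gene_id, stringsAsFactors = FALSE)
  for (ch in unique(removed$chrom_id)) {
    iv <- removed[removed$chrom_id == ch, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      abort("dropped gene loci overlap after margin widening on ", ch)
  }

  assembly <- chrom_chars
  for (ch in unique(removed$chrom_id)) {
    iv <- removed[removed$chrom_id == ch, , drop = FALSE]
    iv <- iv[order(-iv$start), , drop = FALSE]   # right-to-left keeps coords valid
    for (r in seq_len(nrow(iv))) {
      s <- iv$start[r]; e <- iv$end[r]
      assembly[[ch]] <- if (gap_char_policy == "excise") {
        paste0(substr(assembly[[ch]], 1L, s), substring(assembly[[ch]], e + 1L))
      } else {
        paste0(substr(assembly[[ch]], 1L, s), strrep("N", e - s),
               substring(assembly[[ch]], e + 1L))
      }
    }
  }

  with_seed(seed, {
    contig_sets <- vector("list", n_contig_sets)
    lost <- list()
    if (nrow(removed) == 0) {
      truth$chrom_assembly <- as_dna(assembly)
      truth$contig_sets <- replicate(n_contig_sets, Biostrings::DNAStringSet())
      truth$deletions <- removed
      truth$lost_contigs <- data.frame(contig_id = character(), set = integer(),
                                       chrom_id = character(),
                                       gene_id = character(),
                                       start = integer(), end = integer(),
                                       stringsAsFactors = FALSE)
      truth$dropped_genes <- genes_to_drop
      return(truth)
    }
    for (s in seq_len(n_contig_sets)) {
      ids <- character(nrow(removed)); seqs <- character(nrow(removed))
      cs <- integer(nrow(removed)); ce <- integer(nrow(removed))
      for (r in seq_len(nrow(removed))) {
        ch <- removed$chrom_id[r]
        clen <- nchar(chrom_chars[[ch]])
        jl <- sample.int(2L * jitter_bp + 1L, 1L) - jitter_bp - 1L
        jr <- sample.int(2L * jitter_bp + 1L, 1L) - jitter_bp - 1L
        cs[r] <- max(0L, removed$start[r] - contig_margin_bp + jl)
        ce[r] <- min(clen, removed$end[r] + contig_margin_bp + jr)
        ids[r] <- sprintf("set%d_ctg%03d", s, r)
        seqs[r] <- substr(chrom_chars[[ch]], cs[r] + 1L, ce[r])
      }
      contig_sets[[s]] <- as_dna(stats::setNames(seqs, ids))
      lost[[s]] <- data.frame(contig_id = ids, set = s,
                              chrom_id = removed$chrom_id,
                              gene_id = removed$gene_id,
                              start = cs, end = ce, stringsAsFactors = FALSE)
    }
    truth$chrom_assembly <- as_dna(assembly)
    truth$contig_sets <- contig_sets
    truth$deletions <- removed
    truth$lost_contigs <- do.call(rbind, c(lost, list(make.row.names = FALSE)))
    truth$dropped_genes <- genes_to_drop
    truth
  })
}

#' Simulate long, highly accurate reads from a genome
#'
#' Reads are sampled uniformly over the genome (chromosome chosen
#' proportional to length), on a random strand, with normal lengths clamped
#' to at least 1 kb, at per-base substitution error rate `error_rate`. The
#' number of reads is chosen so the expected total bases equal
#' `depth * genome length`. True origins are recorded per read.
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param depth Target sequencing depth.
#' @param read_len_mean,read_len_sd Normal read-length parameters in bp.
#' @param error_rate Per-base substitution probability (0 = exact reads,
#'   approximating HiFi accuracy at desk scale).
#' @param seed Integer seed.
#' @param read_prefix Prefix for generated read ids.
#' @return List with `reads` ([Biostrings::DNAStringSet]) and `origins`
#'   (data frame read_id/chrom_id/start/end/strand, 0-based half-open on
#'   the source genome).
#' @export
simulate_reads <- function(genome, depth = 20, read_len_mean = 15000,
                           read_len_sd = 1500, error_rate = 0, seed = 1,
                           read_prefix = "read") {
  assert_that(depth > 0, "depth must be positive")
  genome <- as.character(as_dna(genome))
  glen <- nchar(genome)
  total <- sum(glen)
  n_reads <- max(1L, as.integer(round(depth * total / read_len_mean)))
  with_seed(seed, {
    lens <- pmax(1000L, as.integer(round(stats::rnorm(n_reads, read_len_mean,
                                                      read_len_sd))))
    chrom_idx <- sample.int(length(genome), n_reads, replace = TRUE,
                            prob = glen / total)
    lens <- pmin(lens, glen[chrom_idx])
    start0 <- vapply(seq_len(n_reads), function(i) {
      sample.int(glen[chrom_idx[i]] - lens[i] + 1L, 1L) - 1L
    }, integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(genome[chrom_idx], start0 + 1L, start0 + lens)
    if (error_rate > 0) {
      seqs <- vapply(seqs, mutate_substitutions, "", rate = error_rate,
                     USE.NAMES = FALSE)
    }
    rc <- strand == "-"
    if (any(rc)) seqs[rc] <- reverse_complement(seqs[rc])
    ids <- sprintf("%s%06d", read_prefix, seq_len(n_reads))
    list(reads = as_dna(stats::setNames(seqs, ids)),
         origins = data.frame(read_id = ids, chrom_id = names(genome)[chrom_idx],
                              start = start0, end = start0 + lens,
                              strand = strand, stringsAsFactors = FALSE))
  })
}

#' @noRd
mutate_substitutions <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Derive a second haplotype by independent per-base mutation
#'
#' Scans each chromosome left to right: at every surviving base a deletion
#' of `indel_len` bases starts with probability `del_rate` (bases inside a
#' deletion are skipped entirely), otherwise the base is substituted with
#' probability `snp_rate` and followed by an insertion of `indel_len`
#' random bases with probability `ins_rate`. Expected output length is
#' `len * (1 + indel_len*ins_rate) / (1 + indel_len*del_rate)`, i.e.
#' `len * (1 + indel_len*(ins_rate - del_rate))` to first order.
#'
#' @param hap1 First haplotype ([Biostrings::DNAStringSet] or named
#'   character vector).
#' @param snp_rate,ins_rate,del_rate Per-base event probabilities in [0, 1).
#' @param indel_len Length of each insertion/deletion event in bp.
#' @param seed Integer seed.
#' @return The second haplotype as a [Biostrings::DNAStringSet], plus
#'   attribute `event_counts` (matrix chrom x c(snp, ins, del) of realized
#'   events).
#' @export
make_diploid <- function(hap1, snp_rate = 0.02, ins_rate = 0.02,
                         del_rate = 0.02, indel_len = 12, seed = 1) {
  assert_that(all(c(snp_rate, ins_rate, del_rate) >= 0 &
                    c(snp_rate, ins_rate, del_rate) < 1),
              "mutation rates must lie in [0, 1)")
  assert_that(indel_len >= 1, "indel_len must be >= 1")
  hap1 <- as.character(as_dna(hap1))
  with_seed(seed, {
    counts <- matrix(0L, length(hap1), 3,
                     dimnames = list(names(hap1), c("snp", "ins", "del")))
    out <- vapply(seq_along(hap1), function(j) {
      res <- mutate_haplotype(hap1[[j]], snp_rate, ins_rate, del_rate, indel_len)
      counts[j, ] <<- res$counts
      res$seq
    }, "")
    hap2 <- as_dna(stats::setNames(out, names(hap1)))
    attr(hap2, "event_counts") <- counts
    hap2
  })
}

#' @noRd
mutate_haplotype <- function(seq, snp_rate, ins_rate, del_rate, indel_len) {
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  # greedy non-overlap thinning of deletion starts == sequential scan semantics
  del_start <- which(stats::runif(L) < del_rate)
  kept <- integer(0)
  last_end <- -1L
  for (p in del_start) {
    if (p > last_end) {
      kept <- c(kept, p)
      last_end <- p + indel_len - 1L
    }
  }
  deleted <- rep(FALSE, L)
  for (p in kept) deleted[p:min(L, p + indel_len - 1L)] <- TRUE
  surv <- which(!deleted)
  sub_at <- surv[stats::runif(length(surv)) < snp_rate]
  for (p in sub_at) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  ins_at <- surv[stats::runif(length(surv)) < ins_rate]
  pieces <- chars
  pieces[deleted] <- ""
  for (p in ins_at) {
    pieces[p] <- paste0(pieces[p], random_dna(indel_len))
  }
  list(seq = paste(pieces, collapse = ""),
       counts = c(snp = length(sub_at), ins = length(ins_at),
                  del = length(kept)))
}
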
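test_that("generate_genome is seed-reproducible and scans all-Complete", {
  g1 <- generate_genome(n_chrom = 2, chrom_len = 30000, n_markers = 4,
                        marker_len = 400, seed = 9)
  g2 <- generate_genome(n_chrom = 2, chrom_len = 30000, n_markers = 4,
                        marker_len = 400, seed = 9)
  expect_identical(as.character(g1$truth_genome), as.character(g2$truth_genome))
  expect_identical(g1$catalog$bases, g2$catalog$bases)

  st <- gene_statuses(toy_marker_scan(g1$truth_genome, g1$catalog))
  expect_true(all(st == "Complete"))
  expect_equal(length(st), 4)

  # planted loci recorded where the marker actually sits
  for (i in seq_len(nrow(g1$marker_loci))) {
    loc <- g1$marker_loci[i, ]
    seg <- substr(as.character(g1$truth_genome)[[loc$chrom_id]],
                  loc$start + 1, loc$end)
    expect_equal(seg, g1$catalog$bases[g1$catalog$gene_id == loc$gene_id])
  }
})

test_that("generate_genome with zero markers yields a plain random genome", {
  g <- generate_genome(n_chrom = 1, chrom_len = 5000, n_markers = 0, seed = 3)
  expect_equal(Biostrings::width(g$truth_genome), 5000L)
  expect_equal(nrow(g$catalog), 0)
})

test_that("degrade_assembly excises dropped loci and emits covering contigs", {
  fx <- small_fixture()
  marker_len <- 500L; margin <- 1000L
  dropped <- fx$dropped_genes
  # chromosome shortened by (marker + 2*margin) per excision on that chromosome
  for (ch in names(fx$truth_genome)) {
    n_cut <- sum(fx$deletions$chrom_id == ch)
    expect_equal(Biostrings::width(fx$chrom_assembly)[match(ch, names(fx$chrom_assembly))],
                 Biostrings::width(fx$truth_genome)[match(ch, names(fx$truth_genome))] -
                   n_cut * (marker_len + 2L * margin))
  }
  chrom_st <- gene_statuses(toy_marker_scan(fx$chrom_assembly, fx$catalog))
  expect_true(all(chrom_st[dropped] == "Missing"))
  expect_true(all(chrom_st[setdiff(names(chrom_st), dropped)] == "Complete"))
  for (s in fx$contig_sets) {
    st <- gene_statuses(toy_marker_scan(s, fx$catalog))
    expect_true(all(st[dropped] == "Complete"))
  }
  # every lost contig is a true substring of its source chromosome
  for (i in seq_len(nrow(fx$lost_contigs))) {
    lc <- fx$lost_contigs[i, ]
    seqs <- as.character(fx$contig_sets[[lc$set]])
    expect_equal(seqs[[lc$contig_id]],
                 substr(as.character(fx$truth_genome)[[lc$chrom_id]],
                        lc$start + 1, lc$end))
  }
})

test_that("degrade_assembly with an empty drop list returns the truth unchanged", {
  g <- generate_genome(n_chrom = 1, chrom_len = 30000, n_markers = 2,
                       marker_len = 400, seed = 5)
  d <- degrade_assembly(g, character(0))
  expect_identical(as.character(d$chrom_assembly), as.character(g$truth_genome))
})

test_that("overlapping drop loci after margin widening are rejected", {
  g <- generate_genome(n_chrom = 1, chrom_len = 40000, n_markers = 2,
                       marker_len = 400, seed = 6, min_spacing = 10000)
  # margins so wide that any two loci on a 40 kb chromosome must collide
  expect_error(degrade_assembly(g, g$catalog$gene_id, contig_margin_bp = 14000),
               "overlap")
})

test_that("n_fill policy preserves coordinates with N runs", {
  g <- generate_genome(n_chrom = 1, chrom_len = 30000, n_markers = 2,
                       marker_len = 400, seed = 8)
  d <- degrade_assembly(g, g$catalog$gene_id[1], gap_char_policy = "n_fill",
                        contig_margin_bp = 500)
  expect_equal(Biostrings::width(d$chrom_assembly),
               Biostrings::width(g$truth_genome))
  del <- d$deletions
  seg <- substr(as.character(d$chrom_assembly)[[del$chrom_id]],
                del$start + 1, del$end)
  expect_equal(seg, strrep("N", del$end - del$start))
})

test_that("simulated reads are exact oriented substrings with ~depth coverage", {
  g <- generate_genome(n_chrom = 2, chrom_len = 50000, n_markers = 0, seed = 21)
  sim <- simulate_reads(g$truth_genome, depth = 20, read_len_mean = 5000,
                        read_len_sd = 500, error_rate = 0, seed = 22)
  sim_again <- simulate_reads(g$truth_genome, depth = 20, read_len_mean = 5000,
                              read_len_sd = 500, error_rate = 0, seed = 22)
  expect_identical(as.character(sim$reads), as.character(sim_again$reads))

  # total bases within 3 SE of depth * genome length
  n <- length(sim$reads)
  total <- sum(Biostrings::width(sim$reads))
  se <- sqrt(n) * 500
  expect_lt(abs(total - 20 * 100000), 3 * se)

  truth <- as.character(g$truth_genome)
  for (i in sample.int(n, 25)) {
    org <- sim$origins[i, ]
    seg <- substr(truth[[org$chrom_id]], org$start + 1, org$end)
    readseq <- as.character(sim$reads)[[org$read_id]]
    expect_equal(readseq, if (org$strand == "+") seg else reverse_complement(seg))
  }
})

test_that("substitution errors appear at the requested rate", {
  g <- generate_genome(n_chrom = 1, chrom_len = 50000, n_markers = 0, seed = 31)
  sim <- simulate_reads(g$truth_genome, depth = 5, read_len_mean = 5000,
                        read_len_sd = 1, error_rate = 0.01, seed = 32)
  truth <- as.character(g$truth_genome)[[1]]
  mism <- 0L; tot <- 0L
  for (i in seq_along(sim$reads)) {
    org <- sim$origins[i, ]
    seg <- substr(truth, org$start + 1, org$end)
    readseq <- as.character(sim$reads)[[i]]
    if (org$strand == "-") readseq <- reverse_complement(readseq)
    a <- strsplit(seg, "")[[1]]; b <- strsplit(readseq, "")[[1]]
    mism <- mism + sum(a != b); tot <- tot + length(a)
  }
  se <- sqrt(tot * 0.01 * 0.99)
  expect_lt(abs(mism - 0.01 * tot), 3 * se)
})

test_that("make_diploid with zero rates is the identity and is seed-stable", {
  g <- generate_genome(n_chrom = 1, chrom_len = 20000, n_markers = 0, seed = 41)
  h0 <- make_diploid(g$truth_genome, 0, 0, 0, 12, seed = 42)
  expect_identical(as.character(h0), as.character(g$truth_genome))
  h1 <- make_diploid(g$truth_genome, 0.02, 0.02, 0.02, 12, seed = 43)
  h2 <- make_diploid(g$truth_genome, 0.02, 0.02, 0.02, 12, seed = 43)
  expect_identical(as.character(h1), as.character(h2))
})

test_that("substitution-only divergence matches the binomial expectation", {
  g <- generate_genome(n_chrom = 1, chrom_len = 100000, n_markers = 0, seed = 44)
  h <- make_diploid(g$truth_genome, snp_rate = 0.02, ins_rate = 0,
                    del_rate = 0, indel_len = 12, seed = 45)
  counts <- attr(h, "event_counts")
  se <- sqrt(100000 * 0.02 * 0.98)
  expect_lt(abs(counts[1, "snp"] - 2000), 3 * se)
  expect_equal(Biostrings::width(h), 100000L)
  a <- strsplit(as.character(g$truth_genome)[[1]], "")[[1]]
  b <- strsplit(as.character(h)[[1]], "")[[1]]
  expect_equal(sum(a != b), unname(counts[1, "snp"]))
})

test_that("balanced indel rates leave the expected haplotype length", {
  g <- generate_genome(n_chrom = 1, chrom_len = 100000, n_markers = 0, seed = 46)
  h <- make_diploid(g$truth_genome, snp_rate = 0.02, ins_rate = 0.02,
                    del_rate = 0.02, indel_len = 12, seed = 47)
  counts <- attr(h, "event_counts")
  # expectation len*(1 + 12*(ins - del)) = len; SE from realized event counts
  se <- 12 * sqrt(counts[1, "ins"] + counts[1, "del"])
  expect_lt(abs(sum(Biostrings::width(h)) - 100000), 3 * se)
})

test_that("toy_align finds an exact containment with full residue matches", {
  set.seed(51)
  target <- c(tgt = random_seq(30000))
  q <- substr(target[[1]], 10001, 15000)
  aln <- toy_align(c(q1 = q), target)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$tp, "P")
  expect_equal(aln$residue_matches, 5000L)
  expect_equal(c(aln$target_start, aln$target_end), c(10000L, 15000L))
  expect_equal(c(aln$query_start, aln$query_end), c(0L, 5000L))

  # reverse-strand containment
  aln_rc <- toy_align(c(q1 = reverse_complement(q)), target)
  expect_equal(aln_rc$strand, "-")
  expect_equal(c(aln_rc$target_start, aln_rc$target_end), c(10000L, 15000L))

  none <- toy_align(c(q2 = strrep("AT", 1000)), target)
  expect_equal(nrow(none), 0)
})

test_that("toy_align intervals equal brute-force substring search for planted queries", {
  set.seed(52)
  target <- c(tgt = random_seq(60000))
  starts <- sample(0:54000, 20)
  lens <- sample(1000:5000, 20, replace = TRUE)
  qs <- setNames(substring(target[[1]], starts + 1, starts + lens),
                 sprintf("pq%02d", 1:20))
  flip <- seq(1, 20, by = 2)
  qs[flip] <- reverse_complement(qs[flip])
  aln <- toy_align(Biostrings::DNAStringSet(qs), target)
  prim <- aln[aln$tp == "P", ]
  expect_equal(nrow(prim), 20)
  for (i in 1:20) {
    id <- sprintf("pq%02d", i)
    probe <- if (i %% 2 == 1) reverse_complement(qs[[id]]) else qs[[id]]
    want_start <- as.integer(regexpr(probe, target[[1]], fixed = TRUE)) - 1L
    row <- prim[prim$query_id == id, ]
    expect_equal(row$target_start, want_start)
    expect_equal(row$target_end, want_start + nchar(probe))
    expect_equal(row$strand, if (i %% 2 == 1) "-" else "+")
  }
})

test_that("toy_align output satisfies record invariants and round-trips PAF", {
  fx <- small_fixture()
  aln <- toy_align(fx$reads[1:40], fx$chrom_assembly)
  expect_gt(nrow(aln), 0)
  expect_true(all(aln$query_start < aln$query_end))
  expect_true(all(aln$query_end <= aln$query_len))
  expect_true(all(aln$target_end <= aln$target_len))
  expect_true(all(aln$residue_matches <= aln$block_len))
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(aln, f)
  back <- parse_paf(f)
  expect_equal(back[, setdiff(names(back), "tags")],
               aln[, setdiff(names(aln), "tags")])
})

test_that("fixtures are bit-reproducible under a fixed seed", {
  f1 <- make_fixture(seed = 77, chrom_len = 30000, n_markers = 2,
                     marker_len = 400, n_drop = 1, contig_margin_bp = 800,
                     depth = 6, read_len_mean = 3000, read_len_sd = 200)
  f2 <- make_fixture(seed = 77, chrom_len = 30000, n_markers = 2,
                     marker_len = 400, n_drop = 1, contig_margin_bp = 800,
                     depth = 6, read_len_mean = 3000, read_len_sd = 200)
  expect_identical(as.character(f1$truth_genome), as.character(f2$truth_genome))
  expect_identical(as.character(f1$chrom_assembly), as.character(f2$chrom_assembly))
  expect_identical(as.character(f1$reads), as.character(f2$reads))
  expect_identical(lapply(f1$contig_sets, as.character),
                   lapply(f2$contig_sets, as.character))
})
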
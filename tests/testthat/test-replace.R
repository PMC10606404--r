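make_candidate <- function(bases, gene_start, gene_end, id = "cand1") {
  structure(list(id = id, bases = bases, gene_status = "Complete",
                 gene_start = as.integer(gene_start),
                 gene_end = as.integer(gene_end), gene_strand = "+"),
            class = "candidate_sequence")
}

test_that("plan_replacement applies an identity candidate in place", {
  set.seed(401)
  chrom <- c(chrA = random_seq(20000))
  cand_seq <- substr(chrom[[1]], 5001, 9000)
  cand <- make_candidate(cand_seq, 1000, 1400)
  aln <- toy_align(c(cand1 = cand_seq), chrom)
  ev <- plan_replacement(cand, "g", NULL, aln)
  expect_equal(ev$status, "applied")
  expect_equal(c(ev$start, ev$end), c(5000L, 9000L))
  expect_equal(nchar(ev$new_bases), ev$end - ev$start)
  expect_equal(ev$new_bases, cand_seq)
})

test_that("plan_replacement skips when the gene lies outside the aligned span", {
  set.seed(402)
  chrom <- c(chrA = random_seq(20000))
  # candidate = 4 kb matching the chromosome + 1 kb novel tail holding the gene
  matching <- substr(chrom[[1]], 2001, 6000)
  cand_seq <- paste0(matching, random_seq(1000))
  cand <- make_candidate(cand_seq, 3000, 3500)
  aln <- toy_align(c(cand1 = cand_seq), chrom)
  ok <- plan_replacement(cand, "g", NULL, aln, min_query_coverage = 0.5)
  expect_equal(ok$status, "applied")

  outside <- make_candidate(cand_seq, 4300, 4990)
  ev <- plan_replacement(outside, "g", NULL, aln, min_query_coverage = 0.5)
  expect_equal(ev$status, "skipped_gene_outside_alignment")
})

test_that("plan_replacement reports missing alignments and low coverage as skips", {
  cand <- make_candidate(strrep("ACGT", 300), 100, 300)
  expect_equal(plan_replacement(cand, "g", NULL, alignment_table())$status,
               "skipped_no_alignment")

  # alignment covering only 40% of the candidate
  aln <- alignment_table("cand1", 1200, 0, 480, "+", "chrA", 50000, 100, 580,
                         480, 480, 60)
  expect_equal(plan_replacement(cand, "g", NULL, aln)$status,
               "skipped_low_coverage")
})

test_that("chosen alignment equals brute-force argmax under the anchor filter", {
  set.seed(403)
  for (trial in 1:10) {
    n <- 8
    ts <- sample(0:40000, n)
    te <- ts + sample(2000:8000, n)
    aln <- alignment_table(rep("cand1", n), 10000, 0, 10000,
                           sample(c("+", "-"), n, TRUE), "chrA", 60000,
                           ts, te, sample(1000:9000, n), 10000, 60)
    anchor <- structure(list(chrom_id = "chrA", start = 20000L, end = 25000L,
                             strand = "+", chrom_len = 60000L),
                        class = "chromosome_anchor")
    cand <- make_candidate(random_seq(10000), 100, 600)
    ev <- plan_replacement(cand, "g", anchor, aln, min_query_coverage = 0)
    over <- aln[pmin(aln$target_end, 25000) - pmax(aln$target_start, 20000) > 0, ]
    if (nrow(over) == 0) {
      expect_equal(ev$status, "skipped_no_alignment")
    } else {
      best <- over[order(-over$residue_matches, -over$block_len,
                         over$target_id, over$target_start)[1], ]
      expect_equal(c(ev$start, ev$end), c(best$target_start, best$target_end))
    }
  }
})

test_that("apply_replacements splices with correct arithmetic and preserves flanks", {
  chrom <- c(chr1 = paste(rep("ACGTACGTAC", 10), collapse = ""))
  ev <- list(structure(list(gene_id = "g", status = "applied",
                            chrom_id = "chr1", start = 10L, end = 20L,
                            new_bases = strrep("T", 15), candidate_id = "c",
                            strand = "+"), class = "replacement_event"))
  out <- apply_replacements(chrom, ev)
  s <- as.character(out$assembly)[["chr1"]]
  expect_equal(nchar(s), 105L)
  expect_equal(substr(s, 1, 10), substr(chrom[[1]], 1, 10))
  expect_equal(substr(s, 11, 25), strrep("T", 15))
  expect_equal(substring(s, 26), substring(chrom[[1]], 21))

  ident <- apply_replacements(chrom, list())
  expect_identical(as.character(ident$assembly), chrom)
})

test_that("splicing equals an independent string rebuild on random event sets", {
  set.seed(404)
  for (trial in 1:50) {
    chrom <- c(c1 = random_seq(2000))
    n_ev <- sample(1:4, 1)
    bounds <- sort(sample(0:2000, 2 * n_ev))
    evs <- lapply(seq_len(n_ev), function(i) {
      s <- bounds[2 * i - 1]; e <- bounds[2 * i]
      if (e == s) e <- s + 1
      structure(list(gene_id = paste0("g", i), status = "applied",
                     chrom_id = "c1", start = as.integer(s),
                     end = as.integer(min(e, 2000)),
                     new_bases = random_seq(sample(1:500, 1)),
                     candidate_id = "c", strand = "+"),
                class = "replacement_event")
    })
    evs <- Filter(function(e) e$start < e$end, evs)
    got <- apply_replacements(chrom, evs)
    expect_equal(as.character(got$assembly)[["c1"]],
                 brute_splice(chrom[[1]], got$ledger$events))
  }
})

test_that("overlapping events demote the later event, out-of-bounds events error", {
  chrom <- c(c1 = strrep("A", 100))
  mk <- function(s, e, g) structure(
    list(gene_id = g, status = "applied", chrom_id = "c1",
         start = as.integer(s), end = as.integer(e), new_bases = "GGGG",
         candidate_id = "c", strand = "+"), class = "replacement_event")
  out <- apply_replacements(chrom, list(mk(10, 40, "g1"), mk(30, 60, "g2")))
  st <- vapply(out$ledger$events, `[[`, "", "status")
  expect_equal(st, c("applied", "skipped_overlap"))

  expect_error(apply_replacements(chrom, list(mk(90, 120, "g3"))), "out of bounds")
})

test_that("ledger offsets map untouched loci onto identical bases", {
  set.seed(405)
  chrom <- c(c1 = random_seq(3000))
  evs <- list(
    structure(list(gene_id = "g1", status = "applied", chrom_id = "c1",
                   start = 500L, end = 800L, new_bases = random_seq(450),
                   candidate_id = "c", strand = "+"),
              class = "replacement_event"),
    structure(list(gene_id = "g2", status = "applied", chrom_id = "c1",
                   start = 1500L, end = 1600L, new_bases = random_seq(20),
                   candidate_id = "c", strand = "+"),
              class = "replacement_event"))
  out <- apply_replacements(chrom, evs)
  final <- as.character(out$assembly)[["c1"]]
  untouched <- c(0:499, 800:1499, 1600:2999)
  mapped <- ledger_map_position(out$ledger, "c1", untouched)
  expect_false(anyNA(mapped))
  orig_b <- strsplit(chrom[[1]], "")[[1]]
  new_b <- strsplit(final, "")[[1]]
  expect_equal(new_b[mapped + 1], orig_b[untouched + 1])
  # replaced loci have no image
  expect_true(all(is.na(ledger_map_position(out$ledger, "c1", c(500, 799, 1550)))))
})

test_that("a minus-strand candidate splices the same bases as its plus-strand twin", {
  set.seed(406)
  chrom <- c(chrA = random_seq(20000))
  seg <- substr(chrom[[1]], 4001, 9000)
  fwd <- make_candidate(seg, 1000, 1500, id = "cand1")
  rev <- make_candidate(reverse_complement(seg), 5000 - 1500, 5000 - 1000,
                        id = "cand1")
  aln_f <- toy_align(c(cand1 = fwd$bases), chrom)
  aln_r <- toy_align(c(cand1 = rev$bases), chrom)
  expect_equal(aln_r$strand, "-")
  ev_f <- plan_replacement(fwd, "g", NULL, aln_f)
  ev_r <- plan_replacement(rev, "g", NULL, aln_r)
  expect_equal(ev_f$status, "applied")
  expect_equal(ev_r$status, "applied")
  expect_equal(ev_r$new_bases, ev_f$new_bases)
  expect_equal(c(ev_r$start, ev_r$end), c(ev_f$start, ev_f$end))
})

test_that("verify_no_regression detects status downgrades and missing increases", {
  t1 <- gene_status_table(c("a", "b"), c("Complete", "Missing"),
                          c("s", NA), c(0, NA), c(10, NA))
  expect_true(verify_no_regression(t1, t1)$ok)

  t2 <- gene_status_table(c("a", "b"), c("Complete", "Complete"),
                          "s", c(0, 20), c(10, 30))
  rep_up <- verify_no_regression(t1, t2)
  expect_true(rep_up$ok)
  expect_equal(rep_up$missing_before, 1)
  expect_equal(rep_up$missing_after, 0)

  rep_down <- verify_no_regression(t2, t1)
  expect_false(rep_down$ok)
  expect_equal(rep_down$worsened$gene_id, "b")
})

test_that("worsened set equals a brute-force status-lattice comparison", {
  set.seed(407)
  rank <- c(Complete = 3, Duplicated = 2, Fragmented = 1, Missing = 0)
  statuses <- names(rank)
  mk_tab <- function(st) {
    n <- length(st)
    gene_status_table(sprintf("g%02d", seq_len(n)), st,
                      sequence_id = ifelse(st == "Missing", NA, "s"),
                      start = ifelse(st == "Missing", NA,
                                     seq(0, by = 100, length.out = n)),
                      end = ifelse(st == "Missing", NA,
                                   seq(50, by = 100, length.out = n)))
  }
  for (trial in 1:10) {
    before <- sample(statuses, 20, replace = TRUE)
    after <- sample(statuses, 20, replace = TRUE)
    # keep Duplicated out: the constructor cannot represent a single
    # Duplicated hit row pair per gene uniformly here
    before[before == "Duplicated"] <- "Fragmented"
    after[after == "Duplicated"] <- "Fragmented"
    rep <- verify_no_regression(mk_tab(before), mk_tab(after))
    brute <- sprintf("g%02d", which(rank[after] < rank[before]))
    expect_equal(sort(rep$worsened$gene_id), sort(brute))
    expect_equal(rep$ok,
                 length(brute) == 0 && sum(after == "Missing") <= sum(before == "Missing"))
  }
})
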
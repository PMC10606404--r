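#' Build a complete truth-tracked pipeline fixture
#'
#' Convenience wrapper chaining [generate_genome()], [degrade_assembly()]
#' and [simulate_reads()] into the full set of pipeline inputs with known
#' ground truth: a truth genome with planted markers, a chromosome assembly
#' with dropped gene loci, jittered lost-contig sets covering them, and
#' simulated long reads with recorded origins. With `diploid = TRUE` a
#' second haplotype is derived by [make_diploid()] and reads are drawn from
#' both haplotypes at half depth each (the assembly and contigs remain
#' haplotype-1).
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_chrom,chrom_len,n_markers,marker_len Passed to
#'   [generate_genome()].
#' @param drop_genes Gene ids to drop; default the lexicographically first
#'   `n_drop` planted genes.
#' @param n_drop Number of genes to drop when `drop_genes` is `NULL`.
#' @param gap_char_policy,contig_margin_bp Passed to [degrade_assembly()].
#' @param depth,read_len_mean,read_len_sd,error_rate Passed to
#'   [simulate_reads()].
#' @param diploid Draw reads from two haplotypes.
#' @param snp_rate,ins_rate,del_rate,indel_len Second-haplotype mutation
#'   parameters (see [make_diploid()]).
#' @return A `fixture_truth` list with, in addition to the
#'   [generate_genome()] fields: `chrom_assembly`, `contig_sets`,
#'   `deletions`, `lost_contigs`, `dropped_genes`, `reads`,
#'   `read_origins` (with a `haplotype` column), and `hap2` when diploid.
#' @export
make_fixture <- function(seed = 1, n_chrom = 2, chrom_len = 100000,
                         n_markers = 6, marker_len = 1000,
                         drop_genes = NULL, n_drop = 3,
                         gap_char_policy = "excise", contig_margin_bp = 2000,
                         depth = 20, read_len_mean = 15000,
                         read_len_sd = 1500, error_rate = 0,
                         diploid = FALSE, snp_rate = 0.02, ins_rate = 0.02,
                         del_rate = 0.02, indel_len = 12) {
  fx <- generate_genome(n_chrom, chrom_len, n_markers, marker_len, seed = seed)
  if (is.null(drop_genes)) {
    drop_genes <- utils::head(sort(fx$catalog$gene_id), n_drop)
  }
  fx <- degrade_assembly(fx, drop_genes, gap_char_policy = gap_char_policy,
                         contig_margin_bp = contig_margin_bp,
                         seed = seed + 1L)
  if (!diploid) {
    sim <- simulate_reads(fx$truth_genome, depth = depth,
                          read_len_mean = read_len_mean,
                          read_len_sd = read_len_sd,
                          error_rate = error_rate, seed = seed + 2L)
    fx$reads <- sim$reads
    fx$read_origins <- cbind(sim$origins, haplotype = "hap1")
  } else {
    fx$hap2 <- make_diploid(fx$truth_genome, snp_rate, ins_rate, del_rate,
                            indel_len, seed = seed + 3L)
    s1 <- simulate_reads(fx$truth_genome, depth = depth / 2,
                         read_len_mean = read_len_mean,
                         read_len_sd = read_len_sd, error_rate = error_rate,
                         seed = seed + 2L, read_prefix = "h1read")
    s2 <- simulate_reads(fx$hap2, depth = depth / 2,
                         read_len_mean = read_len_mean,
                         read_len_sd = read_len_sd, error_rate = error_rate,
                         seed = seed + 4L, read_prefix = "h2read")
    fx$reads <- c(s1$reads, s2$reads)
    fx$read_origins <- rbind(cbind(s1$origins, haplotype = "hap1"),
                             cbind(s2$origins, haplotype = "hap2"))
  }
  fx
}

#' Remove all evidence for one dropped gene from a fixture
#'
#' Deletes the lost contigs covering the gene from every contig set and
#' removes every read whose true origin overlaps the gene's removed
#' interval, producing a fixture in which that gene is unrecoverable — the
#' pipeline must then report it skipped while still recovering the others.
#'
#' @param fixture A fixture from [make_fixture()].
#' @param gene_id One of the fixture's dropped genes.
#' @return The modified fixture.
#' @export
remove_gene_evidence <- function(fixture, gene_id) {
  assert_that(gene_id %in% fixture$dropped_genes,
              gene_id, " is not a dropped gene of this fixture")
  drop_ctg <- fixture$lost_contigs$contig_id[fixture$lost_contigs$gene_id == gene_id]
  fixture$contig_sets <- lapply(fixture$contig_sets, function(s) {
    s[setdiff(names(s), drop_ctg)]
  })
  del <- fixture$deletions[fixture$deletions$gene_id == gene_id, , drop = FALSE]
  org <- fixture$read_origins
  hit <- org$chrom_id == del$chrom_id &
    interval_overlap(org$start, org$end, del$start, del$end) > 0
  fixture$reads <- fixture$reads[setdiff(names(fixture$reads), org$read_id[hit])]
  fixture$read_origins <- org[!hit, , drop = FALSE]
  fixture
}

#' Write a fixture's pipeline inputs to a directory
#'
#' Produces `truth.fasta`, `chrom_asm.fasta`, one `contigs_setN.fasta` per
#' contig set, `reads.fastq`, `catalog.fasta`, a ready-to-run `config.yaml`
#' and a `truth.json` sidecar with the full provenance (planted loci,
#' deletions, lost contigs, read origins).
#'
#' @param fixture A fixture from [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$truth_genome, file.path(dir, "truth.fasta"))
  write_fasta(fixture$chrom_assembly, file.path(dir, "chrom_asm.fasta"))
  set_files <- sprintf("contigs_set%d.fasta", seq_along(fixture$contig_sets))
  for (s in seq_along(fixture$contig_sets)) {
    write_fasta(fixture$contig_sets[[s]], file.path(dir, set_files[s]))
  }
  write_fastq(fixture$reads, file.path(dir, "reads.fastq"))
  write_marker_catalog(fixture$catalog, file.path(dir, "catalog.fasta"))
  yaml::write_yaml(list(chrom_assembly = "chrom_asm.fasta",
                        contig_sets = as.list(set_files),
                        reads = "reads.fastq", catalog = "catalog.fasta"),
                   file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = fixture$seed, marker_loci = fixture$marker_loci,
         deletions = fixture$deletions, lost_contigs = fixture$lost_contigs,
         dropped_genes = fixture$dropped_genes,
         read_origins = fixture$read_origins),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Pipeline configuration for an in-memory fixture
#'
#' @param fixture A fixture from [make_fixture()].
#' @param out_dir Optional output directory.
#' @param ... Tunables passed to [pipeline_config()].
#' @return A `pipeline_config` using the built-in toy adapters.
#' @export
fixture_config <- function(fixture, out_dir = NULL, ...) {
  pipeline_config(chrom_assembly = fixture$chrom_assembly,
                  contig_sets = fixture$contig_sets,
                  reads = fixture$reads, catalog = fixture$catalog,
                  out_dir = out_dir, ...)
}
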
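PIPELINE_DEFAULTS <- list(
  flank_bp = 50000, min_anchor_matches = 500, min_query_coverage = 0.8,
  min_overlap_bp = 1, min_olap = 500, include_fragmented = FALSE,
  force = FALSE, seed = 1, k = 31, stride = 20, max_gap = 20000,
  min_chain_bp = 500, min_fragment_fraction = 0.5)

PIPELINE_KEYS <- c("chrom_assembly", "contig_sets", "reads", "catalog",
                   "out_dir", "adapters", names(PIPELINE_DEFAULTS))

#' Build and validate a pipeline configuration
#'
#' @param chrom_assembly Path to the chromosome-level assembly FASTA (or an
#'   in-memory [Biostrings::DNAStringSet]).
#' @param contig_sets List (>= 1) of contig FASTA paths or DNAStringSets;
#'   multiple sets emulate merged multi-assembler input.
#' @param reads Path to reads FASTA/FASTQ, or a DNAStringSet.
#' @param catalog Path to the marker catalog FASTA, or a [marker_catalog()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param adapters Named list with entries `assessor`, `aligner`,
#'   `assembler`; each either `"builtin-toy"` (default) or a command
#'   template string (see [external_aligner()] and friends).
#' @param ... Tunables overriding the documented defaults: `flank_bp`
#'   (50000), `min_anchor_matches` (500), `min_query_coverage` (0.8),
#'   `min_overlap_bp` (1), `min_olap` (500), `include_fragmented` (FALSE),
#'   `force` (FALSE), `seed` (1), and toy-aligner settings `k` (31),
#'   `stride` (20), `max_gap` (20000), `min_chain_bp` (500),
#'   `min_fragment_fraction` (0.5). Unknown names are an error.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(chrom_assembly, contig_sets, reads, catalog,
                            out_dir = NULL,
                            adapters = list(assessor = "builtin-toy",
                                            aligner = "builtin-toy",
                                            assembler = "builtin-toy"),
                            ...) {
  tun <- list(...)
  unknown <- setdiff(names(tun), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0)
    abort("unknown configuration key(s): ", paste(unknown, collapse = ", "),
          class = "contigrecall_config_error")
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, tun)
  cfg$chrom_assembly <- chrom_assembly
  cfg$contig_sets <- if (is.list(contig_sets)) contig_sets else list(contig_sets)
  cfg$reads <- reads
  cfg$catalog <- catalog
  cfg$out_dir <- out_dir
  known_adapters <- c("assessor", "aligner", "assembler")
  bad <- setdiff(names(adapters), known_adapters)
  if (length(bad) > 0)
    abort("unknown adapter(s): ", paste(bad, collapse = ", "),
          class = "contigrecall_config_error")
  for (a in known_adapters) adapters[[a]] <- adapters[[a]] %||% "builtin-toy"
  cfg$adapters <- adapters
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @noRd
validate_config <- function(cfg) {
  chk_path <- function(x, what) {
    if (is.character(x) && !file.exists(x))
      abort("configured ", what, " file does not exist: ", x,
            class = "contigrecall_config_error")
  }
  chk_path(cfg$chrom_assembly, "chrom_assembly")
  for (p in cfg$contig_sets) chk_path(p, "contig_sets")
  chk_path(cfg$reads, "reads")
  chk_path(cfg$catalog, "catalog")
  rng <- function(val, lo, hi, what) {
    if (!is.numeric(val) || val < lo || val > hi)
      abort("configuration key ", what, " out of range [", lo, ", ", hi, "]",
            class = "contigrecall_config_error")
  }
  rng(cfg$flank_bp, 0, Inf, "flank_bp")
  rng(cfg$min_anchor_matches, 0, Inf, "min_anchor_matches")
  rng(cfg$min_query_coverage, 0, 1, "min_query_coverage")
  rng(cfg$min_overlap_bp, 1, Inf, "min_overlap_bp")
  rng(cfg$min_olap, 1, Inf, "min_olap")
  rng(cfg$k, 11, Inf, "k")
  rng(cfg$min_fragment_fraction, 1e-9, 1, "min_fragment_fraction")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Required keys: `chrom_assembly`, `contig_sets` (a list), `reads`,
#' `catalog`. Optional: `out_dir`, `adapters`, and any tunable accepted by
#' [pipeline_config()]. Unknown keys are an error, so typos never pass
#' silently.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_io("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(unknown) > 0)
    abort("unknown configuration key(s) in ", path, ": ",
          paste(unknown, collapse = ", "), class = "contigrecall_config_error")
  req <- c("chrom_assembly", "contig_sets", "reads", "catalog")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    abort("missing required configuration key(s): ",
          paste(miss, collapse = ", "), class = "contigrecall_config_error")
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p)))
      file.path(base, p) else p
  }
  args <- list(chrom_assembly = resolve(raw$chrom_assembly),
               contig_sets = lapply(as.list(raw$contig_sets), resolve),
               reads = resolve(raw$reads), catalog = resolve(raw$catalog),
               out_dir = raw$out_dir,
               adapters = raw$adapters %||% list())
  tun <- raw[setdiff(names(raw), c(names(args), "adapters"))]
  tun$adapters <- NULL
  do.call(pipeline_config, c(args, tun))
}

#' Write a pipeline configuration as YAML
#'
#' Only path-valued inputs can be serialized; in-memory inputs are an
#' error. The written file round-trips through [load_config()].
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  paths <- c(list(config$chrom_assembly, config$reads, config$catalog),
             config$contig_sets)
  if (!all(vapply(paths, is.character, logical(1))))
    abort("dump_config requires all inputs to be file paths")
  keep <- config[c("chrom_assembly", "contig_sets", "reads", "catalog",
                   names(PIPELINE_DEFAULTS))]
  keep$out_dir <- config$out_dir
  keep$adapters <- config$adapters
  keep <- keep[!vapply(keep, is.null, logical(1))]
  yaml::write_yaml(keep, path)
  invisible(path)
}

#' Merge contig sets from multiple assemblers into one collection
#'
#' Sets are concatenated in order. When an id occurs in more than one set,
#' every occurrence is disambiguated with a set-index prefix (`s1.`,
#' `s2.`, ...); unique ids are kept verbatim.
#'
#' @param sets List (>= 1) of [Biostrings::DNAStringSet] or named character
#'   vectors.
#' @return A single [Biostrings::DNAStringSet].
#' @export
merge_contig_sets <- function(sets) {
  assert_that(length(sets) >= 1, "at least one contig set is required")
  sets <- lapply(sets, as_dna)
  ids <- lapply(sets, names)
  all_ids <- unlist(ids)
  dup <- unique(all_ids[duplicated(all_ids)])
  for (s in seq_along(sets)) {
    clash <- ids[[s]] %in% dup
    names(sets[[s]])[clash] <- paste0("s", s, ".", ids[[s]][clash])
  }
  do.call(c, sets)
}
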
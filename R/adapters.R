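#' External completeness-assessor adapter
#'
#' Wraps a shell command template into the assessor interface
#' `function(seqs) -> gene_status_table`. The template must contain the
#' placeholders `{fasta}` (input sequences) and `{out}` (full-table TSV the
#' command must produce), e.g. a wrapper script around a BUSCO run.
#'
#' @param template Command template string.
#' @return An assessor function.
#' @export
external_assessor <- function(template) {
  force(template)
  function(seqs) {
    fa <- tempfile(fileext = ".fasta")
    out <- tempfile(fileext = ".tsv")
    write_fasta(seqs, fa)
    run_adapter_command(template, c(fasta = fa, out = out))
    parse_busco_full_table(out)
  }
}

#' External aligner adapter
#'
#' Wraps a shell command template into the aligner interface
#' `function(queries, targets) -> alignment data frame`. The template must
#' contain `{queries}`, `{targets}` and `{out}` (PAF output), e.g.
#' `"minimap2 -x asm5 {targets} {queries} > {out}"`.
#'
#' @param template Command template string.
#' @return An aligner function.
#' @export
external_aligner <- function(template) {
  force(template)
  function(queries, targets) {
    qf <- tempfile(fileext = ".fasta")
    tf <- tempfile(fileext = ".fasta")
    out <- tempfile(fileext = ".paf")
    write_fasta(queries, qf)
    write_fasta(targets, tf)
    run_adapter_command(template, c(queries = qf, targets = tf, out = out))
    parse_paf(out)
  }
}

#' External assembler adapter
#'
#' Wraps a shell command template into the assembler interface
#' `function(reads) -> DNAStringSet`. The template must contain
#' `{reads_fasta}` and `{out_dir}`; every FASTA file the command leaves in
#' `{out_dir}` is read back as candidate contigs. Ready-made templates for
#' hifiasm-like and hicanu-like tools are available by name.
#'
#' @param template Command template string, or one of `"hifiasm-like"`,
#'   `"hicanu-like"` to use a standard invocation with default parameters.
#' @return An assembler function.
#' @export
external_assembler <- function(template) {
  template <- switch(template,
    "hifiasm-like" = paste0("hifiasm -o {out_dir}/asm {reads_fasta} && ",
                            "awk '/^S/{print \">\"$2\"\\n\"$3}' ",
                            "{out_dir}/asm.bp.p_ctg.gfa > {out_dir}/asm.fasta"),
    "hicanu-like" = paste0("canu -p asm -d {out_dir} -pacbio-hifi ",
                           "{reads_fasta}"),
    template)
  force(template)
  function(reads) {
    rf <- tempfile(fileext = ".fasta")
    od <- tempfile("asm_out")
    dir.create(od)
    write_fasta(reads, rf)
    run_adapter_command(template, c(reads_fasta = rf, out_dir = od))
    fas <- list.files(od, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (length(fas) == 0)
      abort("external assembler produced no FASTA output in ", od)
    do.call(c, lapply(sort(fas), read_fasta))
  }
}

#' @noRd
run_adapter_command <- function(template, subs) {
  cmd <- template
  for (nm in names(subs)) {
    cmd <- gsub(paste0("{", nm, "}"), subs[[nm]], cmd, fixed = TRUE)
  }
  log_msg("adapter command: ", cmd)
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L))
    abort("adapter command failed with exit status ", status, ": ", cmd)
  invisible(cmd)
}

#' Resolve configured adapters into functions
#' @noRd
resolve_adapters <- function(config, catalog) {
  a <- config$adapters
  assessor <- if (is.function(a$assessor)) a$assessor
  else if (identical(a$assessor, "builtin-toy")) {
    function(seqs) toy_marker_scan(seqs, catalog)
  } else external_assessor(a$assessor)
  aligner <- if (is.function(a$aligner)) a$aligner
  else if (identical(a$aligner, "builtin-toy")) {
    function(queries, targets) {
      toy_align(queries, targets, k = config$k, min_chain_bp = config$min_chain_bp,
                stride = config$stride, max_gap = config$max_gap)
    }
  } else external_aligner(a$aligner)
  assembler <- if (is.function(a$assembler)) a$assembler
  else if (identical(a$assembler, "builtin-toy")) {
    function(reads) toy_assemble(reads, min_olap = config$min_olap)
  } else external_assembler(a$assembler)
  list(assessor = assessor, aligner = aligner, assembler = assembler)
}
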
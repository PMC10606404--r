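`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class = "contigrecall_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

abort_format <- function(...) abort(..., class = "contigrecall_format_error")
abort_io <- function(...) abort(..., class = "contigrecall_io_error")

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) abort(...)
  invisible(TRUE)
}

#' Length of the overlap between two half-open intervals
#' @noRd
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Run code with a fixed RNG state, restoring the caller's state afterwards
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

log_msg <- function(..., verbose = getOption("contigrecall.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[contigrecall] ", ...)
  invisible(NULL)
}
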
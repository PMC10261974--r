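#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim pchisq pwilcox cor.test wilcox.test sd rexp runif
#'   rpois setNames cor
#' @importFrom utils read.delim write.table combn head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Package-wide condition log: operations that drop/skip data append a short
# message here so pipelines can report exclusions without aborting.
cm_log <- local({
  entries <- character(0)
  list(
    add = function(msg) entries <<- c(entries, msg),
    get = function() entries,
    clear = function() entries <<- character(0)
  )
})

#' Retrieve and clear the package condition log
#'
#' Non-fatal data exclusions (dropped records, trimmed codons, skipped
#' alignment pairs) are accumulated in an internal log. `cm_log_entries()`
#' returns the messages logged since the last clear; `cm_log_clear()` empties
#' the log.
#'
#' @return Character vector of log messages.
#' @export
cm_log_entries <- function() cm_log$get()

#' @rdname cm_log_entries
#' @export
cm_log_clear <- function() invisible(cm_log$clear())

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper used throughout the package; ambiguity
#' code N maps to N.
#'
#' @param seq Character scalar over A,C,G,T,N (case-insensitive).
#' @return Uppercase reverse complement.
#' @export
revcomp <- function(seq) {
  stopifnot(is_scalar_string(seq))
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}
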
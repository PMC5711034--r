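# Internal helpers shared across modules.

# Attach a named integer log of filtered/skipped record counts to an object.
# Retrieved with allosim_log(); optionally echoed with message() when verbose.
set_log <- function(x, counts, verbose = FALSE) {
  attr(x, "allosim_log") <- counts
  if (verbose && length(counts)) {
    for (nm in names(counts)) {
      message(sprintf("[allosim] %s: %s", nm, counts[[nm]]))
    }
  }
  x
}

#' Retrieve the processing log attached to an allosim result
#'
#' Most filtering operations record how many records they skipped or removed
#' (indels, terminal-truncated peptide contexts, genes missing from the
#' expression table, ...). The counts are attached as an attribute so they do
#' not pollute the data itself.
#'
#' @param x an object returned by an allosim operation.
#' @return a named numeric vector of counts (possibly empty).
#' @export
allosim_log <- function(x) {
  lg <- attr(x, "allosim_log")
  if (is.null(lg)) setNames(numeric(0), character(0)) else lg
}

# Standard amino-acid alphabet used throughout.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

is_standard_peptide <- function(seqs) {
  !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), seqs)
}

# exp() with the argument clamped to +/- 700 so intermediate states can never
# overflow to Inf; 700 is just inside the double range (exp(709) < .Machine).
safe_exp <- function(x) exp(pmin(pmax(x, -700), 700))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
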
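#' @importFrom stats pbinom rbinom runif setNames p.adjust ave
#' @importFrom utils write.table read.table
NULL

# Locale-independent ordering so outputs are byte-identical across machines.
radix_order <- function(...) order(..., method = "radix")

#' Format a percentage from integer counts
#'
#' Percentages in reports are always derived from the underlying counts at
#' render time, never stored. A zero denominator yields `"NA"` rather than an
#' error, so empty runs still produce a well-formed report.
#'
#' @param num,den Non-negative counts (numerator, denominator).
#' @param digits Decimal places (default 1).
#' @return Character scalar such as `"44.3%"`, or `"NA"` when `den == 0`.
#' @examples
#' percent_label(9293, 20957)
#' @export
percent_label <- function(num, den, digits = 1) {
  if (is.na(den) || den == 0) return("NA")
  sprintf(paste0("%.", digits, "f%%"), 100 * num / den)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(field, "must be a single number in [0, 1]")
  x
}

check_pos_int <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_pos_num <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  x
}

# Random DNA of length n as a character scalar; fast via intToUtf8.
random_dna <- function(n) {
  if (n == 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(s) {
  nchar(s) > 0 && all(strsplit(s, "")[[1]] %in% names(IUPAC_SETS))
}
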
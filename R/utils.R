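#' @keywords internal
"_PACKAGE"

# Stage logging: one-line messages with counts, silenced via option.
stage_log <- function(stage, fmt, ...) {
  if (isTRUE(getOption("crcmir.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[crcmir:%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used
#' throughout the test-suite to score recovery of planted subtypes.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
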
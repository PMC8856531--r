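#' @importFrom rlang %||% .data
#' @importFrom ggplot2 autoplot
#' @import tibble
#' @importFrom dplyr filter mutate arrange select group_by ungroup summarise
#'   bind_rows left_join n distinct pull
#' @useDynLib mrpsupertree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# greatest common divisor / least common multiple on integer-valued doubles;
# denominators here are small (tied-group sizes), so no overflow concern
gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

lcm_all <- function(x) Reduce(lcm2, x, accumulate = FALSE)

# canonical string key for a set of taxon labels
cluster_key <- function(labels) paste(sort(labels), collapse = "\r")

key_to_labels <- function(key) strsplit(key, "\r", fixed = TRUE)[[1]]

`%||%` <- rlang::`%||%`
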
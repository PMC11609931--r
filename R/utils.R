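#' @importFrom stats rnorm runif sd
#' @importFrom utils read.csv write.csv write.table modifyList tail capture.output
#' @importFrom Rcpp evalCpp
#' @useDynLib ildfusion, .registration = TRUE
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise numerically stable softmax
#'
#' Subtracts the row maximum before exponentiating so that large scores
#' (e.g. 1000) do not overflow.
#'
#' @param x numeric matrix or vector.
#' @return object of the same shape with non-negative rows summing to 1.
#' @keywords internal
softmax_rows <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (any(!is.finite(x))) stop("softmax: non-finite scores", call. = FALSE)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  if (any(!is.finite(x))) stop("softmax: non-finite scores", call. = FALSE)
  e <- exp(x - max(x))
  e / sum(e)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a child RNG seed from a base seed
#'
#' Deterministic mixing that stays inside the 32-bit signed integer range,
#' so that per-sample streams are reproducible and independent of how many
#' samples precede them.
#'
#' @keywords internal
derive_seed <- function(seed, index, stream = 0L) {
  s <- (as.double(seed) %% 2147483647) * 2654435761 +
    as.double(index) * 40503 + as.double(stream) * 69069
  as.integer(s %% 2147483563) + 1L
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
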
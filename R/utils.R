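sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) x * (x > 0)

# column maxima of a matrix (C-speed via max.col)
.colMaxs <- function(x) {
  tx <- t(x)
  idx <- max.col(tx, ties.method = "first")
  tx[cbind(seq_len(nrow(tx)), idx)]
}

# slice a 3D array at index t of dim 3, keeping matrix shape
.slice3 <- function(a, t) matrix(a[, , t], dim(a)[1], dim(a)[2])

#' Derive a stage seed from a global seed
#'
#' Stage-scoped seeds keep pipeline stages independently reproducible: the
#' stage seed is a deterministic 31-bit hash of the global seed and the
#' stage name.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483629)
}
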
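# Internal numerical helpers and error classes.

# Classed errors so callers (and the CLI) can distinguish configuration /
# validation problems from bad data.
.glms_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "glms_error", "error")))
}
.stop_config    <- function(msg) .glms_stop(msg, "glms_config_error")
.stop_validation<- function(msg) .glms_stop(msg, "glms_validation_error")
.stop_alignment <- function(msg) .glms_stop(msg, "glms_alignment_error")
.stop_data      <- function(msg) .glms_stop(msg, "glms_data_error")

#' Moore-Penrose pseudo-inverse
#'
#' Computes the pseudo-inverse of a real matrix through its singular value
#' decomposition, dropping singular values at or below
#' `max(dim(x)) * eps * max(d)`. Applied to a design matrix this yields the
#' minimum-Euclidean-norm least-squares solution, which remains defined under
#' rank deficiency.
#'
#' @param x Numeric matrix.
#' @param tol Optional singular-value cutoff; defaults to the machine-precision
#'   rule above.
#' @return Matrix of dimension `ncol(x)` by `nrow(x)`.
#' @export
mppi <- function(x, tol = NULL) {
  x <- as.matrix(x)
  s <- svd(x)
  if (is.null(tol)) tol <- max(dim(x)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Numerical rank via the same SVD tolerance rule used by mppi().
.matrix_rank <- function(x, tol = NULL) {
  d <- svd(as.matrix(x), nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(x)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

# Draw k independent sub-seeds (< 2^31) from a master seed without touching
# the caller's RNG state.
.derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
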
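#' Iterative correction (ICE) balancing
#'
#' Estimates one multiplicative weight per bin so that the balanced matrix
#' `count * w_i * w_j` has equal row sums over valid bins, by iteratively
#' dividing each weight by its (normalized) balanced coverage. Low-coverage
#' bins are masked before iteration: bins with zero raw coverage, plus bins
#' whose nonzero coverage falls below the `mask_quantile` quantile of nonzero
#' coverages.
#'
#' @param M A [contact_matrix()].
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   balanced row sums over valid bins.
#' @param mask_quantile Fraction of the lowest nonzero-coverage bins to mask,
#'   in `[0, 1)`.
#' @return The matrix with `weights` (mean 1 over valid bins, `NA` on masked
#'   bins) and `valid` set, and attributes `ice_iterations`, `ice_cv` and
#'   `ice_converged`. Non-convergence raises a warning, not an error.
#' @export
ice_balance <- function(M, max_iter = 200L, tol = 1e-5, mask_quantile = 0.02) {
  stopifnot(inherits(M, "contact_matrix"))
  if (nrow(M$pixels) == 0L) stop("matrix has no counts")
  if (mask_quantile < 0 || mask_quantile >= 1) stop("mask_quantile must be in [0, 1)")
  A <- sparse_symmetric(M)
  cov0 <- Matrix::rowSums(A)
  nz <- cov0[cov0 > 0]
  thr <- if (mask_quantile > 0) stats::quantile(nz, mask_quantile, names = FALSE) else -Inf
  valid <- cov0 > 0 & cov0 >= thr
  if (!any(valid)) stop("all bins masked")

  w <- as.numeric(valid) # masked bins contribute nothing
  cv <- Inf
  it <- 0L
  while (it < max_iter) {
    s <- w * as.numeric(A %*% w)
    sv <- s[valid]
    m <- mean(sv)
    cv <- stats::sd(sv) / m
    if (is.na(cv)) cv <- 0 # single valid bin
    if (cv < tol) break
    d <- s / m
    d[!valid | d == 0] <- 1
    w <- w / d
    it <- it + 1L
  }
  converged <- cv < tol
  if (!converged)
    warning(sprintf("ICE did not converge in %d iterations (row-sum CV %.3g)", max_iter, cv))
  w[valid] <- w[valid] / mean(w[valid])
  w[!valid] <- NA_real_
  M$weights <- w
  M$valid <- valid
  M$balanced <- TRUE
  attr(M, "ice_iterations") <- it
  attr(M, "ice_cv") <- cv
  attr(M, "ice_converged") <- converged
  M
}

#' Coefficient of variation of balanced row sums
#'
#' Diagnostic for [ice_balance()]: CV of the balanced coverage over valid bins.
#'
#' @param M A balanced `contact_matrix`.
#' @return A single number.
#' @export
balanced_rowsum_cv <- function(M) {
  if (!is_balanced(M)) stop("matrix is not balanced")
  A <- sparse_symmetric(M)
  w <- ifelse(is.na(M$weights), 0, M$weights)
  s <- (w * as.numeric(A %*% w))[M$valid]
  stats::sd(s) / mean(s)
}
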
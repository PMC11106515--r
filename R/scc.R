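#' Edge-truncated 2D mean filter
#'
#' Replaces each cell by the mean of the `(2h+1) x (2h+1)` window centred on
#' it, truncating the window at the matrix edges. `h = 0` is the identity.
#' Used to smooth cis blocks before stratum-adjusted correlation.
#'
#' @param mat A dense numeric matrix.
#' @param h Half-window in bins, `>= 0`.
#' @return A matrix of the same dimension.
#' @export
smooth_matrix <- function(mat, h) {
  h <- as.integer(h)
  if (h < 0L) stop("h must be >= 0")
  if (h == 0L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  S <- sat(mat)
  r1 <- as.vector(pmax(row(mat) - h, 1L)); r2 <- as.vector(pmin(row(mat) + h, nr))
  c1 <- as.vector(pmax(col(mat) - h, 1L)); c2 <- as.vector(pmin(col(mat) + h, nc))
  tot <- sat_rect(S, r1, r2, c1, c2)
  matrix(tot / ((r2 - r1 + 1L) * (c2 - c1 + 1L)), nr, nc)
}

#' Stratum-adjusted correlation coefficient (SCC)
#'
#' HiCRep-style reproducibility measure between two contact maps: after mean
#' smoothing, pixels are stratified by genomic separation; within each stratum
#' `k` the Pearson correlation `r_k` between the paired pixel vectors is
#' combined as `sum(w_k r_k) / sum(w_k)` with `w_k = N_k *
#' sqrt(var_A(k) * var_B(k))`. Zero-variance strata are skipped. Raw counts
#' are compared by default (set `balanced = TRUE` to compare balanced values).
#'
#' @param A,B `contact_matrix` objects on the same grid.
#' @param chroms Chromosomes to use (default all).
#' @param h Smoothing half-window in bins.
#' @param s_max Maximum separation in bp.
#' @param balanced Compare balanced instead of raw values.
#' @return A list of class `scc_result`: `scc` (pooled, weights summed over
#'   chromosomes), `per_chrom` data.frame (`chrom`, `scc`, `n_strata`),
#'   `strata` data.frame (`chrom`, `sep_bins`, `r`, `weight`, `n`).
#' @export
scc <- function(A, B, chroms = NULL, h = 1L, s_max = 5e6, balanced = FALSE) {
  if (!same_grid(A$spec, B$spec)) stop("matrices are on different bin grids")
  res <- A$spec$resolution
  if (s_max < res) stop("s_max must be at least one bin")
  if (is.null(chroms)) chroms <- A$spec$chroms
  strata <- lapply(chroms, function(ch) {
    a <- dense_block(A, ch, balanced = balanced)
    b <- dense_block(B, ch, balanced = balanced)
    a[is.na(a)] <- 0; b[is.na(b)] <- 0 # masked bins carry no signal
    a <- smooth_matrix(a, h)
    b <- smooth_matrix(b, h)
    n <- nrow(a)
    kmax <- min(n - 1L, as.integer(s_max / res))
    if (kmax < 1L) return(NULL)
    out <- lapply(seq_len(kmax), function(k) {
      idx <- cbind(seq_len(n - k), (1L + k):n)
      va <- a[idx]; vb <- b[idx]
      ok <- !is.na(va) & !is.na(vb)
      va <- va[ok]; vb <- vb[ok]
      if (length(va) < 2L) return(NULL)
      sa <- stats::var(va); sb <- stats::var(vb)
      if (sa == 0 || sb == 0) return(NULL)
      data.frame(chrom = ch, sep_bins = k, r = stats::cor(va, vb),
                 weight = length(va) * sqrt(sa * sb), n = length(va),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  strata <- do.call(rbind, strata)
  if (is.null(strata) || nrow(strata) == 0L) stop("no valid strata")
  per <- do.call(rbind, lapply(split(strata, strata$chrom), function(s) {
    data.frame(chrom = s$chrom[1L], scc = sum(s$weight * s$r) / sum(s$weight),
               n_strata = nrow(s), weight = sum(s$weight),
               stringsAsFactors = FALSE)
  }))
  per <- per[match(intersect(chroms, per$chrom), per$chrom), ]
  rownames(per) <- NULL
  structure(list(scc = sum(strata$weight * strata$r) / sum(strata$weight),
                 per_chrom = per, strata = strata, h = h, s_max = s_max),
            class = "scc_result")
}

#' @export
print.scc_result <- function(x, ...) {
  cat(sprintf("SCC = %.4f over %d strata (h = %d, s_max = %s bp)\n",
              x$scc, nrow(x$strata), x$h, format(x$s_max, big.mark = ",")))
  invisible(x)
}
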
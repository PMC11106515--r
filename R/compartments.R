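#' Observed/expected transform of a cis block
#'
#' Divides each pixel of the balanced cis block by the distance expected at
#' its separation. Masked bins become `NaN` rows/columns.
#'
#' @param M A balanced [contact_matrix()].
#' @param chrom Chromosome name.
#' @param expected Optional precomputed per-chrom [compute_expected()] profile.
#' @return Dense symmetric O/E matrix.
#' @export
oe_transform <- function(M, chrom, expected = NULL) {
  if (!is_balanced(M)) stop("matrix must be balanced first")
  if (is.null(expected)) expected <- compute_expected(M, "per-chrom")
  blk <- dense_block(M, chrom, balanced = TRUE)
  n <- nrow(blk)
  e <- expected_vector(expected, chrom, n)
  sep <- abs(row(blk) - col(blk))
  ed <- matrix(e[sep + 1L], n, n)
  out <- blk / ed
  out[!is.finite(out)] <- NaN
  bad <- !chrom_valid(M, chrom)
  out[bad, ] <- NaN
  out[, bad] <- NaN
  out
}

#' Bin-bin correlation matrix of an O/E block
#'
#' Pearson correlation between bin rows (pairwise-complete over `NaN`s). Bins
#' that are all-`NaN` or have zero variance are masked to `NaN`. Separations
#' up to `ignore_diags` bins are excluded from the correlation so that
#' domain-scale (TAD) covariance near the diagonal does not leak into the
#' compartment signal.
#'
#' @param OE Dense O/E matrix from [oe_transform()].
#' @param ignore_diags Number of diagonals (each side) to exclude.
#' @return Dense correlation matrix with unit diagonal on valid bins.
#' @export
correlation_matrix <- function(OE, ignore_diags = 0L) {
  n <- nrow(OE)
  if (ignore_diags > 0L) OE[abs(row(OE) - col(OE)) <= ignore_diags] <- NaN
  finite_n <- colSums(is.finite(OE))
  sds <- apply(OE, 2L, stats::sd, na.rm = TRUE)
  valid <- finite_n >= 3L & !is.na(sds) & sds > 0
  if (sum(valid) < 3L) stop("fewer than 3 valid bins with variance")
  C <- matrix(NaN, n, n)
  Cv <- suppressWarnings(stats::cor(OE[valid, valid, drop = FALSE],
                                    use = "pairwise.complete.obs"))
  diag(Cv) <- 1
  C[valid, valid] <- Cv
  C
}

#' Leading eigenvector (PC1) of a correlation block
#'
#' Principal component of the bin-bin correlation matrix: columns are centred
#' and the dominant eigenvector of the resulting covariance is found by power
#' iteration. The vector has unit norm over valid bins, `NaN` at masked bins,
#' and a provisional sign (orient it with [classify_compartments()]).
#'
#' @param C Correlation matrix from [correlation_matrix()].
#' @param tol Convergence tolerance on the iterate change.
#' @param max_iter Maximum power iterations.
#' @return Numeric vector of PC1 values.
#' @export
compartment_eigenvector <- function(C, tol = 1e-12, max_iter = 10000L) {
  if (nrow(C) != ncol(C)) stop("correlation matrix must be square")
  valid <- apply(C, 1L, function(r) any(is.finite(r)))
  Cv <- C[valid, valid, drop = FALSE]
  if (max(abs(Cv - t(Cv)), na.rm = TRUE) > 1e-8) stop("correlation matrix is not symmetric")
  if (nrow(Cv) < 3L) stop("fewer than 3 valid bins")
  Cv[!is.finite(Cv)] <- 0 # isolated pairwise-incomplete cells
  Cc <- sweep(Cv, 2L, colMeans(Cv))
  S <- crossprod(Cc) / (nrow(Cc) - 1L)
  # deterministic start: the column of S with the largest norm
  v <- S[, which.max(colSums(S^2))]
  v <- v / sqrt(sum(v^2))
  for (it in seq_len(max_iter)) {
    v2 <- as.numeric(S %*% v)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) stop("power iteration collapsed to zero vector")
    v2 <- v2 / nv
    if (sum(v2 * v) < 0) v2 <- -v2
    if (max(abs(v2 - v)) < tol) {
      v <- v2
      break
    }
    v <- v2
    if (it == max_iter) stop("power iteration did not converge")
  }
  out <- rep(NaN, nrow(C))
  out[valid] <- v
  out
}

# top k principal components of a correlation block by power iteration with
# deflation; columns are unit-norm full-length vectors (NaN at masked bins)
top_eigenvectors <- function(C, k = 3L, tol = 1e-12, max_iter = 10000L) {
  valid <- apply(C, 1L, function(r) any(is.finite(r)))
  Cv <- C[valid, valid, drop = FALSE]
  Cv[!is.finite(Cv)] <- 0
  Cc <- sweep(Cv, 2L, colMeans(Cv))
  S <- crossprod(Cc) / (nrow(Cc) - 1L)
  n <- nrow(S)
  out <- matrix(NaN, nrow(C), k)
  for (comp in seq_len(k)) {
    v <- S[, which.max(colSums(S^2))]
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
    for (it in seq_len(max_iter)) {
      v2 <- as.numeric(S %*% v)
      nv <- sqrt(sum(v2^2))
      if (nv == 0) break
      v2 <- v2 / nv
      if (sum(v2 * v) < 0) v2 <- -v2
      conv <- max(abs(v2 - v)) < tol
      v <- v2
      if (conv) break
    }
    out[valid, comp] <- v
    lam <- as.numeric(t(v) %*% S %*% v)
    S <- S - lam * tcrossprod(v)
  }
  out
}

#' Orient PC1 and label A/B compartments
#'
#' Flips the sign of PC1 if it correlates negatively with gene density, so
#' that positive values mark the gene-dense, active (A) state; labels `A`
#' where PC1 > 0, `B` where PC1 < 0, and `unassigned` where PC1 is `NaN` or
#' exactly 0.
#'
#' @param pc1 PC1 values for one chromosome.
#' @param gene_density Per-bin gene counts on the same grid.
#' @return data.frame `pc1`, `label`; attribute `orientation_cor` holds the
#'   (post-flip) correlation with gene density.
#' @export
classify_compartments <- function(pc1, gene_density) {
  if (length(pc1) != length(gene_density)) stop("pc1 and gene_density differ in length")
  ok <- is.finite(pc1) & is.finite(gene_density)
  if (sum(ok) < 3L || stats::sd(gene_density[ok]) == 0)
    stop("gene density has no variance over valid bins")
  r <- stats::cor(pc1[ok], gene_density[ok])
  if (is.na(r) || r == 0) stop("PC1 orientation undecidable: zero correlation with gene density")
  if (r < 0) pc1 <- -pc1
  label <- rep("unassigned", length(pc1))
  label[is.finite(pc1) & pc1 > 0] <- "A"
  label[is.finite(pc1) & pc1 < 0] <- "B"
  out <- data.frame(pc1 = pc1, label = label, stringsAsFactors = FALSE)
  attr(out, "orientation_cor") <- abs(r)
  out
}

#' Genome-wide A/B compartment calling
#'
#' Per chromosome: O/E transform, bin-bin correlation, leading principal
#' components by power iteration, orientation by gene density. As in common
#' practice, the compartment eigenvector is chosen among the top `n_pcs`
#' components as the one most correlated (in absolute value) with gene
#' density, since the first component occasionally captures other large-scale
#' structure.
#'
#' @param M A balanced [contact_matrix()].
#' @param gene_density Per-bin gene counts in [spec_bins()] order.
#' @param ignore_diags Diagonals excluded from the correlation (see
#'   [correlation_matrix()]).
#' @param n_pcs Number of leading components considered.
#' @return A data.frame of class `compartment_track`: `chrom`, `bin`, `pc1`,
#'   `label`.
#' @export
call_compartments <- function(M, gene_density, ignore_diags = 0L, n_pcs = 1L) {
  spec <- M$spec
  if (length(gene_density) != n_bins(spec))
    stop("gene_density must have one value per genome bin")
  expected <- compute_expected(M, "per-chrom")
  parts <- lapply(seq_along(spec$chroms), function(k) {
    ch <- spec$chroms[k]
    rng <- (spec$offsets[k] + 1L):(spec$offsets[k] + spec$nbins[k])
    OE <- oe_transform(M, ch, expected)
    C <- correlation_matrix(OE, ignore_diags = ignore_diags)
    pcs <- top_eigenvectors(C, k = n_pcs)
    dens <- gene_density[rng]
    cors <- suppressWarnings(apply(pcs, 2L, function(p) {
      ok <- is.finite(p) & is.finite(dens)
      if (sum(ok) < 3L) return(NA_real_)
      stats::cor(p[ok], dens[ok])
    }))
    if (all(is.na(cors))) stop("no component correlates with gene density on ", ch)
    pc1 <- pcs[, which.max(abs(cors))]
    cls <- classify_compartments(pc1, dens)
    data.frame(chrom = ch, bin = seq_len(spec$nbins[k]) - 1L,
               pc1 = cls$pc1, label = cls$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Compartment switch classification between two samples
#'
#' Per bin: `A-to-A`, `B-to-B`, `A-to-B`, `B-to-A`, or `unassigned` when
#' either track is unassigned there. Percentages are over assigned bins and
#' sum to 100.
#'
#' @param normal,tumour `compartment_track` data.frames on the same grid.
#' @return A list of class `switch_table`: `per_bin` data.frame (`chrom`,
#'   `bin`, `category`), `percent` named vector, `switch_fraction` (switched /
#'   assigned).
#' @export
switch_classification <- function(normal, tumour) {
  if (nrow(normal) != nrow(tumour) ||
      !identical(normal$chrom, tumour$chrom) || !identical(normal$bin, tumour$bin))
    stop("compartment tracks are on different grids")
  cat_ <- rep("unassigned", nrow(normal))
  ok <- normal$label != "unassigned" & tumour$label != "unassigned"
  cat_[ok] <- paste0(normal$label[ok], "-to-", tumour$label[ok])
  per_bin <- data.frame(chrom = normal$chrom, bin = normal$bin, category = cat_,
                        stringsAsFactors = FALSE)
  lev <- c("A-to-A", "B-to-B", "A-to-B", "B-to-A")
  counts <- vapply(lev, function(l) sum(cat_ == l), 0)
  pct <- 100 * counts / sum(counts)
  structure(list(per_bin = per_bin, percent = pct,
                 switch_fraction = unname((counts["A-to-B"] + counts["B-to-A"]) / sum(counts))),
            class = "switch_table")
}

#' @export
print.switch_table <- function(x, ...) {
  cat("compartment switches (% of assigned bins):\n")
  print(round(x$percent, 1))
  invisible(x)
}
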
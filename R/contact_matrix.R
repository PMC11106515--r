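#' Sparse symmetric Hi-C contact matrix
#'
#' Counts are stored once per unordered bin pair (upper triangle in global bin
#' order); queries are symmetric. Balancing weights (from [ice_balance()]) and
#' a valid-bin mask are carried alongside: the balanced value of a pixel is
#' `count * w_i * w_j`, and weights are `NA` on masked bins.
#'
#' @param spec A [genome_spec()].
#' @param pixels data.frame with columns `chrom1`, `bin1`, `chrom2`, `bin2`,
#'   `count` (bins 0-based). Duplicate / transposed pairs are aggregated.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(spec, pixels) {
  stopifnot(inherits(spec, "genome_spec"))
  need <- c("chrom1", "bin1", "chrom2", "bin2", "count")
  if (!all(need %in% names(pixels))) stop("pixels needs columns ", paste(need, collapse = ", "))
  count <- as.numeric(pixels$count)
  if (any(!is.finite(count)) || any(count < 0)) stop("counts must be finite and >= 0")
  g1 <- global_bin(spec, pixels$chrom1, pixels$bin1)
  g2 <- global_bin(spec, pixels$chrom2, pixels$bin2)
  swap <- g1 > g2
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  px <- data.table::data.table(g1 = g1, g2 = g2, count = count)
  px <- px[count > 0][, list(count = sum(count)), by = c("g1", "g2")]
  data.table::setkeyv(px, c("g1", "g2"))
  structure(
    list(spec = spec, pixels = px,
         weights = rep(NA_real_, n_bins(spec)),
         valid = rep(TRUE, n_bins(spec)),
         balanced = FALSE),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s pixels, %s total counts, %d bins%s\n",
              format(nrow(x$pixels), big.mark = ","),
              format(total_mass(x), big.mark = ","),
              n_bins(x$spec),
              if (x$balanced) " (balanced)" else ""))
  invisible(x)
}

is_balanced <- function(M) isTRUE(M$balanced)

#' Symmetric query of a contact matrix
#'
#' @param M A `contact_matrix`.
#' @param chrom1,bin1,chrom2,bin2 Pixel coordinates (bins 0-based); vectors
#'   are recycled to a common length.
#' @param balanced Return `count * w_i * w_j` instead of the raw count.
#' @return Numeric vector of counts (0 where no pixel is stored; `NA` for
#'   balanced queries touching a masked bin).
#' @export
query <- function(M, chrom1, bin1, chrom2, bin2, balanced = FALSE) {
  g1 <- global_bin(M$spec, chrom1, bin1)
  g2 <- global_bin(M$spec, chrom2, bin2)
  swap <- g1 > g2
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  q <- data.table::data.table(g1 = g1, g2 = g2)
  hit <- M$pixels[q, on = c("g1", "g2")]
  val <- ifelse(is.na(hit$count), 0, hit$count)
  if (balanced) {
    if (!is_balanced(M)) stop("matrix has no balancing weights; run ice_balance() first")
    val <- val * M$weights[g1] * M$weights[g2]
  }
  val
}

#' Total, cis and trans contact mass
#'
#' @param M A `contact_matrix`.
#' @return `total_mass`: one number. `cis_mass`/`trans_mass`: total cis (both
#'   ends on one chromosome) or trans mass.
#' @export
total_mass <- function(M) sum(M$pixels$count)

#' @rdname total_mass
#' @export
cis_mass <- function(M) {
  ci <- global_chrom_index(M$spec, M$pixels$g1)
  cj <- global_chrom_index(M$spec, M$pixels$g2)
  sum(M$pixels$count[ci == cj])
}

#' @rdname total_mass
#' @export
trans_mass <- function(M) total_mass(M) - cis_mass(M)

pixel_table <- function(M) {
  loc1 <- global_to_local(M$spec, M$pixels$g1)
  loc2 <- global_to_local(M$spec, M$pixels$g2)
  data.frame(chrom1 = loc1$chrom, bin1 = loc1$bin,
             chrom2 = loc2$chrom, bin2 = loc2$bin,
             count = M$pixels$count, stringsAsFactors = FALSE)
}

#' Read / write the triplet contact text format
#'
#' Tab-separated with header line `#chromA binA chromB binB count`; one row
#' per unordered bin pair, bins 0-based within their chromosome.
#'
#' @param path File path.
#' @param spec A [genome_spec()] giving the bin grid.
#' @return `load_contact_matrix`: a `contact_matrix`. `write_contacts`: the
#'   path, invisibly.
#' @export
load_contact_matrix <- function(path, spec) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "#"))
    stop("missing '#chromA binA chromB binB count' header line")
  tab <- data.table::fread(path, header = FALSE, skip = 1L, sep = "\t",
                           col.names = c("chrom1", "bin1", "chrom2", "bin2", "count"),
                           colClasses = list(character = c(1L, 3L)))
  if (any(tab$count < 0)) stop("negative count in ", path)
  contact_matrix(spec, tab)
}

#' @rdname load_contact_matrix
#' @param M A `contact_matrix` to write.
#' @export
write_contacts <- function(M, path) {
  px <- pixel_table(M)
  writeLines("#chromA\tbinA\tchromB\tbinB\tcount", path)
  data.table::fwrite(px, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Scale matrices to a common sequencing depth
#'
#' Multiplies each matrix by a scalar so all share the same total genome-wide
#' mass (the mean of the input totals). Relative pixel ratios are preserved
#' exactly; balancing weights are untouched.
#'
#' @param ... Two or more `contact_matrix` objects.
#' @return A list of rescaled matrices, in input order.
#' @export
normalize_depth <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "contact_matrix"))
    ms <- ms[[1]]
  stopifnot(length(ms) >= 2L, all(vapply(ms, inherits, TRUE, "contact_matrix")))
  tot <- vapply(ms, total_mass, 0)
  if (any(tot == 0)) stop("cannot depth-normalize an empty matrix")
  target <- mean(tot)
  lapply(seq_along(ms), function(k) {
    m <- ms[[k]]
    m$pixels <- data.table::copy(m$pixels)
    m$pixels[, "count" := m$pixels$count * (target / tot[k])]
    m
  })
}

#' Aggregate a contact matrix onto a coarser bin grid
#'
#' @param M A `contact_matrix`.
#' @param factor Integer multiple of the current resolution.
#' @return A raw (unbalanced) `contact_matrix` on [coarsen_spec()]'s grid.
#' @export
coarsen <- function(M, factor) {
  spec2 <- coarsen_spec(M$spec, factor)
  px <- pixel_table(M)
  px$bin1 <- px$bin1 %/% as.integer(factor)
  px$bin2 <- px$bin2 %/% as.integer(factor)
  contact_matrix(spec2, px)
}

#' Dense cis block of one chromosome
#'
#' @param M A `contact_matrix`.
#' @param chrom Chromosome name.
#' @param balanced Apply balancing weights (masked bins become `NA` rows/cols).
#' @return An `n x n` symmetric matrix, `n` the chromosome's bin count. Row
#'   `r` corresponds to 0-based bin `r - 1`.
#' @export
dense_block <- function(M, chrom, balanced = FALSE) {
  ci <- match(chrom, M$spec$chroms)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  n <- M$spec$nbins[ci]
  off <- M$spec$offsets[ci]
  lo <- off + 1L; hi <- off + n
  px <- M$pixels[M$pixels$g1 >= lo & M$pixels$g1 <= hi & M$pixels$g2 <= hi]
  i <- as.integer(px$g1 - off); j <- as.integer(px$g2 - off)
  val <- px$count
  out <- matrix(0, n, n)
  if (balanced) {
    if (!is_balanced(M)) stop("matrix has no balancing weights; run ice_balance() first")
    w <- M$weights[lo:hi]
    val <- val * w[i] * w[j]
  }
  out[cbind(i, j)] <- val
  out[cbind(j, i)] <- val
  if (balanced) {
    bad <- !M$valid[lo:hi]
    out[bad, ] <- NA_real_
    out[, bad] <- NA_real_
  }
  out
}

# valid-bin logical vector for one chromosome
chrom_valid <- function(M, chrom) {
  ci <- match(chrom, M$spec$chroms)
  M$valid[(M$spec$offsets[ci] + 1L):(M$spec$offsets[ci] + M$spec$nbins[ci])]
}

# full symmetric sparse Matrix (dsCMatrix) of raw counts
sparse_symmetric <- function(M) {
  N <- n_bins(M$spec)
  Matrix::sparseMatrix(i = M$pixels$g1, j = M$pixels$g2, x = M$pixels$count,
                       dims = c(N, N), symmetric = TRUE)
}
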
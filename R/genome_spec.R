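#' Binned genome specification
#'
#' Defines the bin grid every other object in the package lives on: an ordered
#' set of chromosomes, their lengths in bp, and a single bin resolution. Bins
#' are 0-based half-open: bin `i` of a chromosome covers
#' `[i * resolution, (i + 1) * resolution)`, and a chromosome of length `L`
#' has `ceiling(L / resolution)` bins.
#'
#' @param chroms Character vector of chromosome names (order is genome order).
#' @param lengths Integer vector of chromosome lengths in bp (same order).
#' @param resolution Bin size in bp.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chroms, lengths, resolution) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) == 0L) stop("need at least one chromosome")
  if (length(chroms) != length(lengths)) stop("chroms and lengths differ in length")
  if (anyDuplicated(chroms)) stop("duplicated chromosome names")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) stop("chromosome lengths must be > 0")
  resolution <- as.numeric(resolution)
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("resolution must be a single positive number")
  nbins <- as.integer(ceiling(lengths / resolution))
  offsets <- c(0L, cumsum(nbins))[seq_along(chroms)]
  structure(
    list(chroms = chroms, lengths = stats::setNames(lengths, chroms),
         resolution = resolution,
         nbins = stats::setNames(nbins, chroms),
         offsets = stats::setNames(offsets, chroms)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: %d chromosome(s), %d bins at %s bp resolution\n",
              length(x$chroms), n_bins(x), format(x$resolution, big.mark = ",")))
  invisible(x)
}

#' Total number of bins in a genome spec
#' @param spec A `genome_spec`.
#' @return Integer bin count over all chromosomes.
#' @export
n_bins <- function(spec) sum(spec$nbins)

#' Per-bin table for a genome spec
#'
#' @param spec A `genome_spec`.
#' @return A data.frame with columns `chrom`, `bin` (0-based), `start`, `end`.
#' @export
spec_bins <- function(spec) {
  chrom <- rep(spec$chroms, spec$nbins)
  bin <- unlist(lapply(spec$nbins, function(n) seq_len(n) - 1L), use.names = FALSE)
  start <- bin * spec$resolution
  end <- pmin(start + spec$resolution, spec$lengths[chrom])
  data.frame(chrom = chrom, bin = bin, start = start, end = end,
             row.names = NULL, stringsAsFactors = FALSE)
}

# 1-based global bin index for (chrom, 0-based bin); validates bounds.
global_bin <- function(spec, chrom, bin) {
  idx <- match(chrom, spec$chroms)
  if (anyNA(idx)) stop("unknown chromosome: ", paste(unique(chrom[is.na(idx)]), collapse = ", "))
  bin <- as.integer(bin)
  bad <- bin < 0L | bin >= spec$nbins[idx]
  if (any(bad)) stop("bin index out of range for its chromosome")
  spec$offsets[idx] + bin + 1L
}

# inverse of global_bin: data.frame(chrom, bin) from 1-based global indices
global_to_local <- function(spec, g) {
  cuts <- c(spec$offsets, n_bins(spec))
  ci <- findInterval(g - 1L, cuts[-1], left.open = FALSE) + 1L
  data.frame(chrom = spec$chroms[ci], bin = as.integer(g - 1L - spec$offsets[ci]),
             stringsAsFactors = FALSE)
}

# chromosome index of each 1-based global bin
global_chrom_index <- function(spec, g) {
  findInterval(g - 1L, c(spec$offsets, n_bins(spec))[-1], left.open = FALSE) + 1L
}

#' Read a chrom.sizes file into a genome spec
#'
#' @param path Two-column tab-separated file: chromosome name, length in bp.
#' @param resolution Bin size in bp.
#' @return A `genome_spec`.
#' @export
read_chrom_sizes <- function(path, resolution) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_spec(tab$chrom, tab$length, resolution)
}

#' Write a chrom.sizes file
#' @param spec A `genome_spec`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(spec, path) {
  utils::write.table(data.frame(spec$chroms, spec$lengths),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coarsen a genome spec to a larger bin size
#' @param spec A `genome_spec`.
#' @param factor Integer multiple of the current resolution.
#' @return A `genome_spec` at `resolution * factor`.
#' @export
coarsen_spec <- function(spec, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  genome_spec(spec$chroms, spec$lengths, spec$resolution * factor)
}

same_grid <- function(a, b) {
  identical(a$chroms, b$chroms) &&
    isTRUE(all.equal(unname(a$lengths), unname(b$lengths))) &&
    a$resolution == b$resolution
}
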
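#' Cis/trans contact composition
#'
#' Per chromosome, the cis fraction is that chromosome's intra-chromosomal
#' mass over its total mass (cis plus all trans pixels touching it); the
#' overall fraction is genome cis mass over genome total mass.
#'
#' @param M A [contact_matrix()].
#' @return A list of class `cis_trans_summary`: `per_chrom` data.frame
#'   (`chrom`, `cis`, `trans`, `cis_fraction`), `cis`, `trans`,
#'   `cis_fraction`.
#' @export
cis_trans_fraction <- function(M) {
  if (total_mass(M) == 0) stop("matrix has zero total mass")
  spec <- M$spec
  ci <- global_chrom_index(spec, M$pixels$g1)
  cj <- global_chrom_index(spec, M$pixels$g2)
  x <- M$pixels$count
  nc <- length(spec$chroms)
  cis_c <- vapply(seq_len(nc), function(k) sum(x[ci == k & cj == k]), 0)
  trans_c <- vapply(seq_len(nc), function(k) sum(x[(ci == k) != (cj == k)]), 0)
  per <- data.frame(chrom = spec$chroms, cis = cis_c, trans = trans_c,
                    cis_fraction = ifelse(cis_c + trans_c > 0,
                                          cis_c / (cis_c + trans_c), NA_real_),
                    stringsAsFactors = FALSE)
  tot_cis <- sum(cis_c)
  tot_trans <- sum(trans_c) / 2 # each trans pixel touches two chromosomes
  structure(list(per_chrom = per, cis = tot_cis, trans = tot_trans,
                 cis_fraction = tot_cis / (tot_cis + tot_trans)),
            class = "cis_trans_summary")
}

#' Log2 ratio map of two contact matrices
#'
#' Both matrices are first scaled to equal total mass ([normalize_depth()]);
#' the ratio `log2((a + pc) / (b + pc))` is reported on the union of their
#' nonzero pixels.
#'
#' @param A,B `contact_matrix` objects on the same grid.
#' @param pseudocount Added to both values (in raw-count units, applied after
#'   depth scaling).
#' @param balanced Compare balanced rather than raw values.
#' @return data.frame `chrom1, bin1, chrom2, bin2, value_a, value_b, log2_ratio`.
#' @export
log2_ratio_map <- function(A, B, pseudocount = 1, balanced = FALSE) {
  if (!same_grid(A$spec, B$spec)) stop("matrices are on different bin grids")
  sc <- normalize_depth(A, B)
  a <- sc[[1L]]; b <- sc[[2L]]
  getval <- function(m, g1, g2) {
    q <- data.table::data.table(g1 = g1, g2 = g2)
    hit <- m$pixels[q, on = c("g1", "g2")]
    val <- ifelse(is.na(hit$count), 0, hit$count)
    if (balanced) {
      if (!is_balanced(m)) stop("balanced = TRUE but matrix is not balanced")
      val <- val * m$weights[g1] * m$weights[g2]
    }
    val
  }
  keys <- unique(rbind(a$pixels[, c("g1", "g2")], b$pixels[, c("g1", "g2")]))
  va <- getval(a, keys$g1, keys$g2)
  vb <- getval(b, keys$g1, keys$g2)
  loc1 <- global_to_local(A$spec, keys$g1)
  loc2 <- global_to_local(A$spec, keys$g2)
  out <- data.frame(chrom1 = loc1$chrom, bin1 = loc1$bin,
                    chrom2 = loc2$chrom, bin2 = loc2$bin,
                    value_a = va, value_b = vb,
                    log2_ratio = log2((va + pseudocount) / (vb + pseudocount)),
                    stringsAsFactors = FALSE)
  out[order(out$chrom1, out$bin1, out$chrom2, out$bin2), , drop = FALSE]
}

#' Inter-chromosomal observed/expected matrix
#'
#' Expected trans mass for a chromosome pair is proportional to the product of
#' their valid-bin counts, normalized so total expected equals total observed
#' trans mass. Also reports the strongest individual trans pixels.
#'
#' @param M A [contact_matrix()].
#' @param top_k Number of top trans pixels (by count) to return.
#' @return A list of class `interchrom_oe`: `oe` (chrom x chrom matrix, `NA`
#'   on the diagonal), `observed`, `expected`, `top_pixels` data.frame.
#' @export
interchrom_oe <- function(M, top_k = 1000L) {
  spec <- M$spec
  nc <- length(spec$chroms)
  if (nc < 2L) stop("need at least two chromosomes")
  ci <- global_chrom_index(spec, M$pixels$g1)
  cj <- global_chrom_index(spec, M$pixels$g2)
  tr <- ci != cj
  if (!any(tr)) stop("matrix has no trans contacts")
  x <- M$pixels$count
  obs <- matrix(0, nc, nc, dimnames = list(spec$chroms, spec$chroms))
  agg <- rowsum(x[tr], paste(ci[tr], cj[tr]))
  idx <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  obs[idx] <- agg[, 1L]
  obs <- obs + t(obs)
  # valid-bin counts (all bins if never balanced)
  vb <- vapply(seq_len(nc), function(k) {
    sum(M$valid[(spec$offsets[k] + 1L):(spec$offsets[k] + spec$nbins[k])])
  }, 0)
  expd <- outer(vb, vb)
  diag(expd) <- 0
  expd <- expd / sum(expd) * sum(obs)
  dimnames(expd) <- dimnames(obs)
  oe <- obs / expd
  diag(oe) <- NA_real_
  ord <- order(-x[tr])
  take <- utils::head(ord, top_k)
  sel <- which(tr)[take]
  loc1 <- global_to_local(spec, M$pixels$g1[sel])
  loc2 <- global_to_local(spec, M$pixels$g2[sel])
  top <- data.frame(chrom1 = loc1$chrom, bin1 = loc1$bin,
                    chrom2 = loc2$chrom, bin2 = loc2$bin,
                    count = x[sel], stringsAsFactors = FALSE)
  structure(list(oe = oe, observed = obs, expected = expd, top_pixels = top),
            class = "interchrom_oe")
}
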
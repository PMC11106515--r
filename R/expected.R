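#' Distance-decay (expected) profile of a contact matrix
#'
#' For each genomic separation `s` (in bins), the expected value is the mean
#' over *all* valid cis bin pairs at that separation of the (balanced) pixel
#' value — zero pixels included, masked bins excluded from both numerator and
#' denominator.
#'
#' @param M A [contact_matrix()].
#' @param scope `"per-chrom"` for one profile per chromosome, `"pooled"` for a
#'   single genome-wide profile (strata pooled across chromosomes).
#' @param balanced Use balanced values (default when weights are present).
#' @return A data.frame of class `decay_profile` with columns `chrom`
#'   (`"pooled"` when pooled), `sep_bins`, `sep_bp`, `value`, `n_pairs`.
#' @export
compute_expected <- function(M, scope = c("per-chrom", "pooled"),
                             balanced = is_balanced(M)) {
  scope <- match.arg(scope)
  if (balanced && !is_balanced(M)) stop("matrix has no balancing weights")
  spec <- M$spec
  ci <- global_chrom_index(spec, M$pixels$g1)
  cj <- global_chrom_index(spec, M$pixels$g2)
  cis <- ci == cj
  if (!any(cis)) stop("matrix has no cis contacts")
  res <- spec$resolution

  per <- lapply(seq_along(spec$chroms), function(k) {
    n <- spec$nbins[k]
    off <- spec$offsets[k]
    v <- if (balanced) M$valid[(off + 1L):(off + n)] else rep(TRUE, n)
    sel <- cis & ci == k
    sep <- as.integer(M$pixels$g2[sel] - M$pixels$g1[sel])
    val <- M$pixels$count[sel]
    if (balanced) {
      w <- M$weights[(off + 1L):(off + n)]
      i <- as.integer(M$pixels$g1[sel] - off)
      j <- as.integer(M$pixels$g2[sel] - off)
      val <- val * w[i] * w[j]
      keep <- !is.na(val)
      sep <- sep[keep]; val <- val[keep]
    }
    seps <- 0:(n - 1L)
    num <- numeric(n)
    if (length(sep)) {
      agg <- rowsum(val, sep)
      num[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    }
    # valid pairs at separation s: sum_i v[i] & v[i+s]
    den <- vapply(seps, function(s) {
      if (s == 0L) sum(v) else sum(v[seq_len(n - s)] & v[(1L + s):n])
    }, 0)
    data.frame(chrom = spec$chroms[k], sep_bins = seps, sep_bp = seps * res,
               num = num, n_pairs = den, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  if (scope == "pooled") {
    dt <- data.table::as.data.table(tab)
    tab <- as.data.frame(dt[, list(num = sum(num), n_pairs = sum(n_pairs)),
                            by = c("sep_bins", "sep_bp")])
    tab$chrom <- "pooled"
    tab <- tab[order(tab$sep_bins), c("chrom", "sep_bins", "sep_bp", "num", "n_pairs")]
  }
  tab$value <- ifelse(tab$n_pairs > 0, tab$num / tab$n_pairs, NA_real_)
  tab$num <- NULL
  rownames(tab) <- NULL
  class(tab) <- c("decay_profile", "data.frame")
  attr(tab, "balanced") <- balanced
  tab
}

#' Interaction decay exponent (IDE)
#'
#' Slope of the ordinary least squares fit of `log10(expected)` against
#' `log10(separation)` over a separation range, the conventional summary of
#' how fast contact frequency falls with genomic distance.
#'
#' @param D A [compute_expected()] profile (one chromosome or pooled).
#' @param s_min,s_max Fit range in bp (inclusive).
#' @param chrom Restrict to one chromosome of a per-chrom profile.
#' @return The fitted slope, with the intercept and number of strata used as
#'   attributes.
#' @export
fit_decay_exponent <- function(D, s_min = 5e4, s_max = 1e7, chrom = NULL) {
  tab <- D
  if (!is.null(chrom)) tab <- tab[tab$chrom == chrom, ]
  use <- tab$sep_bp >= s_min & tab$sep_bp <= s_max &
    !is.na(tab$value) & tab$value > 0 & tab$sep_bp > 0
  if (sum(use) < 3L)
    stop("fewer than 3 strata with positive expected value in the fit range")
  fit <- stats::lm(log10(value) ~ log10(sep_bp), data = tab[use, ])
  slope <- unname(stats::coef(fit)[2L])
  attr(slope, "intercept") <- unname(stats::coef(fit)[1L])
  attr(slope, "n_strata") <- sum(use)
  slope
}

# expected value vector indexed by sep_bins + 1 for one chromosome
expected_vector <- function(D, chrom, n) {
  tab <- D[D$chrom == chrom, ]
  if (nrow(tab) == 0L) stop("no expected profile for chromosome ", chrom)
  e <- rep(NA_real_, n)
  e[tab$sep_bins + 1L] <- tab$value
  e
}
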
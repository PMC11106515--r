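# Neighborhood geometry for the donut filter, relative to a pixel (i, j),
# i < j (row i, column j of the upper triangle). With peak half-width p and
# outer half-width w:
#   donut       : p < max(|di|,|dj|) <= w with |di| > p and |dj| > p
#                 (the square annulus minus the width-(2p+1) stripes)
#   horizontal  : |di| <= p, p < |dj| <= w
#   vertical    : p < |di| <= w, |dj| <= p
#   lower-left  : 1 <= di <= w-p, -(w-p) <= dj <= -1 (toward the diagonal)
# Each region is a union of axis-aligned rectangles, so sums come from
# summed-area tables.
region_rects <- function(p, w) {
  q <- w - p
  list(
    donut = rbind(c(-w, -p - 1L, -w, -p - 1L), c(-w, -p - 1L, p + 1L, w),
                  c(p + 1L, w, -w, -p - 1L), c(p + 1L, w, p + 1L, w)),
    horizontal = rbind(c(-p, p, -w, -p - 1L), c(-p, p, p + 1L, w)),
    vertical = rbind(c(-w, -p - 1L, -p, p), c(p + 1L, w, -p, p)),
    lower_left = rbind(c(1L, q, -q, -1L)))
}

# Sum of X over a region's rectangles for pixel vectors (i, j); SX is sat(X).
region_sum <- function(SX, i, j, rects) {
  out <- 0
  for (r in seq_len(nrow(rects))) {
    out <- out + sat_rect(SX, i + rects[r, 1L], i + rects[r, 2L],
                          j + rects[r, 3L], j + rects[r, 4L])
  }
  out
}

# Per-chromosome arrays shared by the loop operations.
loop_chrom_data <- function(M, chrom, expected) {
  O <- dense_block(M, chrom, balanced = TRUE)
  V <- is.finite(O)
  Ob <- ifelse(V, O, 0)
  n <- nrow(O)
  e <- expected_vector(expected, chrom, n)
  E <- matrix(e[abs(row(O) - col(O)) + 1L], n, n)
  E[!V] <- 0
  E[!is.finite(E)] <- 0
  raw <- dense_block(M, chrom, balanced = FALSE)
  ci <- match(chrom, M$spec$chroms)
  rng <- (M$spec$offsets[ci] + 1L):(M$spec$offsets[ci] + M$spec$nbins[ci])
  list(n = n, Ob = Ob, V = V, raw = raw, SO = sat(Ob), SE = sat(E),
       e = e, w = M$weights[rng], valid = M$valid[rng])
}

# lambda estimates for pixel vectors (i, j) in one chromosome, both in
# balanced space and rescaled to raw-count space via the bias weights.
neighborhood_lambdas <- function(cd, i, j, p, w) {
  rects <- region_rects(p, w)
  epix <- cd$e[abs(j - i) + 1L]
  out <- list()
  for (nm in names(rects)) {
    so <- region_sum(cd$SO, i, j, rects[[nm]])
    se <- region_sum(cd$SE, i, j, rects[[nm]])
    lam_bal <- ifelse(se > 0, so / se * epix, NA_real_)
    out[[nm]] <- list(bal = lam_bal, raw = lam_bal / (cd$w[i] * cd$w[j]))
  }
  out
}

#' Local expected neighborhoods of one pixel
#'
#' The four HiCCUPS-style local expecteds (donut, horizontal, vertical,
#' lower-left) of a pixel: each neighborhood's balanced values are summed,
#' scaled by the ratio of the pixel's distance-expected to the neighborhood's
#' summed distance-expected, and rescaled to raw-count space through the
#' balancing weights.
#'
#' @param M A balanced [contact_matrix()].
#' @param chrom Chromosome.
#' @param bin1,bin2 Pixel bins (0-based, `bin1 < bin2`).
#' @param p Peak half-width in bins (excluded region).
#' @param w Outer half-width in bins.
#' @param expected Optional precomputed per-chrom expected profile.
#' @return data.frame with one row per neighborhood: `region`, `mean_balanced`
#'   (plain mean of balanced values over valid cells), `lambda_balanced`,
#'   `lambda_raw`.
#' @export
local_expected_neighborhoods <- function(M, chrom, bin1, bin2, p = 2L, w = 5L,
                                         expected = NULL) {
  if (!(w > p && p >= 1L)) stop("need w > p >= 1")
  if (bin2 - bin1 <= p + w) stop("pixel separation must exceed p + w bins")
  if (is.null(expected)) expected <- compute_expected(M, "per-chrom")
  cd <- loop_chrom_data(M, chrom, expected)
  i <- bin1 + 1L; j <- bin2 + 1L
  if (i - w < 1L || j + w > cd$n || j - w < 1L || i + w > cd$n)
    stop("neighborhood extends past the matrix bounds")
  rects <- region_rects(p, w)
  SV <- sat(cd$V * 1)
  lam <- neighborhood_lambdas(cd, i, j, p, w)
  do.call(rbind, lapply(names(rects), function(nm) {
    so <- region_sum(cd$SO, i, j, rects[[nm]])
    nv <- region_sum(SV, i, j, rects[[nm]])
    data.frame(region = nm,
               mean_balanced = if (nv > 0) so / nv else NA_real_,
               lambda_balanced = lam[[nm]]$bal,
               lambda_raw = lam[[nm]]$raw,
               stringsAsFactors = FALSE)
  }))
}

#' Donut-filter loop calling
#'
#' Tests every cis pixel with a nonzero observed count in the separation band
#' against its four local expecteds with Poisson upper-tail p-values. Multiple
#' testing follows the HiCCUPS lambda-chunking scheme: within each
#' neighborhood family, tested pixels are grouped into multiplicative
#' lambda chunks (factor `2^(1/3)`) and BH-corrected within each chunk, which
#' keeps the test calibrated across the wide dynamic range of local
#' expectation. Pixels significant in all four neighborhoods with observed
#' counts exceeding the enrichment thresholds are clustered; each cluster is
#' reported at its max-observed pixel. Singleton clusters are retained only
#' under the stricter HiCCUPS post-filter (`q <= singleton_fdr` in all four
#' neighborhoods and `observed >= singleton_enrich x` the donut and
#' lower-left expecteds), which removes isolated Poisson excursions and TAD
#' corner artifacts.
#'
#' @param M A balanced [contact_matrix()].
#' @param p,w Peak / outer half-widths in bins.
#' @param fdr BH q-value threshold applied to each neighborhood.
#' @param enrich_donut Required ratio of observed to donut and lower-left
#'   expecteds.
#' @param enrich_hv Required ratio to horizontal and vertical expecteds.
#' @param min_sep,max_sep Separation band in bp (the lower edge is clamped to
#'   `p + w + 1` bins).
#' @param cluster_radius Chebyshev clustering radius in bp.
#' @param singleton_fdr,singleton_enrich,singleton_shoulder Stricter
#'   thresholds a single-pixel cluster must meet to be kept: q-values at most
#'   `singleton_fdr` in all four neighborhoods, observed at least
#'   `singleton_enrich` times the donut and lower-left expecteds, and mean
#'   balanced value of the 8 surrounding pixels at least `singleton_shoulder`
#'   times the balanced donut expected (the peak-shape requirement).
#' @return A data.frame of class `loop_set`: centroids with `chrom`, `bin1`,
#'   `bin2`, `observed`, the four `lambda_*` raw-space expecteds, the four
#'   `q_*` values, `cluster_size`. Attribute `pixels` holds all significant
#'   pixels, attribute `n_tested` the number of tested pixels.
#' @export
call_loops <- function(M, p = 2L, w = 5L, fdr = 0.1,
                       enrich_donut = 1.75, enrich_hv = 1.5,
                       min_sep = 5e4, max_sep = 2e6, cluster_radius = 2e4,
                       singleton_fdr = 0.1, singleton_enrich = 2,
                       singleton_shoulder = 1.75) {
  if (!is_balanced(M)) stop("matrix must be balanced first")
  res <- M$spec$resolution
  lo <- max(as.integer(ceiling(min_sep / res)), p + w + 1L)
  hi <- as.integer(floor(max_sep / res))
  expected <- compute_expected(M, "per-chrom")
  per <- list()
  n_tested <- 0L
  for (ch in M$spec$chroms) {
    cd <- loop_chrom_data(M, ch, expected)
    n <- cd$n
    if (n < 2L * w + lo) next
    idx <- which(cd$raw > 0, arr.ind = TRUE)
    idx <- idx[idx[, 2L] - idx[, 1L] >= lo & idx[, 2L] - idx[, 1L] <= hi, , drop = FALSE]
    if (!nrow(idx)) next
    i <- idx[, 1L]; j <- idx[, 2L]
    inb <- i - w >= 1L & j + w <= n & j - w >= 1L & i + w <= n &
      cd$valid[i] & cd$valid[j]
    i <- i[inb]; j <- j[inb]
    if (!length(i)) next
    lam <- neighborhood_lambdas(cd, i, j, p, w)
    obs <- cd$raw[cbind(i, j)]
    # mean balanced value of the 8 pixels around the centre, relative to the
    # balanced donut expected: a focal peak of width ~1 bin carries shoulder
    # mass, an isolated bright pixel does not
    shoulder <- (sat_rect(cd$SO, i - 1L, i + 1L, j - 1L, j + 1L) -
                   cd$Ob[cbind(i, j)]) / 8
    lam_bal_donut <- lam$donut$raw * cd$w[i] * cd$w[j]
    per[[ch]] <- data.frame(chrom = ch, bin1 = i - 1L, bin2 = j - 1L,
                            observed = obs,
                            lambda_donut = lam$donut$raw,
                            lambda_horizontal = lam$horizontal$raw,
                            lambda_vertical = lam$vertical$raw,
                            lambda_lower_left = lam$lower_left$raw,
                            shoulder_ratio = shoulder / lam_bal_donut,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, per)
  if (is.null(tab) || nrow(tab) == 0L) stop("no tested pixels")
  n_tested <- nrow(tab)
  ok_lam <- stats::complete.cases(tab[, grep("^lambda_", names(tab))]) &
    tab$lambda_donut > 0 & tab$lambda_horizontal > 0 &
    tab$lambda_vertical > 0 & tab$lambda_lower_left > 0
  tab <- tab[ok_lam, , drop = FALSE]
  # lambda-chunked BH: group by lambda in factor-2^(1/3) chunks, adjust
  # within each chunk
  chunked_q <- function(lam) {
    pvals <- stats::ppois(tab$observed - 1, lam, lower.tail = FALSE)
    chunk <- floor(3 * log2(pmax(lam, 2^-10)))
    q <- numeric(length(pvals))
    for (ck in unique(chunk)) {
      sel <- chunk == ck
      q[sel] <- stats::p.adjust(pvals[sel], "BH")
    }
    q
  }
  for (nm in c("donut", "horizontal", "vertical", "lower_left")) {
    tab[[paste0("q_", nm)]] <- chunked_q(tab[[paste0("lambda_", nm)]])
  }
  keep <- tab$q_donut <= fdr & tab$q_horizontal <= fdr &
    tab$q_vertical <= fdr & tab$q_lower_left <= fdr &
    tab$observed >= enrich_donut * tab$lambda_donut &
    tab$observed >= enrich_donut * tab$lambda_lower_left &
    tab$observed >= enrich_hv * tab$lambda_horizontal &
    tab$observed >= enrich_hv * tab$lambda_vertical
  sig <- tab[keep, , drop = FALSE]
  rad <- as.integer(round(cluster_radius / res))
  cent <- cluster_pixels(sig, rad)
  single <- cent$cluster_size == 1L
  strict <- cent$q_donut <= singleton_fdr & cent$q_horizontal <= singleton_fdr &
    cent$q_vertical <= singleton_fdr & cent$q_lower_left <= singleton_fdr &
    cent$observed >= singleton_enrich * cent$lambda_donut &
    cent$observed >= singleton_enrich * cent$lambda_lower_left &
    cent$shoulder_ratio >= singleton_shoulder
  cent <- cent[!single | strict, , drop = FALSE]
  rownames(cent) <- NULL
  class(cent) <- c("loop_set", "data.frame")
  attr(cent, "pixels") <- sig
  attr(cent, "n_tested") <- n_tested
  cent
}

# Greedy clustering of significant pixels: repeatedly take the unassigned
# pixel with the largest observed count as a centroid and absorb pixels
# within Chebyshev distance rad on the same chromosome.
cluster_pixels <- function(sig, rad) {
  if (nrow(sig) == 0L) {
    out <- sig
    out$cluster_size <- integer(0)
    return(out)
  }
  parts <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(-s$observed), ]
    taken <- rep(FALSE, nrow(s))
    rows <- list()
    for (r in seq_len(nrow(s))) {
      if (taken[r]) next
      memb <- !taken & abs(s$bin1 - s$bin1[r]) <= rad & abs(s$bin2 - s$bin2[r]) <= rad
      taken[memb] <- TRUE
      row <- s[r, , drop = FALSE]
      row$cluster_size <- sum(memb)
      rows[[length(rows) + 1L]] <- row
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, parts)
  out[order(out$chrom, out$bin1, out$bin2), , drop = FALSE]
}

#' Gained/lost loop classification
#'
#' Deduplicates the union of the two call sets at the cluster radius, computes
#' each union loop's observed/expected (observed over donut expected) in both
#' samples, and classifies: `gained` = called in the tumour only with tumour
#' O/E at least `ratio_threshold` times the normal O/E; `lost` = the mirror;
#' otherwise `shared`. Loops over masked bins in either sample are flagged
#' `unevaluable`.
#'
#' @param calls_tumour,calls_normal [call_loops()] results.
#' @param M_tumour,M_normal The corresponding balanced matrices.
#' @param ratio_threshold O/E ratio required for gained/lost.
#' @param p,w Neighborhood half-widths (match the calling parameters).
#' @param cluster_radius Dedup radius in bp.
#' @return A data.frame of class `differential_loop_table`: `chrom`, `bin1`,
#'   `bin2`, `called_tumour`, `called_normal`, `oe_tumour`, `oe_normal`,
#'   `ratio`, `class`.
#' @export
differential_loops <- function(calls_tumour, calls_normal, M_tumour, M_normal,
                               ratio_threshold = 2, p = 2L, w = 5L,
                               cluster_radius = 2e4) {
  res <- M_tumour$spec$resolution
  rad <- as.integer(round(cluster_radius / res))
  uni <- calls_tumour[, c("chrom", "bin1", "bin2")]
  uni$called_tumour <- TRUE
  uni$called_normal <- FALSE
  for (r in seq_len(nrow(calls_normal))) {
    ch <- calls_normal$chrom[r]
    b1 <- calls_normal$bin1[r]; b2 <- calls_normal$bin2[r]
    hit <- which(uni$chrom == ch & abs(uni$bin1 - b1) <= rad & abs(uni$bin2 - b2) <= rad)
    if (length(hit)) {
      uni$called_normal[hit[1L]] <- TRUE
    } else {
      uni <- rbind(uni, data.frame(chrom = ch, bin1 = b1, bin2 = b2,
                                   called_tumour = FALSE, called_normal = TRUE,
                                   stringsAsFactors = FALSE))
    }
  }
  if (nrow(uni) == 0L) stop("no loops in either sample")
  expT <- compute_expected(M_tumour, "per-chrom")
  expN <- compute_expected(M_normal, "per-chrom")
  oe_at <- function(M, expected, ch, b1, b2) {
    cd <- loop_chrom_data(M, ch, expected)
    i <- b1 + 1L; j <- b2 + 1L
    bad <- i - w < 1L | j + w > cd$n | !cd$valid[i] | !cd$valid[j]
    lam <- neighborhood_lambdas(cd, pmax(i, w + 1L), pmin(j, cd$n - w), p, w)
    oe <- cd$raw[cbind(i, j)] / lam$donut$raw
    oe[bad] <- NA_real_
    oe
  }
  oeT <- numeric(nrow(uni)); oeN <- numeric(nrow(uni))
  for (ch in unique(uni$chrom)) {
    sel <- uni$chrom == ch
    oeT[sel] <- oe_at(M_tumour, expT, ch, uni$bin1[sel], uni$bin2[sel])
    oeN[sel] <- oe_at(M_normal, expN, ch, uni$bin1[sel], uni$bin2[sel])
  }
  cls <- rep("shared", nrow(uni))
  bad <- !is.finite(oeT) | !is.finite(oeN)
  cls[bad] <- "unevaluable"
  gain <- !bad & uni$called_tumour & !uni$called_normal & oeT >= ratio_threshold * oeN
  lost <- !bad & uni$called_normal & !uni$called_tumour & oeN >= ratio_threshold * oeT
  cls[gain] <- "gained"
  cls[lost] <- "lost"
  out <- data.frame(uni, oe_tumour = oeT, oe_normal = oeN,
                    ratio = oeT / oeN, class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$bin1, out$bin2), ]
  rownames(out) <- NULL
  class(out) <- c("differential_loop_table", "data.frame")
  out
}

#' Aggregate peak analysis (APA)
#'
#' Element-wise mean of observed/expected windows centred on a set of loop
#' pixels; the APA score is the centre value over the mean of the lower-left
#' corner block (side `max(1, half %/% 2 + 1)`), which sits toward the
#' diagonal and captures the local background.
#'
#' @param M A balanced [contact_matrix()].
#' @param loops data.frame with `chrom`, `bin1`, `bin2`.
#' @param half Window half-size in bins.
#' @return A list of class `apa_result`: `stack` (`(2 half + 1)^2` matrix),
#'   `score`, `n_loops` (windows actually stacked).
#' @export
apa <- function(M, loops, half = 10L) {
  if (nrow(loops) == 0L) stop("empty loop list")
  expected <- compute_expected(M, "per-chrom")
  side <- 2L * half + 1L
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  used <- 0L
  for (ch in unique(loops$chrom)) {
    OE <- oe_transform(M, ch, expected)
    n <- nrow(OE)
    sel <- loops[loops$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      i <- sel$bin1[r] + 1L; j <- sel$bin2[r] + 1L
      if (j - i <= 2L * half) next
      if (i - half < 1L || i + half > n || j - half < 1L || j + half > n) next
      win <- OE[(i - half):(i + half), (j - half):(j + half)]
      ok <- is.finite(win)
      acc[ok] <- acc[ok] + win[ok]
      cnt <- cnt + ok
      used <- used + 1L
    }
  }
  if (used == 0L) stop("no loop admits a full window (all truncated or too close to the diagonal)")
  stack <- ifelse(cnt > 0, acc / cnt, NaN)
  cb <- max(1L, half %/% 2L + 1L)
  corner <- stack[(side - cb + 1L):side, 1:cb]
  score <- stack[half + 1L, half + 1L] / mean(corner, na.rm = TRUE)
  structure(list(stack = stack, score = score, n_loops = used, half = half),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA score %.3f over %d loops (window %dx%d)\n",
              x$score, x$n_loops, nrow(x$stack), ncol(x$stack)))
  invisible(x)
}
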
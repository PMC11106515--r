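#' Diamond insulation score
#'
#' For each bin `i`, the raw score is the mean balanced contact value over the
#' `w x w` diamond spanning bins `(i-w .. i-1) x (i+1 .. i+w)` (`w` = window /
#' resolution), i.e. the contacts crossing bin `i` within the window. The
#' reported log2 insulation score is `log2(raw / chromosome mean of raw over
#' valid bins)`, so the chromosome mean of `2^log2IS` is 1 and the score is
#' invariant to rescaling the matrix. Bins within `w` of a chromosome edge,
#' masked bins, and diamonds with no valid cells are `NaN`.
#'
#' @param M A balanced [contact_matrix()].
#' @param window Diamond window in bp; must be a multiple of the resolution,
#'   at least two bins, and smaller than at least one chromosome.
#' @return A data.frame of class `insulation_track`: `chrom`, `bin`, `raw`,
#'   `log2_is`; attribute `window`.
#' @export
insulation_track <- function(M, window = 5e5) {
  if (!is_balanced(M)) stop("matrix must be balanced first")
  res <- M$spec$resolution
  if (window %% res != 0) stop("window must be a multiple of the resolution")
  w <- as.integer(window / res)
  if (w < 2L) stop("window must span at least two bins")
  if (all(M$spec$lengths <= window)) stop("window is too large for every chromosome")
  parts <- lapply(M$spec$chroms, function(ch) {
    n <- M$spec$nbins[[ch]]
    raw <- rep(NaN, n)
    if (n > 2L * w) {
      blk <- dense_block(M, ch, balanced = TRUE)
      ok <- is.finite(blk)
      vals <- ifelse(ok, blk, 0)
      Sv <- sat(vals)
      Sn <- sat(ok * 1)
      i <- (w + 1L):(n - w)
      tot <- sat_rect(Sv, i - w, i - 1L, i + 1L, i + w)
      cnt <- sat_rect(Sn, i - w, i - 1L, i + 1L, i + w)
      raw[i] <- ifelse(cnt > 0, tot / cnt, NaN)
      raw[!chrom_valid(M, ch)] <- NaN
    }
    mu <- mean(raw[is.finite(raw)])
    data.frame(chrom = ch, bin = seq_len(n) - 1L, raw = raw,
               log2_is = if (is.finite(mu) && mu > 0) log2(raw / mu) else rep(NaN, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("insulation_track", "data.frame")
  attr(out, "window") <- window
  attr(out, "resolution") <- res
  out
}

#' Call insulation boundaries
#'
#' Boundaries are local minima of the log2 insulation score whose topographic
#' prominence is at least `min_strength`: from each minimum, walk outward to
#' the nearest strictly lower point (or the end of the contiguous valid
#' segment); the saddle on each side is the running maximum, and prominence
#' is the smaller of the two rises.
#'
#' @param track An [insulation_track()].
#' @param min_strength Minimum prominence in log2 units.
#' @return A data.frame of class `boundary_set`: `chrom`, `bin`, `log2_is`,
#'   `strength`; positions strictly increasing per chromosome.
#' @export
call_boundaries <- function(track, min_strength = 0.1) {
  parts <- lapply(split(track, track$chrom), function(tt) {
    tt <- tt[order(tt$bin), ]
    v <- tt$log2_is
    out <- NULL
    # contiguous finite segments
    fin <- is.finite(v)
    if (!any(fin)) return(NULL)
    runs <- rle(fin)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      a <- starts[r]; b <- ends[r]
      if (b - a < 2L) next
      seg <- v[a:b]
      m <- length(seg)
      is_min <- c(FALSE, seg[2:(m - 1)] < seg[1:(m - 2)] & seg[2:(m - 1)] <= seg[3:m], FALSE)
      mins <- which(is_min)
      if (!length(mins)) next
      prom <- vapply(seq_along(mins), function(k) {
        i <- mins[k]
        # topographic prominence: walk out to the nearest point lower than
        # the minimum (or the segment end); the saddle is the running maximum
        left <- seg[seq_len(i - 1L)]
        below_l <- which(left < seg[i])
        rise_l <- max(left[seq.int(if (length(below_l)) max(below_l) else 1L, i - 1L)]) - seg[i]
        right <- seg[(i + 1L):m]
        below_r <- which(right < seg[i])
        rise_r <- max(right[seq.int(1L, if (length(below_r)) min(below_r) else length(right))]) - seg[i]
        min(rise_l, rise_r)
      }, 0)
      keep <- prom >= min_strength
      if (any(keep)) {
        out <- rbind(out, data.frame(
          chrom = tt$chrom[1L], bin = tt$bin[a + mins[keep] - 1L],
          log2_is = seg[mins[keep]], strength = prom[keep],
          stringsAsFactors = FALSE))
      }
    }
    out
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), bin = integer(),
                      log2_is = numeric(), strength = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(match(out$chrom, unique(track$chrom)), out$bin), ]
  rownames(out) <- NULL
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' TAD intervals from boundary positions
#'
#' One TAD per consecutive boundary pair on a chromosome, half-open in bp;
#' TADs shorter than `min_bins` bins are dropped from the interval list (the
#' adjacent-boundary spacing statistic uses all consecutive pairs).
#'
#' @param boundaries A [call_boundaries()] set.
#' @param spec The [genome_spec()] the boundaries live on.
#' @param min_bins Minimum TAD size in bins.
#' @return A list of class `tad_set`: `tads` data.frame (`chrom`, `start`,
#'   `end`), `n_tads`, `mean_boundary_spacing` (bp, mean over consecutive
#'   boundary gaps), `mean_tad_size` (bp, over kept TADs).
#' @export
tads_from_boundaries <- function(boundaries, spec, min_bins = 3L) {
  res <- spec$resolution
  gaps <- numeric(0)
  tads <- NULL
  for (ch in unique(boundaries$chrom)) {
    b <- sort(boundaries$bin[boundaries$chrom == ch])
    if (length(b) < 2L) next
    d <- diff(b)
    gaps <- c(gaps, d * res)
    keep <- d >= min_bins
    if (any(keep)) {
      tads <- rbind(tads, data.frame(
        chrom = ch, start = b[-length(b)][keep] * res, end = b[-1L][keep] * res,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(tads))
    tads <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       stringsAsFactors = FALSE)
  structure(list(tads = tads, n_tads = nrow(tads),
                 mean_boundary_spacing = if (length(gaps)) mean(gaps) else NaN,
                 mean_tad_size = if (nrow(tads)) mean(tads$end - tads$start) else NaN),
            class = "tad_set")
}

#' Match boundary sets between two samples
#'
#' Greedy nearest matching within `tol_bins`: candidate pairs are ordered by
#' distance and matched one-to-one; the partition into conserved, A-specific
#' and B-specific boundaries is exhaustive and disjoint.
#'
#' @param A,B [call_boundaries()] sets on the same grid.
#' @param tol_bins Maximum distance in bins for a match.
#' @return A list: `conserved` data.frame (`chrom`, `bin_a`, `bin_b`),
#'   `a_specific`, `b_specific` (subsets of the inputs).
#' @export
match_boundaries <- function(A, B, tol_bins = 1L) {
  conserved <- NULL
  used_a <- rep(FALSE, nrow(A))
  used_b <- rep(FALSE, nrow(B))
  for (ch in union(unique(A$chrom), unique(B$chrom))) {
    ia <- which(A$chrom == ch)
    ib <- which(B$chrom == ch)
    if (!length(ia) || !length(ib)) next
    cand <- expand.grid(a = ia, b = ib)
    cand$dist <- abs(A$bin[cand$a] - B$bin[cand$b])
    cand <- cand[cand$dist <= tol_bins, ]
    cand <- cand[order(cand$dist, A$bin[cand$a]), ]
    for (r in seq_len(nrow(cand))) {
      a <- cand$a[r]; b <- cand$b[r]
      if (used_a[a] || used_b[b]) next
      used_a[a] <- TRUE; used_b[b] <- TRUE
      conserved <- rbind(conserved, data.frame(
        chrom = ch, bin_a = A$bin[a], bin_b = B$bin[b], stringsAsFactors = FALSE))
    }
  }
  if (is.null(conserved))
    conserved <- data.frame(chrom = character(), bin_a = integer(),
                            bin_b = integer(), stringsAsFactors = FALSE)
  list(conserved = conserved,
       a_specific = A[!used_a, , drop = FALSE],
       b_specific = B[!used_b, , drop = FALSE])
}

#' Differential-boundary classification
#'
#' Applies the high-confidence filter and the differential rule at a set of
#' candidate positions: a position is `excluded` when the log2 insulation
#' score is greater than 0 in both samples (or `NaN` in either); otherwise it
#' is `enhanced` when `tumour - normal < -delta_threshold` (the tumour is more
#' insulating), `weakened` when `tumour - normal > delta_threshold`, and
#' `unchanged` when `|delta| <= delta_threshold`.
#'
#' @param normal_track,tumour_track [insulation_track()]s on the same grid.
#' @param positions data.frame with `chrom`, `bin` columns; defaults to the
#'   union of called boundaries in the two samples, merged at 1-bin tolerance
#'   (see [boundary_union()]).
#' @param delta_threshold Differential threshold in log2 units.
#' @return A data.frame of class `differential_boundary_table`: `chrom`,
#'   `bin`, `normal_log2_is`, `tumour_log2_is`, `delta`, `class`, `reason`.
#' @export
differential_boundaries <- function(normal_track, tumour_track, positions = NULL,
                                    delta_threshold = 0.4) {
  if (is.null(positions))
    positions <- boundary_union(call_boundaries(normal_track),
                                call_boundaries(tumour_track))
  key <- function(tr) paste(tr$chrom, tr$bin)
  iN <- match(paste(positions$chrom, positions$bin), key(normal_track))
  iT <- match(paste(positions$chrom, positions$bin), key(tumour_track))
  if (anyNA(iN) || anyNA(iT)) stop("positions fall outside the shared grid")
  sN <- normal_track$log2_is[iN]
  sT <- tumour_track$log2_is[iT]
  delta <- sT - sN
  cls <- rep("unchanged", nrow(positions))
  reason <- rep("", nrow(positions))
  nan <- !is.finite(sN) | !is.finite(sT)
  both_pos <- !nan & sN > 0 & sT > 0
  cls[both_pos] <- "excluded"; reason[both_pos] <- "log2IS > 0 in both samples"
  cls[nan] <- "excluded"; reason[nan] <- "insulation score undefined"
  live <- !nan & !both_pos
  cls[live & delta < -delta_threshold] <- "enhanced"
  cls[live & delta > delta_threshold] <- "weakened"
  out <- data.frame(chrom = positions$chrom, bin = positions$bin,
                    normal_log2_is = sN, tumour_log2_is = sT, delta = delta,
                    class = cls, reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("differential_boundary_table", "data.frame")
  out
}

#' Union of two boundary sets as candidate positions
#'
#' Boundaries matched within `tol_bins` contribute one position (the first
#' set's bin); unmatched boundaries contribute their own.
#'
#' @param A,B [call_boundaries()] sets.
#' @param tol_bins Matching tolerance in bins.
#' @return data.frame `chrom`, `bin`.
#' @export
boundary_union <- function(A, B, tol_bins = 1L) {
  m <- match_boundaries(A, B, tol_bins)
  out <- rbind(data.frame(chrom = m$conserved$chrom, bin = m$conserved$bin_a,
                          stringsAsFactors = FALSE),
               m$a_specific[, c("chrom", "bin")],
               m$b_specific[, c("chrom", "bin")])
  out <- unique(out)
  out <- out[order(out$chrom, out$bin), ]
  rownames(out) <- NULL
  out
}

#' Boundary-centred insulation pileup
#'
#' Element-wise (`NaN`-aware) mean of log2 insulation windows of half-width
#' `flank_bins` centred on a set of positions, for both samples.
#'
#' @param normal_track,tumour_track [insulation_track()]s.
#' @param positions data.frame `chrom`, `bin`.
#' @param flank_bins Half-width of the window in bins.
#' @return data.frame `offset_bins`, `normal`, `tumour`.
#' @export
boundary_pileup <- function(normal_track, tumour_track, positions, flank_bins = 50L) {
  if (nrow(positions) == 0L) stop("empty position set")
  stack_one <- function(track) {
    rows <- lapply(seq_len(nrow(positions)), function(r) {
      tt <- track[track$chrom == positions$chrom[r], ]
      tt <- tt[order(tt$bin), ]
      ctr <- match(positions$bin[r], tt$bin)
      idx <- (ctr - flank_bins):(ctr + flank_bins)
      vals <- rep(NaN, 2L * flank_bins + 1L)
      ok <- idx >= 1L & idx <= nrow(tt)
      vals[ok] <- tt$log2_is[idx[ok]]
      vals
    })
    mat <- do.call(rbind, rows)
    colMeans(mat, na.rm = TRUE)
  }
  data.frame(offset_bins = -flank_bins:flank_bins,
             normal = stack_one(normal_track),
             tumour = stack_one(tumour_track))
}
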
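#' Configuration for the synthetic Hi-C generator
#'
#' Default study conditions for the paired tumour-like / normal-like
#' benchmark: three 5-Mb chromosomes of 500 bins at 10 kb, 2 million cis
#' contacts per chromosome, a power-law decay with exponent -1, a
#' two-compartment plaid of relative amplitude 0.3 whose block edges sit on
#' TAD boundaries, ~7 boundaries per chromosome (mean spacing ~650 kb, with
#' two extra tumour-specific boundaries per chromosome bringing tumour spacing
#' near 560 kb), Gaussian focal loops of amplitude 3, multiplicative lognormal
#' bin biases, and a 20% compartment switch fraction with a 60:40 A-to-B /
#' B-to-A split. The tumour map has a higher cis fraction, more boundaries,
#' more enhanced than weakened boundaries and far more gained than lost loops
#' - the qualitative directions reported for somatotroph tumours.
#'
#' @param ... Overrides for any default listed below.
#' @return A named list of class `synthetic_config`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    chroms = c("chr1", "chr2", "chr3"),
    bins_per_chrom = 500L,
    resolution = 1e4,
    depth_cis_per_chrom = 2e6,
    alpha = -1,
    plaid_c = 0.3,
    tad_t = 2,
    bias_sd = 0.2,
    unmappable_fraction = 0.03,
    unmappable_bias_range = c(0.02, 0.2),
    trans_fraction_normal = 0.18,
    trans_fraction_tumour = 0.13,
    n_boundaries_per_chrom = 6L,
    boundary_strength_range = c(0.35, 0.65),
    boundary_local_scale_bins = 40L,
    edge_margin_bins = 55L,
    n_extra_tumour_boundaries_per_chrom = 2L,
    n_enhanced_boundaries = 6L,
    n_weakened_boundaries = 2L,
    boundary_delta_ratio = 0.35,
    switch_fraction = 0.2,
    switch_a_to_b_share = 0.6,
    max_switch_chrom_fraction = 0.3,
    compartment_flip_prob = 0.6,
    n_shared_loops_per_chrom = 8L,
    n_gained_loops = 12L,
    n_lost_loops = 3L,
    loop_sep_range_bins = c(12L, 100L),
    loop_amplitude = 3,
    loop_sigma = 1,
    loop_margin_bins = 16L,
    loop_min_dist_bins = 8L,
    n_genes = 400L,
    gene_density_ratio = 3,
    gene_length_range = c(5e3, 3e4),
    expr_base_a = 8.5,
    expr_base_b = 7,
    expr_gene_sd = 1,
    expr_noise_sd = 0.25,
    effect_switch = 1.5,
    effect_boundary = 1,
    effect_loop = 1.5)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "synthetic_config"
  cfg
}

#' Plant the ground truth for a synthetic tumour/normal pair
#'
#' Deterministic for a fixed `(config, seed)`. Compartment signs are assigned
#' per inter-boundary segment with Markov persistence, so compartment edges
#' coincide with planted boundaries; switched regions are whole segments
#' (plus at most one contiguous partial segment to honour the requested
#' switch fraction exactly); tumour-specific boundaries bisect randomly
#' chosen normal TADs; enhanced/weakened boundary strength deltas and
#' gained/lost loops define the tumour's differences.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_truth`; see fields in the source.
#' @export
make_truth <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  cfg <- config
  nb <- cfg$bins_per_chrom
  spec <- genome_spec(cfg$chroms, rep(nb * cfg$resolution, length(cfg$chroms)),
                      cfg$resolution)
  margin <- cfg$edge_margin_bins
  k <- cfg$n_boundaries_per_chrom
  if (k >= nb - 2L * margin) stop("infeasible config: more boundaries than interior bins")

  boundaries <- NULL
  for (ch in cfg$chroms) {
    gap <- (nb - 2 * margin) / (k + 1)
    pos <- round(margin + (1:k) * gap + stats::runif(k, -gap / 5, gap / 5))
    boundaries <- rbind(boundaries, data.frame(
      chrom = ch, bin = as.integer(sort(pos)),
      strength_normal = stats::runif(k, cfg$boundary_strength_range[1L],
                                     cfg$boundary_strength_range[2L]),
      in_normal = TRUE, in_tumour = TRUE, class = "shared",
      stringsAsFactors = FALSE))
  }
  boundaries$strength_tumour <- boundaries$strength_normal

  # tumour-specific boundaries bisect random normal TADs
  for (ch in cfg$chroms) {
    bpos <- boundaries$bin[boundaries$chrom == ch]
    segs <- cbind(c(0L, bpos), c(bpos, nb))
    interior <- which(segs[, 1L] > 0L & segs[, 2L] < nb)
    pick <- sample(interior, cfg$n_extra_tumour_boundaries_per_chrom)
    mid <- as.integer(round((segs[pick, 1L] + segs[pick, 2L]) / 2))
    boundaries <- rbind(boundaries, data.frame(
      chrom = ch, bin = mid,
      strength_normal = NA_real_,
      in_normal = FALSE, in_tumour = TRUE, class = "tumour_specific",
      strength_tumour = stats::runif(length(mid), 0.45, 0.65),
      stringsAsFactors = FALSE))
  }
  boundaries <- boundaries[order(match(boundaries$chrom, cfg$chroms), boundaries$bin), ]
  rownames(boundaries) <- NULL

  # enhanced / weakened boundaries: the tumour transmits a fixed ratio of the
  # normal cross-boundary contact fraction (1 - s), so the planted log2IS
  # shift is roughly uniform across boundaries of different base strength
  shared <- which(boundaries$class == "shared")
  pick <- sample(shared, cfg$n_enhanced_boundaries + cfg$n_weakened_boundaries)
  enh <- pick[seq_len(cfg$n_enhanced_boundaries)]
  wea <- setdiff(pick, enh)
  boundaries$class[enh] <- "enhanced"
  boundaries$strength_tumour[enh] <-
    1 - (1 - boundaries$strength_normal[enh]) * cfg$boundary_delta_ratio
  boundaries$class[wea] <- "weakened"
  boundaries$strength_tumour[wea] <-
    1 - (1 - boundaries$strength_normal[wea]) / cfg$boundary_delta_ratio

  # compartment segments from the normal segmentation: Markov-persistent
  # signs, resampled until the chromosome's A fraction is roughly balanced
  # (real chromosomes are not single-compartment)
  segments <- NULL
  for (ch in cfg$chroms) {
    bpos <- boundaries$bin[boundaries$chrom == ch & boundaries$in_normal]
    s0 <- c(0L, bpos); s1 <- c(bpos, nb)
    len <- s1 - s0
    for (try in 1:100) {
      sgn <- integer(length(s0))
      sgn[1L] <- sample(c(-1L, 1L), 1L)
      for (q in seq_along(sgn)[-1L]) {
        sgn[q] <- if (stats::runif(1) < cfg$compartment_flip_prob) -sgn[q - 1L] else sgn[q - 1L]
      }
      a_frac <- sum(len[sgn == 1L]) / sum(len)
      if (a_frac >= 0.35 && a_frac <= 0.65) break
    }
    segments <- rbind(segments, data.frame(
      chrom = ch, start_bin = s0, end_bin = s1, sign_normal = sgn,
      stringsAsFactors = FALSE))
  }
  seg_len <- segments$end_bin - segments$start_bin

  # switched regions: whole segments plus one contiguous partial remainder
  total_bins <- n_bins(spec)
  target <- round(cfg$switch_fraction * total_bins)
  target_ab <- round(cfg$switch_a_to_b_share * target)
  # segments flanked by a planted differential boundary are kept out of the
  # switch pool so the two planted effects stay separable
  diff_bins <- boundaries$bin[boundaries$class %in% c("enhanced", "weakened")]
  diff_chrom <- boundaries$chrom[boundaries$class %in% c("enhanced", "weakened")]
  eligible <- !mapply(function(ch, s0, s1) {
    any(diff_chrom == ch & (diff_bins == s0 | diff_bins == s1))
  }, segments$chrom, segments$start_bin, segments$end_bin)
  # fill each direction's bin budget with whole segments (eligible first),
  # topping up with one contiguous partial flip per direction; a partial
  # prefers the end adjacent to an already-flipped segment so it adds at most
  # one new plaid edge
  flipped <- rep(FALSE, nrow(segments))
  partials <- list() # (segment row, n bins, from_start)
  # switched mass is capped per chromosome so no single chromosome inverts
  # its gene-density/compartment relationship (switches are genome-wide in
  # real tumours)
  chrom_cap <- round(cfg$max_switch_chrom_fraction * nb)
  chrom_used <- stats::setNames(rep(0L, length(cfg$chroms)), cfg$chroms)
  fill_direction <- function(sgn, budget) {
    filled <- 0L
    fits <- function(s, len) {
      filled + len <= budget && chrom_used[segments$chrom[s]] + len <= chrom_cap
    }
    take <- function(cand) {
      for (s in cand[sample.int(length(cand))]) {
        if (fits(s, seg_len[s])) {
          flipped[s] <<- TRUE
          filled <<- filled + seg_len[s]
          chrom_used[segments$chrom[s]] <<- chrom_used[segments$chrom[s]] + seg_len[s]
        }
      }
    }
    take(which(eligible & !flipped & segments$sign_normal == sgn))
    take(which(!flipped & segments$sign_normal == sgn))
    rem <- budget - filled
    if (rem > 0L) {
      cand <- which(!flipped & segments$sign_normal == sgn & seg_len > rem)
      cand <- cand[chrom_used[segments$chrom[cand]] + rem <= chrom_cap]
      pref <- cand[eligible[cand]]
      if (length(pref)) cand <- pref
      if (length(cand)) {
        s <- cand[sample.int(length(cand), 1L)]
        left_adj <- any(flipped & segments$chrom == segments$chrom[s] &
                          segments$end_bin == segments$start_bin[s])
        partials[[length(partials) + 1L]] <<- list(seg = s, n = rem, from_start = left_adj)
        chrom_used[segments$chrom[s]] <<- chrom_used[segments$chrom[s]] + rem
        filled <- filled + rem
      }
    }
    filled
  }
  got_ab <- fill_direction(1L, target_ab)
  got_ba <- fill_direction(-1L, target - got_ab)
  if (got_ab + got_ba < target) { # direction supply exhausted; fill with any
    got_ab2 <- fill_direction(1L, target - got_ab - got_ba)
    if (got_ab + got_ba + got_ab2 < target)
      stop("infeasible config: not enough switchable bins")
  }
  segments$sign_tumour <- ifelse(flipped, -segments$sign_normal, segments$sign_normal)

  v_from <- function(col) {
    v <- integer(total_bins)
    for (r in seq_len(nrow(segments))) {
      g <- global_bin(spec, segments$chrom[r], segments$start_bin[r]:(segments$end_bin[r] - 1L))
      v[g] <- segments[[col]][r]
    }
    v
  }
  v_normal <- v_from("sign_normal")
  v_tumour <- v_from("sign_tumour")
  for (pp in partials) {
    r <- pp$seg
    bins <- if (pp$from_start) {
      segments$start_bin[r]:(segments$start_bin[r] + pp$n - 1L)
    } else {
      (segments$end_bin[r] - pp$n):(segments$end_bin[r] - 1L)
    }
    g <- global_bin(spec, segments$chrom[r], bins)
    v_tumour[g] <- -v_normal[g]
  }
  stopifnot(sum(v_normal != v_tumour) == target)

  # loops: shared + gained (tumour only) + lost (normal only); anchors are
  # kept away from strong cross-boundary depletion so every planted loop is
  # recoverable in principle
  Lloc <- cfg$boundary_local_scale_bins
  sample_loops <- function(n_per_chrom_total, existing) {
    out <- existing
    need <- n_per_chrom_total
    for (ch in names(need)) {
      bpos <- boundaries$bin[boundaries$chrom == ch]
      placed <- 0L
      tries <- 0L
      while (placed < need[[ch]] && tries < 5000L) {
        tries <- tries + 1L
        sep <- sample(cfg$loop_sep_range_bins[1L]:cfg$loop_sep_range_bins[2L], 1L)
        i <- sample(cfg$loop_margin_bins:(nb - cfg$loop_margin_bins - sep), 1L)
        j <- i + sep
        between <- bpos[bpos > i & bpos <= j]
        if (length(between) &&
            any(exp(-((between - i)^2 + (j - between)^2) / (2 * Lloc^2)) > 0.2)) next
        ex <- out[out$chrom == ch, , drop = FALSE]
        if (nrow(ex) && any(abs(ex$bin1 - i) <= cfg$loop_min_dist_bins &
                            abs(ex$bin2 - j) <= cfg$loop_min_dist_bins)) next
        out <- rbind(out, data.frame(chrom = ch, bin1 = i, bin2 = j,
                                     amplitude = cfg$loop_amplitude,
                                     in_normal = NA, in_tumour = NA, class = NA,
                                     stringsAsFactors = FALSE))
        placed <- placed + 1L
      }
      if (placed < need[[ch]]) stop("could not place the requested loops")
    }
    out
  }
  empty_loops <- data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
                            amplitude = numeric(), in_normal = logical(),
                            in_tumour = logical(), class = character(),
                            stringsAsFactors = FALSE)
  nshare <- stats::setNames(rep(cfg$n_shared_loops_per_chrom, length(cfg$chroms)), cfg$chroms)
  loops <- sample_loops(nshare, empty_loops)
  loops$in_normal <- TRUE; loops$in_tumour <- TRUE; loops$class <- "shared"
  spread <- function(total) { # split a genome-wide count over chromosomes
    base <- total %/% length(cfg$chroms)
    extra <- total - base * length(cfg$chroms)
    cnt <- rep(base, length(cfg$chroms)) + (seq_along(cfg$chroms) <= extra)
    stats::setNames(cnt, cfg$chroms)
  }
  n0 <- nrow(loops)
  loops <- sample_loops(spread(cfg$n_gained_loops), loops)
  loops$class[(n0 + 1L):nrow(loops)] <- "gained"
  loops$in_normal[(n0 + 1L):nrow(loops)] <- FALSE
  loops$in_tumour[(n0 + 1L):nrow(loops)] <- TRUE
  n0 <- nrow(loops)
  loops <- sample_loops(spread(cfg$n_lost_loops), loops)
  loops$class[(n0 + 1L):nrow(loops)] <- "lost"
  loops$in_normal[(n0 + 1L):nrow(loops)] <- TRUE
  loops$in_tumour[(n0 + 1L):nrow(loops)] <- FALSE

  bias <- exp(stats::rnorm(total_bins, 0, cfg$bias_sd))
  # a small unmappable-bin fraction with strongly reduced bias, kept clear of
  # planted boundaries and loop anchors so the planted structure stays
  # recoverable after low-coverage masking
  n_junk <- round(cfg$unmappable_fraction * total_bins)
  reserved <- unique(c(
    unlist(lapply(-2:2, function(d) global_bin(
      spec, boundaries$chrom, pmin(pmax(boundaries$bin + d, 0L), nb - 1L)))),
    unlist(lapply(-2:2, function(d) c(
      global_bin(spec, loops$chrom, pmin(pmax(loops$bin1 + d, 0L), nb - 1L)),
      global_bin(spec, loops$chrom, pmin(pmax(loops$bin2 + d, 0L), nb - 1L)))))))
  junk <- sample(setdiff(seq_len(total_bins), reserved), n_junk)
  bias[junk] <- bias[junk] *
    stats::runif(n_junk, cfg$unmappable_bias_range[1L], cfg$unmappable_bias_range[2L])

  # genes: TSS density ratio d_A:d_B, expression means coupled to structure
  prob <- ifelse(v_normal == 1L, cfg$gene_density_ratio, 1)
  tssg <- sample.int(total_bins, cfg$n_genes, replace = TRUE, prob = prob)
  loc <- global_to_local(spec, tssg)
  len <- stats::runif(cfg$n_genes, cfg$gene_length_range[1L], cfg$gene_length_range[2L])
  offs <- stats::runif(cfg$n_genes, 0, cfg$resolution - 1)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  tss_bp <- loc$bin * cfg$resolution + floor(offs)
  chrom_len <- spec$lengths[loc$chrom]
  start <- ifelse(strand == "+", tss_bp, pmax(0, tss_bp + 1 - len))
  end <- ifelse(strand == "+", pmin(chrom_len, tss_bp + len), tss_bp + 1)
  genes <- gene_table(sprintf("gene%04d", seq_len(cfg$n_genes)),
                      loc$chrom, start, end, strand)

  mu_n <- ifelse(v_normal[tssg] == 1L, cfg$expr_base_a, cfg$expr_base_b) +
    stats::rnorm(cfg$n_genes, 0, cfg$expr_gene_sd)
  eff <- numeric(cfg$n_genes)
  sw_b_to_a <- v_normal[tssg] == -1L & v_tumour[tssg] == 1L
  sw_a_to_b <- v_normal[tssg] == 1L & v_tumour[tssg] == -1L
  eff[sw_b_to_a] <- eff[sw_b_to_a] + cfg$effect_switch
  eff[sw_a_to_b] <- eff[sw_a_to_b] - cfg$effect_switch
  half_w <- 25L # boundary association half-window in bins (500 kb window)
  gene_bin <- loc$bin
  for (r in which(boundaries$class %in% c("enhanced", "weakened"))) {
    hit <- genes$chrom == boundaries$chrom[r] &
      abs(gene_bin - boundaries$bin[r]) <= half_w
    sgn <- if (boundaries$class[r] == "enhanced") 1 else -1
    eff[hit] <- eff[hit] + sgn * cfg$effect_boundary
  }
  for (r in which(loops$class %in% c("gained", "lost"))) {
    hit <- genes$chrom == loops$chrom[r] &
      (abs(gene_bin - loops$bin1[r]) <= 2L | abs(gene_bin - loops$bin2[r]) <= 2L)
    sgn <- if (loops$class[r] == "gained") 1 else -1
    eff[hit] <- eff[hit] + sgn * cfg$effect_loop
  }
  gene_info <- data.frame(genes, tss_global_bin = tssg,
                          compartment_normal = ifelse(v_normal[tssg] == 1L, "A", "B"),
                          compartment_tumour = ifelse(v_tumour[tssg] == 1L, "A", "B"),
                          mu_normal = mu_n, mu_tumour = mu_n + eff,
                          planted_effect = eff, stringsAsFactors = FALSE)

  structure(list(spec = spec, config = cfg, seed = seed,
                 boundaries = boundaries, segments = segments,
                 v_normal = v_normal, v_tumour = v_tumour,
                 switched_bins = which(v_normal != v_tumour),
                 loops = loops, bias = bias, unmappable_bins = sort(junk),
                 genes = gene_info),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d bins, %d boundaries (%d tumour-specific), ",
                     "%d loops (%d gained, %d lost), %d switched bins, %d genes\n"),
              n_bins(x$spec), nrow(x$boundaries),
              sum(x$boundaries$class == "tumour_specific"),
              nrow(x$loops), sum(x$loops$class == "gained"),
              sum(x$loops$class == "lost"),
              length(x$switched_bins), nrow(x$genes)))
  invisible(x)
}

# expected intensity field (upper triangle as dense matrix) for one
# chromosome and sample; structural modifiers are renormalized per separation
# stratum so the marginal decay is exactly d^alpha, then loop bumps multiply.
chrom_intensity <- function(truth, chrom, sample) {
  cfg <- truth$config
  spec <- truth$spec
  ci <- match(chrom, spec$chroms)
  n <- spec$nbins[ci]
  rng <- (spec$offsets[ci] + 1L):(spec$offsets[ci] + n)
  v <- if (sample == "normal") truth$v_normal[rng] else truth$v_tumour[rng]
  bset <- truth$boundaries[truth$boundaries$chrom == chrom &
                             truth$boundaries[[paste0("in_", sample)]], ]
  strength <- bset[[paste0("strength_", sample)]]

  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  plaid <- 1 + cfg$plaid_c * outer(v, v)
  # boundary insulation is local: pixels crossing boundary b are depleted by
  # (1 - s_b)^G with a Gaussian locality factor G peaking at the boundary
  # corner; far-separation structure stays pure plaid.
  L <- cfg$boundary_local_scale_bins
  logatt <- matrix(0, n, n)
  bsig <- numeric(n + 1L)
  bsig[bset$bin + 1L] <- 1
  edge2 <- 2 * 1.5^2 # depletion ramps in over ~3 bins at the boundary plane
  for (r in seq_len(nrow(bset))) {
    b <- bset$bin[r]
    s <- strength[r]
    ii <- max(1L, b - 4L * L + 1L):b           # 0-based bins b-4L .. b-1
    jj <- (b + 1L):min(n, b + 4L * L)          # 0-based bins b .. b+4L-1
    d1 <- b - ii + 0.5                         # distance to the boundary plane
    d2 <- jj - 1L - b + 0.5
    g1 <- exp(-d1^2 / (2 * L^2)) * (1 - exp(-d1^2 / edge2))
    g2 <- exp(-d2^2 / (2 * L^2)) * (1 - exp(-d2^2 / edge2))
    logatt[ii, jj] <- logatt[ii, jj] + log(1 - s) * outer(g1, g2)
    logatt[jj, ii] <- t(logatt[ii, jj])
  }
  segid <- cumsum(bsig)[seq_len(n)]
  tfac <- ifelse(outer(segid, segid, "=="), cfg$tad_t, 1)
  phi <- plaid * exp(logatt) * tfac
  # renormalize per separation stratum
  m_d <- rowsum(as.vector(phi), as.vector(sep))[, 1L] / tabulate(as.vector(sep) + 1L, n)
  phi <- phi / matrix(m_d[sep + 1L], n, n)
  # focal loop bumps (applied after normalization: planted O/E = 1 + a*G)
  lset <- truth$loops[truth$loops$chrom == chrom &
                        truth$loops[[paste0("in_", sample)]], ]
  L <- matrix(1, n, n)
  if (nrow(lset)) {
    halo <- ceiling(4 * cfg$loop_sigma)
    for (r in seq_len(nrow(lset))) {
      a1 <- lset$bin1[r] + 1L; a2 <- lset$bin2[r] + 1L
      ii <- max(1L, a1 - halo):min(n, a1 + halo)
      jj <- max(1L, a2 - halo):min(n, a2 + halo)
      G <- exp(-(outer((ii - a1)^2, (jj - a2)^2, "+")) / (2 * cfg$loop_sigma^2))
      L[ii, jj] <- L[ii, jj] + lset$amplitude[r] * G
      L[jj, ii] <- t(L[ii, jj])
    }
  }
  dec <- pmax(sep, 0.5)^cfg$alpha
  b <- truth$bias[rng]
  mu <- dec * phi * L * outer(b, b)
  ut <- upper.tri(mu, diag = TRUE)
  mu[ut] <- mu[ut] * (cfg$depth_cis_per_chrom / sum(mu[ut]))
  list(mu = mu, ut = ut, n = n)
}

#' Simulate one contact map from a planted truth
#'
#' Cis intensity per chromosome: power-law decay times the per-separation
#' renormalized structural modifier (compartment plaid, within-TAD enrichment
#' `t`, multiplicative attenuation `1 - strength` per crossed boundary), times
#' Gaussian loop bumps `1 + a G`, times bin biases; scaled to the configured
#' cis depth and Poisson-sampled. Trans intensity is uniform up to bin biases
#' at the sample's configured trans fraction.
#'
#' @param truth A [make_truth()] object.
#' @param sample `"normal"` or `"tumour"`.
#' @param seed Integer seed for the Poisson noise (a replicate is the same
#'   truth and sample with a different seed).
#' @return A raw [contact_matrix()].
#' @export
simulate_contact_map <- function(truth, sample = c("normal", "tumour"), seed = 1L) {
  sample <- match.arg(sample)
  cfg <- truth$config
  if (cfg$depth_cis_per_chrom <= 0) stop("zero depth")
  spec <- truth$spec
  set.seed(seed)
  px <- list()
  for (ch in spec$chroms) {
    fld <- chrom_intensity(truth, ch, sample)
    idx <- which(fld$ut, arr.ind = TRUE)
    cnt <- stats::rpois(nrow(idx), fld$mu[fld$ut])
    keep <- cnt > 0L
    px[[ch]] <- data.frame(chrom1 = ch, bin1 = idx[keep, 1L] - 1L,
                           chrom2 = ch, bin2 = idx[keep, 2L] - 1L,
                           count = cnt[keep], stringsAsFactors = FALSE)
  }
  tf <- if (sample == "normal") cfg$trans_fraction_normal else cfg$trans_fraction_tumour
  if (tf > 0 && length(spec$chroms) > 1L) {
    total_cis <- cfg$depth_cis_per_chrom * length(spec$chroms)
    t_total <- tf / (1 - tf) * total_cis
    pairs <- utils::combn(spec$chroms, 2L)
    wsum <- 0
    for (k in seq_len(ncol(pairs))) {
      r1 <- match(pairs[1L, k], spec$chroms); r2 <- match(pairs[2L, k], spec$chroms)
      b1 <- truth$bias[(spec$offsets[r1] + 1L):(spec$offsets[r1] + spec$nbins[r1])]
      b2 <- truth$bias[(spec$offsets[r2] + 1L):(spec$offsets[r2] + spec$nbins[r2])]
      wsum <- wsum + sum(b1) * sum(b2)
    }
    for (k in seq_len(ncol(pairs))) {
      ch1 <- pairs[1L, k]; ch2 <- pairs[2L, k]
      r1 <- match(ch1, spec$chroms); r2 <- match(ch2, spec$chroms)
      b1 <- truth$bias[(spec$offsets[r1] + 1L):(spec$offsets[r1] + spec$nbins[r1])]
      b2 <- truth$bias[(spec$offsets[r2] + 1L):(spec$offsets[r2] + spec$nbins[r2])]
      mu <- outer(b1, b2) * (t_total / wsum)
      cnt <- stats::rpois(length(mu), mu)
      keep <- cnt > 0L
      ridx <- ((seq_along(mu) - 1L) %% length(b1)) + 1L
      cidx <- ((seq_along(mu) - 1L) %/% length(b1)) + 1L
      px[[paste(ch1, ch2)]] <- data.frame(
        chrom1 = ch1, bin1 = ridx[keep] - 1L,
        chrom2 = ch2, bin2 = cidx[keep] - 1L,
        count = cnt[keep], stringsAsFactors = FALSE)
    }
  }
  contact_matrix(spec, do.call(rbind, px))
}

#' Simulate a paired normal/tumour map set
#'
#' Both maps share all unchanged structure; the tumour applies the planted
#' switched-bin sign flips, boundary strength deltas and tumour-specific
#' boundaries, adds gained loops and drops lost loops.
#'
#' @param truth A [make_truth()] object.
#' @param seed_normal,seed_tumour Poisson seeds for the two maps.
#' @return `list(normal = , tumour = )` of raw [contact_matrix()] objects.
#' @export
simulate_pair <- function(truth, seed_normal = 11L, seed_tumour = 12L) {
  list(normal = simulate_contact_map(truth, "normal", seed_normal),
       tumour = simulate_contact_map(truth, "tumour", seed_tumour))
}

#' Simulate coupled expression and a surrogate DE table
#'
#' Per-gene log2 counts are normal around the planted condition means
#' (structure-coupled shifts for switched compartments, differential
#' boundaries and differential loop anchors); the surrogate differential
#' expression table comes from per-gene two-sample Welch t-tests on the log2
#' counts with BH correction.
#'
#' @param truth A [make_truth()] object.
#' @param n_replicates Replicates per condition, `>= 2`.
#' @param seed Integer seed.
#' @return A list: `genes` ([gene_table()]), `expr` data.frame (`gene`,
#'   `log2FC`, `pvalue`, `padj`, `baseMean`), `counts` matrix (genes x
#'   replicates, log2 scale, columns `normal_*` / `tumour_*`).
#' @export
simulate_expression <- function(truth, n_replicates = 3L, seed = 1L) {
  if (n_replicates < 2L) stop("need at least 2 replicates per condition")
  set.seed(seed)
  gi <- truth$genes
  ng <- nrow(gi)
  sd0 <- truth$config$expr_noise_sd
  cn <- matrix(stats::rnorm(ng * n_replicates, gi$mu_normal, sd0), ng)
  ct <- matrix(stats::rnorm(ng * n_replicates, gi$mu_tumour, sd0), ng)
  lfc <- rowMeans(ct) - rowMeans(cn)
  pv <- vapply(seq_len(ng), function(r) {
    stats::t.test(ct[r, ], cn[r, ])$p.value
  }, 0)
  expr <- data.frame(gene = gi$gene, log2FC = lfc, pvalue = pv,
                     padj = stats::p.adjust(pv, "BH"),
                     baseMean = rowMeans(2^cbind(cn, ct)),
                     stringsAsFactors = FALSE)
  counts <- cbind(cn, ct)
  colnames(counts) <- c(paste0("normal_", seq_len(n_replicates)),
                        paste0("tumour_", seq_len(n_replicates)))
  rownames(counts) <- gi$gene
  list(genes = gi[, c("gene", "chrom", "start", "end", "strand", "tss")],
       expr = expr, counts = counts)
}
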
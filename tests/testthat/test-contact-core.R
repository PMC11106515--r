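test_that("contact matrix queries are symmetric and bounds are enforced", {
  spec <- toy_spec(10)
  M <- contact_matrix(spec, data.frame(chrom1 = "chr1", bin1 = 0L,
                                       chrom2 = "chr1", bin2 = 1L, count = 5))
  expect_equal(query(M, "chr1", 1, "chr1", 0), 5)
  expect_equal(query(M, "chr1", 0, "chr1", 1), 5)
  expect_equal(query(M, "chr1", 3, "chr1", 4), 0)
  expect_error(contact_matrix(spec, data.frame(chrom1 = "chr1", bin1 = 999L,
                                               chrom2 = "chr1", bin2 = 0L, count = 1)),
               "out of range")
  expect_error(contact_matrix(spec, data.frame(chrom1 = "chrX", bin1 = 0L,
                                               chrom2 = "chr1", bin2 = 0L, count = 1)),
               "unknown chromosome")
  expect_error(contact_matrix(spec, data.frame(chrom1 = "chr1", bin1 = 0L,
                                               chrom2 = "chr1", bin2 = 1L, count = -2)),
               ">= 0")
})

test_that("triplet text round trip preserves all entries", {
  spec <- genome_spec(c("chr1", "chr2"), c(1e5, 8e4), 1e4)
  set.seed(4)
  px <- data.frame(chrom1 = sample(c("chr1", "chr2"), 30, TRUE),
                   bin1 = sample(0:7, 30, TRUE),
                   chrom2 = "chr2", bin2 = sample(0:7, 30, TRUE),
                   count = rpois(30, 8) + 1)
  M <- contact_matrix(spec, px)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(M, path)
  M2 <- load_contact_matrix(path, spec)
  expect_equal(as.data.frame(M$pixels), as.data.frame(M2$pixels))
  # malformed file: no header
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t0\tchr1\t1\t5", bad)
  expect_error(load_contact_matrix(bad, spec), "header")
})

test_that("ICE balancing matches an independent dense oracle", {
  # equal row sums: fixed point, weights all equal
  n <- 6
  flat <- matrix(2, n, n)
  M <- ice_balance(cm_from_dense(flat), mask_quantile = 0)
  expect_equal(unname(M$weights), rep(1, n), tolerance = 1e-8)

  # one row scaled x2: balanced row sums equal within 1e-5, weights match the
  # brute-force loop oracle up to scale
  skew <- matrix(3, 4, 4)
  skew[2, ] <- skew[2, ] * 2
  skew[, 2] <- skew[2, ]
  M2 <- ice_balance(cm_from_dense(skew), mask_quantile = 0)
  expect_lt(balanced_rowsum_cv(M2), 1e-5)
  w_oracle <- ice_oracle(skew)
  expect_equal(unname(M2$weights), w_oracle, tolerance = 1e-4)

  # an all-zero row is masked with undefined weight
  z <- matrix(1, 5, 5)
  z[3, ] <- 0
  z[, 3] <- 0
  M3 <- ice_balance(cm_from_dense(z), mask_quantile = 0)
  expect_false(M3$valid[3])
  expect_true(is.na(M3$weights[3]))
  expect_true(all(M3$valid[-3]))
})

test_that("re-balancing an already balanced matrix leaves weights at one", {
  M <- fx("Mn")
  px <- pixel_table(M)
  g1 <- hicdelta:::global_bin(M$spec, px$chrom1, px$bin1)
  g2 <- hicdelta:::global_bin(M$spec, px$chrom2, px$bin2)
  keep <- M$valid[g1] & M$valid[g2]
  px <- px[keep, ]
  px$count <- px$count * M$weights[g1[keep]] * M$weights[g2[keep]]
  M2 <- ice_balance(contact_matrix(M$spec, px), mask_quantile = 0)
  expect_lt(max(abs(M2$weights[M2$valid] - 1)), 1e-3)
})

test_that("expected profile handles edge cases and the decay fit is exact on power laws", {
  # contacts only at separation 1 on a 2-bin chromosome
  spec <- toy_spec(2)
  M <- with_unit_weights(contact_matrix(spec, data.frame(
    chrom1 = "chr1", bin1 = 0L, chrom2 = "chr1", bin2 = 1L, count = 7)))
  D <- compute_expected(M, "per-chrom")
  expect_equal(D$value[D$sep_bins == 1], 7)
  expect_equal(D$value[D$sep_bins == 0], 0)
  expect_error(compute_expected(contact_matrix(toy_spec(4), data.frame(
    chrom1 = character(), bin1 = integer(), chrom2 = character(),
    bin2 = integer(), count = numeric()))), "no counts|no cis")

  # exact closed-form slopes
  for (alpha in c(-1, -1.5)) {
    D <- data.frame(chrom = "pooled", sep_bins = 1:100, sep_bp = (1:100) * 1e4)
    D$value <- D$sep_bp^alpha
    D$n_pairs <- 100
    class(D) <- c("decay_profile", "data.frame")
    expect_equal(unclass(fit_decay_exponent(D, 1e4, 1e6)), alpha,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  D$value <- 0
  expect_error(fit_decay_exponent(D, 1e4, 1e6), "fewer than 3")
})

test_that("cis/trans fractions follow the mass partition", {
  spec <- genome_spec(c("chr1", "chr2"), c(3e4, 3e4), 1e4)
  cis_only <- contact_matrix(spec, data.frame(
    chrom1 = c("chr1", "chr2"), bin1 = c(0L, 1L),
    chrom2 = c("chr1", "chr2"), bin2 = c(1L, 2L), count = c(4, 6)))
  ct <- cis_trans_fraction(cis_only)
  expect_equal(ct$cis_fraction, 1)
  expect_equal(ct$per_chrom$cis_fraction, c(1, 1))

  half <- contact_matrix(spec, data.frame(
    chrom1 = c("chr1", "chr1"), bin1 = c(0L, 0L),
    chrom2 = c("chr1", "chr2"), bin2 = c(1L, 0L), count = c(5, 5)))
  expect_equal(cis_trans_fraction(half)$cis_fraction, 0.5)

  empty <- contact_matrix(spec, data.frame(
    chrom1 = "chr1", bin1 = 0L, chrom2 = "chr1", bin2 = 1L, count = 1e-9))
  empty$pixels$count <- 0
  expect_error(cis_trans_fraction(empty), "zero total mass")
})

test_that("log2 ratio map is zero on identical input and finite with pseudocounts", {
  A <- fx("maps")$normal
  sub <- log2_ratio_map(A, A, pseudocount = 1)
  expect_true(all(sub$log2_ratio == 0))

  # one pixel doubled in A, equal totals by construction -> log2 ratio 1 there
  spec <- toy_spec(6)
  a <- contact_matrix(spec, data.frame(chrom1 = "chr1", bin1 = c(0L, 2L),
                                       chrom2 = "chr1", bin2 = c(1L, 3L),
                                       count = c(10, 4)))
  b <- contact_matrix(spec, data.frame(chrom1 = "chr1", bin1 = c(0L, 2L),
                                       chrom2 = "chr1", bin2 = c(1L, 3L),
                                       count = c(5, 9)))
  r <- log2_ratio_map(a, b, pseudocount = 0)
  expect_equal(r$log2_ratio[r$bin1 == 0 & r$bin2 == 1], 1, tolerance = 1e-12)
  bz <- contact_matrix(spec, data.frame(chrom1 = "chr1", bin1 = 0L,
                                        chrom2 = "chr1", bin2 = 5L, count = 2))
  rz <- log2_ratio_map(a, bz, pseudocount = 1)
  expect_true(all(is.finite(rz$log2_ratio)))
})

test_that("depth normalization preserves relative pixel ratios exactly", {
  A <- fx("maps")$normal
  B <- fx("maps")$tumour
  sc <- normalize_depth(A, B)
  expect_equal(total_mass(sc[[1]]), total_mass(sc[[2]]))
  ratio <- sc[[1]]$pixels$count / A$pixels$count
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("inter-chromosomal O/E is calibrated and responds linearly", {
  spec <- genome_spec(c("chr1", "chr2", "chr3"), c(2e5, 2e5, 1e5), 1e4)
  set.seed(11)
  # trans mass proportional to bin-count products -> O/E ~ 1
  pairs <- utils::combn(spec$chroms, 2)
  px <- NULL
  for (k in seq_len(ncol(pairs))) {
    n1 <- spec$nbins[pairs[1, k]]; n2 <- spec$nbins[pairs[2, k]]
    grid <- expand.grid(bin1 = 0:(n1 - 1), bin2 = 0:(n2 - 1))
    px <- rbind(px, data.frame(chrom1 = pairs[1, k], bin1 = grid$bin1,
                               chrom2 = pairs[2, k], bin2 = grid$bin2,
                               count = rpois(nrow(grid), 40)))
  }
  M <- contact_matrix(spec, px)
  oe <- interchrom_oe(M, top_k = 10)
  expect_lt(max(abs(oe$oe[upper.tri(oe$oe)] - 1)), 0.05)
  expect_equal(nrow(oe$top_pixels), 10)

  # doubling all chr1-chr2 contacts roughly doubles that block's O/E
  px2 <- px
  sel <- px2$chrom1 == "chr1" & px2$chrom2 == "chr2"
  px2$count[sel] <- px2$count[sel] * 2
  oe2 <- interchrom_oe(contact_matrix(spec, px2), top_k = 5)
  scale_shift <- sum(px2$count) / sum(px$count) # total observed changed too
  expect_equal(oe2$oe["chr1", "chr2"] / oe$oe["chr1", "chr2"], 2 / scale_shift,
               tolerance = 1e-6)

  one <- genome_spec("chr1", 2e5, 1e4)
  expect_error(interchrom_oe(contact_matrix(one, data.frame(
    chrom1 = "chr1", bin1 = 0L, chrom2 = "chr1", bin2 = 1L, count = 3))),
    "two chromosomes")
})

test_that("coarsening aggregates counts onto the coarser grid", {
  spec <- toy_spec(10)
  M <- contact_matrix(spec, data.frame(
    chrom1 = "chr1", bin1 = c(0L, 1L, 4L), chrom2 = "chr1",
    bin2 = c(1L, 1L, 5L), count = c(2, 3, 7)))
  M2 <- coarsen(M, 2)
  expect_equal(M2$spec$resolution, 2e4)
  expect_equal(query(M2, "chr1", 0, "chr1", 0), 5)
  expect_equal(query(M2, "chr1", 2, "chr1", 2), 7)
})
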
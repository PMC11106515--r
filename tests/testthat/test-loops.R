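test_that("local expecteds are flat on constant maps and ignore the peak region", {
  n <- 40
  M <- with_unit_weights(cm_from_dense(matrix(6, n, n)))
  le <- local_expected_neighborhoods(M, "chr1", 10, 25)
  expect_equal(le$mean_balanced, rep(6, 4), tolerance = 1e-9)
  expect_equal(le$lambda_balanced, rep(6, 4), tolerance = 1e-9)

  # a bright centre pixel leaves all four expecteds untouched
  bright <- matrix(6, n, n)
  bright[11, 26] <- bright[26, 11] <- 600
  Mb <- with_unit_weights(cm_from_dense(bright))
  leb <- local_expected_neighborhoods(Mb, "chr1", 10, 25)
  expect_equal(leb$mean_balanced, rep(6, 4), tolerance = 1e-9)

  expect_error(local_expected_neighborhoods(M, "chr1", 10, 14), "separation")
})

test_that("donut and stripe means match cell-by-cell enumeration", {
  n <- 41
  vals <- outer(1:n, 1:n, function(i, j) 1 + ((i * 7 + j * 3) %% 5))
  vals <- (vals + t(vals)) / 2
  M <- with_unit_weights(cm_from_dense(vals))
  p <- 2L; w <- 5L
  ci <- 16L; cj <- 31L # 0-based pixel (15, 30)
  le <- local_expected_neighborhoods(M, "chr1", ci - 1L, cj - 1L, p = p, w = w)

  cells <- expand.grid(di = -w:w, dj = -w:w)
  cells$chebyshev <- pmax(abs(cells$di), abs(cells$dj))
  donut <- cells[cells$chebyshev > p & cells$chebyshev <= w &
                   abs(cells$di) > p & abs(cells$dj) > p, ]
  horiz <- cells[abs(cells$di) <= p & abs(cells$dj) > p & abs(cells$dj) <= w, ]
  vert <- cells[abs(cells$di) > p & abs(cells$di) <= w & abs(cells$dj) <= p, ]
  ll <- cells[cells$di >= 1 & cells$di <= w - p & cells$dj <= -1 & cells$dj >= -(w - p), ]
  enum_mean <- function(cc) mean(vals[cbind(ci + cc$di, cj + cc$dj)])
  expect_equal(le$mean_balanced[le$region == "donut"], enum_mean(donut))
  expect_equal(le$mean_balanced[le$region == "horizontal"], enum_mean(horiz))
  expect_equal(le$mean_balanced[le$region == "vertical"], enum_mean(vert))
  expect_equal(le$mean_balanced[le$region == "lower_left"], enum_mean(ll))
  expect_equal(nrow(donut), 4 * (w - p)^2)
})

test_that("a planted focal peak is called once at the right pixel, near-diagonal pixels never", {
  set.seed(77)
  n <- 200
  dec <- outer(1:n, 1:n, function(i, j) 400 / pmax(abs(i - j), 0.5))
  bump <- matrix(0, n, n)
  for (di in -3:3) for (dj in -3:3) {
    bump[80 + di, 140 + dj] <- 10 * exp(-(di^2 + dj^2) / 2)
  }
  lam <- dec * (1 + bump)
  cnt <- matrix(rpois(n * n, lam), n, n)
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  M <- ice_balance(cm_from_dense(cnt), mask_quantile = 0)
  calls <- call_loops(M)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$bin1 - 79), 1)
  expect_lte(abs(calls$bin2 - 139), 1)
  # pixels at separation <= p + w are never tested
  pix <- attr(calls, "pixels")
  expect_true(all(pix$bin2 - pix$bin1 > 7))
})

test_that("loop counts shrink monotonically under stricter enrichment and FDR", {
  M <- fx("Mn")
  base <- nrow(fx("loops_n"))
  stricter_fdr <- nrow(call_loops(M, fdr = 0.01))
  stricter_enrich <- nrow(call_loops(M, enrich_donut = 2.5, enrich_hv = 2))
  expect_lte(stricter_fdr, base)
  expect_lte(stricter_enrich, base)
})

test_that("differential loop classification follows the O/E ratio rule and is antisymmetric", {
  dl <- fx("diff_loops")
  # forced rule check on the table itself
  gained <- dl[dl$class == "gained", ]
  expect_true(all(gained$called_tumour & !gained$called_normal))
  expect_true(all(gained$oe_tumour >= 2 * gained$oe_normal))
  lost <- dl[dl$class == "lost", ]
  expect_true(all(lost$called_normal & !lost$called_tumour))
  expect_true(all(lost$oe_normal >= 2 * lost$oe_tumour))

  # swap antisymmetry
  dl_sw <- differential_loops(fx("loops_n"), fx("loops_t"), fx("Mn"), fx("Mt"))
  key <- function(d) paste(d$chrom, d$bin1, d$bin2)
  m <- match(key(dl), key(dl_sw))
  expect_true(all(dl_sw$class[m][dl$class == "gained"] == "lost"))
  expect_true(all(dl_sw$class[m][dl$class == "lost"] == "gained"))

  # identical call sets on the same matrix -> all shared
  dl_id <- differential_loops(fx("loops_n"), fx("loops_n"), fx("Mn"), fx("Mn"))
  expect_true(all(dl_id$class == "shared"))
})

test_that("APA scores the centre against the lower-left corner", {
  # constructed single-loop field: O/E 1 everywhere except centre 3
  n <- 60
  c0 <- 50
  vals <- matrix(c0, n, n)
  ci <- 18L; cj <- 43L # separation 25
  vals[ci, cj] <- vals[cj, ci] <- 3 * c0
  # compensate the stratum mean with two zero pixels at the same separation
  vals[2, 27] <- vals[27, 2] <- 0
  vals[32, 57] <- vals[57, 32] <- 0
  M <- with_unit_weights(cm_from_dense(vals))
  res <- apa(M, data.frame(chrom = "chr1", bin1 = ci - 1L, bin2 = cj - 1L), half = 10)
  expect_equal(res$score, 3, tolerance = 1e-9)

  # identity O/E field scores exactly 1 for any loop list
  Mf <- with_unit_weights(cm_from_dense(matrix(c0, n, n)))
  res1 <- apa(Mf, data.frame(chrom = "chr1", bin1 = c(14L, 17L), bin2 = c(40L, 45L)),
              half = 10)
  expect_equal(res1$score, 1, tolerance = 1e-12)

  expect_error(apa(Mf, data.frame(chrom = character(), bin1 = integer(),
                                  bin2 = integer())), "empty")

  # planted loops score well above shuffled anchors on the benchmark
  ap <- apa(fx("Mt"), fx("loops_t"))
  expect_gt(ap$score, 1.5)
  set.seed(12)
  shuf <- data.frame(chrom = sample(c("chr1", "chr2", "chr3"), 40, TRUE),
                     bin1 = sample(60:350, 40, TRUE))
  shuf$bin2 <- shuf$bin1 + sample(25:90, 40, TRUE)
  ap0 <- apa(fx("Mt"), shuf)
  expect_lt(abs(ap0$score - 1), 0.5)
  expect_gt(ap$score, 2 * ap0$score)
})

test_that("planted loops are recovered with few false calls and sizes match", {
  truth <- fx("truth")
  rn <- loop_recovery(fx("loops_n"), truth$loops[truth$loops$in_normal, ])
  rt <- loop_recovery(fx("loops_t"), truth$loops[truth$loops$in_tumour, ])
  expect_gte(rn["recall"], 0.8)
  expect_gte(rt["recall"], 0.8)
  expect_lte(rn["false_rate"], 0.1)
  expect_lte(rt["false_rate"], 0.1)

  # mean called separation tracks the planted separation distribution
  called_sep <- mean(fx("loops_t")$bin2 - fx("loops_t")$bin1)
  planted_sep <- mean(truth$loops$bin2[truth$loops$in_tumour] -
                        truth$loops$bin1[truth$loops$in_tumour])
  expect_lt(abs(called_sep - planted_sep) / planted_sep, 0.1)
})
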
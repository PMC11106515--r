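test_that("insulation score normalizes correctly and flags degenerate windows", {
  n <- 60
  M <- with_unit_weights(cm_from_dense(matrix(4, n, n)))
  tr <- insulation_track(M, window = 5e4) # w = 5 bins
  inner <- tr$log2_is[tr$bin >= 5 & tr$bin < n - 5]
  expect_equal(max(abs(inner)), 0, tolerance = 1e-9)
  expect_true(all(is.nan(tr$log2_is[tr$bin < 5])))
  # chromosome mean of 2^log2IS is 1
  expect_equal(mean(2^tr$log2_is[is.finite(tr$log2_is)]), 1, tolerance = 1e-6)

  expect_error(insulation_track(M, window = 5.5e4), "multiple")
  expect_error(insulation_track(M, window = 1e7), "too large")

  # two blocks with zero cross-block contact: global minimum at the junction
  blk <- matrix(0, n, n)
  blk[1:30, 1:30] <- 3
  blk[31:n, 31:n] <- 3
  trb <- insulation_track(with_unit_weights(cm_from_dense(blk)), window = 5e4)
  expect_true(trb$bin[which.min(trb$log2_is)] %in% c(29, 30)) # junction (tie)
})

test_that("insulation is invariant to a global scale factor", {
  M <- fx("Mn")
  tr1 <- fx("ins_n")
  M2 <- M
  M2$pixels <- data.table::copy(M2$pixels)
  M2$pixels[, "count" := M2$pixels$count * 3.7]
  tr2 <- insulation_track(M2)
  expect_equal(tr1$log2_is, tr2$log2_is, tolerance = 1e-9)
})

test_that("boundary calling responds to prominence and threshold", {
  flat <- data.frame(chrom = "chr1", bin = 0:99, raw = 1,
                     log2_is = rep(0, 100), stringsAsFactors = FALSE)
  class(flat) <- c("insulation_track", "data.frame")
  expect_equal(nrow(call_boundaries(flat)), 0)

  notch <- flat
  notch$log2_is <- c(rep(0, 50), -1.2, rep(0, 49))
  b <- call_boundaries(notch)
  expect_equal(b$bin, 50)
  expect_equal(b$strength, 1.2)

  # boundary count is monotone non-increasing in min_strength
  tr <- fx("ins_n")
  counts <- vapply(c(0.05, 0.1, 0.3, 0.8), function(th) nrow(call_boundaries(tr, th)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("TAD construction, size statistics and matching behave on toy sets", {
  spec <- toy_spec(30)
  b <- data.frame(chrom = "chr1", bin = c(10L, 20L), log2_is = -1, strength = 1)
  td <- tads_from_boundaries(b, spec)
  expect_equal(td$tads$start, 1e5)
  expect_equal(td$tads$end, 2e5)
  expect_equal(td$mean_boundary_spacing, 1e5)

  one <- tads_from_boundaries(b[1, ], spec)
  expect_equal(one$n_tads, 0)

  b3 <- data.frame(chrom = "chr1", bin = c(3L, 9L, 21L), log2_is = -1, strength = 1)
  expect_equal(tads_from_boundaries(b3, spec)$mean_boundary_spacing,
               mean(c(6, 12)) * 1e4)
  # TADs shorter than 3 bins are dropped from the interval list
  b4 <- data.frame(chrom = "chr1", bin = c(5L, 7L, 20L), log2_is = -1, strength = 1)
  expect_equal(tads_from_boundaries(b4, spec)$n_tads, 1)

  A <- data.frame(chrom = "chr1", bin = c(5L, 15L, 25L), log2_is = -1, strength = 1)
  m_id <- match_boundaries(A, A, 1)
  expect_equal(nrow(m_id$conserved), 3)
  expect_equal(nrow(m_id$a_specific), 0)
  B <- A
  B$bin <- B$bin + 1L
  m_off <- match_boundaries(A, B, 1)
  expect_equal(nrow(m_off$conserved), 3)
  C <- A
  C$bin <- C$bin + 4L
  m_far <- match_boundaries(A, C, 1)
  expect_equal(nrow(m_far$conserved), 0)
  expect_equal(nrow(m_far$a_specific), 3)
  expect_equal(nrow(m_far$b_specific), 3)
})

test_that("the high-confidence and differential rules follow the published thresholds", {
  mk_track <- function(vals) {
    out <- data.frame(chrom = "chr1", bin = seq_along(vals) - 1L,
                      raw = 2^vals, log2_is = vals, stringsAsFactors = FALSE)
    class(out) <- c("insulation_track", "data.frame")
    out
  }
  normal <- mk_track(c(0.2, -0.2, -0.2, -0.5, NaN))
  tumour <- mk_track(c(0.1, -0.7, -0.5, -0.5, -0.3))
  pos <- data.frame(chrom = "chr1", bin = 0:4)
  db <- differential_boundaries(normal, tumour, pos, delta_threshold = 0.4)
  # (+0.2, +0.1): positive in both groups -> excluded
  expect_equal(db$class[1], "excluded")
  # (-0.2, -0.7): delta -0.5 beyond the 0.4 threshold -> enhanced
  expect_equal(db$class[2], "enhanced")
  # (-0.2, -0.5): |delta| = 0.3 below threshold -> unchanged
  expect_equal(db$class[3], "unchanged")
  expect_equal(db$class[4], "unchanged")
  # NaN score -> excluded with a reason
  expect_equal(db$class[5], "excluded")
  expect_match(db$reason[5], "undefined")

  # antisymmetry: swapping samples swaps enhanced and weakened
  db_sw <- differential_boundaries(tumour, normal, pos, delta_threshold = 0.4)
  expect_equal(db_sw$class[2], "weakened")
  expect_equal(db_sw$class[3], "unchanged")
})

test_that("pileups average aligned windows and show the boundary dip", {
  flat <- data.frame(chrom = "chr1", bin = 0:99, raw = 1, log2_is = 0.3)
  class(flat) <- c("insulation_track", "data.frame")
  pos <- data.frame(chrom = "chr1", bin = c(30L, 60L))
  pp <- boundary_pileup(flat, flat, pos, flank_bins = 5)
  expect_equal(pp$normal, rep(0.3, 11))
  expect_error(boundary_pileup(flat, flat, pos[0, ], 5), "empty")

  bn <- fx("bounds_n")
  tr <- fx("ins_n")
  pp2 <- boundary_pileup(tr, tr, bn[, c("chrom", "bin")], flank_bins = 20)
  centre <- pp2$normal[pp2$offset_bins == 0]
  flanks <- mean(pp2$normal[abs(pp2$offset_bins) > 10])
  expect_lt(centre, flanks)
})

test_that("planted boundaries are recovered and the tumour gains TADs", {
  truth <- fx("truth")
  bn <- fx("bounds_n")
  bt <- fx("bounds_t")
  pn <- truth$boundaries[truth$boundaries$in_normal, c("chrom", "bin")]
  pt <- truth$boundaries[truth$boundaries$in_tumour, c("chrom", "bin")]
  rn <- boundary_recovery(bn, pn)
  rt <- boundary_recovery(bt, pt)
  expect_gte(rn["recall"], 0.9)
  expect_gte(rn["precision"], 0.9)
  expect_gte(rt["recall"], 0.9)
  expect_gte(rt["precision"], 0.9)

  td_n <- tads_from_boundaries(bn, truth$spec)
  td_t <- tads_from_boundaries(bt, truth$spec)
  expect_gt(td_t$n_tads, td_n$n_tads)
  expect_lt(td_t$mean_tad_size, td_n$mean_tad_size)
})
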
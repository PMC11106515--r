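# Shared fixtures. The full synthetic benchmark (truth seed 1, map seeds
# 111/112) is expensive, so it is built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    build <- switch(
      name,
      truth = function() make_truth(synthetic_config(), seed = 1),
      maps = function() simulate_pair(fx("truth"), 111, 112),
      replicate_map = function() simulate_contact_map(fx("truth"), "normal", 113),
      Mn = function() ice_balance(fx("maps")$normal),
      Mt = function() ice_balance(fx("maps")$tumour),
      ins_n = function() insulation_track(fx("Mn")),
      ins_t = function() insulation_track(fx("Mt")),
      bounds_n = function() call_boundaries(fx("ins_n")),
      bounds_t = function() call_boundaries(fx("ins_t")),
      loops_n = function() call_loops(fx("Mn")),
      loops_t = function() call_loops(fx("Mt")),
      diff_loops = function() differential_loops(fx("loops_t"), fx("loops_n"),
                                                 fx("Mt"), fx("Mn")),
      gene_density = function() {
        g <- fx("truth")$genes
        gene_density_track(gene_table(g$gene, g$chrom, g$start, g$end, g$strand),
                           fx("truth")$spec)
      },
      comp_n = function() call_compartments(fx("Mn"), fx("gene_density")),
      comp_t = function() call_compartments(fx("Mt"), fx("gene_density")),
      switches = function() switch_classification(fx("comp_n"), fx("comp_t")),
      expr = function() simulate_expression(fx("truth"), 3, seed = 7),
      stop("unknown fixture: ", name))
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# tiny genome helpers ---------------------------------------------------------

toy_spec <- function(nbins = 10L, chroms = "chr1", resolution = 1e4) {
  genome_spec(chroms, rep(nbins * resolution, length(chroms)), resolution)
}

# dense symmetric matrix -> contact_matrix on a single-chromosome spec
cm_from_dense <- function(mat, resolution = 1e4, chrom = "chr1") {
  n <- nrow(mat)
  spec <- genome_spec(chrom, n * resolution, resolution)
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  contact_matrix(spec, data.frame(
    chrom1 = chrom, bin1 = idx[, 1] - 1L,
    chrom2 = chrom, bin2 = idx[, 2] - 1L,
    count = mat[idx]))
}

# declare a contact matrix already balanced with unit weights (for fixtures
# whose counts are constructed to be the balanced values)
with_unit_weights <- function(M) {
  M$weights <- rep(1, n_bins(M$spec))
  M$valid <- rep(TRUE, n_bins(M$spec))
  M$balanced <- TRUE
  M
}

# independent dense ICE oracle: loop until the balanced row-sum CV converges
ice_oracle <- function(mat, tol = 1e-10, max_iter = 10000) {
  n <- nrow(mat)
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    bal <- mat * outer(w, w)
    s <- rowSums(bal)
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv) || cv < tol) break
    w <- w / (s / mean(s))
  }
  w / mean(w)
}

# greedy matcher shared by recovery metrics
boundary_recovery <- function(called, planted, tol_bins = 1) {
  m <- match_boundaries(called, planted, tol_bins)
  c(recall = nrow(m$conserved) / nrow(planted),
    precision = nrow(m$conserved) / nrow(called))
}

loop_recovery <- function(called, planted, tol = 2) {
  hit <- vapply(seq_len(nrow(planted)), function(r) {
    any(called$chrom == planted$chrom[r] &
          abs(called$bin1 - planted$bin1[r]) <= tol &
          abs(called$bin2 - planted$bin2[r]) <= tol)
  }, TRUE)
  fp <- vapply(seq_len(nrow(called)), function(r) {
    !any(planted$chrom == called$chrom[r] &
           abs(planted$bin1 - called$bin1[r]) <= tol &
           abs(planted$bin2 - called$bin2[r]) <= tol)
  }, TRUE)
  c(recall = mean(hit), false_rate = mean(fp))
}
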
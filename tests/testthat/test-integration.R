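test_that("gene tables carry strand-aware TSSs and survive a BED round trip", {
  g <- gene_table(c("g1", "g2"), c("chr1", "chr1"), c(150000, 300000),
                  c(250000, 420000), c("+", "-"))
  expect_equal(g$tss, c(150000, 419999))
  spec <- genome_spec("chr1", 5e6, 1e5)
  expect_equal(hicdelta:::tss_bin(g, spec), c(1L, 4L))
  expect_error(gene_table("g", "chr1", 100, 100, "+"), "start")

  path <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(g, path)
  g2 <- read_genes_bed(path)
  expect_equal(g2$tss, g$tss)

  bad <- gene_table("g", "chr1", 6e6, 6.1e6, "+")
  expect_error(hicdelta:::tss_bin(bad, spec), "bounds")
})

test_that("genes are assigned to structural layers without double counting", {
  spec <- genome_spec("chr1", 5e6, 1e5)
  genes <- gene_table(paste0("g", 1:4), "chr1",
                      c(150000, 1200000, 2500000, 4000000),
                      c(250000, 1300000, 2600000, 4100000), rep("+", 4))
  track <- data.frame(chrom = "chr1", bin = 0:49,
                      label = rep(c("A", "B"), 25), stringsAsFactors = FALSE)
  ann <- assign_genes(genes, track, spec, mode = "compartment")
  # TSS bins 1, 12, 25, 40 -> labels alternate A/B from bin 0
  expect_equal(ann$category, c("B", "A", "B", "A"))

  bounds <- data.frame(chrom = "chr1", bin = c(2L, 12L), class = c("enhanced", "weakened"),
                       stringsAsFactors = FALSE)
  annb <- assign_genes(genes, bounds, spec, mode = "boundary", window = 5e5)
  expect_equal(annb$category, c("enhanced", "weakened", NA, NA))
  expect_equal(sum(!is.na(annb$category)), 2) # no gene counted twice

  loops <- data.frame(chrom = "chr1", bin1 = c(1L, 24L), bin2 = c(12L, 40L),
                      class = c("gained", "lost"), stringsAsFactors = FALSE)
  annl <- assign_genes(genes, loops, spec, mode = "loop", radius_bins = 1)
  expect_equal(annl$category, c("gained", "gained", "lost", "lost"))

  dens <- gene_density_track(genes, spec)
  expect_equal(sum(dens), 4)
  expect_equal(dens[2], 1) # g1 TSS bin 1 (0-based) -> position 2
})

test_that("the DEG rule uses strict thresholds in both dimensions", {
  expr <- data.frame(gene = c("GSK3B-like", "edge", "weak-p", "down"),
                     log2FC = c(2.22, 1.0, 1.6, -1.8),
                     padj = c(0.0005, 0.001, 0.06, 0.01))
  out <- deg_filter(expr)
  expect_equal(out$direction, c("up", "none", "none", "down"))
  expect_equal(unname(attr(out, "counts")), c(1, 1, 2))
  expect_error(deg_filter(expr[, 1:2]), "columns")
  expr$padj[1] <- 1.2
  expect_error(deg_filter(expr), "\\[0, 1\\]")
})

test_that("rank-sum comparisons report identical groups as p = 1 and detect shifts", {
  # two groups with identical value sequences (a group against itself): p = 1
  set.seed(64)
  vals <- rnorm(10)
  expr <- data.frame(gene = c(paste0("a", 0:9), paste0("b", 0:9)),
                     log2FC = c(vals, vals))
  ann <- data.frame(gene = expr$gene, category = rep(c("x", "y"), each = 10))
  cmp <- compare_expression_by_category(expr, ann)
  expect_equal(cmp$p, 1)

  # two seeded normal samples shifted by one sd: significant in >= 95/100 runs
  set.seed(99)
  hits <- vapply(1:100, function(i) {
    e <- data.frame(gene = paste0("g", 1:200),
                    log2FC = c(rnorm(100), rnorm(100, 1)))
    a <- data.frame(gene = e$gene, category = rep(c("ctl", "shift"), each = 100))
    compare_expression_by_category(e, a)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  expect_error(compare_expression_by_category(
    expr, data.frame(gene = expr$gene, category = "only"), groups = c("only", "none")),
    "empty group")
})

test_that("per-chromosome DEG fractions among switching genes are ratios of counts", {
  expr <- data.frame(gene = paste0("g", 1:12),
                     log2FC = c(rep(2, 5), rep(0, 7)),
                     padj = c(rep(0.001, 5), rep(0.8, 7)))
  ann <- data.frame(gene = expr$gene,
                    chrom = rep(c("chr1", "chr2"), c(10, 2)),
                    category = c(rep("B-to-A", 10), rep("A-to-B", 2)))
  out <- switch_deg_fraction(expr, ann)
  expect_equal(out$fraction[out$chrom == "chr1" & out$direction == "B-to-A"], 0.5)
  expect_true(is.nan(out$fraction[out$chrom == "chr2" & out$direction == "B-to-A"]))
  expect_equal(out$fraction[out$chrom == "chr2" & out$direction == "A-to-B"], 0)
})

test_that("structure-coupled expression reproduces the planted directions", {
  truth <- fx("truth")
  ex <- fx("expr")
  gi <- truth$genes
  swcat <- paste0(gi$compartment_normal, "-to-", gi$compartment_tumour)
  ann <- data.frame(gene = gi$gene,
                    category = ifelse(swcat %in% c("A-to-B", "B-to-A"), swcat, "stable"))
  cmp <- compare_expression_by_category(ex$expr, ann, groups = c("B-to-A", "A-to-B"))
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$median1[cmp$group1 == "B-to-A"], cmp$median2[cmp$group1 == "B-to-A"])

  # A-compartment genes are denser and more expressed than B-compartment genes
  expect_gt(sum(gi$compartment_normal == "A"), sum(gi$compartment_normal == "B"))
  expect_gt(mean(gi$mu_normal[gi$compartment_normal == "A"]),
            mean(gi$mu_normal[gi$compartment_normal == "B"]))
})
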
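#!/usr/bin/env Rscript
# Stage 6: couple each structural layer (compartment switches, differential
# boundaries, differential loops) to the differential-expression table.

source("analysis/common.R")

message("stage 06: expression integration")
spec <- load_spec()
genes <- read_genes_bed(path_in("genes.bed"))
expr <- utils::read.table(path_in("expression.tsv"), header = TRUE, sep = "\t")
expr <- deg_filter(expr)
message(sprintf("  DEGs: %d up, %d down of %d genes",
                sum(expr$direction == "up"), sum(expr$direction == "down"), nrow(expr)))

## compartment switches vs expression
spec_c <- coarsen_spec(spec, as.integer(1e5 / spec$resolution))
switches <- utils::read.table(path_in("compartment_switches.tsv"), header = TRUE, sep = "\t")
ann_sw <- assign_genes(genes, switches, spec_c, mode = "compartment")
cmp_sw <- compare_expression_by_category(expr, ann_sw)
write_tsv(cmp_sw, "expression_by_switch.tsv")
frac <- switch_deg_fraction(expr, ann_sw)
write_tsv(frac, "switch_deg_fraction.tsv")

## differential boundaries vs expression
db <- utils::read.table(path_in("differential_boundaries.tsv"), header = TRUE, sep = "\t")
ann_b <- assign_genes(genes, db[db$class %in% c("enhanced", "weakened"), ],
                      spec, mode = "boundary", window = 5e5)
n_enh_genes <- sum(ann_b$category == "enhanced", na.rm = TRUE)
n_wk_genes <- sum(ann_b$category == "weakened", na.rm = TRUE)
cmp_b <- if (n_enh_genes > 0 && n_wk_genes > 0) {
  compare_expression_by_category(expr, ann_b, groups = c("enhanced", "weakened"))
} else NULL
if (!is.null(cmp_b)) write_tsv(cmp_b, "expression_by_boundary_class.tsv")

## differential loops vs expression
dl <- utils::read.table(path_in("differential_loops.tsv"), header = TRUE, sep = "\t")
ann_l <- assign_genes(genes, dl[dl$class %in% c("gained", "lost"), ],
                      spec, mode = "loop", radius_bins = 2)
cmp_l <- if (sum(ann_l$category == "gained", na.rm = TRUE) > 0 &&
             sum(ann_l$category == "lost", na.rm = TRUE) > 0) {
  compare_expression_by_category(expr, ann_l, groups = c("gained", "lost"))
} else NULL
if (!is.null(cmp_l)) write_tsv(cmp_l, "expression_by_loop_class.tsv")

sw_row <- cmp_sw[cmp_sw$group1 == "B-to-A" & cmp_sw$group2 == "A-to-B" |
                   cmp_sw$group1 == "A-to-B" & cmp_sw$group2 == "B-to-A", ][1, ]
write_summary(list(
  seed = seed,
  n_deg_up = sum(expr$direction == "up"),
  n_deg_down = sum(expr$direction == "down"),
  switch_wilcox_p = sw_row$p,
  median_log2fc_b_to_a = if (sw_row$group1 == "B-to-A") sw_row$median1 else sw_row$median2,
  median_log2fc_a_to_b = if (sw_row$group1 == "B-to-A") sw_row$median2 else sw_row$median1,
  n_enhanced_boundary_genes = n_enh_genes,
  n_weakened_boundary_genes = n_wk_genes,
  boundary_wilcox_p = if (!is.null(cmp_b)) cmp_b$p else NA,
  n_gained_loop_genes = sum(ann_l$category == "gained", na.rm = TRUE),
  n_lost_loop_genes = sum(ann_l$category == "lost", na.rm = TRUE),
  loop_wilcox_p = if (!is.null(cmp_l)) cmp_l$p else NA), "06_integration_summary.json")
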
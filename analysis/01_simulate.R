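#!/usr/bin/env Rscript
# Stage 1: plant the ground truth and simulate the paired tumour/normal Hi-C
# maps (plus one normal replicate for reproducibility checks) and the coupled
# expression tables. Everything later stages need is written as plain text.

source("analysis/common.R")

message("stage 01: simulate (seed ", seed, ")")
truth <- the_truth()
print(truth)

write_chrom_sizes(truth$spec, path_in("genome.chrom.sizes"))

maps <- simulate_pair(truth, sub_seed(11), sub_seed(12))
replicate_map <- simulate_contact_map(truth, "normal", sub_seed(13))
write_contacts(maps$normal, path_in("normal.contacts.tsv"))
write_contacts(maps$tumour, path_in("tumour.contacts.tsv"))
write_contacts(replicate_map, path_in("normal_rep2.contacts.tsv"))

ex <- simulate_expression(truth, n_replicates = 3, seed = sub_seed(19))
write_genes_bed(ex$genes, path_in("genes.bed"))
write_tsv(ex$expr, "expression.tsv")

# planted truth, for the recovery stages
write_tsv(truth$boundaries, "truth_boundaries.tsv")
write_tsv(truth$loops, "truth_loops.tsv")
write_tsv(truth$segments, "truth_segments.tsv")
write_tsv(data.frame(global_bin = truth$switched_bins), "truth_switched_bins.tsv")
write_tsv(truth$genes, "truth_genes.tsv")

write_summary(list(
  seed = seed,
  n_bins = n_bins(truth$spec),
  resolution = truth$spec$resolution,
  total_counts_normal = total_mass(maps$normal),
  total_counts_tumour = total_mass(maps$tumour),
  n_planted_boundaries_normal = sum(truth$boundaries$in_normal),
  n_planted_boundaries_tumour = sum(truth$boundaries$in_tumour),
  n_planted_loops_normal = sum(truth$loops$in_normal),
  n_planted_loops_tumour = sum(truth$loops$in_tumour),
  n_switched_bins = length(truth$switched_bins),
  n_genes = nrow(truth$genes)), "01_simulate_summary.json")
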
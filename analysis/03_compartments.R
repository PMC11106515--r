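#!/usr/bin/env Rscript
# Stage 3: A/B compartments at 100 kb for both samples, orientation by gene
# density, switch classification, and recovery against the planted truth.

source("analysis/common.R")

message("stage 03: compartments (100 kb)")
spec <- load_spec()
factor_100kb <- as.integer(1e5 / spec$resolution)
spec_c <- coarsen_spec(spec, factor_100kb)

genes <- read_genes_bed(path_in("genes.bed"))
gd <- gene_density_track(genes, spec_c)

tracks <- list()
for (sample in c("normal", "tumour")) {
  raw <- load_contact_matrix(path_in(paste0(sample, ".contacts.tsv")), spec)
  M <- ice_balance(coarsen(raw, factor_100kb))
  tracks[[sample]] <- call_compartments(M, gd)
  write_bedgraph(spec_c, tracks[[sample]]$chrom, tracks[[sample]]$bin,
                 tracks[[sample]]$pc1, paste0(sample, ".pc1.bedgraph"))
}

sw <- switch_classification(tracks$normal, tracks$tumour)
write_tsv(sw$per_bin, "compartment_switches.tsv")
print(sw)

# recovery vs planted truth (majority sign per 100 kb bin)
truth <- the_truth()
coarse_labels <- function(v) {
  sb <- spec_bins(truth$spec)
  out <- NULL
  for (ch in truth$spec$chroms) {
    x <- v[sb$chrom == ch]
    out <- c(out, tapply(x, (seq_along(x) - 1L) %/% factor_100kb, sum))
  }
  ifelse(out > 0, "A", ifelse(out < 0, "B", "mixed"))
}
acc <- vapply(c(normal = "v_normal", tumour = "v_tumour"), function(f) {
  lab <- coarse_labels(truth[[f]])
  cc <- tracks[[if (f == "v_normal") "normal" else "tumour"]]
  ok <- cc$label != "unassigned" & lab != "mixed"
  mean(cc$label[ok] == lab[ok])
}, 0)

write_summary(list(
  seed = seed,
  percent = as.list(sw$percent),
  switch_fraction = sw$switch_fraction,
  planted_switch_fraction = length(truth$switched_bins) / n_bins(truth$spec),
  label_accuracy_normal = unname(acc["normal"]),
  label_accuracy_tumour = unname(acc["tumour"])), "03_compartments_summary.json")
message(sprintf("  switch fraction %.3f (planted %.2f); label accuracy %.3f / %.3f",
                sw$switch_fraction, 0.2, acc["normal"], acc["tumour"]))
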
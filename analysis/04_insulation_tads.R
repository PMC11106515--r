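#!/usr/bin/env Rscript
# Stage 4: diamond insulation at 10 kb, boundary calling, TAD statistics,
# cross-sample boundary matching, the high-confidence differential rule
# (|delta log2IS| > 0.4), and boundary-centred pileups.

source("analysis/common.R")

message("stage 04: insulation and TADs")
spec <- load_spec()
Mn <- load_balanced("normal")
Mt <- load_balanced("tumour")

ins_n <- insulation_track(Mn)
ins_t <- insulation_track(Mt)
write_bedgraph(spec, ins_n$chrom, ins_n$bin, ins_n$log2_is, "normal.log2is.bedgraph")
write_bedgraph(spec, ins_t$chrom, ins_t$bin, ins_t$log2_is, "tumour.log2is.bedgraph")

bounds_n <- call_boundaries(ins_n)
bounds_t <- call_boundaries(ins_t)
write_tsv(bounds_n, "normal.boundaries.tsv")
write_tsv(bounds_t, "tumour.boundaries.tsv")

td_n <- tads_from_boundaries(bounds_n, spec)
td_t <- tads_from_boundaries(bounds_t, spec)
write_tsv(rbind(cbind(sample = "normal", td_n$tads), cbind(sample = "tumour", td_t$tads)),
          "tads.tsv")

m <- match_boundaries(bounds_n, bounds_t, tol_bins = 1)
db <- differential_boundaries(ins_n, ins_t)
write_tsv(db, "differential_boundaries.tsv")

enh <- db[db$class == "enhanced", c("chrom", "bin")]
wk <- db[db$class == "weakened", c("chrom", "bin")]
pp_e <- boundary_pileup(ins_n, ins_t, enh, flank_bins = 30)
write_tsv(cbind(set = "enhanced", pp_e), "boundary_pileup_enhanced.tsv")
if (nrow(wk)) {
  write_tsv(cbind(set = "weakened", boundary_pileup(ins_n, ins_t, wk, flank_bins = 30)),
            "boundary_pileup_weakened.tsv")
}

truth <- the_truth()
rec <- function(called, flag) {
  planted <- truth$boundaries[truth$boundaries[[flag]], c("chrom", "bin")]
  mm <- match_boundaries(called, planted, tol_bins = 1)
  c(recall = nrow(mm$conserved) / nrow(planted),
    precision = nrow(mm$conserved) / nrow(called))
}
rn <- rec(bounds_n, "in_normal")
rt <- rec(bounds_t, "in_tumour")

write_summary(list(
  seed = seed,
  n_boundaries_normal = nrow(bounds_n),
  n_boundaries_tumour = nrow(bounds_t),
  n_conserved = nrow(m$conserved),
  tad_count_normal = td_n$n_tads,
  tad_count_tumour = td_t$n_tads,
  mean_boundary_spacing_kb_normal = td_n$mean_boundary_spacing / 1e3,
  mean_boundary_spacing_kb_tumour = td_t$mean_boundary_spacing / 1e3,
  n_enhanced = sum(db$class == "enhanced"),
  n_weakened = sum(db$class == "weakened"),
  recall_normal = unname(rn["recall"]), precision_normal = unname(rn["precision"]),
  recall_tumour = unname(rt["recall"]), precision_tumour = unname(rt["precision"]),
  pileup_centre_normal = pp_e$normal[pp_e$offset_bins == 0],
  pileup_centre_tumour = pp_e$tumour[pp_e$offset_bins == 0]),
  "04_insulation_summary.json")
message(sprintf("  %d/%d boundaries (normal/tumour), spacing %.0f/%.0f kb, %d enhanced / %d weakened",
                nrow(bounds_n), nrow(bounds_t), td_n$mean_boundary_spacing / 1e3,
                td_t$mean_boundary_spacing / 1e3,
                sum(db$class == "enhanced"), sum(db$class == "weakened")))
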
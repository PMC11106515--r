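#!/usr/bin/env Rscript
# Stage 2: ICE balancing and map-level QC - cis/trans composition, distance
# decay and interaction decay exponents, reproducibility (SCC), the tumour vs
# normal log2-ratio map at 1 Mb, and the inter-chromosomal O/E blocks.

source("analysis/common.R")

message("stage 02: balancing and map statistics")
spec <- load_spec()
raw_n <- load_contact_matrix(path_in("normal.contacts.tsv"), spec)
raw_t <- load_contact_matrix(path_in("tumour.contacts.tsv"), spec)
raw_r <- load_contact_matrix(path_in("normal_rep2.contacts.tsv"), spec)

Mn <- ice_balance(raw_n)
Mt <- ice_balance(raw_t)
message(sprintf("  ICE: normal cv %.2g (%d it), tumour cv %.2g (%d it)",
                attr(Mn, "ice_cv"), attr(Mn, "ice_iterations"),
                attr(Mt, "ice_cv"), attr(Mt, "ice_iterations")))

ct_n <- cis_trans_fraction(raw_n)
ct_t <- cis_trans_fraction(raw_t)
write_tsv(rbind(cbind(sample = "normal", ct_n$per_chrom),
                cbind(sample = "tumour", ct_t$per_chrom)), "cis_trans.tsv")

exp_n <- compute_expected(Mn, "per-chrom")
exp_t <- compute_expected(Mt, "per-chrom")
write_tsv(rbind(cbind(sample = "normal", exp_n), cbind(sample = "tumour", exp_t)),
          "expected_decay.tsv")
ide <- do.call(rbind, lapply(spec$chroms, function(ch) data.frame(
  chrom = ch,
  ide_normal = as.numeric(fit_decay_exponent(exp_n, 5e4, 2e6, chrom = ch)),
  ide_tumour = as.numeric(fit_decay_exponent(exp_t, 5e4, 2e6, chrom = ch)))))
write_tsv(ide, "decay_exponents.tsv")

s_rep <- scc(raw_n, raw_r)
s_cross <- scc(raw_n, raw_t)
write_tsv(rbind(cbind(pair = "normal_vs_replicate", s_rep$per_chrom[1:3]),
                cbind(pair = "normal_vs_tumour", s_cross$per_chrom[1:3])),
          "scc.tsv")

coarse_n <- coarsen(raw_n, 100L) # 1 Mb comparison maps
coarse_t <- coarsen(raw_t, 100L)
write_tsv(log2_ratio_map(coarse_t, coarse_n), "log2_ratio_1mb.tsv")

oe <- interchrom_oe(coarsen(raw_t, 100L), top_k = 1000L)
write_tsv(as.data.frame(as.table(oe$oe)), "interchrom_oe_tumour.tsv")
write_tsv(oe$top_pixels, "top_trans_pixels_tumour.tsv")

write_summary(list(
  seed = seed,
  cis_fraction_normal = ct_n$cis_fraction,
  cis_fraction_tumour = ct_t$cis_fraction,
  ice_rowsum_cv_normal = balanced_rowsum_cv(Mn),
  ide_pooled_normal = as.numeric(fit_decay_exponent(compute_expected(Mn, "pooled"), 5e4, 2e6)),
  ide_pooled_tumour = as.numeric(fit_decay_exponent(compute_expected(Mt, "pooled"), 5e4, 2e6)),
  scc_replicates = s_rep$scc,
  scc_tumour_vs_normal = s_cross$scc), "02_balance_qc_summary.json")
message(sprintf("  cis fraction: tumour %.3f > normal %.3f; SCC rep %.3f > cross %.3f",
                ct_t$cis_fraction, ct_n$cis_fraction, s_rep$scc, s_cross$scc))
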
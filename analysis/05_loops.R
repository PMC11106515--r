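#!/usr/bin/env Rscript
# Stage 5: donut-filter loop calling at 10 kb in both samples, gained/lost
# classification by the observed/expected ratio, and aggregate peak analysis.

source("analysis/common.R")

message("stage 05: chromatin loops")
spec <- load_spec()
Mn <- load_balanced("normal")
Mt <- load_balanced("tumour")

loops_n <- call_loops(Mn)
loops_t <- call_loops(Mt)

as_bedpe <- function(calls) {
  res <- spec$resolution
  data.frame(chrom1 = calls$chrom, start1 = calls$bin1 * res, end1 = (calls$bin1 + 1) * res,
             chrom2 = calls$chrom, start2 = calls$bin2 * res, end2 = (calls$bin2 + 1) * res,
             name = sprintf("loop_%03d", seq_len(nrow(calls))),
             score = calls$observed,
             calls[, c("lambda_donut", "lambda_horizontal", "lambda_vertical",
                       "lambda_lower_left", "q_donut", "cluster_size")])
}
write_tsv(as_bedpe(loops_n), "normal.loops.bedpe")
write_tsv(as_bedpe(loops_t), "tumour.loops.bedpe")

dl <- differential_loops(loops_t, loops_n, Mt, Mn)
write_tsv(dl, "differential_loops.tsv")

ap_t <- apa(Mt, loops_t)
ap_n <- apa(Mn, loops_n)
ap_gained_t <- apa(Mt, dl[dl$class == "gained", ])
ap_gained_n <- apa(Mn, dl[dl$class == "gained", ]) # same pixels in the normal map
write_tsv(as.data.frame(ap_gained_t$stack), "apa_stack_gained_tumour.tsv")
write_tsv(as.data.frame(ap_gained_n$stack), "apa_stack_gained_normal.tsv")

truth <- the_truth()
rec <- function(called, flag, tol = 2) {
  planted <- truth$loops[truth$loops[[flag]], ]
  hit <- vapply(seq_len(nrow(planted)), function(r) {
    any(called$chrom == planted$chrom[r] & abs(called$bin1 - planted$bin1[r]) <= tol &
          abs(called$bin2 - planted$bin2[r]) <= tol)
  }, TRUE)
  mean(hit)
}

write_summary(list(
  seed = seed,
  n_loops_normal = nrow(loops_n),
  n_loops_tumour = nrow(loops_t),
  n_gained = sum(dl$class == "gained"),
  n_lost = sum(dl$class == "lost"),
  recall_normal = rec(loops_n, "in_normal"),
  recall_tumour = rec(loops_t, "in_tumour"),
  apa_score_normal = ap_n$score,
  apa_score_tumour = ap_t$score,
  apa_gained_in_tumour = ap_gained_t$score,
  apa_gained_in_normal = ap_gained_n$score), "05_loops_summary.json")
message(sprintf("  %d/%d loops (normal/tumour); %d gained, %d lost; APA gained %.2f (tumour) vs %.2f (normal)",
                nrow(loops_n), nrow(loops_t), sum(dl$class == "gained"),
                sum(dl$class == "lost"), ap_gained_t$score, ap_gained_n$score))
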
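# Shared plumbing for the numbered analysis drivers. Each driver is run from
# the repository root as e.g.
#   Rscript analysis/01_simulate.R [seed]
# and reads/writes under results/<seed>/ so stages can be re-run alone.

suppressPackageStartupMessages({
  library(hicdelta)
  library(jsonlite)
})

seed <- {
  a <- commandArgs(trailingOnly = TRUE)
  if (length(a) >= 1) as.integer(a[[1]]) else 1L
}
run_dir <- file.path("results", sprintf("seed%03d", seed))
dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)

path_in <- function(...) file.path(run_dir, ...)

write_tsv <- function(x, name) {
  utils::write.table(x, path_in(name), sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path_in(name))
}

write_summary <- function(x, name) {
  jsonlite::write_json(x, path_in(name), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("  wrote ", path_in(name))
}

# deterministic per-stage sub-seeds, all well below 2^31
sub_seed <- function(k) seed * 1000L + k

the_truth <- function() make_truth(synthetic_config(), seed = seed)

load_spec <- function() read_chrom_sizes(path_in("genome.chrom.sizes"), 1e4)

load_balanced <- function(sample) {
  M <- load_contact_matrix(path_in(paste0(sample, ".contacts.tsv")), load_spec())
  ice_balance(M)
}

write_bedgraph <- function(spec, chrom, bin, value, name) {
  ok <- is.finite(value)
  utils::write.table(
    data.frame(chrom = chrom[ok], start = bin[ok] * spec$resolution,
               end = (bin[ok] + 1) * spec$resolution, value = value[ok]),
    path_in(name), sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  message("  wrote ", path_in(name))
}
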
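#' Gene table utilities
#'
#' A gene table carries `gene`, `chrom`, `start`, `end`, `strand`; the TSS is
#' `start` on the + strand and `end - 1` on the - strand (0-based half-open
#' coordinates throughout).
#'
#' @param path A 6-column BED file (`chrom start end name score strand`).
#' @return data.frame `gene`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_genes_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end", "gene", "score", "strand"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character", "character"))
  gene_table(tab$gene, tab$chrom, tab$start, tab$end, tab$strand)
}

#' @rdname read_genes_bed
#' @param gene,chrom,start,end,strand Vectors defining the genes directly.
#' @export
gene_table <- function(gene, chrom, start, end, strand) {
  if (any(start >= end)) stop("gene start must be < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(gene = as.character(gene), chrom = as.character(chrom),
             start = as.numeric(start), end = as.numeric(end),
             strand = as.character(strand),
             tss = ifelse(strand == "+", start, end - 1),
             stringsAsFactors = FALSE)
}

#' @rdname read_genes_bed
#' @param genes A gene table.
#' @export
write_genes_bed <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "gene")] |>
                       cbind(score = 0, strand = genes$strand),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# TSS bin (0-based) of each gene on a spec's grid; errors on out-of-bounds.
tss_bin <- function(genes, spec) {
  idx <- match(genes$chrom, spec$chroms)
  if (anyNA(idx)) stop("gene on unknown chromosome")
  if (any(genes$tss < 0 | genes$tss >= spec$lengths[idx]))
    stop("gene TSS beyond chromosome bounds")
  as.integer(genes$tss %/% spec$resolution)
}

#' Per-bin gene (TSS) density track
#'
#' @param genes A [gene_table()].
#' @param spec A [genome_spec()].
#' @return Numeric vector of TSS counts, one per bin in [spec_bins()] order.
#' @export
gene_density_track <- function(genes, spec) {
  g <- global_bin(spec, genes$chrom, tss_bin(genes, spec))
  out <- numeric(n_bins(spec))
  tab <- table(g)
  out[as.integer(names(tab))] <- as.numeric(tab)
  out
}

#' Annotate genes with a structural layer
#'
#' Three modes. `compartment`: each gene gets the category of its TSS bin from
#' a per-bin category table (a [call_compartments()] track or a
#' [switch_classification()] `per_bin` table). `boundary`: a gene is
#' associated when its body overlaps `[boundary - window/2, boundary +
#' window/2)`; ties go to the nearest boundary, so no gene is double-counted.
#' `loop`: a gene is associated when its TSS bin lies within `radius_bins` of
#' either anchor of a loop; the gene is annotated with the loop's class column
#' when one is present (e.g. from [differential_loops()]).
#'
#' @param genes A [gene_table()].
#' @param annotation The structural table for the chosen mode (see above).
#' @param spec The [genome_spec()] of the structural layer.
#' @param mode `"compartment"`, `"boundary"` or `"loop"`.
#' @param window Boundary association window in bp (total width).
#' @param radius_bins Loop anchor tolerance in bins.
#' @return The gene table with a `category` column (`NA` when unassociated)
#'   and, for boundary mode, `boundary_bin`.
#' @export
assign_genes <- function(genes, annotation, spec,
                         mode = c("compartment", "boundary", "loop"),
                         window = 5e5, radius_bins = 2L) {
  mode <- match.arg(mode)
  out <- genes
  if (mode == "compartment") {
    bins <- tss_bin(genes, spec)
    col <- if ("category" %in% names(annotation)) "category" else "label"
    key <- paste(annotation$chrom, annotation$bin)
    hit <- match(paste(genes$chrom, bins), key)
    out$category <- annotation[[col]][hit]
  } else if (mode == "boundary") {
    res <- spec$resolution
    out$category <- NA_character_
    out$boundary_bin <- NA_integer_
    col <- if ("class" %in% names(annotation)) "class" else NULL
    for (r in seq_len(nrow(genes))) {
      cand <- annotation[annotation$chrom == genes$chrom[r], , drop = FALSE]
      if (!nrow(cand)) next
      pos <- cand$bin * res
      ov <- genes$start[r] < pos + window / 2 & genes$end[r] > pos - window / 2
      if (!any(ov)) next
      ctr <- (genes$start[r] + genes$end[r]) / 2
      best <- which(ov)[which.min(abs(pos[ov] - ctr))]
      out$boundary_bin[r] <- cand$bin[best]
      out$category[r] <- if (is.null(col)) "boundary" else cand[[col]][best]
    }
  } else {
    bins <- tss_bin(genes, spec)
    out$category <- NA_character_
    col <- if ("class" %in% names(annotation)) "class" else NULL
    for (r in seq_len(nrow(genes))) {
      cand <- annotation[annotation$chrom == genes$chrom[r], , drop = FALSE]
      if (!nrow(cand)) next
      d <- pmin(abs(cand$bin1 - bins[r]), abs(cand$bin2 - bins[r]))
      hit <- d <= radius_bins
      if (!any(hit)) next
      best <- which(hit)[which.min(d[hit])]
      out$category[r] <- if (is.null(col)) "loop" else cand[[col]][best]
    }
  }
  out
}

#' Flag differentially expressed genes
#'
#' DEG rule: `|log2FC| > 1` and adjusted p < .05 (strict inequalities);
#' direction by the sign of the fold change.
#'
#' @param expr data.frame with `gene`, `log2FC`, `padj` (and optionally
#'   `baseMean`).
#' @param lfc_threshold,p_threshold Rule thresholds.
#' @return The table with logical `deg` and `direction`
#'   (`"up"`/`"down"`/`"none"`); attribute `counts` = named vector
#'   (up, down, none).
#' @export
deg_filter <- function(expr, lfc_threshold = 1, p_threshold = 0.05) {
  need <- c("gene", "log2FC", "padj")
  if (!all(need %in% names(expr)))
    stop("expression table needs columns ", paste(need, collapse = ", "))
  p <- expr$padj
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("padj outside [0, 1]")
  deg <- !is.na(expr$log2FC) & !is.na(p) &
    abs(expr$log2FC) > lfc_threshold & p < p_threshold
  dir <- rep("none", nrow(expr))
  dir[deg & expr$log2FC > 0] <- "up"
  dir[deg & expr$log2FC < 0] <- "down"
  out <- expr
  out$deg <- deg
  out$direction <- dir
  attr(out, "counts") <- c(up = sum(dir == "up"), down = sum(dir == "down"),
                           none = sum(dir == "none"))
  out
}

#' Compare expression between structural categories
#'
#' Two-sided Wilcoxon rank-sum tests on `log2FC` between every pair of
#' categories, with BH correction across the pairs.
#'
#' @param expr Expression table with `gene`, `log2FC`.
#' @param annotation Gene table with a `category` column ([assign_genes()]).
#' @param groups Categories to compare (default: all non-`NA` categories).
#' @return data.frame `group1`, `group2`, `n1`, `n2`, `median1`, `median2`,
#'   `p`, `q`.
#' @export
compare_expression_by_category <- function(expr, annotation, groups = NULL) {
  merged <- merge(expr, annotation[, c("gene", "category")], by = "gene")
  merged <- merged[!is.na(merged$category) & !is.na(merged$log2FC), ]
  if (is.null(groups)) groups <- sort(unique(merged$category))
  if (length(groups) < 2L) stop("need at least two non-empty groups")
  sizes <- vapply(groups, function(g) sum(merged$category == g), 0)
  if (any(sizes == 0)) stop("empty group: ", paste(groups[sizes == 0], collapse = ", "))
  pairs <- utils::combn(groups, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    x <- merged$log2FC[merged$category == g1]
    y <- merged$log2FC[merged$category == g2]
    p <- if (identical(x, y)) 1 else
      suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
    data.frame(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
               median1 = stats::median(x), median2 = stats::median(y),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' DEG fraction among compartment-switching genes
#'
#' For each chromosome and switch direction, the number of DEGs among genes in
#' switching bins over the number of switching genes (`NaN` when a chromosome
#' has none).
#'
#' @param expr A [deg_filter()]ed expression table.
#' @param switch_annotation Gene table with switch `category`
#'   ([assign_genes()] on a [switch_classification()] `per_bin` table).
#' @param directions Switch categories to tabulate.
#' @return data.frame `chrom`, `direction`, `n_genes`, `n_deg`, `fraction`.
#' @export
switch_deg_fraction <- function(expr, switch_annotation,
                                directions = c("A-to-B", "B-to-A")) {
  if (!"deg" %in% names(expr)) expr <- deg_filter(expr)
  merged <- merge(expr, switch_annotation[, c("gene", "chrom", "category")], by = "gene")
  chroms <- unique(switch_annotation$chrom)
  grid <- expand.grid(chrom = chroms, direction = directions,
                      stringsAsFactors = FALSE)
  grid$n_genes <- mapply(function(ch, d) {
    sum(merged$chrom == ch & merged$category == d, na.rm = TRUE)
  }, grid$chrom, grid$direction)
  grid$n_deg <- mapply(function(ch, d) {
    sum(merged$chrom == ch & merged$category == d & merged$deg, na.rm = TRUE)
  }, grid$chrom, grid$direction)
  grid$fraction <- ifelse(grid$n_genes > 0, grid$n_deg / grid$n_genes, NaN)
  grid
}
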
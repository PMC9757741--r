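# Direct-target calling: genes differentially expressed in the TF mutant
# whose associated promoter carries a ChIP peak, plus the headline summary
# fractions.

#' Percentage to one decimal place
#'
#' The reporting convention used throughout the summaries: truncation to one
#' decimal (63.48% prints as 63.4), which reproduces the source convention
#' for every worked ratio (193/304 -> 63.4, 284/782 -> 36.3, 171/284 -> 60.2).
#' `0/N` is 0.0 and `N/0` is `NA`.
#'
#' @param numerator,denominator Counts (vectorized).
#' @return Numeric percentage(s), one decimal place.
#' @export
fraction_percent <- function(numerator, denominator) {
  out <- floor(1000 * numerator / denominator + 1e-9) / 10
  out[rep_len(denominator == 0, length(out))] <- NA_real_
  out
}

#' Label differential-expression records
#'
#' `up` iff LFC > 0 and adjusted p < `padj_cut`; `down` iff LFC < 0 and
#' adjusted p < `padj_cut`; otherwise `ns` (thresholds default to the
#' mutant-vs-wild-type convention p.adj < 0.001).
#'
#' @param de data.frame with columns `gene_id`, `lfc`, `padj`.
#' @param padj_cut Adjusted-p threshold (default 0.001).
#' @return `de` with a `direction` column; errors on duplicated gene ids.
#' @export
de_directions <- function(de, padj_cut = 0.001) {
  need <- c("gene_id", "lfc", "padj")
  if (!all(need %in% names(de))) {
    stop("de_directions: need columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(de$gene_id)) stop("de_directions: duplicate gene ids in DE table")
  de$direction <- ifelse(de$padj < padj_cut & de$lfc > 0, "up",
                         ifelse(de$padj < padj_cut & de$lfc < 0, "down", "ns"))
  de
}

#' Call direct targets from DE results, ChIP peaks, and promoter calls
#'
#' A gene is a direct target iff it is significantly down-regulated in the
#' mutant (default mode) and at least one ChIP peak overlaps a promoter
#' linked to the gene. `mode = "misregulated"` additionally admits
#' up-regulated genes (the two published definitions are surfaced as this
#' flag rather than silently merged).
#'
#' @param de DE data.frame (`gene_id`, `lfc`, `padj`); duplicated ids error.
#' @param chip_peaks `GRanges` of ChIP peaks.
#' @param promoters Promoter-call data.frame (after [flag_coopted()] if
#'   co-option summaries are wanted).
#' @param mode `"down_only"` (default) or `"misregulated"`.
#' @param padj_cut Passed to [de_directions()].
#' @return data.frame per DE gene: `gene_id`, `direction`, `bound`
#'   (peak on a linked promoter), `is_direct_target`,
#'   `has_coopted_promoter`.
#' @export
call_direct_targets <- function(de, chip_peaks, promoters,
                                mode = c("down_only", "misregulated"),
                                padj_cut = 0.001) {
  mode <- match.arg(mode)
  de <- de_directions(de, padj_cut)
  bound_genes <- character(0)
  coopted_genes <- character(0)
  if (nrow(promoters)) {
    pr <- GenomicRanges::GRanges(promoters$chrom,
                                 IRanges::IRanges(promoters$start, promoters$end))
    has_peak <- GenomicRanges::countOverlaps(pr, chip_peaks, ignore.strand = TRUE) > 0L
    bound_genes <- unique(promoters$gene_id[has_peak])
    if (!is.null(promoters$is_coopted)) {
      coopted_genes <- unique(promoters$gene_id[promoters$is_coopted])
    }
  }
  admitted <- if (mode == "down_only") "down" else c("down", "up")
  data.frame(
    gene_id = de$gene_id,
    direction = de$direction,
    bound = de$gene_id %in% bound_genes,
    is_direct_target = de$direction %in% admitted & de$gene_id %in% bound_genes,
    has_coopted_promoter = de$gene_id %in% coopted_genes,
    stringsAsFactors = FALSE)
}

#' Headline summary fractions
#'
#' Reports, with percentages rounded to one decimal:
#' direct targets regulated by a co-opted promoter; germline-specific
#' promoters containing an m1m2 pair; and germline-specific co-opted
#' promoters that are the only promoter of their gene.
#'
#' @param calls Output of [call_direct_targets()].
#' @param promoters Promoter-call data.frame (after [flag_coopted()]).
#' @return data.frame with columns `metric`, `count`, `total`, `percent`.
#' @export
summarize_fractions <- function(calls, promoters) {
  if (!nrow(calls)) stop("summarize_fractions: empty call list")
  dt <- calls[calls$is_direct_target, ]
  gs <- promoters[promoters$is_germline_specific, , drop = FALSE]
  gs_sites <- unique(gs[, c("site_id", "is_coopted")])
  gsc <- gs[gs$is_coopted, , drop = FALSE]
  promoters_per_gene <- table(promoters$gene_id)
  only <- sum(promoters_per_gene[gsc$gene_id] == 1L)
  df <- data.frame(
    metric = c("direct_targets_with_coopted_promoter",
               "germline_specific_promoters_with_pair",
               "coopted_promoters_sole_promoter"),
    count = c(sum(dt$has_coopted_promoter), sum(gs_sites$is_coopted), only),
    total = c(nrow(dt), nrow(gs_sites), nrow(gsc)),
    stringsAsFactors = FALSE)
  df$percent <- fraction_percent(df$count, df$total)
  df
}

#' Fraction of promoters overlapped by ChIP peaks
#'
#' @param peaks `GRanges` of peaks.
#' @param promoters `GRanges` of promoter intervals (deduplicated sites; see
#'   [promoter_ranges()]); must be nonempty.
#' @return Fraction in `[0, 1]`.
#' @export
peak_promoter_overlap_fraction <- function(peaks, promoters) {
  if (!length(promoters)) stop("peak_promoter_overlap_fraction: empty promoter set")
  count_overlapping(promoters, peaks) / length(promoters)
}

#' Down- vs up-regulation skew among bound genes
#'
#' Standard hypergeometric (Fisher's exact) test of association between
#' direction (down vs up) and promoter binding, reported as a summary
#' statistic for the direct-target table.
#'
#' @param calls Output of [call_direct_targets()].
#' @return `htest` from [stats::fisher.test()].
#' @export
direction_bound_fisher <- function(calls) {
  de <- calls[calls$direction %in% c("down", "up"), ]
  tab <- table(factor(de$direction, c("down", "up")),
               factor(de$bound, c(TRUE, FALSE)))
  fisher.test(tab)
}
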
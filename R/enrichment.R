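# Permutation test for repeat enrichment at promoters: chromosome-preserving,
# length-preserving interval shuffles that avoid an exclusion set (gene
# bodies), shuffleBed-style, with an add-one empirical p-value.

# Sorted-interval index for fast any-overlap tests without GRanges overhead:
# per chromosome, exclusion starts sorted ascending and the running maximum
# of the matching ends. A candidate [s, e] overlaps some indexed interval iff
# at least one indexed start is <= e (k = findInterval(e, starts)) and the
# largest end among those k intervals is >= s.
interval_index <- function(chr, s, e, chrom_names) {
  idx <- lapply(chrom_names, function(ch) {
    sel <- chr == ch
    if (!any(sel)) return(NULL)
    o <- order(s[sel])
    list(starts = s[sel][o], maxend = cummax(e[sel][o]))
  })
  names(idx) <- chrom_names
  idx
}

index_any_overlap <- function(chr, s, e, idx) {
  hit <- logical(length(s))
  for (ch in unique(chr)) {
    ix <- idx[[ch]]
    if (is.null(ix)) next
    sel <- which(chr == ch)
    k <- findInterval(e[sel], ix$starts)
    hit[sel] <- k >= 1L & ix$maxend[pmax(k, 1L)] >= s[sel]
  }
  hit
}

# core rejection sampler over plain vectors; returns start positions
shuffle_starts <- function(chr, w, maxstart, excl_idx, max_attempts) {
  starts <- integer(length(chr))
  pending <- seq_along(chr)
  attempts <- 0L
  while (length(pending)) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("shuffle_intervals: no legal placement after ", max_attempts,
           " attempts on chromosome(s): ",
           paste(unique(chr[pending]), collapse = ", "))
    }
    draw <- 1L + as.integer(floor(runif(length(pending)) * maxstart[pending]))
    bad <- index_any_overlap(chr[pending], draw, draw + w[pending] - 1L, excl_idx)
    starts[pending[!bad]] <- draw[!bad]
    pending <- pending[bad]
  }
  starts
}

#' Shuffle intervals on their chromosomes, avoiding an exclusion set
#'
#' Each interval is re-placed uniformly at random on its original chromosome
#' among start positions where it does not intersect any excluded interval,
#' by rejection sampling (uniform draw over the chromosome, redraw on
#' collision). Lengths and chromosome assignment are preserved; shuffled
#' intervals may overlap one another (only the exclusion set is forbidden).
#'
#' @param intervals `GRanges` to shuffle.
#' @param sizes A [chrom_sizes()] vector.
#' @param excluded `GRanges` exclusion set (e.g. gene bodies); may be empty.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @param max_attempts Rejection-sampling cap per interval (default 10000);
#'   exceeding it raises an error naming the chromosome.
#' @return Shuffled `GRanges` (strand cleared), parallel to `intervals`.
#' @export
shuffle_intervals <- function(intervals, sizes, excluded = GenomicRanges::GRanges(),
                              seed = NULL, max_attempts = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  validate_intervals(intervals, sizes)
  chr <- as.character(GenomicRanges::seqnames(intervals))
  w <- GenomicRanges::width(intervals)
  maxstart <- unname(sizes[chr] - w + 1L)
  if (any(maxstart < 1L)) stop("shuffle_intervals: interval longer than its chromosome")
  excl_idx <- interval_index(as.character(GenomicRanges::seqnames(excluded)),
                             GenomicRanges::start(excluded),
                             GenomicRanges::end(excluded), names(sizes))
  starts <- shuffle_starts(chr, w, maxstart, excl_idx, max_attempts)
  GenomicRanges::GRanges(chr, IRanges::IRanges(starts, width = w))
}

#' Permutation test for repeat enrichment at promoters
#'
#' Observed statistic: number of repeat intervals overlapping at least one
#' promoter. Null: the same count over `n` shuffles of the repeat set
#' ([shuffle_intervals()], excluding gene bodies and preserving chromosome
#' assignment). Empirical p-value uses the add-one convention
#' p = (1 + #\{null >= observed\}) / (n + 1), so p is never 0 and
#' p = 1/(n+1) reports as "< 1/n"; fold enrichment is observed over null
#' mean.
#'
#' @param repeats `GRanges` of repeat annotations.
#' @param promoters `GRanges` of promoter intervals.
#' @param gene_bodies `GRanges` exclusion set for the shuffles.
#' @param sizes A [chrom_sizes()] vector.
#' @param n Number of permutations (default 1000).
#' @param seed Optional integer seed; same seed gives an identical null vector.
#' @return List of class `permutation_result`: `observed`, `null` (length-n
#'   integer vector), `fold`, `pvalue`, `n`, `seed`.
#' @export
permutation_enrichment <- function(repeats, promoters, gene_bodies, sizes,
                                   n = 1000L, seed = NULL) {
  if (n < 1L) stop("permutation_enrichment: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  validate_intervals(repeats, sizes)
  observed <- count_overlapping(repeats, promoters)
  # the null loop works on plain vectors with sorted-interval indexes
  chr <- as.character(GenomicRanges::seqnames(repeats))
  w <- GenomicRanges::width(repeats)
  maxstart <- unname(sizes[chr] - w + 1L)
  if (any(maxstart < 1L)) stop("permutation_enrichment: repeat longer than chromosome")
  excl_idx <- interval_index(as.character(GenomicRanges::seqnames(gene_bodies)),
                             GenomicRanges::start(gene_bodies),
                             GenomicRanges::end(gene_bodies), names(sizes))
  prom_idx <- interval_index(as.character(GenomicRanges::seqnames(promoters)),
                             GenomicRanges::start(promoters),
                             GenomicRanges::end(promoters), names(sizes))
  null <- vapply(seq_len(n), function(k) {
    s <- shuffle_starts(chr, w, maxstart, excl_idx, 10000L)
    sum(index_any_overlap(chr, s, s + w - 1L, prom_idx))
  }, integer(1))
  res <- list(observed = observed, null = null,
              fold = observed / mean(null),
              pvalue = (1 + sum(null >= observed)) / (n + 1),
              n = as.integer(n), seed = seed)
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation enrichment: observed %d, null mean %.2f (sd %.2f), fold %.2f, p = %.4g (n = %d)\n",
    x$observed, mean(x$null), stats::sd(x$null), x$fold, x$pvalue, x$n))
  invisible(x)
}

#' Write a permutation result as TSV
#' @param x A `permutation_result`.
#' @param path Output path.
#' @param null_path Optional path for the full null distribution.
#' @return Invisibly, `path`.
#' @export
write_permutation_result <- function(x, path, null_path = NULL) {
  write_tsv_table(data.frame(
    observed = x$observed, null_mean = mean(x$null),
    null_sd = stats::sd(x$null), fold = x$fold, pvalue = x$pvalue,
    n = x$n, seed = if (is.null(x$seed)) NA_integer_ else x$seed), path)
  if (!is.null(null_path)) {
    write_tsv_table(data.frame(null = x$null), null_path)
  }
  invisible(path)
}
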
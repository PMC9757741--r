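# Promoter annotation from nuclear RNA-seq signal. In trans-splicing
# nematodes the annotated gene start is usually the trans-splice acceptor;
# the promoter lies further upstream and the intervening outron is visible as
# nascent/nuclear RNA signal. An accessible site is annotated as the promoter
# of a gene when (i) strand-matched RNA signal connects the site to the
# gene's annotated first exon, allowing zero-coverage gaps of at most 200 bp,
# and (ii) RNA signal downstream of the site midpoint (+75..+350 bp, gene
# orientation) is significantly higher than upstream (-350..-75 bp).

site_midpoint <- function(site) {
  as.integer(floor((GenomicRanges::start(site) + GenomicRanges::end(site)) / 2))
}

#' Link an accessible site to a gene's first exon through RNA signal
#'
#' Walks from the site midpoint toward the gene's annotated first exon along
#' the gene strand over strand-matched RNA coverage. A maximal run of
#' zero-coverage positions longer than `max_gap` breaks the link. A midpoint
#' already inside the first exon links trivially (path length 0, flagged).
#' A midpoint strand-downstream of the first exon cannot link.
#'
#' @param site Single-interval `GRanges`.
#' @param rna Stranded [coverage_track()] of nuclear RNA signal.
#' @param gene One row of a [gene_models()] table.
#' @param max_gap Largest tolerated zero-coverage run in bp (default 200).
#' @return List: `reached`, `path_length`, `max_gap_seen`, `inside_exon`.
#' @export
link_site_to_first_exon <- function(site, rna, gene, max_gap = 200L) {
  if (!rna$stranded) stop("link_site_to_first_exon: RNA track must be stranded")
  if (as.character(GenomicRanges::seqnames(site)) != gene$chrom) {
    stop("link_site_to_first_exon: site and gene on different chromosomes")
  }
  m <- site_midpoint(site)
  if (m >= gene$exon1_start && m <= gene$exon1_end) {
    return(list(reached = TRUE, path_length = 0L, max_gap_seen = 0L,
                inside_exon = TRUE))
  }
  upstream <- if (gene$strand == "+") m < gene$exon1_start else m > gene$exon1_end
  if (!upstream) {
    return(list(reached = FALSE, path_length = NA_integer_,
                max_gap_seen = NA_integer_, inside_exon = FALSE))
  }
  span <- if (gene$strand == "+") c(m, gene$exon1_start - 1L)
          else c(gene$exon1_end + 1L, m)
  v <- track_view(rna, gene$chrom, span[1], span[2], gene$strand)
  r <- rle(v == 0)
  gap <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  list(reached = gap <= max_gap, path_length = length(v),
       max_gap_seen = as.integer(gap), inside_exon = FALSE)
}

#' Directional RNA-signal asymmetry test
#'
#' Compares summed strand-matched RNA coverage in the window `+near..+far` bp
#' from the site midpoint (in the orientation of the downstream gene) against
#' the `-far..-near` window. "Significantly higher" is operationalized as a
#' one-sided binomial test on the integerized window sums (success =
#' downstream), requiring a total of at least `min_total` and p < `alpha`.
#'
#' @param site Single-interval `GRanges`.
#' @param gene_strand `"+"` or `"-"`: orientation of the downstream gene.
#' @param rna Stranded [coverage_track()].
#' @param near,far Window bounds in bp from the midpoint (defaults 75, 350).
#' @param alpha Significance level (default 0.05).
#' @param min_total Minimum summed evidence (default 10).
#' @return List: `downstream`, `upstream` (integerized sums), `pvalue`,
#'   `pass`, `truncated` (TRUE when a window would leave the chromosome, in
#'   which case the test fails).
#' @export
directional_signal_test <- function(site, gene_strand, rna, near = 75L,
                                    far = 350L, alpha = 0.05, min_total = 10L) {
  if (!rna$stranded) stop("directional_signal_test: RNA track must be stranded")
  chrom <- as.character(GenomicRanges::seqnames(site))
  m <- site_midpoint(site)
  len <- rna$sizes[[chrom]]
  if (m - far < 1L || m + far > len) {
    return(list(downstream = NA_integer_, upstream = NA_integer_,
                pvalue = NA_real_, pass = FALSE, truncated = TRUE))
  }
  dir <- if (gene_strand == "+") 1L else -1L
  win <- function(a, b) sum(track_view(rna, chrom, min(a, b), max(a, b), gene_strand))
  down <- round(win(m + dir * near, m + dir * far))
  up <- round(win(m - dir * near, m - dir * far))
  n <- down + up
  p <- if (n > 0) pbinom(down - 1, n, 0.5, lower.tail = FALSE) else 1
  list(downstream = as.integer(down), upstream = as.integer(up), pvalue = p,
       pass = n >= min_total && p < alpha, truncated = FALSE)
}

#' Annotate accessible sites as promoters
#'
#' A site is annotated as a promoter of gene *g* iff the outron link to *g*'s
#' first exon holds ([link_site_to_first_exon()]) and the directional test
#' passes in *g*'s orientation ([directional_signal_test()]). A site may be
#' the promoter of two genes (bidirectional promoter of a divergent gene
#' pair). Candidate genes are those whose first exon lies strand-downstream
#' of the site midpoint within `search_radius` bp (or contains the midpoint).
#' Walks that traverse another gene's body are linked but flagged.
#'
#' @param sites `GRanges` of accessible sites (named, or with a `name`
#'   column, to give stable site ids).
#' @param rna Stranded [coverage_track()].
#' @param genes A [gene_models()] table.
#' @param accessibility_calls Optional data.frame from
#'   [classify_germline_specific()]; germline-specificity is copied onto
#'   calls by site overlap.
#' @param max_gap,near,far,alpha,min_total Passed to the two criteria.
#' @param search_radius Candidate-gene search radius in bp (default 5000).
#' @return data.frame of promoter calls: site coordinates and id, `gene_id`,
#'   `gene_strand`, `path_length`, `max_gap_seen`, `inside_exon`,
#'   `crosses_gene`, `dir_pvalue`, `is_promoter` (always TRUE),
#'   `is_germline_specific`, `is_coopted` (FALSE until [flag_coopted()]).
#' @export
annotate_promoters <- function(sites, rna, genes, accessibility_calls = NULL,
                               max_gap = 200L, near = 75L, far = 350L,
                               alpha = 0.05, min_total = 10L,
                               search_radius = 5000L) {
  ids <- if (!is.null(names(sites))) names(sites) else
    if (!is.null(sites$name)) as.character(sites$name) else
      sprintf("site_%05d", seq_along(sites))
  bodies <- gene_body_ranges(genes)
  rows <- list()
  for (i in seq_along(sites)) {
    site <- sites[i]
    chrom <- as.character(GenomicRanges::seqnames(site))
    m <- site_midpoint(site)
    cand <- which(genes$chrom == chrom &
      ((m >= genes$exon1_start & m <= genes$exon1_end) |
       (genes$strand == "+" & m < genes$exon1_start &
          genes$exon1_start - m <= search_radius) |
       (genes$strand == "-" & m > genes$exon1_end &
          m - genes$exon1_end <= search_radius)))
    for (gi in cand) {
      gene <- genes[gi, ]
      link <- link_site_to_first_exon(site, rna, gene, max_gap = max_gap)
      if (!isTRUE(link$reached)) next
      dt <- directional_signal_test(site, gene$strand, rna, near = near,
                                    far = far, alpha = alpha,
                                    min_total = min_total)
      if (!isTRUE(dt$pass)) next
      walk <- if (link$inside_exon) GenomicRanges::GRanges(chrom, IRanges::IRanges(m, m))
        else if (gene$strand == "+") GenomicRanges::GRanges(chrom, IRanges::IRanges(m, gene$exon1_start - 1L))
        else GenomicRanges::GRanges(chrom, IRanges::IRanges(gene$exon1_end + 1L, m))
      other <- bodies[names(bodies) != gene$gene_id]
      crosses <- count_overlapping(walk, other) > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = GenomicRanges::start(site),
        end = GenomicRanges::end(site), site_id = ids[i],
        gene_id = gene$gene_id, gene_strand = gene$strand,
        path_length = link$path_length, max_gap_seen = link$max_gap_seen,
        inside_exon = link$inside_exon, crosses_gene = crosses,
        dir_pvalue = dt$pvalue, is_promoter = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    site_id = character(0), gene_id = character(0), gene_strand = character(0),
    path_length = integer(0), max_gap_seen = integer(0),
    inside_exon = logical(0), crosses_gene = logical(0),
    dir_pvalue = numeric(0), is_promoter = logical(0))
  out$is_germline_specific <- rep(FALSE, nrow(out))
  if (!is.null(accessibility_calls) && nrow(out)) {
    gl <- accessibility_calls[accessibility_calls$label == "germline_specific", ]
    if (nrow(gl)) {
      glr <- GenomicRanges::GRanges(gl$chrom, IRanges::IRanges(gl$start, gl$end))
      sr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start, out$end))
      out$is_germline_specific <-
        GenomicRanges::countOverlaps(sr, glr, ignore.strand = TRUE) > 0L
    }
  }
  out$is_coopted <- rep(FALSE, nrow(out))
  out
}

#' Write promoter intervals as a colored BED file
#'
#' One record per promoter site, colored by germline-specificity (purple for
#' germline-specific, grey otherwise), for genome-browser inspection.
#'
#' @param promoters Promoter-call data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_promoter_bed <- function(promoters, path) {
  gr <- promoter_ranges(promoters)
  germ <- tapply(promoters$is_germline_specific, promoters$site_id, any)[names(gr)]
  gr$name <- names(gr)
  gr$score <- 0L
  gr$itemRgb <- ifelse(germ, "#7B3294", "#A6ACAF")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Promoter calls as intervals
#' @param promoters Promoter-call data.frame.
#' @return `GRanges` of the (deduplicated) promoter site intervals.
#' @export
promoter_ranges <- function(promoters) {
  u <- unique(promoters[, c("chrom", "start", "end", "site_id")])
  gr <- GenomicRanges::GRanges(u$chrom, IRanges::IRanges(u$start, u$end))
  names(gr) <- u$site_id
  gr
}
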
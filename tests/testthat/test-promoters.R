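# outron linking and the directional signal test

sizes1 <- function(L = 10000L) chrom_sizes(c(chrI = L))

plus_gene <- function(exon1_start = 3000L) {
  gene_models(data.frame(
    gene_id = "g1", chrom = "chrI", strand = "+", tss = exon1_start,
    exon1_start = exon1_start, exon1_end = exon1_start + 200L,
    body_start = exon1_start, body_end = exon1_start + 1500L))[1, ]
}

rna_from <- function(segments, L = 10000L) {
  track_from_segments(segments, sizes1(L), stranded = TRUE)
}

seg <- function(s, e, strand = "+", h = 10) {
  GenomicRanges::GRanges("chrI", IRanges::IRanges(s, e), strand = strand,
                         score = h)
}

test_that("continuous coverage links site to exon with zero max gap", {
  gene <- plus_gene()
  site <- genomic_intervals("chrI", 1901, 2200)  # midpoint 2050
  rna <- rna_from(seg(2050, 3200))
  r <- link_site_to_first_exon(site, rna, gene)
  expect_true(r$reached)
  expect_identical(r$max_gap_seen, 0L)
  expect_identical(r$path_length, 950L)
  expect_false(r$inside_exon)
})

test_that("the 200-bp gap tolerance is a sharp boundary", {
  gene <- plus_gene()
  site <- genomic_intervals("chrI", 1901, 2200)
  # coverage everywhere except a zero run of exactly 201 bp
  rna201 <- rna_from(c(seg(2050, 2399), seg(2601, 3200)))
  expect_false(link_site_to_first_exon(site, rna201, gene)$reached)
  rna200 <- rna_from(c(seg(2050, 2399), seg(2600, 3200)))
  r <- link_site_to_first_exon(site, rna200, gene)
  expect_true(r$reached)
  expect_identical(r$max_gap_seen, 200L)
})

test_that("linking agrees with a position-by-position scan oracle", {
  set.seed(51)
  gene <- plus_gene()
  site <- genomic_intervals("chrI", 1901, 2200)
  for (rep in 1:20) {
    # random on/off coverage between midpoint and exon
    n_seg <- sample(3:8, 1)
    s <- sort(sample(2050:2950, n_seg))
    e <- pmin(s + sample(30:400, n_seg, replace = TRUE), 2999)
    rna <- rna_from(seg(s, e))
    got <- link_site_to_first_exon(site, rna, gene)
    # oracle: explicit walk over the per-base vector
    v <- track_view(rna, "chrI", 2050, 2999, "+")
    runs <- rle(v == 0)
    want <- !any(runs$lengths[runs$values] > 200)
    expect_identical(got$reached, want)
  }
})

test_that("linking handles exon-contained and downstream midpoints", {
  gene <- plus_gene()
  rna <- rna_from(seg(1, 9999))
  inside <- genomic_intervals("chrI", 2951, 3250)  # midpoint 3100 in exon
  r <- link_site_to_first_exon(inside, rna, gene)
  expect_true(r$reached)
  expect_true(r$inside_exon)
  expect_identical(r$path_length, 0L)
  downstream <- genomic_intervals("chrI", 3501, 3800)
  expect_false(link_site_to_first_exon(downstream, rna, gene)$reached)
  minus_rna <- rna_from(seg(2050, 3200, "-"))
  expect_false(link_site_to_first_exon(
    genomic_intervals("chrI", 1901, 2200), minus_rna, gene)$reached)
})

test_that("directional test requires downstream asymmetry", {
  site <- genomic_intervals("chrI", 1901, 2200)  # midpoint 2050
  # strong signal only downstream
  down <- rna_from(seg(2125, 2400, h = 4))
  r <- directional_signal_test(site, "+", down)
  expect_true(r$pass)
  expect_identical(r$upstream, 0L)
  # perfectly symmetric signal fails
  sym <- rna_from(c(seg(2125, 2400, h = 4), seg(1700, 1975, h = 4)))
  expect_false(directional_signal_test(site, "+", sym)$pass)
  # no signal at all fails without error
  none <- rna_from(seg(1, 10, h = 1))
  expect_false(directional_signal_test(site, "+", none)$pass)
  # too little evidence fails on min_total
  weak <- rna_from(seg(2125, 2130, h = 1))
  expect_false(directional_signal_test(site, "+", weak)$pass)
  # minus-strand gene: downstream window lies left of the midpoint
  downm <- rna_from(seg(1700, 1975, "-", h = 4))
  expect_true(directional_signal_test(site, "-", downm)$pass)
})

test_that("windows truncated by the chromosome edge fail with a flag", {
  site <- genomic_intervals("chrI", 101, 200)  # midpoint 150 < far
  rna <- rna_from(seg(160, 500))
  r <- directional_signal_test(site, "+", rna)
  expect_false(r$pass)
  expect_true(r$truncated)
})

test_that("annotate_promoters requires both criteria and finds both genes of a bidirectional site", {
  genes <- gene_models(data.frame(
    gene_id = c("gp", "gm"), chrom = "chrI", strand = c("+", "-"),
    tss = c(3000, 1000), exon1_start = c(3000, 800), exon1_end = c(3200, 1000),
    body_start = c(3000, 200), body_end = c(4500, 1000)))
  site <- genomic_intervals("chrI", 1901, 2200)
  names(site) <- "s1"
  rna <- rna_from(c(seg(2050, 3200, "+"), seg(800, 2050, "-")))
  calls <- annotate_promoters(site, rna, genes)
  expect_identical(sort(calls$gene_id), c("gm", "gp"))
  expect_true(all(calls$is_promoter))
  # site with no gene in range yields no call
  far_site <- genomic_intervals("chrI", 8001, 8300)
  names(far_site) <- "s2"
  expect_identical(nrow(annotate_promoters(far_site, rna, genes)), 0L)
  # linking without directional asymmetry is not enough
  rna_link_only <- rna_from(c(seg(2050, 3200, "+"), seg(1700, 1975, "+", 10)))
  one <- annotate_promoters(site, rna_link_only, genes)
  expect_false("gp" %in% one$gene_id &&
    directional_signal_test(site, "+", rna_link_only)$pass)
})

test_that("promoter BED output colors sites by germline-specificity", {
  pr <- data.frame(chrom = "chrI", start = c(100L, 900L), end = c(400L, 1200L),
                   site_id = c("s1", "s2"), gene_id = c("g1", "g2"),
                   is_germline_specific = c(TRUE, FALSE), is_coopted = FALSE)
  f <- file.path(withr::local_tempdir(), "prom.bed")
  write_promoter_bed(pr, f)
  txt <- readLines(f)
  expect_length(txt, 2L)
  expect_true(grepl("123,50,148", txt[grepl("s1", txt)]))  # purple RGB
})

test_that("adding coverage never unlinks a linked site", {
  set.seed(52)
  gene <- plus_gene()
  site <- genomic_intervals("chrI", 1901, 2200)
  for (rep in 1:10) {
    n_seg <- sample(3:6, 1)
    s <- sort(sample(2050:2900, n_seg))
    e <- pmin(s + sample(50:400, n_seg, replace = TRUE), 2999)
    base_seg <- seg(s, e)
    base <- link_site_to_first_exon(site, rna_from(base_seg), gene)
    extra_s <- sample(2050:2950, 1)
    more <- rna_from(c(base_seg, seg(extra_s, min(extra_s + 120, 2999))))
    grown <- link_site_to_first_exon(site, more, gene)
    if (base$reached) expect_true(grown$reached)
  }
})

test_that("promoter calls are invariant under coordinate translation and renaming", {
  gene_df <- data.frame(
    gene_id = "g1", chrom = "chrI", strand = "+", tss = 3000,
    exon1_start = 3000, exon1_end = 3200, body_start = 3000, body_end = 4500)
  site <- genomic_intervals("chrI", 1901, 2200)
  names(site) <- "s1"
  mk <- function(shift, new_chrom) {
    chrom <- new_chrom
    genes <- gene_models(transform(gene_df, chrom = new_chrom, tss = tss + shift,
                                   exon1_start = exon1_start + shift,
                                   exon1_end = exon1_end + shift,
                                   body_start = body_start + shift,
                                   body_end = body_end + shift))
    s <- GenomicRanges::shift(site, shift)
    s <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      GenomicRanges::start(s), GenomicRanges::end(s)))
    names(s) <- "s1"
    segs <- seg(2050 + shift, 3200 + shift)
    segs <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      GenomicRanges::start(segs), GenomicRanges::end(segs)),
      strand = "+", score = 10)
    rna <- track_from_segments(segs, chrom_sizes(setNames(20000L, chrom)),
                               stranded = TRUE)
    annotate_promoters(s, rna, genes)
  }
  a <- mk(0L, "chrI")
  b <- mk(1234L, "scaffold_9")
  expect_identical(a$gene_id, b$gene_id)
  expect_identical(a$path_length, b$path_length)
  expect_identical(a$dir_pvalue, b$dir_pvalue)
})
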
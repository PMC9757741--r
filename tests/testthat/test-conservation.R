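# conservation classification over 1:1 orthologs

# minimal two-species scene builders
mini_genes <- function(prefix) {
  gene_models(data.frame(
    gene_id = paste0(prefix, c("g1", "g2")), chrom = "chrI", strand = "+",
    tss = c(5000, 20000), exon1_start = c(5000, 20000),
    exon1_end = c(5200, 20200), body_start = c(5000, 20000),
    body_end = c(6500, 21500)))
}

mini_promoter <- function(gene_id, coopted, family = "CERP2_like",
                          start = 4000L) {
  data.frame(chrom = "chrI", start = start, end = start + 300L,
             site_id = paste0("s_", gene_id), gene_id = gene_id,
             is_promoter = TRUE, is_germline_specific = TRUE,
             is_coopted = coopted,
             coopted_family = if (coopted) family else "none",
             stringsAsFactors = FALSE)
}

div_pair <- function(start) {
  GenomicRanges::GRanges("chrI", IRanges::IRanges(start, start + 37L),
                         m1_start = start, m1_end = start + 11L, m1_strand = "-",
                         m2_start = start + 26L, m2_end = start + 37L,
                         m2_strand = "+", spacing = 14L,
                         arrangement = "divergent", family = "CERP2_like")
}

single_hit <- function(start, motif) {
  GenomicRanges::GRanges("chrI", IRanges::IRanges(start, start + 9L),
                         strand = "+", motif = motif, score = 10, pvalue = 1e-6)
}

no_gr <- GenomicRanges::GRanges()

test_that("ortholog tables must be 1:1", {
  expect_error(ortholog_pairs(c("a", "a"), c("x", "y")), "1:1")
  expect_silent(ortholog_pairs(c("a", "b"), c("x", "y")))
})

test_that("conservation classes follow the fixed rule order", {
  genes_a <- mini_genes("ce_")
  genes_b <- mini_genes("cb_")
  pairs <- ortholog_pairs(c("ce_g1", "ce_g2"), c("cb_g1", "cb_g2"))
  pa <- rbind(mini_promoter("ce_g1", TRUE), mini_promoter("ce_g2", TRUE, start = 19000L))
  mp_a <- c(div_pair(4100L), div_pair(19100L))

  # (1) both co-opted -> conserved
  pb <- mini_promoter("cb_g1", TRUE)
  out <- classify_conservation(pairs[1, ], pa, pb, mp_a, div_pair(4100L),
                               no_gr, no_gr, genes_a, genes_b)
  expect_identical(out$class, "conserved")
  expect_identical(out$evidence_a, "coopted_CERP2")

  # (2a) other species: promoter containing a lone m2 -> potentially conserved
  pb2 <- mini_promoter("cb_g1", FALSE)
  out2 <- classify_conservation(pairs[1, ], pa, pb2, mp_a, no_gr,
                                no_gr, single_hit(4100L, "m2"),
                                genes_a, genes_b)
  expect_identical(out2$class, "potentially_conserved")
  expect_identical(out2$evidence_b, "promoter_single_m2")

  # (2b) other species: divergent pair near the TSS, no promoter there
  out3 <- classify_conservation(pairs[1, ], pa, pb2[0, ], mp_a,
                                div_pair(4300L), no_gr, no_gr,
                                genes_a, genes_b)
  expect_identical(out3$class, "potentially_conserved")
  expect_identical(out3$evidence_b, "window_pair")
  # ... but a pair inside an annotated promoter does not count
  out3b <- classify_conservation(pairs[1, ], pa, pb2, mp_a,
                                 div_pair(4100L), no_gr, no_gr,
                                 genes_a, genes_b)
  expect_identical(out3b$class, "species_specific")

  # (3) nothing in the other species -> species specific
  out4 <- classify_conservation(pairs[1, ], pa, pb2, mp_a, no_gr,
                                no_gr, no_gr, genes_a, genes_b)
  expect_identical(out4$class, "species_specific")

  # ineligible: co-option is CELE2-like only
  pa5 <- mini_promoter("ce_g1", TRUE, family = "CELE2_like")
  out5 <- classify_conservation(pairs[1, ], pa5, pb2, no_gr, no_gr,
                                no_gr, no_gr, genes_a, genes_b)
  expect_false(out5$eligible)
  expect_true(is.na(out5$class))

  # unknown gene ids error
  bad <- ortholog_pairs("ce_gX", "cb_g1")
  expect_error(classify_conservation(bad, pa, pb, mp_a, no_gr, no_gr, no_gr,
                                     genes_a, genes_b), "ce_gX")
})

test_that("the TSS window is oriented by gene strand", {
  genes_a <- mini_genes("ce_")
  # minus-strand gene in species B: window is [tss - 200, tss + 1000]
  genes_b <- gene_models(data.frame(
    gene_id = "cb_g1", chrom = "chrI", strand = "-", tss = 8000,
    exon1_start = 7800, exon1_end = 8000, body_start = 6500, body_end = 8000))
  pairs <- ortholog_pairs("ce_g1", "cb_g1")
  pa <- mini_promoter("ce_g1", TRUE)
  inside <- classify_conservation(pairs, pa, pa[0, ], div_pair(4100L),
                                  div_pair(8700L), no_gr, no_gr,
                                  genes_a, genes_b)
  expect_identical(inside$class, "potentially_conserved")
  outside <- classify_conservation(pairs, pa, pa[0, ], div_pair(4100L),
                                   div_pair(9300L), no_gr, no_gr,
                                   genes_a, genes_b)
  expect_identical(outside$class, "species_specific")
})

test_that("classification is symmetric in the species labels", {
  w <- small_world()
  ra <- world_pipeline(small_world, "a")
  rb <- world_pipeline(small_world, "b")
  fwd <- classify_conservation(w$orthologs, ra$promoters, rb$promoters,
                               ra$pairs, rb$pairs,
                               c(ra$m1_hits, ra$m2_hits),
                               c(rb$m1_hits, rb$m2_hits),
                               w$species$a$genes, w$species$b$genes)
  swapped <- ortholog_pairs(w$orthologs$gene_b, w$orthologs$gene_a)
  rev <- classify_conservation(swapped, rb$promoters, ra$promoters,
                               rb$pairs, ra$pairs,
                               c(rb$m1_hits, rb$m2_hits),
                               c(ra$m1_hits, ra$m2_hits),
                               w$species$b$genes, w$species$a$genes)
  expect_identical(fwd$eligible, rev$eligible)
  expect_identical(fwd$class, rev$class)
  expect_identical(fwd$evidence_a, rev$evidence_b)
  expect_identical(fwd$evidence_b, rev$evidence_a)
  # every eligible pair receives exactly one class
  expect_false(any(is.na(fwd$class[fwd$eligible])))
  expect_true(all(is.na(fwd$class[!fwd$eligible])))
})
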
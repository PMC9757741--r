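# Synthetic two-species benchmark: genomes with planted MITE-like elements,
# gene models, ATAC/RNA coverage, DE tables, ChIP peaks, ortholog maps, and a
# full truth table, so the entire pipeline is testable without downloads.
#
# The stated world is noise-free by default: planted motifs are exact
# consensus copies, replicate ATAC counts are deterministic, and RNA gaps are
# bounded below the 200-bp linking tolerance, so downstream recovery of every
# planted feature is guaranteed by construction. Because a scan threshold of
# P <= 5e-4 by definition admits ~p*2L chance windows on an iid background,
# the generator scrubs its own background after assembly: it scans the
# genome with the configured PWMs and rewrites any hit not at a planted
# coordinate, iterating to convergence. See the methods vignette.

#' Default configuration for the synthetic world
#'
#' All sizes and rates are free parameters of the generator (the statistical
#' *structure* mimics germline ATAC/RNA data; the magnitudes do not come from
#' any measured dataset). Defaults give a 5-Mb two-chromosome genome with 600
#' planted MITE-like elements of which ~270 are active promoters.
#'
#' @param seed Master seed; all randomness flows from it.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_genes Number of ortholog-paired genes per species.
#' @param n_cerp2,n_cele2 Planted element counts per family (CERP2-like:
#'   divergent m1m2; CELE2-like: tandem m2+m1+).
#' @param cerp2_spacing,cele2_spacing Inter-motif spacing supports (12-16 and
#'   23-28 bp).
#' @param promoter_fraction Fraction of elements planted as active promoters.
#' @param germline_fraction Fraction of active promoters that are
#'   germline-specific (wild-type-only ATAC).
#' @param n_bidirectional Divergent gene pairs sharing one accessible site.
#' @param m1_consensus,m2_consensus Motif consensus sequences.
#' @param pwm_match_prob Consensus-base probability of the generated PWMs.
#' @param mutation_rate Per-base probability of mutating planted motif copies
#'   (0 = noise-free stated world).
#' @param base_composition Background base probabilities (AT-rich, worm-like).
#' @param atac_high,atac_low Per-replicate ATAC counts at accessible sites
#'   (high) and at germline-specific sites in germline-less animals (low).
#' @param count_noise `"none"` (deterministic counts) or `"poisson"`.
#' @param n_replicates ATAC replicates per condition.
#' @param rna_height Outron/first-exon RNA coverage height.
#' @param rna_gap_rate Per-base probability of starting a zero-coverage gap in
#'   the outron signal.
#' @param rna_max_gap Maximum injected gap length (must stay < 200 so linking
#'   succeeds for true promoters).
#' @param scan_p_threshold Threshold used when scrubbing background motif
#'   hits; keep equal to the scan threshold used downstream.
#' @param conservation_props Proportions of eligible ortholog pairs per
#'   conservation scenario: both co-opted; other species has a lone motif in
#'   a promoter; other species has a non-promoter divergent pair near the
#'   TSS; co-opted in species A only; co-opted in species B only.
#' @param chip_plain_fraction Fraction of plain (motif-free) promoters that
#'   also receive a ChIP peak (HOT-region stand-ins).
#' @param chip_false_positives ChIP peaks dropped on random intergenic spots.
#' @param p_down_coopted,p_down_plain_bound,p_down_other,p_up DE simulation
#'   probabilities (down for co-opted-promoter genes, for bound plain
#'   promoter genes, for other genes; up among the rest).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    chrom_lengths = c(chrI = 2500000L, chrII = 2500000L),
    n_genes = 500L,
    n_cerp2 = 360L,
    n_cele2 = 240L,
    cerp2_spacing = 12:16,
    cele2_spacing = 23:28,
    promoter_fraction = 0.45,
    germline_fraction = 0.7,
    n_bidirectional = 0L,
    m1_consensus = "TATCCAGCCCTC",
    m2_consensus = "TATTGTACTC",
    pwm_match_prob = 0.91,
    mutation_rate = 0,
    base_composition = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
    atac_high = 2000L,
    atac_low = 4L,
    count_noise = c("none", "poisson"),
    n_replicates = 2L,
    rna_height = 20,
    rna_gap_rate = 0.02,
    rna_max_gap = 150L,
    scan_p_threshold = 0.0005,
    conservation_props = c(conserved = 0.53, potential_single = 0.15,
                           potential_pair = 0.09, specific_a = 0.13,
                           specific_b = 0.10),
    chip_plain_fraction = 0.8,
    chip_false_positives = 20L,
    p_down_coopted = 0.45, p_down_plain_bound = 0.6, p_down_other = 0.05,
    p_up = 0.06) {
  count_noise <- match.arg(count_noise)
  chrom_lengths <- chrom_sizes(unlist(chrom_lengths))  # tolerate JSON lists
  base_composition <- unlist(base_composition)
  conservation_props <- unlist(conservation_props)
  cfg <- as.list(environment())
  stopifnot(promoter_fraction >= 0, promoter_fraction <= 1,
            germline_fraction >= 0, germline_fraction <= 1,
            all(cerp2_spacing >= 12), all(cerp2_spacing <= 16),
            all(cele2_spacing >= 23), all(cele2_spacing <= 28),
            rna_max_gap < 200, n_replicates >= 2)
  if (abs(sum(conservation_props) - 1) > 1e-6) {
    stop("synthetic_config: conservation_props must sum to 1")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483629)
}

random_bases <- function(n, comp) {
  sample(DNA, n, replace = TRUE, prob = comp[DNA])
}

#' Simulate outron RNA signal from a promoter to a first exon
#'
#' Emits strand-matched coverage segments of height `height` running from the
#' promoter midpoint through the gene's annotated first exon, with injected
#' zero-coverage gaps whose lengths never exceed `max_gap_len` (kept below
#' the 200-bp linking tolerance so true promoters always link). Consecutive
#' gaps are separated by at least one covered base.
#'
#' @param gene One row of a [gene_models()] table.
#' @param promoter Single-interval `GRanges`, strand-upstream of the first
#'   exon (error otherwise).
#' @param height Coverage height (0 models an inactive site: empty signal).
#' @param gap_rate Per-base probability of starting a gap.
#' @param max_gap_len Maximum gap length in bp (default 150).
#' @param seed Optional seed.
#' @return `GRanges` segments with a `score` column on the gene strand
#'   (possibly empty), covering the outron and first exon.
#' @export
simulate_rna_outron <- function(gene, promoter, height, gap_rate = 0,
                                max_gap_len = 150L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- site_midpoint(promoter)
  upstream <- if (gene$strand == "+") m < gene$exon1_start else m > gene$exon1_end
  if (!upstream) stop("simulate_rna_outron: promoter not upstream of first exon")
  span <- if (gene$strand == "+") c(m, gene$exon1_end) else c(gene$exon1_start, m)
  n <- span[2] - span[1] + 1L
  if (height == 0) {
    return(GenomicRanges::GRanges(score = numeric(0)))
  }
  v <- rep(height, n)
  if (gap_rate > 0) {
    i <- 1L
    while (i <= n) {
      if (runif(1) < gap_rate) {
        glen <- sample(seq(10L, max_gap_len), 1L)
        v[i:min(n, i + glen - 1L)] <- 0
        i <- i + glen + 1L  # >= 1 covered base between gaps
      } else {
        i <- i + 1L
      }
    }
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0
  GenomicRanges::GRanges(gene$chrom,
                         IRanges::IRanges(span[1] + starts[keep] - 1L,
                                          span[1] + ends[keep] - 1L),
                         strand = gene$strand, score = r$values[keep])
}

# ---- world planning ----------------------------------------------------------

# block geometries (local 1-based coordinates)
GENE_BLOCK_W <- 2600L
INTER_BLOCK_W <- 400L
BIDIR_BLOCK_W <- 4600L

gene_block_geometry <- function(strand) {
  if (strand == "+") {
    list(site = c(401L, 700L), exon1 = c(1001L, 1200L), body = c(1001L, 2500L),
         tss = 1001L, elem_center = 550L)
  } else {
    list(site = c(1901L, 2200L), exon1 = c(1401L, 1600L), body = c(101L, 1600L),
         tss = 1600L, elem_center = 2050L)
  }
}

# assign per-gene feature types for species A
plan_types_a <- function(cfg) {
  n_cerp2_prom <- round(cfg$n_cerp2 * cfg$promoter_fraction)
  n_cele2_prom <- round(cfg$n_cele2 * cfg$promoter_fraction)
  n_plain <- round(0.24 * cfg$n_genes)
  n_used <- n_cerp2_prom + n_cele2_prom + n_plain
  if (n_used > cfg$n_genes) stop("synthetic world: more planted promoters than genes")
  types <- c(rep("cerp2_promoter", n_cerp2_prom),
             rep("cele2_promoter", n_cele2_prom),
             rep("plain_promoter", n_plain),
             rep("none", cfg$n_genes - n_used))
  sample(types)
}

# species B types follow from A types plus the drawn conservation class
plan_types_b <- function(cfg, types_a) {
  idx_cerp2 <- which(types_a == "cerp2_promoter")
  k <- length(idx_cerp2)
  pr <- cfg$conservation_props
  pa <- pr[c("conserved", "potential_single", "potential_pair", "specific_a")]
  counts <- floor(k * pa / sum(pa))
  counts[1] <- counts[1] + (k - sum(counts))
  class_a <- sample(rep(names(counts), counts))
  n_sb <- round(k * pr["specific_b"] / sum(pa))
  pool_b <- which(types_a %in% c("plain_promoter", "none"))
  idx_sb <- sample(pool_b, min(n_sb, length(pool_b)))

  types_b <- types_a  # default: mirror A
  types_b[types_a == "cele2_promoter"] <- "plain_promoter"  # CELE2 is A-specific
  class_pair <- rep(NA_character_, length(types_a))
  for (j in seq_along(idx_cerp2)) {
    i <- idx_cerp2[j]
    types_b[i] <- switch(class_a[j],
      conserved = "cerp2_promoter",
      potential_single = if (j %% 2 == 0) "single_m1" else "single_m2",
      potential_pair = "window_pair",
      specific_a = "plain_promoter")
    class_pair[i] <- switch(class_a[j],
      conserved = "conserved",
      potential_single = "potentially_conserved",
      potential_pair = "potentially_conserved",
      specific_a = "species_specific")
  }
  types_b[idx_sb] <- "cerp2_promoter"
  class_pair[idx_sb] <- "species_specific"
  list(types_b = types_b, class_pair = class_pair)
}

# lay gene and intergenic-element blocks onto chromosomes
layout_blocks <- function(cfg, n_gene_blocks, n_bidir, n_inter) {
  widths <- c(rep(GENE_BLOCK_W, n_gene_blocks),
              rep(BIDIR_BLOCK_W, n_bidir),
              rep(INTER_BLOCK_W, n_inter))
  kind <- c(rep("gene", n_gene_blocks), rep("bidir", n_bidir),
            rep("inter", n_inter))
  ord <- sample(seq_along(widths))
  widths <- widths[ord]; kind <- kind[ord]
  chrom <- character(length(widths))
  start <- integer(length(widths))
  ci <- 1L
  cursor <- 0L
  nms <- names(cfg$chrom_lengths)
  for (i in seq_along(widths)) {
    gap <- sample(200:800, 1L)
    repeat {
      s <- cursor + gap + 1L
      if (s + widths[i] - 1L <= cfg$chrom_lengths[ci] - 200L) break
      ci <- ci + 1L
      cursor <- 0L
      if (ci > length(nms)) {
        stop("synthetic world: requested elements/genes do not fit the genome ",
             "(capacity error)")
      }
    }
    chrom[i] <- nms[ci]
    start[i] <- s
    cursor <- s + widths[i] - 1L
  }
  data.frame(kind = kind, chrom = chrom, start = start, width = widths,
             stringsAsFactors = FALSE)
}

mutate_bases <- function(b, rate) {
  if (rate <= 0) return(b)
  hit <- runif(length(b)) < rate
  b[hit] <- sample(DNA, sum(hit), replace = TRUE)
  b
}

# Describe one planted element as a truth row plus sequence edits, without
# touching the genome (edits are batched and applied once per chromosome to
# avoid repeated full-vector copies).  family: CERP2_like (divergent m1m2:
# left motif is m1 on minus strand, then spacer, then m2 on plus), CELE2_like
# (tandem m2+ then m1+), single_m1 / single_m2 (lone motif, plus strand).
plant_element <- function(cfg, chrom, center, family) {
  m1 <- strsplit(cfg$m1_consensus, "")[[1]]
  m2 <- strsplit(cfg$m2_consensus, "")[[1]]
  rc <- function(b) rev(chartr("ACGT", "TGCA", b))
  if (family %in% c("CERP2_like", "CELE2_like")) {
    if (family == "CERP2_like") {
      sp <- sample(cfg$cerp2_spacing, 1L)
      left <- mutate_bases(rc(m1), cfg$mutation_rate)   # m1 on minus strand
      right <- mutate_bases(m2, cfg$mutation_rate)      # m2 on plus strand
    } else {
      sp <- sample(cfg$cele2_spacing, 1L)
      left <- mutate_bases(m2, cfg$mutation_rate)       # m2 on plus strand
      right <- mutate_bases(m1, cfg$mutation_rate)      # m1 on plus strand
    }
    L <- length(left) + sp + length(right)
    s <- center - floor(L / 2)
    s2 <- s + length(left) + sp
    row <- if (family == "CERP2_like") data.frame(
      family = family, arrangement = "divergent", spacing = sp,
      start = s, end = s + L - 1L,
      m1_start = s, m1_end = s + length(left) - 1L, m1_strand = "-",
      m2_start = s2, m2_end = s2 + length(right) - 1L, m2_strand = "+")
    else data.frame(
      family = family, arrangement = "tandem_m2_m1", spacing = sp,
      start = s, end = s + L - 1L,
      m1_start = s2, m1_end = s2 + length(right) - 1L, m1_strand = "+",
      m2_start = s, m2_end = s + length(left) - 1L, m2_strand = "+")
    pos <- c(s:(s + length(left) - 1L), s2:(s2 + length(right) - 1L))
    bases <- c(left, right)
  } else {
    mot <- if (family == "single_m1") m1 else m2
    b <- mutate_bases(mot, cfg$mutation_rate)
    s <- center - floor(length(b) / 2)
    row <- data.frame(
      family = family, arrangement = NA_character_, spacing = NA_integer_,
      start = s, end = s + length(b) - 1L,
      m1_start = if (family == "single_m1") s else NA_integer_,
      m1_end = if (family == "single_m1") s + length(b) - 1L else NA_integer_,
      m1_strand = if (family == "single_m1") "+" else NA_character_,
      m2_start = if (family == "single_m2") s else NA_integer_,
      m2_end = if (family == "single_m2") s + length(b) - 1L else NA_integer_,
      m2_strand = if (family == "single_m2") "+" else NA_character_)
    pos <- s:(s + length(b) - 1L)
    bases <- b
  }
  row$chrom <- chrom
  list(row = row, chrom = chrom, pos = pos, bases = bases)
}

# Rewrite chance motif hits in the background until a fresh scan finds
# exactly the planted occurrences. `planted` is a GRanges of planted motif
# instances with strand and a `motif` column. A chance hit may overlap a
# planted motif (partial self-match); then only its non-planted bases are
# redrawn, which disrupts the hit without touching planted sequence. The
# default consensus pair was chosen so that no window fully contained in
# planted bases can reach the scan threshold, making convergence certain.
scrub_background <- function(seqs, cfg, pwms, planted, max_rounds = 30L) {
  hit_key <- function(gr) {
    paste(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr),
          as.character(GenomicRanges::strand(gr)), gr$motif)
  }
  planted_keys <- hit_key(planted)
  # mask of planted motif bases, per chromosome
  mask <- lapply(names(seqs), function(ch) {
    m <- logical(length(seqs[[ch]]))
    sel <- as.character(GenomicRanges::seqnames(planted)) == ch
    for (i in which(sel)) {
      m[GenomicRanges::start(planted)[i]:GenomicRanges::end(planted)[i]] <- TRUE
    }
    m
  })
  names(mask) <- names(seqs)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop("synthetic world: background scrubbing did not converge")
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
    hits <- suppressWarnings(c(scan_pwm(genome, pwms$m1, cfg$scan_p_threshold),
                               scan_pwm(genome, pwms$m2, cfg$scan_p_threshold)))
    chance <- hits[!hit_key(hits) %in% planted_keys]
    if (!length(chance)) {
      return(list(seqs = seqs, rounds = rounds))
    }
    chs <- as.character(GenomicRanges::seqnames(chance))
    ss <- GenomicRanges::start(chance)
    es <- GenomicRanges::end(chance)
    # batch the rewrites: one subassignment per chromosome per round
    for (ch in unique(chs)) {
      sel <- chs == ch
      pos <- unique(unlist(mapply(seq.int, ss[sel], es[sel], SIMPLIFY = FALSE)))
      pos <- pos[!mask[[ch]][pos]]
      if (length(pos)) {
        seqs[[ch]][pos] <- random_bases(length(pos), cfg$base_composition)
      }
    }
  }
}

# ---- species assembly --------------------------------------------------------

build_species <- function(cfg, prefix, types, pwms, seed,
                          germline = NULL) {
  set.seed(seed)
  n_genes <- length(types)
  n_prom_elem <- sum(types %in% c("cerp2_promoter", "cele2_promoter"))
  n_cerp2_used <- sum(types %in% c("cerp2_promoter", "window_pair"))
  n_inter_cerp2 <- cfg$n_cerp2 - n_cerp2_used
  n_inter_cele2 <- cfg$n_cele2 - sum(types == "cele2_promoter")
  if (n_inter_cerp2 < 0 || n_inter_cele2 < 0) {
    stop("synthetic world: element budget exceeded by gene plan")
  }
  blocks <- layout_blocks(cfg, n_genes, cfg$n_bidirectional,
                          n_inter_cerp2 + n_inter_cele2)
  inter_family <- sample(c(rep("CERP2_like", n_inter_cerp2),
                           rep("CELE2_like", n_inter_cele2)))

  seqs <- lapply(cfg$chrom_lengths, function(L) random_bases(L, cfg$base_composition))
  names(seqs) <- names(cfg$chrom_lengths)

  gene_rows <- list(); elem_rows <- list(); site_rows <- list(); edits <- list()
  gi <- 0L; ii <- 0L; si <- 0L
  gene_ids_regular <- sprintf("%s_g%04d", prefix, seq_len(n_genes))
  if (is.null(germline)) {
    germline <- runif(n_genes + 2L * cfg$n_bidirectional) < cfg$germline_fraction
  }

  add_gene <- function(id, chrom, off, strand, type, gl) {
    geo <- gene_block_geometry(strand)
    g <- data.frame(gene_id = id, chrom = chrom, strand = strand,
                    tss = off + geo$tss - 1L,
                    exon1_start = off + geo$exon1[1] - 1L,
                    exon1_end = off + geo$exon1[2] - 1L,
                    body_start = off + geo$body[1] - 1L,
                    body_end = off + geo$body[2] - 1L,
                    stringsAsFactors = FALSE)
    has_site <- type %in% c("cerp2_promoter", "cele2_promoter", "plain_promoter",
                            "single_m1", "single_m2")
    site <- if (has_site) {
      si <<- si + 1L
      data.frame(site_id = sprintf("%s_pk%04d", prefix, si), chrom = chrom,
                 start = off + geo$site[1] - 1L, end = off + geo$site[2] - 1L,
                 gene_id = id, germline = gl, stringsAsFactors = FALSE)
    } else NULL
    fam <- switch(type, cerp2_promoter = "CERP2_like",
                  cele2_promoter = "CELE2_like",
                  window_pair = "CERP2_like",
                  single_m1 = "single_m1", single_m2 = "single_m2", NULL)
    erow <- NULL
    if (!is.null(fam)) {
      pl <- plant_element(cfg, chrom, off + geo$elem_center - 1L, fam)
      edits[[length(edits) + 1L]] <<- pl
      erow <- pl$row
      erow$is_promoter <- has_site
      erow$is_germline_specific <- has_site && gl
      erow$gene_id <- id
    }
    list(gene = g, site = site, elem = erow)
  }

  bidir_ids <- if (cfg$n_bidirectional > 0) {
    sprintf("%s_gb%03d", prefix, seq_len(2L * cfg$n_bidirectional))
  } else character(0)
  bi <- 0L
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r, ]
    if (b$kind == "gene") {
      gi <- gi + 1L
      res <- add_gene(gene_ids_regular[gi], b$chrom, b$start,
                      sample(c("+", "-"), 1L), types[gi], germline[gi])
      gene_rows[[length(gene_rows) + 1L]] <- res$gene
      if (!is.null(res$site)) site_rows[[length(site_rows) + 1L]] <- res$site
      if (!is.null(res$elem)) elem_rows[[length(elem_rows) + 1L]] <- res$elem
    } else if (b$kind == "bidir") {
      # divergent gene pair sharing one central accessible site
      off <- b$start
      gl <- germline[n_genes + bi + 1L]
      si <- si + 1L
      site <- data.frame(site_id = sprintf("%s_pk%04d", prefix, si),
                         chrom = b$chrom, start = off + 2150L, end = off + 2449L,
                         gene_id = NA_character_, germline = gl,
                         stringsAsFactors = FALSE)
      gp <- data.frame(gene_id = bidir_ids[bi + 1L], chrom = b$chrom, strand = "+",
                       tss = off + 2750L, exon1_start = off + 2750L,
                       exon1_end = off + 2949L, body_start = off + 2750L,
                       body_end = off + 4249L, stringsAsFactors = FALSE)
      gm <- data.frame(gene_id = bidir_ids[bi + 2L], chrom = b$chrom, strand = "-",
                       tss = off + 1850L, exon1_start = off + 1651L,
                       exon1_end = off + 1850L, body_start = off + 350L,
                       body_end = off + 1850L, stringsAsFactors = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- gp
      gene_rows[[length(gene_rows) + 1L]] <- gm
      site$gene_id <- paste(gp$gene_id, gm$gene_id, sep = ",")
      site_rows[[length(site_rows) + 1L]] <- site
      bi <- bi + 2L
    } else {
      ii <- ii + 1L
      pl <- plant_element(cfg, b$chrom, b$start + 200L, inter_family[ii])
      edits[[length(edits) + 1L]] <- pl
      erow <- pl$row
      erow$is_promoter <- FALSE
      erow$is_germline_specific <- FALSE
      erow$gene_id <- NA_character_
      elem_rows[[length(elem_rows) + 1L]] <- erow
    }
  }
  # apply all planted-element edits, one subassignment per chromosome
  edit_chrom <- vapply(edits, `[[`, character(1), "chrom")
  for (ch in unique(edit_chrom)) {
    sel <- which(edit_chrom == ch)
    seqs[[ch]][unlist(lapply(edits[sel], `[[`, "pos"))] <-
      unlist(lapply(edits[sel], `[[`, "bases"))
  }

  genes <- gene_models(do.call(rbind, gene_rows))
  sites <- do.call(rbind, site_rows)
  elems <- if (length(elem_rows)) do.call(rbind, elem_rows) else NULL
  elems <- elems[, c("chrom", "start", "end", "family", "arrangement", "spacing",
                     "m1_start", "m1_end", "m1_strand",
                     "m2_start", "m2_end", "m2_strand",
                     "is_promoter", "is_germline_specific", "gene_id")]
  elems$element_id <- sprintf("%s_el%04d", prefix, seq_len(nrow(elems)))

  # scrub chance motif hits from the background
  has1 <- !is.na(elems$m1_start); has2 <- !is.na(elems$m2_start)
  planted <- GenomicRanges::GRanges(
    c(elems$chrom[has1], elems$chrom[has2]),
    IRanges::IRanges(c(elems$m1_start[has1], elems$m2_start[has2]),
                     c(elems$m1_end[has1], elems$m2_end[has2])),
    strand = c(elems$m1_strand[has1], elems$m2_strand[has2]),
    motif = c(rep("m1", sum(has1)), rep("m2", sum(has2))))
  sc <- scrub_background(seqs, cfg, pwms, planted)
  seqs <- sc$seqs
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- names(cfg$chrom_lengths)

  # ATAC counts and tracks
  sites_gr <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$start, sites$end))
  names(sites_gr) <- sites$site_id
  nrep <- cfg$n_replicates
  mk_counts <- function(high_mask) {
    base <- ifelse(high_mask, cfg$atac_high, cfg$atac_low)
    m <- replicate(nrep, if (cfg$count_noise == "poisson") rpois(length(base), base)
                   else base)
    m
  }
  wt <- mk_counts(rep(TRUE, nrow(sites)))
  gl <- mk_counts(!sites$germline)
  counts <- cbind(wt, gl)
  colnames(counts) <- c(paste0("wt_", seq_len(nrep)), paste0("gl_", seq_len(nrep)))

  atac_tracks <- lapply(seq_len(ncol(counts)), function(j) {
    seg <- sites_gr
    seg$score <- counts[, j] / GenomicRanges::width(sites_gr)
    track_from_segments(seg, chrom_sizes(genome), stranded = FALSE)
  })
  names(atac_tracks) <- colnames(counts)

  # RNA track: outron + first exon signal for every active promoter
  rna_segs <- list()
  for (i in seq_len(nrow(sites))) {
    gids <- strsplit(sites$gene_id[i], ",")[[1]]
    gids <- gids[!is.na(gids)]
    if (!length(gids) && is.na(sites$gene_id[i])) next
    for (gid in gids) {
      gene <- genes[genes$gene_id == gid, ]
      seg <- simulate_rna_outron(
        gene, sites_gr[i], cfg$rna_height, cfg$rna_gap_rate, cfg$rna_max_gap)
      rna_segs[[length(rna_segs) + 1L]] <- seg
    }
  }
  rna <- track_from_segments(
    if (length(rna_segs)) do.call(c, rna_segs) else
      GenomicRanges::GRanges(score = numeric(0)),
    chrom_sizes(genome), stranded = TRUE)

  list(prefix = prefix, genome = genome, genes = genes, sites = sites,
       sites_gr = sites_gr, counts = counts, atac_tracks = atac_tracks,
       rna = rna, elements = elems, types = types, germline = germline,
       scrub_rounds = sc$rounds)
}

# ---- world assembly ----------------------------------------------------------

#' Generate the synthetic two-species world
#'
#' Builds two species ("elegans-like" A with prefix `ce`, "briggsae-like" B
#' with prefix `cb`) from a shared ortholog scaffold, plants MITE-like
#' elements, simulates ATAC counts, stranded RNA coverage, a DE table and
#' ChIP peaks for species A, and writes every file plus the truth tables.
#' Identical seeds give byte-identical outputs.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory (created). `NULL` skips file output and
#'   returns the in-memory world only.
#' @return A `synthetic_world` list: `config`, `species$a`, `species$b`
#'   (genomes, gene models, sites, counts, tracks, element truth),
#'   `orthologs`, `truth_orthologs`, `pwms`, `paths`.
#' @export
generate_world <- function(cfg = synthetic_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  pwms <- list(m1 = pwm_from_consensus("m1", cfg$m1_consensus, cfg$pwm_match_prob),
               m2 = pwm_from_consensus("m2", cfg$m2_consensus, cfg$pwm_match_prob))
  types_a <- plan_types_a(cfg)
  pb <- plan_types_b(cfg, types_a)
  seed_a <- sub_seed(cfg$seed, 1L)
  seed_b <- sub_seed(cfg$seed, 2L)
  sp_a <- build_species(cfg, "ce", types_a, pwms, seed_a)
  # conserved pairs keep the A germline status on the B side
  germ_b <- runif(length(sp_a$germline)) < cfg$germline_fraction
  conserved_idx <- which(!is.na(pb$class_pair) & pb$class_pair == "conserved")
  germ_b[conserved_idx] <- sp_a$germline[conserved_idx]
  sp_b <- build_species(cfg, "cb", pb$types_b, pwms, seed_b, germline = germ_b)

  set.seed(sub_seed(cfg$seed, 3L))
  # ---- ChIP peaks and DE for species A
  # per-gene view of the site table (bidirectional sites list two gene ids)
  site_map <- do.call(rbind, lapply(seq_len(nrow(sp_a$sites)), function(i) {
    data.frame(gene_id = strsplit(sp_a$sites$gene_id[i], ",")[[1]],
               site_row = i, germline = sp_a$sites$germline[i],
               stringsAsFactors = FALSE)
  }))
  coopted_genes <- sprintf("ce_g%04d",
                           which(types_a %in% c("cerp2_promoter", "cele2_promoter")))
  plain_prom_genes <- setdiff(site_map$gene_id, coopted_genes)
  plain_bound <- plain_prom_genes[runif(length(plain_prom_genes)) <
                                    cfg$chip_plain_fraction]
  bound_rows <- unique(site_map$site_row[site_map$gene_id %in%
                                           c(coopted_genes, plain_bound)])
  # binding is a property of the site: every gene sharing a bound site is bound
  bound_genes <- site_map$gene_id[site_map$site_row %in% bound_rows]
  chip_rows <- sp_a$sites[bound_rows, ]
  chip_gr <- GenomicRanges::GRanges(
    chip_rows$chrom,
    IRanges::IRanges(pmax(1L, chip_rows$start - 50L), chip_rows$end + 50L))
  # false-positive peaks on random intergenic spots
  if (cfg$chip_false_positives > 0) {
    bodies <- gene_body_ranges(sp_a$genes)
    fp <- shuffle_intervals(
      GenomicRanges::GRanges(
        rep(names(cfg$chrom_lengths)[1], cfg$chip_false_positives),
        IRanges::IRanges(rep(1L, cfg$chip_false_positives), width = 200L)),
      chrom_sizes(sp_a$genome), c(bodies, sp_a$sites_gr))
    chip_gr <- c(chip_gr, fp)
  }
  names(chip_gr) <- sprintf("chip_%04d", seq_along(chip_gr))

  gene_ids <- sp_a$genes$gene_id
  has_prom <- gene_ids %in% site_map$gene_id
  is_coopt <- gene_ids %in% coopted_genes
  is_bound <- gene_ids %in% bound_genes
  is_germ <- has_prom & gene_ids %in% site_map$gene_id[site_map$germline]
  p_down <- ifelse(is_coopt, cfg$p_down_coopted,
                   ifelse(is_bound, cfg$p_down_plain_bound, cfg$p_down_other))
  down <- runif(length(gene_ids)) < p_down
  up <- !down & runif(length(gene_ids)) < cfg$p_up
  de <- data.frame(
    gene_id = gene_ids,
    lfc = ifelse(down, -runif(length(gene_ids), 1, 4),
                 ifelse(up, runif(length(gene_ids), 1, 4),
                        stats::rnorm(length(gene_ids), 0, 0.3))),
    padj = ifelse(down | up, 10^-runif(length(gene_ids), 4, 10),
                  runif(length(gene_ids), 0.05, 1)),
    stringsAsFactors = FALSE)
  type_of <- setNames(c(types_a, rep("bidirectional",
                                     sum(grepl("^ce_gb", gene_ids)))),
                      c(sprintf("ce_g%04d", seq_along(types_a)),
                        grep("^ce_gb", gene_ids, value = TRUE)))
  truth_genes_a <- data.frame(
    gene_id = gene_ids,
    type = unname(type_of[gene_ids]),
    has_promoter = has_prom,
    is_germline_specific = is_germ,
    direction = ifelse(down, "down", ifelse(up, "up", "ns")),
    bound = is_bound,
    is_direct_target = down & is_bound,
    has_coopted_promoter = is_coopt,
    stringsAsFactors = FALSE)

  orthologs <- ortholog_pairs(sprintf("ce_g%04d", seq_along(types_a)),
                              sprintf("cb_g%04d", seq_along(types_a)))
  truth_orthologs <- cbind(orthologs,
                           data.frame(eligible = !is.na(pb$class_pair),
                                      class = pb$class_pair,
                                      stringsAsFactors = FALSE))

  world <- list(config = cfg, pwms = pwms,
                species = list(a = sp_a, b = sp_b),
                chip_peaks = chip_gr, de = de,
                truth_genes_a = truth_genes_a,
                orthologs = orthologs, truth_orthologs = truth_orthologs,
                seeds = c(master = cfg$seed, species_a = seed_a,
                          species_b = seed_b, annex = sub_seed(cfg$seed, 3L)))
  class(world) <- "synthetic_world"
  if (!is.null(out_dir)) world <- write_world(world, out_dir)
  world
}

write_species_files <- function(sp, dir, cfg) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(dir, f)
  write_genome(sp$genome, p("genome.fa")); paths <- c(paths, p("genome.fa"))
  write_gene_models(sp$genes, p("genes.gff3")); paths <- c(paths, p("genes.gff3"))
  sg <- sp$sites_gr; sg$name <- names(sg)
  write_intervals(sg, p("peaks.bed")); paths <- c(paths, p("peaks.bed"))
  rep_rows <- sp$elements[sp$elements$family %in% c("CERP2_like", "CELE2_like"), ]
  rp <- GenomicRanges::GRanges(rep_rows$chrom,
                               IRanges::IRanges(rep_rows$start, rep_rows$end))
  rp$name <- paste0(rep_rows$family, "|", rep_rows$element_id)
  write_intervals(rp, p("repeats.bed")); paths <- c(paths, p("repeats.bed"))
  cdf <- cbind(data.frame(peak_id = sp$sites$site_id), as.data.frame(sp$counts))
  write_tsv_table(cdf, p("atac_counts.tsv")); paths <- c(paths, p("atac_counts.tsv"))
  for (nm in names(sp$atac_tracks)) {
    f <- p(sprintf("atac_%s.bedGraph", nm))
    write_coverage(sp$atac_tracks[[nm]], f); paths <- c(paths, f)
  }
  paths <- c(paths, write_coverage(sp$rna, p("rna")))
  write_tsv_table(sp$elements, p("truth_elements.tsv"))
  paths <- c(paths, p("truth_elements.tsv"))
  paths
}

write_world <- function(world, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- world$config
  paths <- c(write_species_files(world$species$a, file.path(out_dir, "species_a"), cfg),
             write_species_files(world$species$b, file.path(out_dir, "species_b"), cfg))
  p <- function(f) file.path(out_dir, f)
  ch <- world$chip_peaks; ch$name <- names(ch)
  write_intervals(ch, p("chip_peaks.bed")); paths <- c(paths, p("chip_peaks.bed"))
  write_tsv_table(world$de, p("de.tsv")); paths <- c(paths, p("de.tsv"))
  write_tsv_table(world$orthologs, p("orthologs.tsv"))
  paths <- c(paths, p("orthologs.tsv"))
  write_tsv_table(world$truth_genes_a, p("truth_genes.tsv"))
  paths <- c(paths, p("truth_genes.tsv"))
  write_tsv_table(world$truth_orthologs, p("truth_orthologs.tsv"))
  paths <- c(paths, p("truth_orthologs.tsv"))
  write_meme(world$pwms, p("motifs.meme"),
             background = cfg$base_composition)
  paths <- c(paths, p("motifs.meme"))
  # flat manifest: config echo, seeds, md5 checksums
  man <- c("# synthetic world manifest",
           sprintf("seed: %d", cfg$seed),
           sprintf("seed_species_a: %d", world$seeds[["species_a"]]),
           sprintf("seed_species_b: %d", world$seeds[["species_b"]]),
           sprintf("seed_annex: %d", world$seeds[["annex"]]),
           sprintf("scrub_rounds_a: %d", world$species$a$scrub_rounds),
           sprintf("scrub_rounds_b: %d", world$species$b$scrub_rounds),
           "checksums:",
           sprintf("  %s: %s", basename(paths), unname(tools::md5sum(paths))))
  writeLines(man, p("manifest.yaml"))
  world$paths <- c(paths, p("manifest.yaml"))
  world$dir <- out_dir
  world
}
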
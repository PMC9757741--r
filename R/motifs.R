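# Motif machinery: position weight matrices, genome scanning with exact
# p-values computed by dynamic programming over a discretized score
# distribution (the FIMO approach), m1/m2 pair annotation with arrangement
# classes, co-option flagging, and the TT-dinucleotide periodicity profile.

DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param name Motif name (e.g. `"m1"`, `"m2"`).
#' @param mat 4 x w numeric matrix of per-position base probabilities, rows
#'   A, C, G, T; each column must sum to 1 within 1e-9. Width >= 4.
#' @param pseudocount Fraction of background probability mixed into each cell
#'   before log-odds are taken (keeps scores finite at zero cells).
#' @return A `pwm` object.
#' @export
pwm <- function(name, mat, pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("pwm: matrix must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 4L) stop("pwm: width must be >= 4")
  if (any(colSums(mat) == 0)) stop("pwm: column summing to 0")
  if (any(abs(colSums(mat) - 1) > 1e-9)) stop("pwm: columns must sum to 1")
  if (any(mat < 0)) stop("pwm: negative probabilities")
  rownames(mat) <- DNA
  structure(list(name = name, mat = mat, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, pseudocount %g\n", x$name, ncol(x$mat),
              x$pseudocount))
  invisible(x)
}

#' PWM width
#' @param x A `pwm`.
#' @return Integer width.
#' @export
pwm_width <- function(x) ncol(x$mat)

#' Build a sharp PWM from a consensus string
#'
#' Gives the consensus base probability `match_prob` at each position and
#' splits the remainder evenly; used by the synthetic-data generator, whose
#' planted motifs are consensus-derived.
#'
#' @param name Motif name.
#' @param consensus DNA string over ACGT.
#' @param match_prob Probability of the consensus base (default 0.91).
#' @param pseudocount Passed to [pwm()].
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(name, consensus, match_prob = 0.91,
                               pseudocount = 0.001) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (!all(b %in% DNA)) stop("pwm_from_consensus: consensus must be over ACGT")
  mat <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(b),
                dimnames = list(DNA, NULL))
  mat[cbind(match(b, DNA), seq_along(b))] <- match_prob
  pwm(name, mat, pseudocount)
}

#' Reverse complement of a PWM
#' @param x A `pwm`.
#' @return A `pwm` scoring the reverse-complement motif.
#' @export
pwm_revcomp <- function(x) {
  pwm(x$name, x$mat[4:1, ncol(x$mat):1, drop = FALSE], x$pseudocount)
}

# ---- MEME minimal format -----------------------------------------------------

#' Read motifs in MEME minimal format
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of [pwm()] objects; the file's background line (if any)
#'   is attached as attribute `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- NULL
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])[DNA]
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) stop("read_meme: no MOTIF entries in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hi <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
    rows <- lines[(hi + 1):(hi + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4), USE.NAMES = FALSE))
    # MEME rows are positions; renormalize tiny rounding drift from text files
    mat <- t(mat / rowSums(mat))
    out[[name]] <- pwm(name, mat)
  }
  attr(out, "background") <- bg
  out
}

#' Write motifs in MEME minimal format
#'
#' @param pwms List of [pwm()] objects.
#' @param path Output path.
#' @param background Optional named base-frequency vector (A,C,G,T).
#' @return Invisibly, `path`.
#' @export
write_meme <- function(pwms, path, background = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", ""), con)
  if (!is.null(background)) {
    writeLines(c("Background letter frequencies",
                 paste(sprintf("%s %.6f", DNA, background[DNA]), collapse = " "), ""),
               con)
  }
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(p$mat)), con)
    writeLines(apply(p$mat, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- background and score tables --------------------------------------------

#' Estimate a 0-order background from sequence
#'
#' Mononucleotide composition, complement-symmetrized (A and T pooled, C and
#' G pooled) so plus- and minus-strand scans share one null distribution.
#'
#' @param genome `DNAStringSet`, `DNAString`, or character vector.
#' @return Named numeric vector over A,C,G,T summing to 1.
#' @export
estimate_background <- function(genome) {
  genome <- as_dss(genome)
  counts <- colSums(Biostrings::letterFrequency(genome, DNA))
  if (sum(counts) == 0) stop("estimate_background: no ACGT content")
  at <- (counts["A"] + counts["T"]) / 2
  cg <- (counts["C"] + counts["G"]) / 2
  f <- c(A = at, C = cg, G = cg, T = at)
  f <- f / sum(f)
  # guard against degenerate compositions
  f <- pmax(f, 1e-4)
  setNames(f / sum(f), DNA)
}

as_dss <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (methods::is(genome, "DNAString")) return(Biostrings::DNAStringSet(genome))
  if (is.character(genome)) {
    dss <- Biostrings::DNAStringSet(genome)
    if (is.null(names(dss))) names(dss) <- paste0("seq", seq_along(dss))
    return(dss)
  }
  stop("expected DNAString(Set) or character sequence(s)")
}

# Integerized log-odds score table plus the exact null distribution of the
# integer score under the 0-order background, computed by DP (convolution of
# per-column score distributions). Scores are discretized once onto a common
# grid (`bins` bins across the attainable score range) and *both* the scan and
# the p-value lookup use the integer scores, so reported p-values are exact
# for the discretized matrix; discretization perturbs each window score by at
# most width * eps / 2.
pwm_score_table <- function(x, background, bins = 1000L) {
  p2 <- (1 - x$pseudocount) * x$mat + x$pseudocount * background
  if (any(p2 == 0)) stop("pwm_score_table: zero cell with zero pseudocount")
  S <- log2(p2 / background)
  rng <- sum(apply(S, 2, max)) - sum(apply(S, 2, min))
  eps <- if (rng > 0) rng / bins else 1
  I <- round(S / eps)
  q <- background[DNA]
  d <- 1; lo <- 0L
  for (j in seq_len(ncol(I))) {
    cmin <- min(I[, j]); cmax <- max(I[, j])
    nlo <- lo + cmin
    nd <- numeric(length(d) + (cmax - cmin))
    for (b in 1:4) {
      sh <- I[b, j] - cmin
      idx <- (1 + sh):(length(d) + sh)
      nd[idx] <- nd[idx] + d * q[b]
    }
    d <- nd; lo <- nlo
  }
  surv <- rev(cumsum(rev(d)))  # surv[k] = P(int score >= lo + k - 1)
  list(I = I, eps = eps, lo = lo, surv = surv, width = ncol(I))
}

# p-value of integer scores against a score table
pwm_int_pvalue <- function(tab, s_int) {
  k <- s_int - tab$lo + 1L
  k <- pmin(pmax(k, 1L), length(tab$surv) + 1L)
  out <- numeric(length(k))
  inside <- k <= length(tab$surv)
  out[inside] <- tab$surv[k[inside]]
  out[!inside] <- 0
  pmin(out, 1)
}

#' Exact p-value of a PWM score
#'
#' P(score >= s) for a window drawn from the 0-order background, computed by
#' exact dynamic programming over the discretized score distribution.
#'
#' @param x A `pwm`.
#' @param scores Numeric log2 odds score(s).
#' @param background Named base-frequency vector (A,C,G,T).
#' @param bins Number of discretization bins across the score range.
#' @return Numeric p-value(s).
#' @export
pwm_score_pvalue <- function(x, scores, background, bins = 1000L) {
  tab <- pwm_score_table(x, background, bins)
  pwm_int_pvalue(tab, as.integer(round(scores / tab$eps)))
}

# ---- scanning ----------------------------------------------------------------

# Candidate windows are located at C speed with Biostrings::matchPWM on the
# integerized score matrix (score >= the smallest integer score whose exact
# p-value passes the threshold), then windows containing non-ACGT letters are
# dropped (FIMO skips them; matchPWM would weight them 0).
scan_one_strand <- function(subject, tab, p_threshold) {
  k <- which(tab$surv <= p_threshold)[1]
  if (is.na(k)) return(list(pos = integer(0), s = integer(0)))
  t_int <- tab$lo + k - 1L
  I <- tab$I
  storage.mode(I) <- "double"
  hits <- suppressWarnings(Biostrings::matchPWM(I, subject, min.score = t_int))
  pos <- BiocGenerics::start(hits)
  if (length(pos)) {
    af <- Biostrings::alphabetFrequency(hits, baseOnly = TRUE)
    pos <- pos[af[, "other"] == 0L]
  }
  if (!length(pos)) return(list(pos = integer(0), s = integer(0)))
  s <- as.integer(suppressWarnings(
    Biostrings::PWMscoreStartingAt(I, subject, pos)))
  list(pos = pos, s = s)
}

#' Scan a genome with a PWM
#'
#' Both strands are scanned with log-odds scores against a 0-order background;
#' the p-value of a score is computed exactly by dynamic programming over the
#' discretized score distribution under that background, and windows with
#' p <= `p_threshold` are reported (the FIMO convention, default P < 0.0005).
#' Windows containing N are skipped. With the default complement-symmetrized
#' background the two strands share one null distribution, and scanning the
#' reverse-complement genome yields the mirror-image hit set.
#'
#' @param genome `DNAStringSet` (or character vector) of chromosome sequences.
#' @param x A [pwm()].
#' @param p_threshold Report occurrences with p-value <= this (default 5e-4).
#' @param background Optional named A/C/G/T frequency vector; default
#'   estimated from `genome` via [estimate_background()].
#' @param bins Score-discretization bins (default 1000).
#' @return `GRanges` of occurrences sorted by position, with metadata columns
#'   `motif`, `score` (log2 odds, discretized), `pvalue`.
#' @export
scan_pwm <- function(genome, x, p_threshold = 0.0005, background = NULL,
                     bins = 1000L) {
  genome <- as_dss(genome)
  if (is.null(background)) background <- estimate_background(genome)
  background <- background[DNA] / sum(background[DNA])
  tab_f <- pwm_score_table(x, background, bins)
  tab_r <- pwm_score_table(pwm_revcomp(x), background, bins)
  w <- pwm_width(x)
  res <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (st in c("+", "-")) {
      tab <- if (st == "+") tab_f else tab_r
      hit <- scan_one_strand(subject, tab, p_threshold)
      p <- pwm_int_pvalue(tab, hit$s)
      keep <- p <= p_threshold
      if (!any(keep)) next
      res[[length(res) + 1L]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(hit$pos[keep], width = w), strand = st,
        motif = x$name, score = hit$s[keep] * tab$eps, pvalue = p[keep])
    }
  }
  if (!length(res)) {
    return(GenomicRanges::GRanges(motif = character(0), score = numeric(0),
                                  pvalue = numeric(0)))
  }
  out <- do.call(c, res)
  out[order(as.character(GenomicRanges::seqnames(out)), GenomicRanges::start(out),
            as.character(GenomicRanges::strand(out)))]
}

# ---- pairing and arrangement classification ---------------------------------

#' Pair m1 and m2 occurrences and classify their arrangement
#'
#' Every (m1, m2) occurrence pair on one chromosome whose inter-motif gap
#' (bases strictly between the two occurrence intervals) lies within
#' `[min_spacing, max_spacing]` is emitted. Arrangements follow inverted-
#' repeat geometry: *divergent* = opposite strands pointing away from each
#' other (left motif on -, right on +), *convergent* = opposite strands
#' pointing toward each other, *tandem* = same strand, named by 5'-to-3'
#' order along that strand. Family hints: `CERP2_like` iff divergent with
#' spacing 12-16 bp; `CELE2_like` iff tandem m2+m1+ with spacing 23-28 bp.
#' Overlapping occurrences (negative spacing) are excluded.
#'
#' @param m1_hits,m2_hits `GRanges` of occurrences from [scan_pwm()].
#' @param min_spacing,max_spacing Allowed gap in bp (defaults 10 and 30).
#' @return `GRanges` of pair footprints (leftmost to rightmost motif base)
#'   with metadata: coordinates/strands of both motifs, `spacing`,
#'   `arrangement`, `family`.
#' @export
pair_and_classify <- function(m1_hits, m2_hits, min_spacing = 10L,
                              max_spacing = 30L) {
  empty <- GenomicRanges::GRanges(
    m1_start = integer(0), m1_end = integer(0), m1_strand = character(0),
    m2_start = integer(0), m2_end = integer(0), m2_strand = character(0),
    spacing = integer(0), arrangement = character(0), family = character(0))
  if (!length(m1_hits) || !length(m2_hits)) return(empty)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(
    m1_hits, m2_hits, maxgap = max_spacing, ignore.strand = TRUE))
  if (!length(ov)) return(empty)
  a <- m1_hits[S4Vectors::queryHits(ov)]
  b <- m2_hits[S4Vectors::subjectHits(ov)]
  s1 <- GenomicRanges::start(a); e1 <- GenomicRanges::end(a)
  s2 <- GenomicRanges::start(b); e2 <- GenomicRanges::end(b)
  gap <- pmax(s2 - e1, s1 - e2) - 1L
  keep <- gap >= min_spacing & gap <= max_spacing
  if (!any(keep)) return(empty)
  a <- a[keep]; b <- b[keep]; gap <- gap[keep]
  s1 <- s1[keep]; e1 <- e1[keep]; s2 <- s2[keep]; e2 <- e2[keep]
  st1 <- as.character(GenomicRanges::strand(a))
  st2 <- as.character(GenomicRanges::strand(b))
  m1_left <- s1 < s2
  left_st <- ifelse(m1_left, st1, st2)
  right_st <- ifelse(m1_left, st2, st1)
  arrangement <- ifelse(
    st1 == st2,
    # same strand: 5'->3' order along that strand
    ifelse((st1 == "+") == m1_left, "tandem_m1_m2", "tandem_m2_m1"),
    ifelse(left_st == "-" & right_st == "+", "divergent", "convergent"))
  family <- rep("none", length(arrangement))
  family[arrangement == "divergent" & gap >= 12 & gap <= 16] <- "CERP2_like"
  family[arrangement == "tandem_m2_m1" & gap >= 23 & gap <= 28] <- "CELE2_like"
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(a),
    IRanges::IRanges(pmin(s1, s2), pmax(e1, e2)),
    strand = "*",
    m1_start = s1, m1_end = e1, m1_strand = st1,
    m2_start = s2, m2_end = e2, m2_strand = st2,
    spacing = gap, arrangement = arrangement, family = family)
  out[order(as.character(GenomicRanges::seqnames(out)), GenomicRanges::start(out))]
}

#' Flag promoters as co-opted
#'
#' A promoter is co-opted iff its site interval overlaps at least one m1m2
#' pair footprint (leftmost to rightmost motif base).
#'
#' @param promoters Promoter-call data.frame from [annotate_promoters()].
#' @param pairs Pair `GRanges` from [pair_and_classify()].
#' @return `promoters` with `is_coopted` (and `coopted_family`, the family of
#'   an overlapping pair, CERP2_like taking precedence) filled in.
#' @export
flag_coopted <- function(promoters, pairs) {
  if (!nrow(promoters)) {
    promoters$is_coopted <- logical(0)
    promoters$coopted_family <- character(0)
    return(promoters)
  }
  sites <- GenomicRanges::GRanges(promoters$chrom,
                                  IRanges::IRanges(promoters$start, promoters$end))
  promoters$is_coopted <- FALSE
  promoters$coopted_family <- "none"
  if (length(pairs)) {
    ov <- GenomicRanges::findOverlaps(sites, pairs, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    fam <- pairs$family[S4Vectors::subjectHits(ov)]
    promoters$is_coopted[unique(qh)] <- TRUE
    # prefer a named family over "none", CERP2_like over CELE2_like
    rank <- c(CERP2_like = 3, CELE2_like = 2, none = 1)
    best <- tapply(rank[fam], qh, max)
    promoters$coopted_family[as.integer(names(best))] <-
      names(rank)[match(best, rank)]
  }
  promoters
}

#' Extract pair-anchored sequence windows
#'
#' Returns the sequence of each pair footprint plus `flank` bp on each side,
#' oriented by the m1 strand (reverse-complemented when m1 is on the minus
#' strand) — the input used for cross-element comparisons such as guide-tree
#' construction or the TT-periodicity profile.
#'
#' @param pairs Pair `GRanges` from [pair_and_classify()].
#' @param genome `DNAStringSet`.
#' @param flank Flank size in bp (default 50).
#' @return `DNAStringSet`; pairs whose window would leave the chromosome are
#'   dropped with a warning.
#' @export
pair_window_sequences <- function(pairs, genome, flank = 50L) {
  genome <- as_dss(genome)
  sizes <- chrom_sizes(genome)
  chr <- as.character(GenomicRanges::seqnames(pairs))
  s <- GenomicRanges::start(pairs) - flank
  e <- GenomicRanges::end(pairs) + flank
  ok <- s >= 1L & e <= sizes[chr]
  if (!all(ok)) warning(sum(!ok), " pair window(s) out of bounds; dropped")
  idx <- which(ok)
  seqs <- Biostrings::DNAStringSet(vapply(idx, function(i) {
    as.character(Biostrings::subseq(genome[[chr[i]]], s[i], e[i]))
  }, character(1)))
  flip <- pairs$m1_strand[idx] == "-"
  if (any(flip)) seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
  names(seqs) <- sprintf("%s:%d-%d", chr[idx], s[idx], e[idx])
  seqs
}

# ---- TT periodicity ----------------------------------------------------------

#' TT-dinucleotide periodicity profile
#'
#' Computes, over a set of equal-length anchored sequences, the frequency of
#' a TT dinucleotide starting at each offset, and a periodicity score: the
#' spectral power of the mean-centered profile at the given period divided by
#' the profile's total power. Germline promoters and the MITEs they derive
#' from carry a ~10-bp periodic TT bias linked to nucleosome positioning.
#'
#' @param seqs `DNAStringSet` or character vector, all the same length >= 2.
#' @param period Period in bp to score (default 10).
#' @return List with `profile` (per-offset TT frequency), `score` (fraction of
#'   power at `period`, in `[0,1]`; 0 for a flat profile), and `period`.
#' @export
tt_periodicity <- function(seqs, period = 10) {
  seqs <- as.character(as_dss(seqs))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("tt_periodicity: sequences must be equal length")
  if (L < 2L) stop("tt_periodicity: sequences shorter than 2")
  m <- t(vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    as.numeric(b[-length(b)] == "T" & b[-1] == "T")
  }, numeric(L - 1), USE.NAMES = FALSE))
  profile <- colMeans(m)
  x <- profile - mean(profile)
  total <- sum(x^2)
  if (total == 0) return(list(profile = profile, score = 0, period = period))
  t0 <- seq_along(x) - 1
  a <- sum(x * cos(2 * pi * t0 / period))
  b <- sum(x * sin(2 * pi * t0 / period))
  score <- min(1, (a^2 + b^2) * 2 / length(x) / total)
  list(profile = profile, score = score, period = period)
}

#' Spectral power share at each integer period
#'
#' Companion to [tt_periodicity()]: the share of total power attributed to
#' each candidate period, for checking that one period dominates.
#'
#' @param profile Numeric per-offset frequency profile.
#' @param periods Integer periods to evaluate.
#' @return Named numeric vector of power shares.
#' @export
periodicity_spectrum <- function(profile, periods = 2:25) {
  x <- profile - mean(profile)
  total <- sum(x^2)
  if (total == 0) return(setNames(rep(0, length(periods)), periods))
  t0 <- seq_along(x) - 1
  share <- vapply(periods, function(p) {
    a <- sum(x * cos(2 * pi * t0 / p))
    b <- sum(x * sin(2 * pi * t0 / p))
    (a^2 + b^2) * 2 / length(x) / total
  }, numeric(1))
  setNames(pmin(share, 1), periods)
}
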
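# PWM scanning with exact p-values, pair classification, TT periodicity

test_that("pwm constructor validates matrices", {
  m <- matrix(0.25, 4, 6)
  expect_s3_class(pwm("x", m), "pwm")
  bad <- m; bad[, 2] <- 0
  expect_error(pwm("x", bad), "0")
  expect_error(pwm("x", m[, 1:3]), "width")
  expect_error(pwm("x", matrix(c(0.5, 0.5, 0.5, -0.5), 4, 5)))
})

test_that("exact p-value DP equals exhaustive enumeration for widths 4-8", {
  set.seed(31)
  for (w in 4:8) {
    m <- matrix(runif(4 * w), 4)
    m <- sweep(m, 2, colSums(m), "/")
    x <- pwm(paste0("w", w), m)
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    tab <- mitecoopt:::pwm_score_table(x, bg)
    km <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- rowSums(vapply(seq_len(w), function(j) tab$I[km[, j], j],
                             numeric(nrow(km))))
    probs <- apply(km, 1, function(r) prod(bg[r]))
    # oracle: exact survival over all 4^w words under the background
    uniq <- sort(unique(scores))
    p_or <- vapply(uniq, function(s) sum(probs[scores >= s]), numeric(1))
    p_dp <- mitecoopt:::pwm_int_pvalue(tab, uniq)
    expect_equal(p_dp, p_or, tolerance = 1e-12)
    # discretization perturbs continuous scores by at most w * eps / 2
    S <- log2(((1 - x$pseudocount) * x$mat + x$pseudocount * bg) / bg)
    cont <- rowSums(vapply(seq_len(w), function(j) S[km[, j], j],
                           numeric(nrow(km))))
    expect_lte(max(abs(cont - scores * tab$eps)), w * tab$eps / 2 + 1e-9)
  }
})

test_that("scan finds an indicator PWM's string and respects strand symmetry", {
  set.seed(32)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE, prob = c(.32, .18, .18, .32)),
             collapse = "")
  motif <- "TATCCAGCCCTC"
  substr(s, 1501, 1512) <- motif
  x <- pwm_from_consensus("m1", motif)
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  hits <- scan_pwm(genome, x)
  plus <- hits[as.character(GenomicRanges::strand(hits)) == "+"]
  expect_true(1501 %in% GenomicRanges::start(plus))
  expect_true(all(hits$pvalue <= 0.0005))
  expect_true(all(GenomicRanges::width(hits) == pwm_width(x)))

  rcg <- Biostrings::reverseComplement(genome)
  names(rcg) <- names(genome)
  hits_rc <- scan_pwm(rcg, x)
  L <- nchar(s)
  mirror_start <- sort(L - GenomicRanges::end(hits) + 1L)
  expect_identical(sort(GenomicRanges::start(hits_rc)), mirror_start)
  flip <- c("+" = "-", "-" = "+")
  expect_identical(
    table(as.character(GenomicRanges::strand(hits_rc))),
    table(flip[as.character(GenomicRanges::strand(hits))]))
})

test_that("windows containing N are skipped and thresholds are monotone", {
  x <- pwm_from_consensus("m1", "TATCCAGCCCTC")
  s <- paste0(strrep("A", 50), "TATCCNGCCCTC", strrep("A", 50))
  hits <- scan_pwm(Biostrings::DNAStringSet(c(chr1 = s)), x,
                   background = c(A = .25, C = .25, G = .25, T = .25))
  expect_false(51 %in% GenomicRanges::start(hits))
  set.seed(33)
  s2 <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  g2 <- Biostrings::DNAStringSet(c(chr1 = s2))
  loose <- scan_pwm(g2, x, p_threshold = 0.005)
  tight <- scan_pwm(g2, x, p_threshold = 0.0005)
  k <- function(h) paste(GenomicRanges::start(h), GenomicRanges::strand(h))
  expect_true(all(k(tight) %in% k(loose)))
})

make_hit <- function(chrom, start, width, strand, motif) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width),
                         strand = strand, motif = motif, score = 10,
                         pvalue = 1e-6)
}

test_that("pair arrangement and family classification follow the geometry", {
  w1 <- 12L; w2 <- 10L
  # divergent, gap 14: m1 on minus (left), m2 on plus (right) -> CERP2-like
  m1 <- make_hit("chrI", 100, w1, "-", "m1")
  m2 <- make_hit("chrI", 100 + w1 + 14, w2, "+", "m2")
  p <- pair_and_classify(m1, m2)
  expect_identical(p$arrangement, "divergent")
  expect_identical(p$spacing, 14L)
  expect_identical(p$family, "CERP2_like")
  expect_identical(GenomicRanges::start(p), 100L)
  expect_identical(GenomicRanges::end(p), 100L + w1 + 14L + w2 - 1L)

  # tandem m2+ then m1+, gap 25 -> CELE2-like
  m2b <- make_hit("chrI", 500, w2, "+", "m2")
  m1b <- make_hit("chrI", 500 + w2 + 25, w1, "+", "m1")
  p2 <- pair_and_classify(m1b, m2b)
  expect_identical(p2$arrangement, "tandem_m2_m1")
  expect_identical(p2$family, "CELE2_like")

  # convergent: left +, right -
  p3 <- pair_and_classify(make_hit("chrI", 100, w1, "+", "m1"),
                          make_hit("chrI", 140, w2, "-", "m2"))
  expect_identical(p3$arrangement, "convergent")
  expect_identical(p3$family, "none")

  # tandem on minus strand: 5'->3' order along minus runs right-to-left
  p4 <- pair_and_classify(make_hit("chrI", 100, w1, "-", "m1"),
                          make_hit("chrI", 140, w2, "-", "m2"))
  expect_identical(p4$arrangement, "tandem_m2_m1")

  # spacing limits: 31 excluded, 10 and 30 included, overlap excluded
  expect_length(pair_and_classify(m1, GenomicRanges::shift(m2, 17)), 0)
  expect_length(pair_and_classify(m1, GenomicRanges::shift(m2, -4)), 1)
  expect_length(pair_and_classify(m1, GenomicRanges::shift(m2, 16)), 1)
  expect_length(pair_and_classify(make_hit("chrI", 100, w1, "-", "m1"),
                                  make_hit("chrI", 105, w2, "+", "m2")), 0)
  # different chromosomes never pair
  expect_length(pair_and_classify(m1, make_hit("chrII", 126, w2, "+", "m2")), 0)
})

test_that("pair classification is symmetric under genome-wide reverse complement", {
  set.seed(34)
  L <- 100000L
  for (rep in 1:5) {
    n1 <- 30L; n2 <- 30L
    h1 <- make_hit("c", sort(sample(L - 50L, n1)), 12L,
                   sample(c("+", "-"), n1, TRUE), "m1")
    h2 <- make_hit("c", sort(sample(L - 50L, n2)), 10L,
                   sample(c("+", "-"), n2, TRUE), "m2")
    p <- pair_and_classify(h1, h2)
    # mirror all hits
    mir <- function(h) {
      GenomicRanges::GRanges("c",
        IRanges::IRanges(L - GenomicRanges::end(h) + 1L,
                         L - GenomicRanges::start(h) + 1L),
        strand = c("+" = "-", "-" = "+")[as.character(GenomicRanges::strand(h))],
        motif = h$motif, score = h$score, pvalue = h$pvalue)
    }
    pm <- pair_and_classify(mir(h1), mir(h2))
    expect_identical(length(pm), length(p))
    key <- function(x) paste(GenomicRanges::start(x), x$arrangement, x$spacing,
                             x$family)
    mkey <- paste(L - GenomicRanges::end(p) + 1L, p$arrangement, p$spacing,
                  p$family)
    expect_setequal(key(pm), mkey)
  }
})

test_that("flag_coopted marks promoters overlapping a pair footprint only", {
  pr <- data.frame(chrom = "chrI", start = c(90, 400), end = c(160, 470),
                   site_id = c("s1", "s2"), gene_id = c("g1", "g2"),
                   is_germline_specific = TRUE)
  pairs <- pair_and_classify(make_hit("chrI", 100, 12, "-", "m1"),
                             make_hit("chrI", 126, 10, "+", "m2"))
  lone <- make_hit("chrI", 420, 12, "+", "m1")  # lone m1 inside s2
  out <- flag_coopted(pr, pairs)
  expect_identical(out$is_coopted, c(TRUE, FALSE))
  expect_identical(out$coopted_family, c("CERP2_like", "none"))
})

test_that("MEME minimal format round-trips", {
  dir <- withr::local_tempdir()
  pwms <- list(m1 = pwm_from_consensus("m1", "TATCCAGCCCTC"),
               m2 = pwm_from_consensus("m2", "TATTGTACTC"))
  f <- file.path(dir, "m.meme")
  write_meme(pwms, f, background = c(A = .32, C = .18, G = .18, T = .32))
  back <- read_meme(f)
  expect_named(back, c("m1", "m2"))
  expect_equal(back$m1$mat, pwms$m1$mat, tolerance = 1e-5)
  expect_equal(attr(back, "background"),
               c(A = .32, C = .18, G = .18, T = .32), tolerance = 1e-6)
})

test_that("tt_periodicity scores planted 10-bp TT periodicity", {
  allA <- rep(strrep("A", 60), 5)
  r <- tt_periodicity(allA)
  expect_identical(r$profile, rep(0, 59))
  expect_identical(r$score, 0)
  expect_error(tt_periodicity(c("A", "C")), "shorter")

  # a 10-bp repeating T-block pattern: the fundamental at period 10 carries
  # most of the power (harmonics decay as a sinc envelope)
  unit <- paste0(strrep("T", 5), strrep("A", 5))
  seqs <- rep(paste(rep(unit, 8), collapse = ""), 4)
  r10 <- tt_periodicity(seqs, period = 10)
  expect_gt(r10$score, 0.4)
  spec <- periodicity_spectrum(r10$profile, periods = 2:25)
  expect_identical(names(which.max(spec)), "10")

  # near-uniform random sequences: profile close to 1/16
  set.seed(35)
  rs <- vapply(1:400, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""), character(1))
  pr <- tt_periodicity(rs)$profile
  expect_lt(max(abs(pr - 1 / 16)), 4 * sqrt(1 / 16 * 15 / 16 / 400))
})

test_that("pair windows are extracted oriented by m1", {
  genome <- Biostrings::DNAStringSet(c(chrI = paste(rep("ACGT", 200), collapse = "")))
  pairs <- pair_and_classify(make_hit("chrI", 101, 12, "+", "m1"),
                             make_hit("chrI", 127, 10, "+", "m2"))
  fwd <- pair_window_sequences(pairs, genome, flank = 10)
  expect_identical(unname(nchar(as.character(fwd))), 10L + 36L + 10L)
  pairs_m <- pair_and_classify(make_hit("chrI", 101, 12, "-", "m1"),
                               make_hit("chrI", 127, 10, "-", "m2"))
  rev <- pair_window_sequences(pairs_m, genome, flank = 10)
  expect_identical(unname(as.character(rev)),
                   as.character(Biostrings::reverseComplement(fwd[[1]])))
  edge <- pair_and_classify(make_hit("chrI", 3, 12, "+", "m1"),
                            make_hit("chrI", 29, 10, "+", "m2"))
  expect_warning(pair_window_sequences(edge, genome, flank = 10), "dropped")
})
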
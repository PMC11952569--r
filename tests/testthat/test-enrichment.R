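toy_repeats <- function() {
  repeats(seqid = "chr", start = c(100, 150, 2000, 5000),
          end = c(200, 250, 2100, 5200), strand = "+",
          family = c("famA", "famA", "famA", "famB"),
          te_class = c("LTR", "LTR", "LTR", "LINE"),
          pct_div = c(1, 2, 3, 4))
}

test_that("composition unions overlapping copies and reports zero classes", {
  locus <- intervals("chr", 0, 1000)
  comp <- composition(toy_repeats(), locus)
  # two overlapping 100 bp LTR copies at 100-200 and 150-250 -> 150 bp
  expect_equal(comp$bp[comp$te_class == "LTR"], 150)
  expect_equal(comp$fraction[comp$te_class == "LTR"], 0.15)
  expect_equal(comp$bp[comp$te_class == "SINE"], 0)
  expect_error(composition(toy_repeats(), intervals("zzz", 0, 1)[0, ]),
               "zero length")
})

test_that("enrichment reproduces the bp-ratio formula", {
  # locus 1 kb of a 10 kb genome; 100 bp in locus, 200 bp genome-wide -> 5.0
  rep <- repeats("chr", c(0, 5000), c(100, 5100), "+", "fam", "LTR", c(1, 1))
  e <- te_enrichment(rep, "fam", intervals("chr", 0, 1000), 10000)
  expect_equal(e$ratio, 5)
  expect_equal(e$log2_ratio, log2(5), tolerance = 1e-12)
  expect_equal(round(e$log2_ratio, 4), 2.3219)
})

test_that("uniform density gives ratio exactly 1 and absent families are flagged", {
  # same fraction of locus and genome covered
  rep <- repeats("chr", c(0, 9000), c(100, 9900), "+", "fam", "LTR", c(1, 1))
  e <- te_enrichment(rep, "fam", intervals("chr", 0, 1000), 10000)
  expect_identical(e$ratio, 1)
  expect_identical(e$log2_ratio, 0)
  miss <- te_enrichment(rep, "nope", intervals("chr", 0, 1000), 10000)
  expect_false(miss$defined)
  expect_true(is.na(miss$ratio))
})

test_that("a family entirely inside the locus hits the algebraic limit", {
  rep <- repeats("chr", 100, 300, "+", "fam", "LTR", 1)
  e <- te_enrichment(rep, "fam", intervals("chr", 0, 1000), 25000)
  expect_equal(e$ratio, 25000 / 1000)
})

test_that("enrichment ratio is scale invariant", {
  rep <- repeats("chr", c(0, 5000), c(130, 5070), "+", "f", "LTR", c(1, 1))
  e1 <- te_enrichment(rep, "f", intervals("chr", 0, 1000), 10000)
  k <- 17
  rep2 <- repeats("chr", k * c(0, 5000), k * c(130, 5070), "+", "f", "LTR",
                  c(1, 1))
  e2 <- te_enrichment(rep2, "f", intervals("chr", 0, k * 1000), k * 10000)
  expect_equal(e1$ratio, e2$ratio)
})

test_that("permutation p is maximal for a self-overlap and 1 for full coverage", {
  set.seed(1)
  space <- intervals("chr", 0, 100000)
  query <- intervals("chr", c(1000, 50000), c(1500, 50500))
  res <- permutation_test(query, query, space, n_perm = 99)
  expect_equal(res$p_perm, 1 / 100)
  full <- intervals("chr", 0, 100000)
  res2 <- permutation_test(query, full, space, n_perm = 49)
  expect_equal(res2$p_perm, 1)
  expect_true(is.na(res2$z_score))  # degenerate null
})

test_that("an interval larger than every allowed block errors", {
  space <- intervals("chr", c(0, 5000), c(1000, 6000))
  query <- intervals("chr", 0, 3000)
  ref <- intervals("chr", 0, 10)
  expect_error(permutation_test(query, ref, space, n_perm = 9), "large enough")
})

test_that("family_fraction implements the midpoint rule", {
  # 4 of 16 copies have their midpoint in the locus -> 25%
  start <- c(seq(0, 300, by = 100), seq(10000, 11100, by = 100))
  rep <- repeats("chr", start, start + 50, "+", "fam", "LTR", 1)
  locus <- intervals("chr", 0, 400)
  expect_equal(family_fraction(rep, "fam", locus), 25)
  expect_equal(family_fraction(rep, "fam", intervals("chr", 0, 2e4)), 100)
  # a copy straddling the boundary with midpoint outside is excluded
  rep2 <- repeats("chr", c(390, 1000), c(450, 1050), "+", "fam", "LTR", 1)
  expect_equal(family_fraction(rep2, "fam", locus), 0)
  expect_error(family_fraction(rep2, "ghost", locus), "no genome-wide")
})

test_that("select_families applies both cutoffs and sorts by fraction", {
  mk <- function(fam, n_in, n_out) {
    s_in <- seq(0, by = 100, length.out = n_in)
    s_out <- seq(1e6, by = 100, length.out = n_out)
    repeats("chr", c(s_in, s_out), c(s_in, s_out) + 50, "+", fam, "LTR", 1)
  }
  locus <- intervals("chr", 0, 1e5)
  rep <- rbind(mk("hiFrac_lowN", 8, 250),    # 3.1% but only 8 copies
               mk("ok1", 11, 100),           # 9.9%, 11 copies
               mk("ok2", 12, 230),           # 5.0%, 12 copies
               mk("lowFrac", 11, 800))       # 1.4%
  sel <- select_families(rep, locus)
  expect_equal(sel$family, c("ok1", "ok2"))
  expect_true(all(diff(sel$fraction) <= 0))
})

test_that("peak filtering removes control overlaps then walks the thresholds", {
  mkpeaks <- function(n, q, fe, start0 = 0) {
    data.frame(seqid = "chr", start = start0 + seq(0, by = 1000,
                                                   length.out = n),
               end = start0 + seq(0, by = 1000, length.out = n) + 200,
               strand = ".", name = paste0("p", seq_len(n)),
               summit = 100, q_value = q, fold_enrichment = fe,
               stringsAsFactors = FALSE)
  }
  # 25 control-free peaks pass at the primary cutoff
  pk <- mkpeaks(25, 0.001, 12)
  got <- filter_peaks(pk, pk[0, ])
  expect_equal(nrow(got), 25)
  expect_equal(attr(got, "fe_cutoff"), 10)
  # 30 peaks, 15 with fe >= 10, 28 with fe >= 5 -> fallback fires
  pk2 <- mkpeaks(30, 0.005, c(rep(12, 15), rep(7, 13), rep(2, 2)))
  got2 <- filter_peaks(pk2, pk2[0, ])
  expect_equal(nrow(got2), 28)
  expect_equal(attr(got2, "fe_cutoff"), 5)
  # 1 bp overlap with a control peak removes a peak before thresholding
  ctl <- data.frame(seqid = "chr", start = 199, end = 300)
  got3 <- filter_peaks(mkpeaks(25, 0.001, 12), ctl)
  expect_equal(nrow(got3), 24)
  # monotonicity: the fallback set contains the primary set
  prim <- filter_peaks(pk2, pk2[0, ], min_peaks = 1)
  expect_true(all(prim$name %in% got2$name))
})
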
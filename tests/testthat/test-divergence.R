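test_that("tie_groups chains by sorted gaps and reports the tied fraction", {
  res <- tie_groups(c(1.0, 1.1, 1.2, 5.0, 9.0), epsilon = 0.2, min_size = 3)
  expect_equal(length(res$groups), 1)
  expect_equal(res$groups[[1]], 1:3)
  expect_equal(res$tied_fraction, 0.6)
  all_eq <- tie_groups(rep(4.2, 7))
  expect_equal(all_eq$tied_fraction, 1)
  spread <- tie_groups(c(0, 1, 2, 3), epsilon = 0.2)
  expect_equal(spread$tied_fraction, 0)
  expect_error(tie_groups(1:5, epsilon = -1), "epsilon")
  expect_equal(tie_groups(c(1, 1), min_size = 3)$tied_fraction, 0)
})

test_that("tie_groups equals the O(n^2) pairwise-chaining oracle", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    v <- round(runif(n, 0, 10), 2)
    eps <- sample(c(0.05, 0.2, 0.5), 1)
    got <- tie_groups(v, eps, min_size = 3)
    exp <- tie_groups_oracle(v, eps, min_size = 3)
    expect_equal(got$tied_fraction, exp$tied_fraction)
    ordg <- order(vapply(got$groups, function(g) min(v[g]), numeric(1)))
    expect_equal(got$groups[ordg], exp$groups)
  }
})

test_that("tie_group_test is maximal for identical copies and errors sensibly", {
  set.seed(3)
  genome <- runif(200, 0, 25)
  res <- tie_group_test(rep(3.7, 5), c(genome, rep(3.7, 5)),
                        n_resample = 200)
  expect_equal(res$p_resample, 1 / 201)
  expect_error(tie_group_test(1:10, 1:5), "at least as many")
})

test_that("locus values drawn from the genome continuum give calibrated p", {
  set.seed(21)
  pvals <- replicate(800, {
    genome <- runif(400, 0, 25)
    locus <- sample(genome, 80)
    tie_group_test(locus, genome, n_resample = 200)$p_resample
  })
  frac <- mean(pvals <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("divergence profiles restrict to the locus by midpoint rule", {
  rep <- repeats("chr", c(0, 1000, 5000), c(100, 1100, 5100), "+",
                 c("f", "f", "f"), "LTR", c(3.1, 1.0, 2.0))
  locus <- intervals("chr", 0, 200)
  pr <- divergence_profiles(rep, locus, c("f", "ghost"))
  expect_equal(pr$f$locus_values, 3.1)
  expect_equal(sort(pr$f$genome_values), c(1.0, 2.0, 3.1))
  expect_false(pr$ghost$present)
  expect_equal(length(pr$ghost$locus_values), 0)
  # locus values are a sub-multiset of genome values
  expect_true(all(pr$f$locus_values %in% pr$f$genome_values))
})

test_that("identity is 1 for identical sequences and counts substitutions", {
  s <- random_dna_str(100)
  s2 <- s
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                substr(s, 50, 50))[1]
  mat <- exon3_identity(c(a = s, b = s, c = s2))
  expect_equal(mat["a", "b"], 1)
  expect_equal(mat["a", "c"], 0.99)
  expect_equal(mat, t(mat), ignore_attr = TRUE)
  expect_equal(diag(mat), c(a = 1, b = 1, c = 1))
  expect_error(exon3_identity(c("ACGT", "")), "empty")
})

test_that("alignment scores equal an independent affine-gap DP oracle", {
  set.seed(5)
  # a fully-mismatched toy pair plus random pairs of varying length
  pairs <- c(list(c("ACGT", "TGCA")), lapply(1:50, function(i) {
    c(random_dna_str(sample(20:120, 1)), random_dna_str(sample(20:120, 1)))
  }))
  for (p in pairs) {
    mat <- exon3_identity(p)
    got <- attr(mat, "scores")[1, 2]
    expect_equal(got, nw_affine_score(p[1], p[2]))
  }
})

test_that("paralog clustering is single linkage with coordinate-order labels", {
  mat <- diag(1, 4)
  mat[1, 2] <- mat[2, 1] <- 0.97   # chain 1-2
  mat[2, 3] <- mat[3, 2] <- 0.96   # chain 2-3; 1-3 below threshold
  labs <- cluster_paralogs(mat, threshold = 0.95)
  expect_equal(unname(labs), c("A", "A", "A", "B"))
  none <- cluster_paralogs(diag(1, 3), threshold = 0.95)
  expect_equal(unname(none), c("A", "B", "C"))
  expect_error(cluster_paralogs(mat, threshold = 1.5), "threshold")
})

test_that("paralog labels are stable under permutation of the input", {
  set.seed(9)
  n <- 12
  base <- matrix(runif(n * n, 0.5, 1), n, n)
  mat <- (base + t(base)) / 2
  diag(mat) <- 1
  labs <- cluster_paralogs(mat, 0.9)
  perm <- sample(n)
  labs_p <- cluster_paralogs(mat[perm, perm], 0.9)
  # same partition: co-membership is preserved
  same <- outer(labs, labs, "==")
  same_p <- outer(labs_p, labs_p, "==")[order(perm), order(perm)]
  expect_equal(same, same_p, ignore_attr = TRUE)
})

test_that("find_blocks reports maximal repeated runs and reversals", {
  b <- find_blocks(strsplit("ABCDABC", "")[[1]])
  expect_equal(length(b), 1)
  expect_equal(b[[1]]$labels, c("A", "B", "C"))
  expect_equal(b[[1]]$occurrences$start, c(0, 4))
  expect_equal(find_blocks(LETTERS[1:10]), list())
  rv <- find_blocks(strsplit("ABCXCBA", "")[[1]])
  expect_equal(length(rv), 1)
  expect_equal(rv[[1]]$labels, c("A", "B", "C"))
  expect_equal(rv[[1]]$occurrences$orientation, c("forward", "reversed"))
})

test_that("a partial duplication surfaces only with an outside occurrence", {
  # (A,B) has a third occurrence outside the (A,B,C) blocks -> reported
  b <- find_blocks(strsplit("ABCDABCXAB", "")[[1]], min_len = 2)
  keys <- vapply(b, function(x) paste(x$labels, collapse = ""), character(1))
  expect_setequal(keys, c("ABC", "AB"))
  # without it, (A,B) is subsumed
  b2 <- find_blocks(strsplit("ABCDABC", "")[[1]], min_len = 2)
  keys2 <- vapply(b2, function(x) paste(x$labels, collapse = ""), character(1))
  expect_setequal(keys2, "ABC")
})

test_that("find_blocks equals the exhaustive enumeration oracle", {
  set.seed(13)
  canon <- function(labels) {
    f <- paste(labels, collapse = "")
    r <- paste(rev(labels), collapse = "")
    min(f, r)
  }
  for (i in 1:60) {
    n <- sample(8:30, 1)
    labels <- sample(LETTERS[1:sample(3:6, 1)], n, replace = TRUE)
    got <- find_blocks(labels, min_len = 3, min_occurrences = 2)
    exp <- blocks_oracle(labels, min_len = 3, min_occurrences = 2)
    got_k <- sort(vapply(got, function(b) {
      paste(canon(b$labels), paste(b$occurrences$start, collapse = ","))
    }, character(1)))
    exp_k <- sort(vapply(exp, function(b) {
      paste(canon(b$labels), paste(b$starts, collapse = ","))
    }, character(1)))
    expect_equal(got_k, exp_k)
  }
})
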
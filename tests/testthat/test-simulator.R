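toy_nahr_genome <- function(p_dup = 1) {
  cfg <- sim_config(genome_len = 50000, cluster_start = 0,
                    cluster_end = 50000, n_init_genes = 0,
                    init_line_density = 0, p_nahr = 1,
                    p_dup_given_nahr = p_dup, mu = 0, exon_mu = 0,
                    generations = 1, seed = 1, max_pair_dist = 30000,
                    te_families = default_te_families())
  seg <- data.frame(
    kind = c("neutral", "te", "gene", "gene", "neutral", "te", "neutral"),
    family = c(NA, "ERVK_sim", "g1", "g2", NA, "ERVK_sim", NA),
    te_class = c(NA, "LTR", NA, NA, NA, "LTR", NA),
    strand = c(".", "+", "+", "-", ".", "+", "."),
    len = c(5000, 500, 4000, 4000, 1500, 500, 34500),
    birth_gen = 0L, pct_div = c(NA, 0.5, NA, NA, NA, 0.5, NA),
    origin = "ancestral", in_cluster = TRUE, copy_id = 1:7,
    exon3 = c(NA, NA, "ACGTACGT", "GGGTTTCC", NA, NA, NA),
    fingers = c(NA, NA, "MC", "MC", NA, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(seg = seg, gen = 1L, next_id = 8L, config = cfg,
                 log = list()), class = "evolved_genome")
}

test_that("an empty cluster config yields an all-neutral genome", {
  cfg <- sim_config(genome_len = 1e5, cluster_start = 2e4, cluster_end = 4e4,
                    n_init_genes = 0, init_line_density = 0, seed = 1)
  set.seed(1)
  g <- init_genome(cfg)
  expect_true(all(g$seg$kind == "neutral"))
  expect_equal(genome_length(g), 1e5)
})

test_that("init seeds the requested genes inside the cluster", {
  cfg <- sim_config(genome_len = 1e6, cluster_start = 1e5, cluster_end = 4e5,
                    n_init_genes = 5, init_line_density = 10, seed = 2)
  set.seed(2)
  g <- init_genome(cfg)
  expect_equal(sum(g$seg$kind == "gene"), 5)
  expect_true(all(g$seg$in_cluster[g$seg$kind == "gene"]))
  expect_true(all(g$seg$pct_div[g$seg$kind == "te"] == 0))
  # a cluster too small for its genes errors
  tiny <- sim_config(genome_len = 1e6, cluster_start = 0, cluster_end = 5000,
                     n_init_genes = 5, seed = 1)
  set.seed(1)
  expect_error(init_genome(tiny), "too small")
})

test_that("segments tile the genome without gaps in every run", {
  for (s in 1:5) {
    g <- simulate_cluster(small_sim_config(s))
    expect_true(all(g$seg$len > 0))
    expect_equal(genome_length(g), sum(g$seg$len))
  }
})

test_that("simulation is deterministic given the seed", {
  g1 <- simulate_cluster(small_sim_config(99))
  g2 <- simulate_cluster(small_sim_config(99))
  expect_identical(g1$seg, g2$seg)
  expect_identical(length(g1$log), length(g2$log))
})

test_that("zero insertion rates leave the genome unchanged", {
  cfg <- small_sim_config(1)
  cfg$te_families$insertion_rate <- 0
  set.seed(1)
  g <- init_genome(cfg)
  before <- g$seg
  g$gen <- 1L
  g2 <- step_insertion(g)
  expect_identical(g2$seg, before)
})

test_that("with full cluster bias every new copy lands inside the cluster", {
  cfg <- small_sim_config(4)
  cfg$te_families <- data.frame(name = "ERVK_sim", class = "LTR",
                                consensus_len = 500, insertion_rate = 30,
                                cluster_bias = 1, stringsAsFactors = FALSE)
  set.seed(4)
  g <- init_genome(cfg)
  g$gen <- 1L
  g <- step_insertion(g)
  new <- g$seg[g$seg$origin == "insertion", ]
  expect_gt(nrow(new), 10)
  expect_true(all(new$in_cluster))
  # and genes were never split
  expect_equal(sum(g$seg$kind == "gene"), cfg$n_init_genes)
})

test_that("insertion counts follow the Poisson mean over many seeds", {
  rate <- 2
  gens <- 20
  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(genome_len = 5e5, cluster_start = 1e5,
                      cluster_end = 2e5, n_init_genes = 0,
                      init_line_density = 0, p_nahr = 0, mu = 0,
                      exon_mu = 0, generations = gens, seed = s,
                      te_families = data.frame(
                        name = "f", class = "LTR", consensus_len = 100,
                        insertion_rate = rate, cluster_bias = 0.2,
                        stringsAsFactors = FALSE))
    g <- simulate_cluster(cfg)
    sum(g$seg$kind == "te")
  }, numeric(1))
  expected <- rate * gens
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("an NAHR duplication copies the anchored span in tandem", {
  g <- toy_nahr_genome(p_dup = 1)
  set.seed(1)
  g2 <- step_nahr(g)
  expect_equal(genome_length(g2), 50000 + 10000)
  expect_equal(sum(g2$seg$kind == "gene"), 4)
  dup <- g2$seg[g2$seg$origin == "duplication", ]
  expect_equal(nrow(dup), 4)
  expect_equal(dup$pct_div[dup$kind == "te"], 0.5)
  expect_equal(sort(dup$exon3[dup$kind == "gene"]),
               sort(c("ACGTACGT", "GGGTTTCC")))
  # tandem: the copied block sits immediately left of the right anchor
  r <- which(g2$seg$kind == "te")[3]
  expect_equal(g2$seg$origin[r], "ancestral")
})

test_that("the deletion branch removes the span and keeps the right anchor", {
  g <- toy_nahr_genome(p_dup = 0)
  set.seed(1)
  g2 <- step_nahr(g)
  expect_equal(genome_length(g2), 50000 - 10000)
  expect_equal(sum(g2$seg$kind == "gene"), 0)
  expect_equal(sum(g2$seg$kind == "te"), 1)
})

test_that("genomes without a same-family pair are never rearranged", {
  g <- toy_nahr_genome()
  g$seg$family[g$seg$kind == "te"] <- c("A", "B")
  set.seed(1)
  expect_identical(step_nahr(g)$seg, g$seg)
})

test_that("mutation leaves the genome unchanged at zero rates", {
  g <- toy_nahr_genome()
  g$config$mu <- 0
  g$config$exon_mu <- 0
  set.seed(1)
  expect_identical(step_mutation(g)$seg, g$seg)
})

test_that("mean divergence of ancestral copies approaches mu * generations", {
  mu <- 0.05
  gens <- 40
  means <- vapply(1:50, function(s) {
    cfg <- sim_config(genome_len = 5e5, cluster_start = 1e5,
                      cluster_end = 3e5, n_init_genes = 0,
                      init_line_density = 50, p_nahr = 0, mu = mu,
                      exon_mu = 0, generations = gens, seed = s,
                      te_families = data.frame(
                        name = "L1", class = "LINE", consensus_len = 1000,
                        insertion_rate = 0, cluster_bias = 0,
                        stringsAsFactors = FALSE))
    g <- simulate_cluster(cfg)
    mean(g$seg$pct_div[g$seg$kind == "te"])
  }, numeric(1))
  expected <- mu * gens
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 1e-9)
})

test_that("copies born of one duplication share divergence then drift apart", {
  g <- toy_nahr_genome(p_dup = 1)
  g$config$mu <- 0.1
  set.seed(1)
  g2 <- step_nahr(g)
  te <- g2$seg[g2$seg$kind == "te", ]
  expect_equal(length(unique(te$pct_div)), 1)  # identical at birth
  g3 <- step_mutation(g2)
  te3 <- g3$seg[g3$seg$kind == "te", ]
  expect_true(all(te3$pct_div > te$pct_div))   # strictly nondecreasing
  expect_gt(length(unique(te3$pct_div)), 1)    # independent afterwards
})

test_that("generations = 0 reproduces init_genome and replay is exact", {
  cfg <- small_sim_config(5)
  cfg$generations <- 0
  g0 <- simulate_cluster(cfg)
  set.seed(cfg$seed)
  expect_identical(g0$seg, init_genome(cfg)$seg)
  g <- simulate_cluster(small_sim_config(5))
  r <- replay_log(g)
  expect_identical(r$seg, g$seg)
})

test_that("duplication-only runs never shrink; deletion-only never grow", {
  for (s in 1:5) {
    cfg <- small_sim_config(s, p_nahr = 0.05, p_dup_given_nahr = 1)
    g <- simulate_cluster(cfg)
    expect_gte(genome_length(g), sum(g$init_seg$len))
    cfg0 <- small_sim_config(s, p_nahr = 0.05, p_dup_given_nahr = 0)
    cfg0$te_families$insertion_rate <- 0
    g0 <- simulate_cluster(cfg0)
    expect_lte(genome_length(g0), sum(g0$init_seg$len))
  }
})

test_that("the event-log length identity holds and divergence never decreases", {
  for (s in 1:5) {
    g <- simulate_cluster(small_sim_config(s, p_nahr = 0.02))
    li <- length_identity(g)
    expect_identical(li$expected, li$actual)
    incs <- unlist(lapply(g$log, function(e) {
      if (e$type == "mutate_tick") e$te_inc else numeric(0)
    }))
    expect_true(all(incs >= 0))
  }
})

test_that("export writes files the analysis readers consume unchanged", {
  g <- simulate_cluster(small_sim_config(3))
  out <- withr::local_tempdir()
  paths <- export_genome(g, out)
  rep <- read_repeatmasker_out(paths["repeats"])
  mem <- as_repeats(g)
  expect_equal(nrow(rep), nrow(mem))
  expect_equal(rep$family, mem$family)
  expect_equal(rep$pct_div, mem$pct_div, tolerance = 1e-4)
  locus <- read_intervals(paths["locus"], "bed")
  expect_equal(locus$end - locus$start,
               sum(g$seg$len[g$seg$in_cluster]))
  genes <- read_intervals(paths["genes"], "bed")
  expect_equal(nrow(genes), sum(g$seg$kind == "gene"))
  exon3 <- Biostrings::readDNAStringSet(paths["exon3"])
  expect_equal(unname(as.character(exon3)), gene_table(g)$exon3)
  aa <- Biostrings::readAAStringSet(paths["fingers"])
  arr <- build_array("g1", as.character(aa[[1]]))
  expect_true(arr$is_kzfp)
})

test_that("a duplicated span of three genes is recovered as a gene block", {
  set.seed(31)
  cfg <- sim_config(genome_len = 1e5, cluster_start = 0, cluster_end = 1e5,
                    n_init_genes = 0, init_line_density = 0, p_nahr = 1,
                    p_dup_given_nahr = 1, mu = 0, exon_mu = 0,
                    generations = 1, seed = 31, max_pair_dist = 30000,
                    te_families = default_te_families())
  exons <- vapply(1:5, function(i) random_dna_str(300), character(1))
  seg <- data.frame(
    kind = c("gene", "te", "gene", "gene", "gene", "te", "gene"),
    family = c("gA", "ERVK_sim", "gB", "gC", "gD", "ERVK_sim", "gE"),
    te_class = c(NA, "LTR", NA, NA, NA, "LTR", NA),
    strand = c("+", "+", "+", "-", "+", "+", "+"),
    len = c(1000, 500, 1000, 1000, 1000, 500, 1000),
    birth_gen = 0L, pct_div = c(NA, 0, NA, NA, NA, 0, NA),
    origin = "ancestral", in_cluster = TRUE, copy_id = 1:7,
    exon3 = c(exons[1], NA, exons[2], exons[3], exons[4], NA, exons[5]),
    fingers = c("M", NA, "M", "M", "M", NA, "M"),
    stringsAsFactors = FALSE)
  g <- structure(list(seg = seg, gen = 1L, next_id = 8L, config = cfg,
                      log = list()), class = "evolved_genome")
  g2 <- step_nahr(g)  # duplicates [anchor, gB, gC, gD] in tandem
  genes <- gene_table(g2)
  expect_equal(nrow(genes), 8)
  mat <- exon3_identity(stats::setNames(genes$exon3, genes$gene_id))
  labels <- cluster_paralogs(mat)
  blocks <- find_blocks(unname(labels))
  expect_equal(length(blocks), 1)
  expect_gte(length(blocks[[1]]$labels), 3)
  expect_equal(nrow(blocks[[1]]$occurrences), 2)
})

test_that("an export of an event-free run reflects the initial LINE count", {
  cfg <- small_sim_config(8, p_nahr = 0)
  cfg$te_families$insertion_rate <- 0
  cfg$mu <- 0
  g <- simulate_cluster(cfg)
  expect_equal(nrow(as_repeats(g)),
               round(cfg$init_line_density *
                       (cfg$cluster_end - cfg$cluster_start) / 1e6))
})
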
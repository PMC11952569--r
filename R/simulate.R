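#' Configuration for the cluster-expansion simulator
#'
#' The simulator implements a mechanistic model of young KZFP gene-cluster
#' evolution: ERV/LINE copies insert into a genome carrying one gene cluster,
#' pairs of young same-family copies provide microhomology anchors for
#' non-allelic homologous recombination (NAHR) whose repair either duplicates
#' or deletes the intervening span (genes and TEs alike), and every copy
#' independently accumulates divergence over time. One generation is an
#' abstract coarse time step; the rates are model parameters chosen at desk
#' scale, not estimates of murine rates.
#'
#' @param genome_len Genome length in bp.
#' @param cluster_start,cluster_end Cluster locus (0-based half-open), within
#'   the genome.
#' @param n_init_genes Number of ancestral KZFP genes seeded in the cluster.
#' @param init_line_density Ancestral LINE copies per Mb inside the cluster
#'   (the locus starts out LINE-rich).
#' @param te_families data.frame with columns `name`, `class`,
#'   `consensus_len` (bp), `insertion_rate` (expected new insertions per
#'   generation genome-wide, Poisson), `cluster_bias` (probability a new copy
#'   lands inside the cluster), and optionally `ltr_pair` (logical; an
#'   insertion deposits two identical LTR copies flanking an internal
#'   segment, the canonical LTR-retrotransposon structure and NAHR substrate)
#'   with `int_len` (bp of the internal segment, annotated as family
#'   `<name>-int`).
#' @param p_nahr Per-generation, per-eligible-anchor-pair probability of an
#'   NAHR event; at most one event is applied per generation (the first
#'   triggered pair in coordinate order).
#' @param p_dup_given_nahr Probability that a triggered event duplicates the
#'   anchored span (otherwise it is deleted).
#' @param mu Mean divergence gain per copy per generation, in percentage
#'   points; per-copy increments are Gamma(shape = 2, mean = mu), so copies
#'   of the same age spread into a continuum.
#' @param exon_mu Per-site substitution probability per generation for gene
#'   3' exon DNA and finger-array protein sequences.
#' @param generations Number of generations to simulate.
#' @param seed RNG seed used by [simulate_cluster()].
#' @param max_pair_dist Maximum gap (bp) between two copies for them to act
#'   as an anchor pair.
#' @param div_tol Microhomology tolerance: both anchors must differ by at
#'   most this many percentage points of divergence.
#' @param max_div Maximum per-anchor divergence (old, diverged copies lose
#'   recombinogenic potential).
#' @param nahr_geometry `"tandem"` (duplicate placed immediately right of the
#'   copied span) or `"scatter"` (placed at a random position inside the
#'   cluster).
#' @param n_fingers_range Range of zinc-finger counts for seeded genes.
#' @param gene_flank Non-exonic bp on each side of a gene's 3' exon.
#' @param seqid Sequence name used when exporting annotations.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 2e7,
                       cluster_start = 8e6, cluster_end = 8.5e6,
                       n_init_genes = 12,
                       init_line_density = 40,
                       te_families = default_te_families(),
                       p_nahr = 0.02,
                       p_dup_given_nahr = 0.7,
                       mu = 0.0133,
                       exon_mu = 2e-5,
                       generations = 800,
                       seed = 1,
                       max_pair_dist = 10000,
                       div_tol = 1,
                       max_div = 1.2,
                       nahr_geometry = c("tandem", "scatter"),
                       n_fingers_range = c(4, 10),
                       gene_flank = 800,
                       seqid = "chrSim") {
  nahr_geometry <- match.arg(nahr_geometry)
  if (is.null(te_families$ltr_pair)) te_families$ltr_pair <- FALSE
  if (is.null(te_families$int_len)) te_families$int_len <- 0
  stopifnot(all(!te_families$ltr_pair | te_families$int_len > 0))
  cfg <- list(genome_len = genome_len, cluster_start = cluster_start,
              cluster_end = cluster_end, n_init_genes = n_init_genes,
              init_line_density = init_line_density,
              te_families = te_families, p_nahr = p_nahr,
              p_dup_given_nahr = p_dup_given_nahr, mu = mu,
              exon_mu = exon_mu, generations = generations, seed = seed,
              max_pair_dist = max_pair_dist, div_tol = div_tol,
              max_div = max_div, nahr_geometry = nahr_geometry,
              n_fingers_range = n_fingers_range, gene_flank = gene_flank,
              seqid = seqid)
  stopifnot(genome_len > 0,
            cluster_start >= 0, cluster_start < cluster_end,
            cluster_end <= genome_len,
            n_init_genes >= 0, init_line_density >= 0,
            is.data.frame(te_families),
            all(c("name", "class", "consensus_len", "insertion_rate",
                  "cluster_bias") %in% names(te_families)),
            all(te_families$insertion_rate >= 0),
            all(te_families$cluster_bias >= 0 & te_families$cluster_bias <= 1),
            p_nahr >= 0, p_nahr <= 1,
            p_dup_given_nahr >= 0, p_dup_given_nahr <= 1,
            mu >= 0, exon_mu >= 0, exon_mu <= 1,
            generations >= 0, max_pair_dist >= 0, div_tol >= 0, max_div >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Default TE families for the simulator
#'
#' One young ERV family that inserts as a full-length provirus (two identical
#' LTRs flanking an internal segment — the LTR pairs are the NAHR anchors)
#' and one background LINE family. Rates are per generation genome-wide; the
#' mild cluster bias keeps most copies outside the locus, as observed for the
#' ERV families over-represented at young KZFP clusters.
#'
#' @return data.frame accepted by [sim_config()]'s `te_families`.
#' @export
default_te_families <- function() {
  data.frame(name = c("ERVK_sim", "L1MUS_sim"),
             class = c("LTR", "LINE"),
             consensus_len = c(600, 1200),
             insertion_rate = c(0.18, 0.1),
             cluster_bias = c(0.05, 0.07),
             ltr_pair = c(TRUE, FALSE),
             int_len = c(5400, 0),
             stringsAsFactors = FALSE)
}

DNA4 <- c("A", "C", "G", "T")
ZF_SAFE_AA <- c("A", "D", "E", "G", "I", "K", "M", "N", "Q", "R", "S", "T", "V")

# One 28-aa zinc-finger unit (7-aa linker + 21-aa C2H2 core, cys gap 2,
# his gap 3) carrying the given 4-residue fingerprint at helix -1/+2/+3/+6
# and the conserved structural residues (-12 Y, -3 F, +4 L).
zf_unit <- function(fingerprint) {
  core <- sample(ZF_SAFE_AA, 21, replace = TRUE)
  core[c(1, 4, 17, 21)] <- c("C", "C", "H", "H")
  core[8] <- "F"   # helix -3
  core[14] <- "L"  # helix +4
  core[c(10, 12, 13, 16)] <- strsplit(fingerprint, "")[[1]]  # -1/+2/+3/+6
  paste0("TGEKPYS", paste(core, collapse = ""))
}

# A KZFP-like protein: Met + n tandem zinc-finger units.
make_zf_protein <- function(n_fingers) {
  fps <- replicate(n_fingers,
                   paste(sample(ZF_SAFE_AA, 4, replace = TRUE), collapse = ""))
  paste0("M", paste(vapply(fps, zf_unit, character(1)), collapse = ""))
}

random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

new_seg_df <- function(kind = character(0)) {
  data.frame(kind = kind, family = character(0), te_class = character(0),
             strand = character(0), len = numeric(0), birth_gen = integer(0),
             pct_div = numeric(0), origin = character(0),
             in_cluster = logical(0), copy_id = integer(0),
             exon3 = character(0), fingers = character(0),
             stringsAsFactors = FALSE)
}

seg_row <- function(kind, family = NA_character_, te_class = NA_character_,
                    strand = ".", len, birth_gen = 0L, pct_div = NA_real_,
                    origin = "ancestral", in_cluster = FALSE, copy_id,
                    exon3 = NA_character_, fingers = NA_character_) {
  data.frame(kind = kind, family = family, te_class = te_class,
             strand = strand, len = len, birth_gen = as.integer(birth_gen),
             pct_div = pct_div, origin = origin, in_cluster = in_cluster,
             copy_id = as.integer(copy_id), exon3 = exon3, fingers = fingers,
             stringsAsFactors = FALSE)
}

#' Initialise a simulated genome
#'
#' Seeds the cluster with `n_init_genes` KZFP genes (random 3' exon DNA and
#' zinc-finger arrays) interleaved in random order with ancestral LINE copies
#' at `init_line_density`; everything else is neutral sequence, and all
#' initial divergences are 0. Uses the current RNG state (callers that need
#' reproducibility should use [simulate_cluster()], which seeds the RNG).
#'
#' @param config A [sim_config()].
#' @return An `evolved_genome`: a list with the segment table `seg` (segments
#'   tile the genome in order), `gen`, `next_id`, `config` and event `log`.
#' @export
init_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cluster_len <- config$cluster_end - config$cluster_start
  n_lines <- round(config$init_line_density * cluster_len / 1e6)
  line_fam <- config$te_families[config$te_families$class == "LINE", ,
                                 drop = FALSE]
  line_name <- if (nrow(line_fam) > 0) line_fam$name[1] else "L1_init"
  line_len <- if (nrow(line_fam) > 0) line_fam$consensus_len[1] else 1000
  items <- list()
  next_id <- 1L
  for (i in seq_len(config$n_init_genes)) {
    nf <- sample(seq(config$n_fingers_range[1], config$n_fingers_range[2]), 1)
    exon3 <- random_dna(84 * nf + 60)
    prot <- make_zf_protein(nf)
    items[[length(items) + 1L]] <- seg_row(
      kind = "gene", family = sprintf("kzfp%03d", i),
      strand = sample(c("+", "-"), 1),
      len = nchar(exon3) + 2 * config$gene_flank,
      in_cluster = TRUE, copy_id = next_id, exon3 = exon3, fingers = prot)
    next_id <- next_id + 1L
  }
  for (i in seq_len(n_lines)) {
    items[[length(items) + 1L]] <- seg_row(
      kind = "te", family = line_name, te_class = "LINE",
      strand = sample(c("+", "-"), 1), len = line_len, pct_div = 0,
      in_cluster = TRUE, copy_id = next_id)
    next_id <- next_id + 1L
  }
  item_bp <- sum(vapply(items, function(x) x$len, numeric(1)))
  if (item_bp > cluster_len) {
    stop("cluster too small (", cluster_len, " bp) to host ", item_bp,
         " bp of genes and LINE copies")
  }
  k <- length(items)
  if (k > 0) items <- items[sample.int(k)]
  gaps <- if (k >= 0) {
    as.numeric(stats::rmultinom(1, cluster_len - item_bp, rep(1, k + 1)))
  }
  rows <- list()
  add_neutral <- function(len, in_cl) {
    if (len <= 0) return(NULL)
    r <- seg_row(kind = "neutral", len = len, in_cluster = in_cl,
                 copy_id = next_id)
    next_id <<- next_id + 1L
    r
  }
  rows[[length(rows) + 1L]] <- add_neutral(config$cluster_start, FALSE)
  for (i in seq_len(k)) {
    rows[[length(rows) + 1L]] <- add_neutral(gaps[i], TRUE)
    rows[[length(rows) + 1L]] <- items[[i]]
  }
  rows[[length(rows) + 1L]] <- add_neutral(gaps[k + 1], TRUE)
  rows[[length(rows) + 1L]] <- add_neutral(
    config$genome_len - config$cluster_end, FALSE)
  seg <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(seg) <- NULL
  # re-number copy ids in final segment order so replay is deterministic
  seg$copy_id <- seq_len(nrow(seg))
  structure(list(seg = seg, gen = 0L, next_id = nrow(seg) + 1L,
                 config = config, log = list()),
            class = "evolved_genome")
}

seg_starts <- function(seg) cumsum(c(0, seg$len[-nrow(seg)]))

#' @export
print.evolved_genome <- function(x, ...) {
  cat("evolved_genome:", nrow(x$seg), "segments,",
      format(sum(x$seg$len), big.mark = ","), "bp, generation", x$gen,
      "\n  genes:", sum(x$seg$kind == "gene"),
      " TE copies:", sum(x$seg$kind == "te"),
      " events logged:", length(x$log), "\n")
  invisible(x)
}

log_event <- function(g, ev) {
  g$log[[length(g$log) + 1L]] <- ev
  g
}

# ---- event application (shared by the live steps and replay) --------------

apply_insert <- function(g, at, family, te_class, len, strand, gen,
                         log = TRUE) {
  seg <- g$seg
  starts <- seg_starts(seg)
  r <- findInterval(at, starts)  # at >= starts[r]
  off <- at - starts[r]
  new <- seg_row(kind = "te", family = family, te_class = te_class,
                 strand = strand, len = len, birth_gen = gen, pct_div = 0,
                 origin = "insertion", in_cluster = seg$in_cluster[r],
                 copy_id = g$next_id)
  g$next_id <- g$next_id + 1L
  n <- nrow(seg)
  if (off == 0) {
    new$in_cluster <- seg$in_cluster[r]
    pieces <- list(if (r > 1) seg[1:(r - 1), ] else NULL, new, seg[r:n, ])
  } else {
    left <- seg[r, ]
    right <- seg[r, ]
    left$len <- off
    right$len <- seg$len[r] - off
    right$copy_id <- g$next_id
    g$next_id <- g$next_id + 1L
    pieces <- list(if (r > 1) seg[1:(r - 1), ] else NULL, left, new, right,
                   if (r < n) seg[(r + 1):n, ] else NULL)
  }
  g$seg <- do.call(rbind, Filter(Negate(is.null), pieces))
  rownames(g$seg) <- NULL
  if (log) {
    g <- log_event(g, list(type = "insert", gen = gen, at = at,
                           family = family, te_class = te_class, len = len,
                           strand = strand))
  }
  g
}

apply_duplicate <- function(g, left, right, dest, gen, log = TRUE) {
  seg <- g$seg
  block <- seg[left:(right - 1), , drop = FALSE]
  span_bp <- sum(block$len)
  block$origin <- "duplication"
  block$birth_gen <- gen
  block$copy_id <- g$next_id + seq_len(nrow(block)) - 1L
  g$next_id <- g$next_id + nrow(block)
  n <- nrow(seg)
  g$seg <- rbind(if (dest > 1) seg[1:(dest - 1), ] else NULL, block,
                 seg[dest:n, ])
  rownames(g$seg) <- NULL
  if (log) {
    g <- log_event(g, list(type = "duplicate", gen = gen, left = left,
                           right = right, dest = dest, span_bp = span_bp,
                           anchor_family = seg$family[left]))
  }
  g
}

apply_delete <- function(g, left, right, gen, log = TRUE) {
  seg <- g$seg
  span_bp <- sum(seg$len[left:(right - 1)])
  fam <- seg$family[left]
  g$seg <- seg[-(left:(right - 1)), , drop = FALSE]
  rownames(g$seg) <- NULL
  if (log) {
    g <- log_event(g, list(type = "delete", gen = gen, left = left,
                           right = right, span_bp = span_bp,
                           anchor_family = fam))
  }
  g
}

apply_mutate <- function(g, te_rows, te_inc, gene_muts, gen, log = TRUE) {
  if (length(te_rows) > 0) {
    g$seg$pct_div[te_rows] <- pmin(100, g$seg$pct_div[te_rows] + te_inc)
  }
  for (m in gene_muts) {
    s <- strsplit(g$seg[[m$field]][m$row], "", fixed = TRUE)[[1]]
    s[m$pos] <- m$new
    g$seg[[m$field]][m$row] <- paste(s, collapse = "")
  }
  if (log) {
    g <- log_event(g, list(type = "mutate_tick", gen = gen,
                           te_rows = te_rows, te_inc = te_inc,
                           gene_muts = gene_muts))
  }
  g
}

# ---- per-generation steps -------------------------------------------------

#' One generation of TE insertion
#'
#' For each family, `Poisson(insertion_rate)` new copies are placed: each
#' lands inside the cluster with probability `cluster_bias`, otherwise
#' uniformly genome-wide. Insertions split neutral (and TE) segments; genes
#' are never disrupted, so positions are drawn bp-uniformly over non-gene
#' sequence of the targeted region.
#'
#' @param g An `evolved_genome`.
#' @return The updated genome.
#' @export
step_insertion <- function(g) {
  fams <- g$config$te_families
  for (fi in seq_len(nrow(fams))) {
    rate <- fams$insertion_rate[fi]
    if (rate <= 0) next
    n_new <- stats::rpois(1, rate)
    for (j in seq_len(n_new)) {
      in_cl <- stats::runif(1) < fams$cluster_bias[fi]
      strand <- sample(c("+", "-"), 1)
      at <- draw_insertion_position(g, in_cl)
      if (is.na(at)) next
      len <- fams$consensus_len[fi]
      g <- apply_insert(g, at, fams$name[fi], fams$class[fi], len, strand,
                        gen = g$gen)
      if (isTRUE(fams$ltr_pair[fi])) {
        # full-length element: 5' LTR + internal segment + identical 3' LTR
        g <- apply_insert(g, at + len, paste0(fams$name[fi], "-int"),
                          fams$class[fi], fams$int_len[fi], strand,
                          gen = g$gen)
        g <- apply_insert(g, at + len + fams$int_len[fi], fams$name[fi],
                          fams$class[fi], len, strand, gen = g$gen)
      }
    }
  }
  g
}

draw_insertion_position <- function(g, in_cluster) {
  seg <- g$seg
  # cluster_bias is the exact probability of landing inside the cluster, so
  # the complementary draw is uniform over the rest of the genome
  ok <- seg$kind != "gene" & (seg$in_cluster == in_cluster)
  tot <- sum(seg$len[ok])
  if (tot <= 0) return(NA_real_)
  u <- floor(stats::runif(1) * tot)
  rows <- which(ok)
  cum <- cumsum(seg$len[rows])
  i <- findInterval(u, c(0, cum[-length(cum)]))
  starts <- seg_starts(seg)
  starts[rows[i]] + (u - c(0, cum)[i])
}

#' One generation of non-allelic homologous recombination
#'
#' Eligible anchor pairs are same-family, same-strand TE copies at most
#' `max_pair_dist` bp apart whose divergences are within `div_tol` percentage
#' points of each other and each at most `max_div` (a microhomology proxy:
#' old, diverged copies no longer recombine). Pairs trigger independently
#' with probability `p_nahr`; the first triggered pair in coordinate order is
#' applied (at most one event per generation). With probability
#' `p_dup_given_nahr` the span from the start of the left anchor to the start
#' of the right anchor is duplicated (tandem, or scattered into the cluster
#' under the `"scatter"` geometry), carrying all contained genes and TE
#' copies at their current divergence; otherwise the span is deleted and the
#' right anchor survives as the hybrid copy.
#'
#' @param g An `evolved_genome`.
#' @return The updated genome.
#' @export
step_nahr <- function(g) {
  p <- g$config$p_nahr
  if (p <= 0) return(g)
  pairs <- eligible_pairs(g)
  if (nrow(pairs) == 0) return(g)
  trig <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (stats::runif(1) < p) { trig <- i; break }
  }
  if (trig == 0L) return(g)
  left <- pairs$left[trig]
  right <- pairs$right[trig]
  if (stats::runif(1) < g$config$p_dup_given_nahr) {
    dest <- right
    if (g$config$nahr_geometry == "scatter") {
      in_cl <- which(g$seg$in_cluster)
      dest <- in_cl[sample.int(length(in_cl), 1)]
      if (dest >= left && dest < right) dest <- right
    }
    g <- apply_duplicate(g, left, right, dest, gen = g$gen)
  } else {
    g <- apply_delete(g, left, right, gen = g$gen)
  }
  g
}

eligible_pairs <- function(g) {
  seg <- g$seg
  # anchor pairs are considered within the cluster locus only: structural
  # variants elsewhere in the (gene-dense) genome are removed by selection
  te <- which(seg$kind == "te" & seg$in_cluster)
  out <- list()
  if (length(te) >= 2) {
    starts <- seg_starts(seg)
    key <- paste(seg$family[te], seg$strand[te])
    for (grp in split(te, key)) {
      if (length(grp) < 2) next
      grp <- grp[order(starts[grp])]
      s <- starts[grp]
      e <- s + seg$len[grp]
      d <- seg$pct_div[grp]
      for (a in seq_len(length(grp) - 1)) {
        if (d[a] > g$config$max_div) next
        for (b in (a + 1):length(grp)) {
          if (s[b] - e[a] > g$config$max_pair_dist) break
          if (d[b] > g$config$max_div) next
          if (abs(d[a] - d[b]) > g$config$div_tol) next
          out[[length(out) + 1L]] <- c(grp[a], grp[b])
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(left = integer(0), right = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(left = m[, 1], right = m[, 2])
  starts <- seg_starts(seg)
  df[order(starts[df$left], starts[df$right]), , drop = FALSE]
}

#' One generation of mutation accumulation
#'
#' Every TE copy gains a Gamma(shape = 2, mean = `mu`) divergence increment
#' (capped at 100), and every gene's 3' exon and finger-array sequence is
#' substituted per site with probability `exon_mu`. Copies born by the same
#' duplication event share their divergence at birth and drift apart
#' independently afterwards.
#'
#' @param g An `evolved_genome`.
#' @return The updated genome.
#' @export
step_mutation <- function(g) {
  cfg <- g$config
  te_rows <- which(g$seg$kind == "te")
  te_inc <- numeric(0)
  if (cfg$mu > 0 && length(te_rows) > 0) {
    te_inc <- stats::rgamma(length(te_rows), shape = 2, rate = 2 / cfg$mu)
  } else {
    te_rows <- integer(0)
  }
  gene_muts <- list()
  if (cfg$exon_mu > 0) {
    for (r in which(g$seg$kind == "gene")) {
      for (field in c("exon3", "fingers")) {
        nch <- nchar(g$seg[[field]][r])
        nm <- stats::rbinom(1, nch, cfg$exon_mu)
        if (nm == 0) next
        pos <- sort(sample.int(nch, nm))
        alphabet <- if (field == "exon3") DNA4 else AA20
        old <- substring(g$seg[[field]][r], pos, pos)
        new <- vapply(old, function(o) sample(setdiff(alphabet, o), 1),
                      character(1), USE.NAMES = FALSE)
        gene_muts[[length(gene_muts) + 1L]] <- list(row = r, field = field,
                                                    pos = pos, new = new)
      }
    }
  }
  if (length(te_rows) == 0 && length(gene_muts) == 0) return(g)
  apply_mutate(g, te_rows, te_inc, gene_muts, gen = g$gen)
}

#' Run the full cluster-expansion simulation
#'
#' Seeds the RNG from `config$seed`, initialises the genome and runs
#' `generations` rounds of insertion, NAHR and mutation. The result carries
#' the complete event log and the post-initialisation snapshot, so
#' [replay_log()] can reproduce the final genome exactly. Identical configs
#' (including the seed) give identical results.
#'
#' @param config A [sim_config()].
#' @return An `evolved_genome` with elements `init_seg` and `init_next_id`
#'   (the replay starting point) in addition to the live state.
#' @export
simulate_cluster <- function(config) {
  set.seed(config$seed)
  g <- init_genome(config)
  init_seg <- g$seg
  init_next_id <- g$next_id
  for (gen in seq_len(config$generations)) {
    g$gen <- gen
    g <- step_insertion(g)
    g <- step_nahr(g)
    g <- step_mutation(g)
  }
  g$init_seg <- init_seg
  g$init_next_id <- init_next_id
  g
}

#' Replay an event log from the initial state
#'
#' Applies the logged events deterministically (no RNG) to the
#' post-initialisation snapshot; the result's segment table equals the live
#' simulation's exactly.
#'
#' @param genome An `evolved_genome` from [simulate_cluster()].
#' @return The replayed `evolved_genome`.
#' @export
replay_log <- function(genome) {
  stopifnot(!is.null(genome$init_seg))
  g <- structure(list(seg = genome$init_seg, gen = 0L,
                      next_id = genome$init_next_id,
                      config = genome$config, log = list()),
                 class = "evolved_genome")
  for (ev in genome$log) {
    g$gen <- ev$gen
    g <- switch(ev$type,
      insert = apply_insert(g, ev$at, ev$family, ev$te_class, ev$len,
                            ev$strand, gen = ev$gen, log = FALSE),
      duplicate = apply_duplicate(g, ev$left, ev$right, ev$dest,
                                  gen = ev$gen, log = FALSE),
      delete = apply_delete(g, ev$left, ev$right, gen = ev$gen, log = FALSE),
      mutate_tick = apply_mutate(g, ev$te_rows, ev$te_inc, ev$gene_muts,
                                 gen = ev$gen, log = FALSE),
      stop("unknown event type: ", ev$type))
  }
  g
}

# ---- accessors ------------------------------------------------------------

#' Total genome length of a simulated genome
#' @param genome An `evolved_genome`.
#' @return Length in bp.
#' @export
genome_length <- function(genome) sum(genome$seg$len)

#' Event-log bookkeeping identity for the genome length
#'
#' The final length must equal the initial length plus all inserted bp plus
#' all duplicated span bp minus all deleted span bp.
#'
#' @param genome An `evolved_genome` from [simulate_cluster()].
#' @return A list with `expected`, `actual` and the three totals.
#' @export
length_identity <- function(genome) {
  ins <- sum(vapply(genome$log, function(e) {
    if (e$type == "insert") e$len else 0
  }, numeric(1)))
  dup <- sum(vapply(genome$log, function(e) {
    if (e$type == "duplicate") e$span_bp else 0
  }, numeric(1)))
  del <- sum(vapply(genome$log, function(e) {
    if (e$type == "delete") e$span_bp else 0
  }, numeric(1)))
  list(expected = sum(genome$init_seg$len) + ins + dup - del,
       actual = genome_length(genome),
       inserted = ins, duplicated = dup, deleted = del)
}

#' Count NAHR duplication events anchored by one family
#' @param genome An `evolved_genome`.
#' @param family Anchor family name.
#' @return Number of duplication events with that anchor family.
#' @export
n_duplications <- function(genome, family) {
  sum(vapply(genome$log, function(e) {
    e$type == "duplicate" && identical(e$anchor_family, family)
  }, logical(1)))
}

#' Repeat annotation table of a simulated genome
#' @param genome An `evolved_genome`.
#' @return A repeat table (see [repeats()]) with coordinates from segment
#'   order.
#' @export
as_repeats <- function(genome) {
  seg <- genome$seg
  starts <- seg_starts(seg)
  te <- seg$kind == "te"
  if (!any(te)) return(empty_repeats())
  repeats(seqid = genome$config$seqid, start = starts[te],
          end = starts[te] + seg$len[te], strand = seg$strand[te],
          family = seg$family[te], te_class = seg$te_class[te],
          pct_div = seg$pct_div[te])
}

#' Gene table of a simulated genome
#' @param genome An `evolved_genome`.
#' @return data.frame in coordinate order: `gene_id` (unique per copy),
#'   `family` (ancestral gene identity), `seqid`, `start`, `end`, `strand`,
#'   `origin`, `birth_gen`, `exon3`, `fingers`.
#' @export
gene_table <- function(genome) {
  seg <- genome$seg
  starts <- seg_starts(seg)
  gi <- which(seg$kind == "gene")
  data.frame(gene_id = paste0(seg$family[gi], ".", seg$copy_id[gi]),
             family = seg$family[gi], seqid = genome$config$seqid,
             start = starts[gi], end = starts[gi] + seg$len[gi],
             strand = seg$strand[gi], origin = seg$origin[gi],
             birth_gen = seg$birth_gen[gi], exon3 = seg$exon3[gi],
             fingers = seg$fingers[gi], stringsAsFactors = FALSE)
}

#' Current cluster locus of a simulated genome
#' @param genome An `evolved_genome`.
#' @return A one-row interval table spanning the (contiguous) cluster.
#' @export
locus_interval <- function(genome) {
  seg <- genome$seg
  starts <- seg_starts(seg)
  ci <- which(seg$in_cluster)
  stopifnot(length(ci) > 0)
  intervals(genome$config$seqid, starts[ci[1]],
            starts[ci[length(ci)]] + seg$len[ci[length(ci)]], ".")
}

#' Export a simulated genome as analysis-ready files
#'
#' Writes `repeats.out` (RepeatMasker-style layout), `genes.bed`,
#' `exon3.fasta`, `fingers.fasta` and `locus.bed` into `out_dir`; the files
#' are directly consumable by the fingerprint, enrichment and divergence
#' analyses.
#'
#' @param genome An `evolved_genome`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the file paths, invisibly.
#' @export
export_genome <- function(genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(repeats = file.path(out_dir, "repeats.out"),
             genes = file.path(out_dir, "genes.bed"),
             exon3 = file.path(out_dir, "exon3.fasta"),
             fingers = file.path(out_dir, "fingers.fasta"),
             locus = file.path(out_dir, "locus.bed"))
  write_repeatmasker_out(as_repeats(genome), paths["repeats"])
  genes <- gene_table(genome)
  write_bed(data.frame(seqid = genes$seqid, start = genes$start,
                       end = genes$end, name = genes$gene_id, score = 0,
                       strand = genes$strand), paths["genes"])
  dna <- Biostrings::DNAStringSet(stats::setNames(genes$exon3, genes$gene_id))
  Biostrings::writeXStringSet(dna, paths["exon3"])
  aa <- Biostrings::AAStringSet(stats::setNames(genes$fingers, genes$gene_id))
  Biostrings::writeXStringSet(aa, paths["fingers"])
  loc <- locus_interval(genome)
  write_bed(data.frame(seqid = loc$seqid, start = loc$start, end = loc$end,
                       name = "cluster", score = 0, strand = "."),
            paths["locus"])
  invisible(paths)
}
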
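#' Per-class repeat composition of a genomic space
#'
#' For each transposable-element class, reports the bp covered inside the
#' space (union of copy intervals, clipped to the space) and the fraction of
#' the space length. Classes with no copies are reported with 0.
#'
#' @param rep Repeat table (see [repeats()]).
#' @param space Interval table defining the queried space (a locus or the
#'   whole genome); must have positive total length.
#' @return A data.frame with `te_class`, `bp`, `fraction`.
#' @export
composition <- function(rep, space) {
  space_len <- interval_union_bp(space)
  if (space_len <= 0) stop("queried space has zero length")
  classes <- c("LTR", "LINE", "SINE", "DNA", "other")
  bp <- vapply(classes, function(cl) {
    sub <- rep[rep$te_class == cl, , drop = FALSE]
    if (nrow(sub) == 0) return(0)
    interval_overlap_bp(sub, space)
  }, numeric(1))
  data.frame(te_class = classes, bp = bp, fraction = bp / space_len,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Base-pair ratio enrichment of a repeat family at a locus
#'
#' Enrichment is the family's bp density inside the locus over its density
#' genome-wide: `(bp of TE in locus / locus bp) / (bp of TE genome-wide /
#' genome bp)`. bp are counted as the union of the family's copy intervals,
#' clipped to the locus (or to the genome). The ratio is scale-invariant. A
#' family absent genome-wide yields an undefined (flagged) result, not 0.
#'
#' @param rep Repeat table covering the whole genome.
#' @param family Family name.
#' @param locus Interval table for the locus.
#' @param genome_len Genome length in bp (>= locus length).
#' @return One-row data.frame: `family`, `bp_in_locus`, `locus_len`,
#'   `bp_genome`, `genome_len`, `ratio`, `log2_ratio`, `defined`.
#' @export
te_enrichment <- function(rep, family, locus, genome_len) {
  locus_len <- interval_union_bp(locus)
  stopifnot(locus_len > 0, genome_len >= locus_len)
  fam <- rep[rep$family == family, , drop = FALSE]
  bp_genome <- interval_union_bp(fam)
  bp_locus <- interval_overlap_bp(fam, locus)
  if (bp_genome == 0) {
    return(data.frame(family = family, bp_in_locus = 0, locus_len = locus_len,
                      bp_genome = 0, genome_len = genome_len, ratio = NA_real_,
                      log2_ratio = NA_real_, defined = FALSE,
                      stringsAsFactors = FALSE))
  }
  ratio <- (bp_locus / locus_len) / (bp_genome / genome_len)
  data.frame(family = family, bp_in_locus = bp_locus, locus_len = locus_len,
             bp_genome = bp_genome, genome_len = genome_len, ratio = ratio,
             log2_ratio = log2(ratio), defined = TRUE,
             stringsAsFactors = FALSE)
}

#' Permutation test of interval-set overlap
#'
#' Measures how surprising the observed overlap between `query` and
#' `reference` is under uniform random re-placement of the query within an
#' allowed placement space, preserving interval lengths.
#'
#' Two modes match the two directions in which such tests are run:
#' `"randomize_locus"` re-places the query (typically a single locus) and
#' scores the overlap in bp; `"randomize_query"` re-places the query set
#' (typically ChIP-seq peaks), preserving each interval's chromosome, and
#' scores the number of query intervals overlapping the reference by >= 1 bp.
#' The empirical p-value uses the +1-corrected estimator
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`, so `p >= 1/(n_perm + 1)`.
#' The Z-score is `(observed - null mean) / null sd`, `NA` when the null is
#' degenerate (sd = 0).
#'
#' @param query Interval table to randomize.
#' @param reference Interval table held fixed.
#' @param allowed_space Interval table of the placement universe; every
#'   randomized interval must fit inside a single allowed block.
#' @param n_perm Number of permutations (default 1000).
#' @param mode `"randomize_locus"` (bp statistic) or `"randomize_query"`
#'   (count statistic).
#' @return A one-row data.frame: `observed`, `p_perm`, `z_score`,
#'   `null_mean`, `null_sd`, `n_perm`, `mode`.
#' @export
permutation_test <- function(query, reference, allowed_space,
                             n_perm = 1000,
                             mode = c("randomize_locus", "randomize_query")) {
  mode <- match.arg(mode)
  stopifnot(nrow(query) > 0, nrow(reference) > 0, nrow(allowed_space) > 0,
            n_perm >= 1)
  stat_bp <- mode == "randomize_locus"
  obs <- if (stat_bp) {
    interval_overlap_bp(query, reference)
  } else {
    count_overlapping(query, reference)
  }
  widths <- query$end - query$start
  k <- nrow(query)
  # draw all n_perm * k placements at once, then score per permutation
  placed <- place_uniform(widths,
                          seqids = if (stat_bp) NULL else query$seqid,
                          allowed_space, n_draws = n_perm)
  null <- score_placements(placed, reference, n_perm, k, stat_bp)
  p <- (1 + sum(null >= obs)) / (n_perm + 1)
  mu <- mean(null)
  sdv <- stats::sd(null)
  z <- if (is.na(sdv) || sdv == 0) NA_real_ else (obs - mu) / sdv
  data.frame(observed = obs, p_perm = p, z_score = z, null_mean = mu,
             null_sd = sdv, n_perm = n_perm, mode = mode,
             stringsAsFactors = FALSE)
}

count_overlapping <- function(query, reference) {
  n <- 0L
  for (s in unique(query$seqid)) {
    q <- query[query$seqid == s, , drop = FALSE]
    r <- reference[reference$seqid == s, , drop = FALSE]
    if (nrow(r) == 0) next
    rq <- IRanges::IRanges(q$start + 1, q$end)
    rr <- IRanges::reduce(IRanges::IRanges(r$start + 1, r$end))
    n <- n + sum(IRanges::countOverlaps(rq, rr) > 0)
  }
  n
}

# Uniformly place intervals of the given widths inside allowed_space,
# n_draws independent times. When `seqids` is given, each interval is
# restricted to allowed blocks on its own seqid. Returns a data.frame with
# seqid/start/end/perm columns (n_draws * length(widths) rows).
place_uniform <- function(widths, seqids, allowed_space, n_draws) {
  blocks <- allowed_space
  total <- length(widths) * n_draws
  w <- rep(widths, times = n_draws)
  sq <- if (is.null(seqids)) NULL else rep(seqids, times = n_draws)
  start <- numeric(total)
  chosen_seq <- character(total)
  # group intervals by (seqid restriction, width) for vectorised sampling
  for (uw in unique(w)) {
    idx_w <- which(w == uw)
    groups <- if (is.null(sq)) list(idx_w) else split(idx_w, sq[idx_w])
    for (idx in groups) {
      bl <- if (is.null(sq)) blocks else {
        blocks[blocks$seqid == sq[idx[1]], , drop = FALSE]
      }
      slots <- pmax(0, (bl$end - bl$start) - uw + 1)
      if (sum(slots) <= 0) {
        stop("allowed_space has no block large enough for an interval of ",
             uw, " bp")
      }
      bi <- sample.int(nrow(bl), length(idx), replace = TRUE,
                       prob = slots / sum(slots))
      off <- floor(stats::runif(length(idx)) * slots[bi])
      start[idx] <- bl$start[bi] + off
      chosen_seq[idx] <- bl$seqid[bi]
    }
  }
  data.frame(seqid = chosen_seq, start = start, end = start + w,
             perm = rep(seq_len(n_draws), each = length(widths)),
             stringsAsFactors = FALSE)
}

# Per-permutation statistic for a block of placements.
score_placements <- function(placed, reference, n_perm, k, stat_bp) {
  null <- numeric(n_perm)
  for (s in unique(placed$seqid)) {
    p <- placed[placed$seqid == s, , drop = FALSE]
    r <- reference[reference$seqid == s, , drop = FALSE]
    if (nrow(r) == 0) next
    rp <- IRanges::IRanges(p$start + 1, p$end)
    rr <- IRanges::reduce(IRanges::IRanges(r$start + 1, r$end))
    if (stat_bp) {
      hits <- IRanges::findOverlaps(rp, rr)
      if (length(hits) == 0) next
      qi <- S4Vectors::queryHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        rp[qi], rr[S4Vectors::subjectHits(hits)]))
      contrib <- tapply(ov, p$perm[qi], sum)
    } else {
      hit <- IRanges::countOverlaps(rp, rr) > 0
      contrib <- tapply(as.numeric(hit), p$perm, sum)
    }
    pi <- as.integer(names(contrib))
    null[pi] <- null[pi] + as.numeric(contrib)
  }
  null
}

#' Fraction of a family's annotations that fall inside a locus, in percent
#'
#' Under `unit = "count"` (default) a copy is inside the locus when its
#' midpoint is (an unambiguous in/out call for boundary-straddling copies);
#' under `unit = "bp"` the bp of the family's interval union inside the locus
#' is divided by its genome-wide union bp.
#'
#' @param rep Repeat table covering the genome.
#' @param family Family name; must have at least one copy genome-wide.
#' @param locus Locus interval table.
#' @param unit `"count"` or `"bp"`.
#' @return Percentage (0-100).
#' @export
family_fraction <- function(rep, family, locus, unit = c("count", "bp")) {
  unit <- match.arg(unit)
  fam <- rep[rep$family == family, , drop = FALSE]
  if (nrow(fam) == 0) stop("family ", family, " has no genome-wide copies")
  if (unit == "count") {
    100 * sum(midpoint_in_locus(fam, locus)) / nrow(fam)
  } else {
    100 * interval_overlap_bp(fam, locus) / interval_union_bp(fam)
  }
}

#' Select repeat families over-represented at a locus
#'
#' Retains families for which strictly more than `min_frac` percent of all
#' genome-wide annotation records (midpoint rule) and strictly more than
#' `min_copies` records occur within the locus, sorted by decreasing
#' fraction.
#'
#' @param rep Repeat table.
#' @param locus Locus interval table.
#' @param min_frac Minimum percent of total annotations inside the locus
#'   (default 2).
#' @param min_copies Minimum copy count inside the locus (default 10).
#' @return A data.frame: `family`, `fraction`, `n_locus`, `n_genome`.
#' @export
select_families <- function(rep, locus, min_frac = 2, min_copies = 10) {
  if (nrow(rep) == 0) {
    return(data.frame(family = character(0), fraction = numeric(0),
                      n_locus = numeric(0), n_genome = numeric(0)))
  }
  in_locus <- midpoint_in_locus(rep, locus)
  n_genome <- table(rep$family)
  n_locus <- table(factor(rep$family[in_locus], levels = names(n_genome)))
  fraction <- 100 * as.numeric(n_locus) / as.numeric(n_genome)
  df <- data.frame(family = names(n_genome), fraction = fraction,
                   n_locus = as.numeric(n_locus),
                   n_genome = as.numeric(n_genome),
                   stringsAsFactors = FALSE)
  df <- df[df$fraction > min_frac & df$n_locus > min_copies, , drop = FALSE]
  df <- df[order(-df$fraction, df$family), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Filter ChIP-seq peaks against controls and quality thresholds
#'
#' Step 1 removes every peak overlapping any negative-control peak by >= 1 bp.
#' Step 2 keeps peaks with `q_value <= q_max` and fold enrichment >=
#' `fe_primary`. Step 3: when fewer than `min_peaks` peaks survive, step 2 is
#' redone with the fallback fold-enrichment cutoff. Relaxing the
#' fold-enrichment threshold can only grow the retained set, so the fallback
#' result is a superset of the primary one.
#'
#' @param peaks Peak table (see [read_narrowpeak()]).
#' @param control_peaks Peak/interval table of control peaks (may be empty).
#' @param q_max Plain-scale q-value cutoff (default 0.01).
#' @param fe_primary Primary fold-enrichment cutoff (default 10).
#' @param fe_fallback Fallback cutoff used when too few peaks survive
#'   (default 5).
#' @param min_peaks Minimum retained count before the fallback fires
#'   (default 20).
#' @return The retained peaks, with an attribute `fe_cutoff` recording the
#'   cutoff actually used.
#' @export
filter_peaks <- function(peaks, control_peaks, q_max = 0.01, fe_primary = 10,
                         fe_fallback = 5, min_peaks = 20) {
  keep <- peaks
  if (!is.null(control_peaks) && nrow(control_peaks) > 0 && nrow(keep) > 0) {
    drop <- logical(nrow(keep))
    for (s in unique(keep$seqid)) {
      i <- which(keep$seqid == s)
      ctl <- control_peaks[control_peaks$seqid == s, , drop = FALSE]
      if (nrow(ctl) == 0) next
      rq <- IRanges::IRanges(keep$start[i] + 1, keep$end[i])
      rc <- IRanges::IRanges(ctl$start + 1, ctl$end)
      drop[i] <- IRanges::countOverlaps(rq, rc) > 0
    }
    keep <- keep[!drop, , drop = FALSE]
  }
  pass <- keep[keep$q_value <= q_max & keep$fold_enrichment >= fe_primary, ,
               drop = FALSE]
  fe_used <- fe_primary
  if (nrow(pass) < min_peaks) {
    pass <- keep[keep$q_value <= q_max & keep$fold_enrichment >= fe_fallback, ,
                 drop = FALSE]
    fe_used <- fe_fallback
  }
  rownames(pass) <- NULL
  attr(pass, "fe_cutoff") <- fe_used
  pass
}
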
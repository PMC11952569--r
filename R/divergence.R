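#' Per-family divergence profiles at a locus versus genome-wide
#'
#' For each family, collects the percent-divergence values of the copies
#' whose midpoint falls inside the locus and of all copies genome-wide. The
#' locus values are a sub-multiset of the genome values by construction.
#'
#' @param rep Repeat table covering the genome.
#' @param locus Locus interval table.
#' @param families Character vector of family names.
#' @return A named list; each element is a list with `family`,
#'   `locus_values`, `genome_values`, `present` (`FALSE` for a family absent
#'   genome-wide).
#' @export
divergence_profiles <- function(rep, locus, families) {
  stopifnot(length(families) > 0)
  in_locus <- midpoint_in_locus(rep, locus)
  out <- lapply(families, function(f) {
    sel <- rep$family == f
    list(family = f,
         locus_values = rep$pct_div[sel & in_locus],
         genome_values = rep$pct_div[sel],
         present = any(sel))
  })
  names(out) <- families
  out
}

#' One-dimensional tie groups among divergence values
#'
#' Single-linkage clustering on the line: values are sorted and chained while
#' consecutive gaps are at most `epsilon`; chains of at least `min_size`
#' values are tie groups. Copies duplicated together carry (nearly) identical
#' divergence, so an excess of tie groups at a locus is the signature of
#' expansion by segmental duplication rather than by independent insertion.
#'
#' @param values Numeric divergence values (percent).
#' @param epsilon Maximum gap chaining two values, in percentage points
#'   (default 0.2, one reporting step of 0.1 on each side).
#' @param min_size Minimum group size (default 3).
#' @return A list with `groups` (list of integer index vectors into `values`),
#'   `centers` (group means) and `tied_fraction` (total grouped values over
#'   `length(values)`); all empty/0 when `length(values) < min_size`.
#' @export
tie_groups <- function(values, epsilon = 0.2, min_size = 3) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  n <- length(values)
  if (n < min_size) {
    return(list(groups = list(), centers = numeric(0), tied_fraction = 0))
  }
  ord <- order(values)
  v <- values[ord]
  new_chain <- c(TRUE, diff(v) > epsilon)
  chain_id <- cumsum(new_chain)
  groups <- list()
  centers <- numeric(0)
  for (g in unique(chain_id)) {
    members <- ord[chain_id == g]
    if (length(members) >= min_size) {
      groups[[length(groups) + 1L]] <- sort(members)
      centers <- c(centers, mean(values[members]))
    }
  }
  tied <- sum(lengths(groups))
  list(groups = groups, centers = centers, tied_fraction = tied / n)
}

#' Resampling test for an excess of divergence tie groups at a locus
#'
#' The observed statistic is the locus tied fraction ([tie_groups()]). The
#' null draws `length(locus_values)` values without replacement from the
#' genome-wide values (the locus copies are a subset of the finite
#' genome-wide population) and recomputes the tied fraction, `n_resample`
#' times. `p = (1 + #(null >= observed)) / (n_resample + 1)`.
#'
#' @param locus_values Divergence values of the locus copies.
#' @param genome_values Divergence values of all copies genome-wide; must be
#'   at least as many as `locus_values`.
#' @param epsilon,min_size Passed to [tie_groups()].
#' @param n_resample Number of resamples (default 1000).
#' @return A list with `observed`, `p_resample`, `n_resample`,
#'   `null_tied_fraction` (the vector of null statistics).
#' @export
tie_group_test <- function(locus_values, genome_values, epsilon = 0.2,
                           min_size = 3, n_resample = 1000) {
  if (length(genome_values) < length(locus_values)) {
    stop("genome_values must contain at least as many values as locus_values")
  }
  stopifnot(length(locus_values) >= min_size, n_resample >= 1)
  obs <- tie_groups(locus_values, epsilon, min_size)$tied_fraction
  k <- length(locus_values)
  null <- vapply(seq_len(n_resample), function(i) {
    tie_groups(sample(genome_values, k), epsilon, min_size)$tied_fraction
  }, numeric(1))
  p <- (1 + sum(null >= obs)) / (n_resample + 1)
  list(observed = obs, p_resample = p, n_resample = n_resample,
       null_tied_fraction = null)
}

#' Pairwise identity matrix from global alignment of 3' exon sequences
#'
#' Every pair is globally aligned (Needleman-Wunsch with affine gaps; match
#' +1, mismatch -1, a gap of length L costs `2 + 0.5 * L`) and identity is
#' the number of matched columns over the total alignment columns. The
#' matrix is symmetric with unit diagonal.
#'
#' @param seqs Character vector or `DNAStringSet` of >= 2 DNA sequences; all
#'   must be nonempty.
#' @return A symmetric numeric matrix in `[0, 1]`, dimnames from `names(seqs)`
#'   when present. The matrix of raw alignment scores is attached as
#'   attribute `"scores"`.
#' @export
exon3_identity <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(length(seqs) >= 2)
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  n <- length(seqs)
  mat <- diag(1, n)
  scores <- diag(as.numeric(nchar(seqs)), n)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  for (i in seq_len(n - 1)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[(i + 1):n]), seqs[i],
      substitutionMatrix = sm, gapOpening = 2, gapExtension = 0.5,
      type = "global")
    ncol_aln <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- Biostrings::nmatch(pa) / ncol_aln
    mat[i, (i + 1):n] <- ident
    mat[(i + 1):n, i] <- ident
    scores[i, (i + 1):n] <- Biostrings::score(pa)
    scores[(i + 1):n, i] <- Biostrings::score(pa)
  }
  if (!is.null(names(seqs))) dimnames(mat) <- list(names(seqs), names(seqs))
  attr(mat, "scores") <- scores
  mat
}

#' Single-linkage paralog clustering from an identity matrix
#'
#' Genes are linked when their pairwise identity is at least `threshold`;
#' paralog groups are the connected components of that graph (single
#' linkage). Labels are assigned in first-occurrence order along the input
#' (i.e. locus coordinate) order: A, B, C, ..., Z, AA, AB, ...
#'
#' @param mat Symmetric identity matrix (see [exon3_identity()]).
#' @param threshold Identity threshold in `(0, 1]` (default 0.95).
#' @return Character vector of labels, one per gene, named like `mat`'s rows.
#' @export
cluster_paralogs <- function(mat, threshold = 0.95) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  adj <- (mat >= threshold)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # relabel in first-occurrence order
  first <- match(unique(comp), comp)
  relabel <- stats::setNames(seq_along(first), comp[first])
  labels <- block_label(relabel[as.character(comp)])
  names(labels) <- rownames(mat)
  labels
}

# 1 -> A, 26 -> Z, 27 -> AA, ...
block_label <- function(i) {
  vapply(i, function(k) {
    s <- ""
    while (k > 0) {
      r <- (k - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      k <- (k - 1) %/% 26
    }
    s
  }, character(1))
}

#' Detect duplicated gene blocks from an ordered label sequence
#'
#' A gene block is a run of at least `min_len` consecutive paralog labels
#' that recurs at least `min_occurrences` times along the cluster, counting
#' occurrences in reversed order (inverted duplications). Occurrences of a
#' block are made non-overlapping greedily left-to-right in gene-index
#' space. A block is reported only when it is maximal: extending its label
#' sequence by one gene on either side would lose an occurrence. Shorter
#' blocks sharing a prefix or suffix with a longer one therefore surface
#' exactly when they have an occurrence outside the longer block's
#' occurrences (partial duplications).
#'
#' @param labels Character vector of paralog labels in locus coordinate
#'   order (see [cluster_paralogs()]).
#' @param min_len Minimum block length in genes (default 3).
#' @param min_occurrences Minimum number of (non-overlapping) occurrences
#'   (default 2).
#' @return A list of blocks; each block is a list with `labels` (the label
#'   sequence, oriented as its leftmost occurrence), and `occurrences`, a
#'   data.frame with `start` (0-based gene index) and `orientation`
#'   (`"forward"`/`"reversed"`).
#' @export
find_blocks <- function(labels, min_len = 3, min_occurrences = 2) {
  n <- length(labels)
  if (n == 0) stop("labels must be nonempty")
  if (n < min_len) return(list())
  # enumerate all distinct patterns (canonical form: pattern vs its reverse)
  cand <- list()
  for (len in min_len:n) {
    for (s in 1:(n - len + 1)) {
      pat <- labels[s:(s + len - 1)]
      key <- canonical_key(pat)
      if (!is.null(cand[[key]])) next
      occ <- pattern_occurrences(labels, pat)
      occ <- greedy_nonoverlap(occ, len)
      if (nrow(occ) >= min_occurrences) {
        cand[[key]] <- list(pat = pat, len = len, occ = occ)
      } else {
        cand[[key]] <- list(pat = NULL)  # memoize the rejection
      }
    }
  }
  cand <- Filter(function(x) !is.null(x$pat), cand)
  if (length(cand) == 0) return(list())
  # maximality: drop a block when some one-gene extension retains all its
  # occurrence count
  occ_count <- function(pat) {
    occ <- pattern_occurrences(labels, pat)
    nrow(greedy_nonoverlap(occ, length(pat)))
  }
  keep <- vapply(cand, function(b) {
    cnt <- nrow(b$occ)
    for (ext in extensions(labels, b$pat)) {
      if (occ_count(ext) == cnt) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- lapply(cand[keep], function(b) {
    first <- b$occ[which.min(b$occ$start), ]
    pat <- if (first$orientation == "forward") b$pat else rev(b$pat)
    occ <- b$occ
    if (first$orientation == "reversed") {
      occ$orientation <- ifelse(occ$orientation == "forward",
                                "reversed", "forward")
    }
    list(labels = pat, occurrences = occ[order(occ$start), , drop = FALSE])
  })
  names(out) <- NULL
  # stable order: by length desc, then first occurrence
  firsts <- vapply(out, function(b) b$occurrences$start[1], numeric(1))
  lens <- vapply(out, function(b) length(b$labels), numeric(1))
  out[order(-lens, firsts)]
}

canonical_key <- function(pat) {
  f <- paste(pat, collapse = "\r")
  r <- paste(rev(pat), collapse = "\r")
  if (f <= r) f else r
}

# All occurrences (0-based start, orientation) of `pat` or its reverse in
# `labels`. A window equal to both (palindrome) counts once, as forward.
pattern_occurrences <- function(labels, pat) {
  n <- length(labels)
  len <- length(pat)
  starts <- integer(0)
  orient <- character(0)
  rpat <- rev(pat)
  for (s in 1:(n - len + 1)) {
    win <- labels[s:(s + len - 1)]
    if (identical(win, pat)) {
      starts <- c(starts, s - 1L); orient <- c(orient, "forward")
    } else if (identical(win, rpat)) {
      starts <- c(starts, s - 1L); orient <- c(orient, "reversed")
    }
  }
  data.frame(start = starts, orientation = orient, stringsAsFactors = FALSE)
}

greedy_nonoverlap <- function(occ, len) {
  if (nrow(occ) == 0) return(occ)
  occ <- occ[order(occ$start), , drop = FALSE]
  chosen <- logical(nrow(occ))
  last_end <- -1
  for (i in seq_len(nrow(occ))) {
    if (occ$start[i] > last_end) {
      chosen[i] <- TRUE
      last_end <- occ$start[i] + len - 1
    }
  }
  occ[chosen, , drop = FALSE]
}

# All one-gene extensions of `pat` that actually occur in `labels` adjacent
# to one of its (or its reverse's) occurrences.
extensions <- function(labels, pat) {
  n <- length(labels)
  len <- length(pat)
  occ <- pattern_occurrences(labels, pat)
  exts <- list()
  for (i in seq_len(nrow(occ))) {
    s <- occ$start[i] + 1L  # 1-based
    win_pat <- if (occ$orientation[i] == "forward") pat else rev(pat)
    if (s > 1) {
      exts[[length(exts) + 1L]] <- labels[(s - 1):(s + len - 1)]
    }
    if (s + len - 1 < n) {
      exts[[length(exts) + 1L]] <- labels[s:(s + len)]
    }
  }
  # deduplicate on canonical keys
  if (length(exts) == 0) return(list())
  keys <- vapply(exts, canonical_key, character(1))
  exts[!duplicated(keys)]
}
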
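# Independent brute-force oracles used to cross-check the implementations.
# These deliberately do not share code with the package internals.

# ---- zinc fingers ----------------------------------------------------------

SAFE_AA <- c("A", "D", "E", "G", "I", "K", "M", "N", "Q", "R", "S", "T", "V")

# Build a protein with fingers planted at known positions. Linkers and finger
# interiors use an alphabet without C/H so the planted fingers are the only
# matches. Returns the protein plus the expected finger table.
plant_protein <- function(n_fingers, intact = TRUE) {
  parts <- character(0)
  pos <- 0L
  exp <- list()
  lead <- paste(sample(SAFE_AA, sample(3:10, 1), replace = TRUE),
                collapse = "")
  parts <- c(parts, lead)
  pos <- pos + nchar(lead)
  for (i in seq_len(n_fingers)) {
    cg <- sample(2:4, 1)
    hg <- sample(3:5, 1)
    body <- sample(SAFE_AA, cg + hg + 16, replace = TRUE)
    body[1] <- "C"
    body[cg + 2] <- "C"
    body[cg + 15] <- "H"
    body[cg + hg + 16] <- "H"
    first_his <- pos + cg + 14       # 0-based
    fp <- sample(SAFE_AA, 4, replace = TRUE)
    body[cg + 15 - c(7, 5, 4, 1)] <- fp   # helix -1/+2/+3/+6
    if (intact) {
      body[cg + 15 - 9] <- "F"       # helix -3
      body[cg + 15 - 3] <- "L"       # helix +4
    }
    finger <- paste(body, collapse = "")
    parts <- c(parts, finger)
    exp[[i]] <- data.frame(start = pos, first_his = first_his,
                           fingerprint = paste(fp, collapse = ""),
                           stringsAsFactors = FALSE)
    pos <- pos + nchar(finger)
    link <- paste(sample(SAFE_AA, sample(4:9, 1), replace = TRUE),
                  collapse = "")
    parts <- c(parts, link)
    pos <- pos + nchar(link)
  }
  list(seq = paste(parts, collapse = ""), expected = do.call(rbind, exp))
}

# Regex-scan oracle for canonical finger detection: leftmost non-overlapping
# matches of the lazy C2H2 pattern, with first_his derived from capture
# groups.
regex_finger_oracle <- function(seq) {
  pat <- "(C.{2,4}?C)(.{12})H.{3,5}?H"
  out <- data.frame(start = integer(0), first_his = integer(0))
  offset <- 0L
  while (TRUE) {
    m <- regexec(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) break
    start0 <- offset + m[1] - 1L                       # 0-based
    fh0 <- start0 + attr(m, "match.length")[2] + 12L   # C..C block + 12
    out <- rbind(out, data.frame(start = start0, first_his = fh0))
    consumed <- m[1] + attr(m, "match.length")[1] - 1L
    offset <- offset + consumed
    seq <- substring(seq, consumed + 1L)
  }
  out
}

# ---- global alignment ------------------------------------------------------

# Gotoh affine-gap global alignment score oracle: match 1, mismatch -1, a gap
# of length L costs open + L * ext.
nw_affine_score <- function(a, b, open = 2, ext = 0.5) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes x)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes y)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- 1-D tie groups --------------------------------------------------------

# O(n^2) pairwise-chaining oracle: union values whose distance is <= epsilon,
# then keep components of size >= min_size.
tie_groups_oracle <- function(values, epsilon, min_size) {
  n <- length(values)
  if (n < min_size) return(list(groups = list(), tied_fraction = 0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(values[i] - values[j]) <= epsilon) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  groups <- unname(groups[lengths(groups) >= min_size])
  groups <- lapply(groups, sort)
  ord <- order(vapply(groups, function(g) min(values[g]), numeric(1)))
  list(groups = groups[ord],
       tied_fraction = sum(lengths(groups)) / n)
}

# ---- gene blocks -----------------------------------------------------------

# Exhaustive repeated-substring oracle (with reversal), implementing the
# reported-block definition directly: candidates are patterns with >=
# min_occurrences greedily non-overlapping occurrences; a candidate is
# reported unless some one-label extension keeps its occurrence count.
blocks_oracle <- function(labels, min_len = 3, min_occurrences = 2) {
  n <- length(labels)
  occs <- function(pat) {
    len <- length(pat)
    res <- list()
    if (len > n) return(data.frame(start = integer(0),
                                   orientation = character(0)))
    for (s in 0:(n - len)) {
      w <- labels[(s + 1):(s + len)]
      if (identical(w, pat)) {
        res[[length(res) + 1]] <- data.frame(start = s,
                                             orientation = "forward")
      } else if (identical(w, rev(pat))) {
        res[[length(res) + 1]] <- data.frame(start = s,
                                             orientation = "reversed")
      }
    }
    if (length(res) == 0) return(data.frame(start = integer(0),
                                            orientation = character(0)))
    do.call(rbind, res)
  }
  nonoverlap <- function(pat) {
    oc <- occs(pat)
    if (nrow(oc) == 0) return(oc)
    oc <- oc[order(oc$start), , drop = FALSE]
    keep <- logical(nrow(oc)); last <- -1L
    for (i in seq_len(nrow(oc))) {
      if (oc$start[i] > last) { keep[i] <- TRUE; last <- oc$start[i] + length(pat) - 1L }
    }
    oc[keep, , drop = FALSE]
  }
  seen <- character(0)
  result <- list()
  if (n >= min_len) {
    for (len in min_len:n) {
      for (s in 1:(n - len + 1)) {
        pat <- labels[s:(s + len - 1)]
        key <- min(paste(pat, collapse = "\r"), paste(rev(pat), collapse = "\r"))
        if (key %in% seen) next
        seen <- c(seen, key)
        oc <- nonoverlap(pat)
        if (nrow(oc) < min_occurrences) next
        # every possible one-label extension, exhaustively over the alphabet
        subsumed <- FALSE
        for (lab in unique(labels)) {
          for (ext in list(c(lab, pat), c(pat, lab))) {
            if (nrow(nonoverlap(ext)) == nrow(oc)) { subsumed <- TRUE; break }
          }
          if (subsumed) break
        }
        if (!subsumed) {
          first <- oc[which.min(oc$start), ]
          rep_pat <- if (first$orientation == "forward") pat else rev(pat)
          result[[length(result) + 1]] <- list(labels = rep_pat,
                                               starts = sort(oc$start))
        }
      }
    }
  }
  result
}

# ---- contig filtering ------------------------------------------------------

# Brute-force contig-curation oracle: exhaustive bp summation for chromosome
# assignment and explicit pairwise containment checks in decreasing
# aligned-bp order.
contigs_oracle <- function(paf, known_chroms) {
  contigs <- unique(paf$query)
  dec <- lapply(contigs, function(ct) {
    sub <- paf[paf$query == ct & paf$target %in% known_chroms, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(list(contig = ct, reason = "unplaced", chrom = NA_character_,
                  bp = NA_real_, fs = NA_real_, fe = NA_real_, flip = FALSE))
    }
    chroms <- unique(sub$target)
    bp <- vapply(chroms, function(ch) sum(sub$aln_len[sub$target == ch]),
                 numeric(1))
    best <- chroms[order(-bp, chroms)][1]
    onb <- sub[sub$target == best, , drop = FALSE]
    list(contig = ct, reason = "kept", chrom = best, bp = sum(onb$aln_len),
         fs = min(onb$target_start), fe = max(onb$target_end),
         flip = sum(onb$aln_len[onb$strand == "-"]) > sum(onb$aln_len) / 2)
  })
  for (ch in unique(stats::na.omit(vapply(dec, function(d) d$chrom,
                                          character(1))))) {
    idx <- which(vapply(dec, function(d) {
      identical(d$chrom, ch) && d$reason != "unplaced"
    }, logical(1)))
    bp <- vapply(dec[idx], function(d) d$bp, numeric(1))
    nm <- vapply(dec[idx], function(d) d$contig, character(1))
    idx <- idx[order(-bp, nm)]
    kept <- integer(0)
    for (i in idx) {
      contained <- any(vapply(kept, function(j) {
        dec[[i]]$fs >= dec[[j]]$fs && dec[[i]]$fe <= dec[[j]]$fe
      }, logical(1)))
      if (contained) dec[[i]]$reason <- "nested" else kept <- c(kept, i)
    }
  }
  dec
}

random_paf <- function(n_contigs = 6, chroms = c("chr1", "chr2", "scaf7")) {
  rows <- list()
  for (i in seq_len(n_contigs)) {
    ct <- sprintf("ctg%02d", i)
    qlen <- sample(50:500, 1) * 1000
    for (j in seq_len(sample(1:4, 1))) {
      tgt <- sample(chroms, 1)
      alen <- sample(5:200, 1) * 1000
      qs <- sample(0:(qlen - 1000), 1)
      qe <- min(qlen, qs + alen)
      ts <- sample(0:5e6, 1)
      rows[[length(rows) + 1]] <- data.frame(
        query = ct, query_len = qlen, query_start = qs, query_end = qe,
        strand = sample(c("+", "-"), 1), target = tgt, target_len = 1e7,
        target_start = ts, target_end = ts + alen,
        n_match = round(0.95 * (qe - qs)), aln_len = alen, mapq = 60,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- misc ------------------------------------------------------------------

small_sim_config <- function(seed, ...) {
  sim_config(genome_len = 2e6, cluster_start = 8e5, cluster_end = 1e6,
             n_init_genes = 4, init_line_density = 20,
             te_families = data.frame(
               name = c("ERVK_sim", "L1MUS_sim"), class = c("LTR", "LINE"),
               consensus_len = c(600, 1200), insertion_rate = c(0.3, 0.2),
               cluster_bias = c(0.3, 0.1), stringsAsFactors = FALSE),
             generations = 60, seed = seed, ...)
}
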
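#' Detect C2H2 zinc fingers in a protein sequence
#'
#' The primary detector scans N-to-C for the canonical C2H2 pattern
#' `C-x(2,4)-C-x(12)-H-x(3,5)-H`, taking at each anchor the smallest
#' cysteine and histidine spacings that complete a match, and never letting
#' fingers overlap. An optional rescue pass then inspects inter-finger gaps
#' whose length is within 3 residues of one canonical finger period (28 aa)
#' and accepts a degenerate finger at the expected stride when at least two
#' of the four C2H2 residues are present; such fingers are classified by
#' [classify_finger()] (typically as C/H mutants).
#'
#' @param protein_seq Uppercase amino-acid string (standard 20-letter
#'   alphabet; `X` and `*` are rejected).
#' @param rescue Run the degenerate-finger rescue pass (default `TRUE`).
#' @return A data.frame, one row per finger in N-to-C order: `start`,
#'   `first_his`, `second_his`, `end` (all 0-based residue indices; `end`
#'   exclusive), `cys_gap`, `his_gap`, `residues`, `status`, `rescued`,
#'   `truncated`.
#' @export
detect_fingers <- function(protein_seq, rescue = TRUE) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1)
  aa <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
  if (length(aa) > 0 && !all(aa %in% AA20)) {
    stop("protein sequence contains non-amino-acid characters: ",
         paste(unique(aa[!aa %in% AA20]), collapse = ""))
  }
  n <- length(aa)
  hits <- list()
  pos <- 1L
  while (pos <= n - 18L) {
    f <- match_finger_at(aa, pos, n)
    if (!is.null(f)) {
      hits[[length(hits) + 1L]] <- f
      pos <- f$end_excl + 1L  # 1-based index just past the finger
    } else {
      pos <- pos + 1L
    }
  }
  res <- finger_rows(aa, hits, rescued = FALSE)
  if (rescue && nrow(res) > 0) {
    res <- rescue_fingers(aa, res)
  }
  res
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Try to match a canonical finger with first cysteine at 1-based position i.
# Smallest cys gap, then smallest his gap, wins (equivalent to a lazy regex
# C.{2,4}?C.{12}H.{3,5}?H anchored at i).
match_finger_at <- function(aa, i, n) {
  if (aa[i] != "C") return(NULL)
  for (cg in 2:4) {
    j <- i + cg + 1L            # second cysteine
    h1 <- j + 13L               # first histidine (after x(12))
    if (h1 > n || aa[j] != "C" || aa[h1] != "H") next
    for (hg in 3:5) {
      h2 <- h1 + hg + 1L
      if (h2 > n) break
      if (aa[h2] == "H") {
        return(list(start = i, cys_gap = cg, his_gap = hg,
                    first_his = h1, second_his = h2, end_excl = h2))
      }
    }
  }
  NULL
}

finger_rows <- function(aa, hits, rescued) {
  if (length(hits) == 0) {
    return(data.frame(start = integer(0), first_his = integer(0),
                      second_his = integer(0), end = integer(0),
                      cys_gap = integer(0), his_gap = integer(0),
                      residues = character(0), status = character(0),
                      rescued = logical(0), truncated = logical(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(f) {
    data.frame(start = f$start - 1L, first_his = f$first_his - 1L,
               second_his = f$second_his - 1L, end = f$end_excl,
               cys_gap = f$cys_gap, his_gap = f$his_gap,
               residues = paste(aa[f$start:f$end_excl], collapse = ""),
               stringsAsFactors = FALSE)
  }))
  cls <- classify_rows(aa, df)
  df$status <- cls$status
  df$rescued <- rescued
  df$truncated <- cls$truncated
  df
}

# Rescue pass over the gaps between (and flanking) canonical fingers.
rescue_fingers <- function(aa, res) {
  n <- length(aa)
  period <- 28L
  # gap list: (left bound exclusive, right bound exclusive, expected start),
  # all 0-based; expected start anchored on the neighbouring finger.
  gaps <- list()
  starts <- res$start
  ends <- res$end
  if (starts[1] >= period - 3L) {
    gaps[[length(gaps) + 1L]] <- c(lo = 0L, hi = starts[1],
                                   exp = starts[1] - period)
  }
  if (nrow(res) > 1) {
    for (k in seq_len(nrow(res) - 1L)) {
      # one missing finger shows up either as a gap of about one period or as
      # a start-to-start stride of about two periods
      if (abs((starts[k + 1L] - starts[k]) - 2L * period) <= 3L ||
          abs((starts[k + 1L] - ends[k]) - period) <= 3L) {
        gaps[[length(gaps) + 1L]] <- c(lo = ends[k], hi = starts[k + 1L],
                                       exp = starts[k] + period,
                                       forced = 1L)
      }
    }
  }
  if (n - ends[nrow(res)] >= period - 3L) {
    gaps[[length(gaps) + 1L]] <- c(lo = ends[nrow(res)], hi = n,
                                   exp = starts[nrow(res)] + period)
  }
  extra <- list()
  for (g in gaps) {
    if (!("forced" %in% names(g))) {
      gap_len <- g[["hi"]] - g[["lo"]]
      if (abs(gap_len - period) > 3L) next
    }
    cand <- best_relaxed_match(aa, lo = g[["lo"]], hi = g[["hi"]],
                               exp = g[["exp"]])
    if (!is.null(cand)) extra[[length(extra) + 1L]] <- cand
  }
  if (length(extra) == 0) return(res)
  add <- finger_rows(aa, extra, rescued = TRUE)
  out <- rbind(res, add)
  out[order(out$start), , drop = FALSE]
}

# Relaxed C2H2 match inside [lo, hi) (0-based bounds), anchored at the
# expected stride: start within +/- 3 of `exp`, window fully inside the gap,
# at least 2 of the 4 C2H2 residues present. Best score wins; ties break on
# smallest |start - exp|, then smallest spacings.
best_relaxed_match <- function(aa, lo, hi, exp) {
  best <- NULL
  for (delta in order(abs(-3:3))) {
    s0 <- exp + (-3:3)[delta]            # 0-based candidate start
    if (s0 < lo || s0 < 0) next
    for (cg in 2:4) {
      for (hg in 3:5) {
        len <- cg + hg + 16L
        if (s0 + len > hi) next
        i <- s0 + 1L                     # 1-based
        j <- i + cg + 1L
        h1 <- j + 13L
        h2 <- h1 + hg + 1L
        score <- (aa[i] == "C") + (aa[j] == "C") +
          (aa[h1] == "H") + (aa[h2] == "H")
        if (score >= 2 && (is.null(best) || score > best$score)) {
          best <- list(start = i, cys_gap = cg, his_gap = hg,
                       first_his = h1, second_his = h2, end_excl = h2,
                       score = score)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}

classify_rows <- function(aa, df) {
  n <- length(aa)
  status <- character(nrow(df))
  truncated <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    fh <- df$first_his[k] + 1L   # 1-based
    sh <- df$second_his[k] + 1L
    st <- df$start[k] + 1L
    cg <- df$cys_gap[k]
    chz_ok <- aa[st] == "C" && aa[st + cg + 1L] == "C" &&
      aa[fh] == "H" && aa[sh] == "H"
    if (fh - 18L < 1L) {
      # structural positions fall before the sequence start: the finger
      # cannot be certified intact; treated as degenerate (C/H-mutant class)
      status[k] <- "chz_mutant"
      truncated[k] <- TRUE
    } else if (!chz_ok) {
      status[k] <- "chz_mutant"
    } else if (!(aa[fh - 18L] %in% c("F", "Y")) || aa[fh - 9L] != "F" ||
               aa[fh - 3L] != "L") {
      status[k] <- "structural_mutant"
    } else {
      status[k] <- "intact"
    }
  }
  list(status = status, truncated = truncated)
}

#' Classify one zinc finger as intact or mutant
#'
#' A finger is a C/H mutant ("red") when any of the two cysteines or two
#' histidines is absent from its expected position; otherwise it is a
#' structural mutant ("yellow") when the conserved structural residues are
#' violated (helix position -12, i.e. `first_his - 18`, not F/Y; -3
#' (`first_his - 9`) not F; +4 (`first_his - 3`) not L); otherwise intact.
#' The C/H check takes precedence. Fingers whose structural positions fall
#' before the start of the protein are flagged truncated and conservatively
#' classified with the C/H-mutant status.
#'
#' @param protein_seq Protein sequence containing the finger.
#' @param start 0-based index of the first (expected) cysteine.
#' @param first_his 0-based index of the first histidine of the H..H pair.
#' @param cys_gap Spacing between the two cysteines (2-4).
#' @return One of `"intact"`, `"structural_mutant"`, `"chz_mutant"`.
#' @export
classify_finger <- function(protein_seq, start, first_his, cys_gap = 2) {
  aa <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
  second_his <- NA_integer_
  # locate the second H if present at any accepted spacing; absence = mutant
  for (hg in 3:5) {
    idx <- first_his + hg + 2L
    if (idx <= length(aa) && aa[idx] == "H") { second_his <- idx - 1L; break }
  }
  if (is.na(second_his)) second_his <- min(first_his + 5L, length(aa) - 1L)
  df <- data.frame(start = start, first_his = first_his,
                   second_his = second_his, cys_gap = cys_gap)
  classify_rows(aa, df)$status[1]
}

#' Extract the 4-residue recognition-helix fingerprint of a finger
#'
#' The fingerprint consists of the residues at helical positions -1, +2, +3
#' and +6, which sit at offsets `first_his - 7`, `- 5`, `- 4` and `- 1`
#' respectively, concatenated N-to-C.
#'
#' @param protein_seq Protein sequence.
#' @param first_his 0-based index of the first histidine of the finger.
#' @param start 0-based finger start; `first_his - 7 < start` is a malformed
#'   finger and raises an error.
#' @return A 4-character fingerprint string.
#' @examples
#' # Zif268 finger 1: helix ...RSDELTR preceding the first histidine
#' extract_fingerprint("PYACPVESCDRRFSRSDELTRHIRIH", first_his = 21, start = 3)
#' @export
extract_fingerprint <- function(protein_seq, first_his, start = 0) {
  if (first_his - 7 < start) {
    stop("malformed finger: fingerprint position -1 precedes finger start")
  }
  aa <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
  idx <- first_his + 1L - c(7L, 5L, 4L, 1L)
  paste(aa[idx], collapse = "")
}

#' Build the fingerprint array of a protein
#'
#' Detects fingers, extracts per-finger fingerprints, classifies each finger
#' and joins the fingerprints N-to-C with `"|"` into the array signature used
#' as the exact-match key for cross-assembly comparison. Mutant fingers'
#' fingerprints are included by default; `intact_only = TRUE` restricts the
#' signature to intact fingers.
#'
#' @param protein_id Identifier carried through to the output.
#' @param protein_seq Protein sequence.
#' @param intact_only Drop mutant fingers from the signature.
#' @param rescue Passed to [detect_fingers()].
#' @return A list with `protein_id`, `fingers` (the [detect_fingers()] table
#'   plus a `fingerprint` column), `signature`, and `is_kzfp` (`FALSE` when
#'   no finger was found; the signature is then empty).
#' @export
build_array <- function(protein_id, protein_seq, intact_only = FALSE,
                        rescue = TRUE) {
  fingers <- detect_fingers(protein_seq, rescue = rescue)
  if (nrow(fingers) > 0) {
    fingers$fingerprint <- vapply(seq_len(nrow(fingers)), function(k) {
      extract_fingerprint(protein_seq, fingers$first_his[k], fingers$start[k])
    }, character(1))
  } else {
    fingers$fingerprint <- character(0)
  }
  use <- if (intact_only) fingers$status == "intact" else rep(TRUE, nrow(fingers))
  list(protein_id = protein_id,
       fingers = fingers,
       signature = paste(fingers$fingerprint[use], collapse = "|"),
       is_kzfp = nrow(fingers) > 0)
}

#' Fingerprint arrays for every sequence of a protein FASTA
#'
#' @param path Protein FASTA file.
#' @param ... Passed to [build_array()].
#' @return A data.frame with `protein_id`, `n_fingers`, `signature`,
#'   `is_kzfp`.
#' @export
fingerprints_from_fasta <- function(path, ...) {
  seqs <- Biostrings::readAAStringSet(path)
  rows <- lapply(seq_along(seqs), function(i) {
    arr <- build_array(names(seqs)[i], as.character(seqs[[i]]), ...)
    data.frame(protein_id = arr$protein_id, n_fingers = nrow(arr$fingers),
               signature = arr$signature, is_kzfp = arr$is_kzfp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare fingerprint-array repertoires across assemblies
#'
#' Signatures are matched by exact string equality. The result is a
#' Venn-style partition: each distinct signature is assigned to the subset of
#' assemblies that carry it, with per-assembly copy counts (repertoires are
#' multisets; the same array can be present in several gene copies).
#'
#' @param repertoires Named list (>= 2 entries, unique names) of character
#'   vectors of array signatures.
#' @return A data.frame with `signature`, `cell` (assembly names joined with
#'   `"+"`), and one copy-count column per assembly.
#' @export
compare_repertoires <- function(repertoires) {
  stopifnot(is.list(repertoires), length(repertoires) >= 2)
  nm <- names(repertoires)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("repertoires must have unique, nonempty assembly names")
  }
  sigs <- sort(unique(unlist(repertoires, use.names = FALSE)))
  counts <- vapply(repertoires, function(r) {
    as.numeric(table(factor(r, levels = sigs)))
  }, numeric(length(sigs)))
  counts <- matrix(counts, nrow = length(sigs),
                   dimnames = list(sigs, nm))
  cell <- apply(counts > 0, 1, function(p) paste(nm[p], collapse = "+"))
  out <- data.frame(signature = sigs, cell = cell, stringsAsFactors = FALSE)
  for (a in nm) out[[a]] <- counts[, a]
  rownames(out) <- NULL
  out[order(out$cell, out$signature), , drop = FALSE]
}
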
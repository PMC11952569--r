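#' Reference-guided contig filtering and strand correction
#'
#' Applies the assembly-curation rules to contig-to-reference alignments:
#' (i) contigs with no alignment to a known chromosome are dropped
#' (`unplaced`); (ii) a contig aligning to several chromosomes is assigned to
#' the chromosome receiving its largest total aligned bp; (iii) per
#' chromosome, a contig whose reference footprint (min target start to max
#' target end over its assigned-chromosome alignments) is fully contained in
#' a kept contig's footprint is dropped as `nested` — contigs are considered
#' in decreasing total aligned bp (ties broken by contig name), so the
#' smaller alignment loses. A kept contig is flagged for strand flipping when
#' the majority of its assigned-chromosome aligned bp lies on the minus
#' strand.
#'
#' @param paf PAF alignment table (see [read_paf()]).
#' @param known_chroms Character vector of recognised chromosome names.
#' @return A data.frame with one row per contig: `contig`, `kept`,
#'   `assigned_chrom` (`NA` when unplaced), `flip`, `reason`
#'   (`"kept"`/`"unplaced"`/`"nested"`), `aligned_bp`, `footprint_start`,
#'   `footprint_end`.
#' @export
filter_contigs <- function(paf, known_chroms) {
  stopifnot(length(known_chroms) > 0)
  if (nrow(paf) == 0) {
    warning("empty PAF: no contigs to keep")
    return(data.frame(contig = character(0), kept = logical(0),
                      assigned_chrom = character(0), flip = logical(0),
                      reason = character(0), aligned_bp = numeric(0),
                      footprint_start = numeric(0),
                      footprint_end = numeric(0), stringsAsFactors = FALSE))
  }
  contigs <- unique(paf$query)
  res <- data.frame(contig = contigs, kept = FALSE,
                    assigned_chrom = NA_character_, flip = FALSE,
                    reason = "unplaced", aligned_bp = NA_real_,
                    footprint_start = NA_real_, footprint_end = NA_real_,
                    stringsAsFactors = FALSE)
  known <- paf[paf$target %in% known_chroms, , drop = FALSE]
  for (i in seq_along(contigs)) {
    sub <- known[known$query == contigs[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    bp <- tapply(sub$aln_len, sub$target, sum)
    # largest total aligned bp wins; ties break lexicographically
    best <- names(bp)[order(-as.numeric(bp), names(bp))][1]
    on_best <- sub[sub$target == best, , drop = FALSE]
    res$assigned_chrom[i] <- best
    res$aligned_bp[i] <- sum(on_best$aln_len)
    res$footprint_start[i] <- min(on_best$target_start)
    res$footprint_end[i] <- max(on_best$target_end)
    minus_bp <- sum(on_best$aln_len[on_best$strand == "-"])
    res$flip[i] <- minus_bp > res$aligned_bp[i] / 2
    res$reason[i] <- "kept"
  }
  for (chrom in unique(stats::na.omit(res$assigned_chrom))) {
    idx <- which(res$assigned_chrom == chrom & res$reason != "unplaced")
    idx <- idx[order(-res$aligned_bp[idx], res$contig[idx])]
    kept <- integer(0)
    for (i in idx) {
      nested <- any(res$footprint_start[i] >= res$footprint_start[kept] &
                      res$footprint_end[i] <= res$footprint_end[kept])
      if (nested) {
        res$reason[i] <- "nested"
        res$flip[i] <- FALSE
      } else {
        kept <- c(kept, i)
      }
    }
  }
  res$kept <- res$reason == "kept"
  res$assigned_chrom[!res$kept] <- ifelse(res$reason[!res$kept] == "nested",
                                          res$assigned_chrom[!res$kept],
                                          NA_character_)
  res
}
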
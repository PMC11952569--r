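#' Construct a table of genomic intervals
#'
#' All coordinates inside the package are 0-based half-open; conversion from
#' 1-based formats (GFF, RepeatMasker .out) happens only at file boundaries.
#'
#' @param seqid Character vector of sequence names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end; must satisfy `start < end`.
#' @param strand Character vector in `+`, `-`, `.` (unstranded).
#' @return A `data.frame` with columns `seqid`, `start`, `end`, `strand`.
#' @export
intervals <- function(seqid, start, end, strand = ".") {
  df <- data.frame(
    seqid = as.character(seqid),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(seqid)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' @param df A data.frame with at least `seqid`, `start`, `end` columns.
#' @return `df`, invisibly; errors on violated invariants.
#' @export
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("seqid", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

# Effective strand for operations that require orientation: '.' is treated
# as '+' with a warning (deterministic behaviour over silent drops).
effective_strand <- function(strand) {
  if (any(strand == ".")) {
    warning("unstranded intervals treated as '+'")
    strand[strand == "."] <- "+"
  }
  strand
}

# Convert an interval table to a per-seqid IRangesList (1-based inclusive).
iv_to_iranges <- function(df) {
  if (nrow(df) == 0) {
    return(split(IRanges::IRanges(), factor(character(0))))
  }
  split(IRanges::IRanges(start = df$start + 1, end = df$end), df$seqid)
}

#' Total base pairs covered by an interval set (union)
#'
#' Overlapping or nested intervals are counted once, which avoids
#' double-counting fragmented or nested RepeatMasker hits.
#'
#' @param df Interval table.
#' @return Total covered bp (numeric scalar).
#' @export
interval_union_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  rl <- iv_to_iranges(df)
  sum(vapply(rl, function(r) sum(IRanges::width(IRanges::reduce(r))), numeric(1)))
}

#' Base pairs shared between two interval sets
#'
#' Computes the union of each set first, then the bp of their intersection,
#' so multiplicity on either side does not inflate the overlap.
#'
#' @param a,b Interval tables.
#' @return Overlap bp (numeric scalar).
#' @export
interval_overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  seqs <- intersect(unique(a$seqid), unique(b$seqid))
  tot <- 0
  for (s in seqs) {
    ra <- IRanges::reduce(iv_to_iranges(a[a$seqid == s, , drop = FALSE])[[s]])
    rb <- IRanges::reduce(iv_to_iranges(b[b$seqid == s, , drop = FALSE])[[s]])
    tot <- tot + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  tot
}

# Clip intervals in `df` to the (union of the) intervals in `space`,
# preserving per-row identity of `df` where possible.
iv_clip <- function(df, space) {
  if (nrow(df) == 0) return(df)
  keep <- list()
  for (s in unique(df$seqid)) {
    sub <- df[df$seqid == s, , drop = FALSE]
    sp <- space[space$seqid == s, , drop = FALSE]
    if (nrow(sp) == 0) next
    rsub <- IRanges::IRanges(sub$start + 1, sub$end)
    rsp <- IRanges::reduce(IRanges::IRanges(sp$start + 1, sp$end))
    hits <- IRanges::findOverlaps(rsub, rsp)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    inter <- IRanges::pintersect(rsub[qi], rsp[S4Vectors::subjectHits(hits)])
    out <- sub[qi, , drop = FALSE]
    out$start <- IRanges::start(inter) - 1
    out$end <- IRanges::end(inter)
    keep[[s]] <- out
  }
  if (length(keep) == 0) return(df[0, , drop = FALSE])
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

# Midpoint of each interval (numeric, may be half-integral).
iv_midpoint <- function(df) (df$start + df$end) / 2

# TRUE for rows whose midpoint falls inside any interval of `locus`
# (same seqid, start <= mid < end).
midpoint_in_locus <- function(df, locus) {
  if (nrow(df) == 0) return(logical(0))
  mid <- iv_midpoint(df)
  res <- logical(nrow(df))
  for (i in seq_len(nrow(locus))) {
    res <- res | (df$seqid == locus$seqid[i] &
                    mid >= locus$start[i] & mid < locus$end[i])
  }
  res
}

#' Fraction of a genome occupied by a locus, in percent
#'
#' @param locus_len Locus length in bp.
#' @param genome_len Genome length in bp.
#' @return `100 * locus_len / genome_len`.
#' @examples
#' # a 5.4 Mb cluster in a 2.53 Gb genome occupies ~0.2% of it
#' round(locus_fraction(5.4e6, 2525297504), 1)
#' @export
locus_fraction <- function(locus_len, genome_len) {
  stopifnot(locus_len > 0, genome_len >= locus_len)
  100 * locus_len / genome_len
}
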
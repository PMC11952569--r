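#' Read genomic intervals from BED or GFF
#'
#' BED is 0-based half-open and used as-is; GFF ("gff_lite", the 9-column
#' seqid/source/type/start/end/score/strand/frame/attributes subset) is
#' 1-based inclusive and converted to the internal 0-based half-open
#' convention on read. Input record order is preserved.
#'
#' @param path Path to the file.
#' @param format `"bed"` (>= 3 tab-separated columns) or `"gff_lite"`.
#' @return Interval table with columns `seqid`, `start`, `end`, `strand`,
#'   plus `name`/`score` (BED) or `source`/`type`/`score`/`attributes` (GFF).
#' @export
read_intervals <- function(path, format = c("bed", "gff_lite")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(intervals(character(0), numeric(0), numeric(0), character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nmin <- if (format == "bed") 3L else 9L
  short <- which(lengths(fields) < nmin)
  if (length(short) > 0) {
    stop("malformed ", format, " line ", lineno[short[1]], " in ", path,
         ": fewer than ", nmin, " columns")
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  opt <- function(i, default) {
    v <- vapply(fields, function(f) if (length(f) >= i) f[i] else default,
                character(1))
    v[v == "."] <- default
    v
  }
  if (format == "bed") {
    start <- suppressWarnings(as.numeric(get(2)))
    end <- suppressWarnings(as.numeric(get(3)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad) > 0) {
      stop("malformed bed line ", lineno[bad[1]], " in ", path,
           ": non-numeric coordinates")
    }
    df <- data.frame(seqid = get(1), start = start, end = end,
                     strand = opt(6, "."), name = opt(4, "."),
                     score = suppressWarnings(as.numeric(opt(5, "0"))),
                     stringsAsFactors = FALSE)
  } else {
    start1 <- suppressWarnings(as.numeric(get(4)))
    end1 <- suppressWarnings(as.numeric(get(5)))
    bad <- which(is.na(start1) | is.na(end1))
    if (length(bad) > 0) {
      stop("malformed gff line ", lineno[bad[1]], " in ", path,
           ": non-numeric coordinates")
    }
    df <- data.frame(seqid = get(1), start = start1 - 1, end = end1,
                     strand = opt(7, "."), source = get(2), type = get(3),
                     score = suppressWarnings(as.numeric(opt(6, "0"))),
                     attributes = get(9), stringsAsFactors = FALSE)
  }
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    stop("invalid coordinates (start >= end) at line ", lineno[bad[1]],
         " in ", path)
  }
  df
}

#' Write intervals as BED
#'
#' @param df Interval table (`seqid`, `start`, `end`, optional `name`,
#'   `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$seqid, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as GFF (1-based inclusive coordinates)
#'
#' Round trip with [read_intervals()] (`format = "gff_lite"`) reproduces the
#' input coordinates exactly.
#'
#' @param df Interval table.
#' @param path Output path.
#' @param source,type GFF column 2/3 values (recycled).
#' @return `path`, invisibly.
#' @export
write_gff <- function(df, path, source = "kzfpcluster", type = "region") {
  validate_intervals(df)
  out <- data.frame(
    df$seqid, rep_len(source, nrow(df)), rep_len(type, nrow(df)),
    format(df$start + 1, scientific = FALSE, trim = TRUE),
    format(df$end, scientific = FALSE, trim = TRUE),
    if ("score" %in% names(df)) df$score else ".",
    if ("strand" %in% names(df)) df$strand else ".",
    ".",
    if ("attributes" %in% names(df)) df$attributes else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a RepeatMasker .out annotation table
#'
#' Expects the standard whitespace-delimited layout with 3 header lines.
#' Column 2 is the percent divergence to the family consensus, column 10 the
#' repeat (family) name and column 11 the class/family string; the class is
#' the text before the "/" and is mapped onto LTR/LINE/SINE/DNA/other.
#' Orientation "C" (complement) is mapped to strand "-". Query coordinates
#' (1-based inclusive in .out) are converted to 0-based half-open.
#'
#' @param path Path to the .out file.
#' @return A repeat table: `seqid`, `start`, `end`, `strand`, `family`,
#'   `te_class`, `pct_div`.
#' @export
read_repeatmasker_out <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_repeats())
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  n <- lengths(fields)
  bad <- which(n < 11)
  if (length(bad) > 0) {
    stop("unparseable RepeatMasker row ", bad[1] + 3, " in ", path)
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  pct_div <- suppressWarnings(as.numeric(get(2)))
  qstart <- suppressWarnings(as.numeric(get(6)))
  qend <- suppressWarnings(as.numeric(get(7)))
  bad <- which(is.na(pct_div) | is.na(qstart) | is.na(qend) | qstart > qend)
  if (length(bad) > 0) {
    stop("unparseable RepeatMasker row ", bad[1] + 3, " in ", path)
  }
  orient <- get(9)
  strand <- ifelse(orient == "C", "-", "+")
  cls_fam <- get(11)
  cls <- sub("/.*$", "", cls_fam)
  repeats(seqid = get(5), start = qstart - 1, end = qend, strand = strand,
          family = get(10), te_class = cls, pct_div = pct_div)
}

#' Construct a repeat-copy table
#'
#' @param seqid,start,end,strand Interval fields (0-based half-open).
#' @param family Repeat family name (e.g. `MLTR18A_MM`); must be nonempty.
#' @param te_class Repeat class; anything outside LTR/LINE/SINE/DNA is
#'   normalised to "other".
#' @param pct_div Percent divergence to the family consensus, in `[0, 100]`.
#' @return Repeat table.
#' @export
repeats <- function(seqid, start, end, strand = "+", family, te_class,
                    pct_div) {
  te_class <- as.character(te_class)
  te_class[!te_class %in% c("LTR", "LINE", "SINE", "DNA")] <- "other"
  df <- intervals(seqid, start, end, strand)
  df$family <- as.character(family)
  df$te_class <- te_class
  df$pct_div <- as.numeric(pct_div)
  if (any(!nzchar(df$family))) stop("repeat family names must be nonempty")
  if (any(df$pct_div < 0 | df$pct_div > 100)) {
    stop("pct_div must lie in [0, 100]")
  }
  df
}

empty_repeats <- function() {
  repeats(character(0), numeric(0), numeric(0), character(0),
          character(0), character(0), numeric(0))
}

#' Write a repeat table in RepeatMasker .out layout
#'
#' Emits the 3 header lines and the standard column order so the file can be
#' re-read with [read_repeatmasker_out()].
#'
#' @param rep Repeat table (see [repeats()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(rep, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query     matching repeat        position in repeat",
    "score   div. del. ins.  sequence  begin  end   (left)   repeat   class/family  begin end (left) ID",
    "")
  rows <- sprintf("%5d %.4f %4.1f %4.1f %s %d %d (0) %s %s %s/%s %d %d (0) %d",
                  1000L, rep$pct_div, 0, 0, rep$seqid,
                  as.integer(rep$start) + 1L, as.integer(rep$end),
                  ifelse(rep$strand == "-", "C", "+"),
                  rep$family, rep$te_class, rep$family,
                  1L, as.integer(rep$end - rep$start), seq_len(nrow(rep)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Maps the 12 mandatory columns; SAM-style tag columns are ignored.
#'
#' @param path Path to the PAF file.
#' @return A data.frame with columns `query`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target`, `target_len`, `target_start`,
#'   `target_end`, `n_match`, `aln_len`, `mapq`.
#' @export
read_paf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12)
  if (length(bad) > 0) {
    stop("PAF line ", bad[1], " in ", path, " has fewer than 12 columns")
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(i) suppressWarnings(as.numeric(get(i)))
  df <- data.frame(query = get(1), query_len = num(2), query_start = num(3),
                   query_end = num(4), strand = get(5), target = get(6),
                   target_len = num(7), target_start = num(8),
                   target_end = num(9), n_match = num(10), aln_len = num(11),
                   mapq = num(12), stringsAsFactors = FALSE)
  bad <- which(!(df$query_start < df$query_end &
                   df$query_end <= df$query_len &
                   df$target_start < df$target_end &
                   df$n_match <= df$aln_len))
  if (length(bad) > 0) {
    stop("PAF line ", bad[1], " in ", path, " violates coordinate invariants")
  }
  df
}

empty_paf <- function() {
  data.frame(query = character(0), query_len = numeric(0),
             query_start = numeric(0), query_end = numeric(0),
             strand = character(0), target = character(0),
             target_len = numeric(0), target_start = numeric(0),
             target_end = numeric(0), n_match = numeric(0),
             aln_len = numeric(0), mapq = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read a MACS-style narrowPeak file
#'
#' narrowPeak column 9 carries the q-value; MACS emits it as -log10 so the
#' default dialect converts it back to a plain q-value. Column 7
#' (signalValue) is taken as fold enrichment over input; column 10 is the
#' summit offset.
#'
#' @param path Path to the narrowPeak file.
#' @param q_dialect `"neglog10"` (MACS convention, default) or `"plain"`.
#' @return Peak table: `seqid`, `start`, `end`, `strand`, `name`, `summit`,
#'   `q_value` (plain scale), `fold_enrichment`.
#' @export
read_narrowpeak <- function(path, q_dialect = c("neglog10", "plain")) {
  q_dialect <- match.arg(q_dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track)", lines)]
  if (length(lines) == 0) {
    return(data.frame(seqid = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      name = character(0), summit = numeric(0),
                      q_value = numeric(0), fold_enrichment = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 10)
  if (length(bad) > 0) {
    stop("narrowPeak line ", bad[1], " in ", path, " has fewer than 10 columns")
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(i) suppressWarnings(as.numeric(get(i)))
  q <- num(9)
  if (q_dialect == "neglog10") q <- 10^(-q)
  df <- data.frame(seqid = get(1), start = num(2), end = num(3),
                   strand = get(6), name = get(4), summit = num(10),
                   q_value = q, fold_enrichment = num(7),
                   stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "."
  bad <- which(df$summit < 0 | df$summit > (df$end - df$start) |
                 df$fold_enrichment < 0)
  if (length(bad) > 0) {
    stop("narrowPeak line ", bad[1], " in ", path, " violates peak invariants")
  }
  df
}

#' Write a table of records as TSV (with header)
#'
#' Reading the file back with [read_table_tsv()] reproduces the records
#' field-for-field. A list of per-record data.frames is accepted and must be
#' schema-homogeneous.
#'
#' @param records A data.frame, or a list of 1-row data.frames sharing the
#'   same columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (!is.list(records) || length(records) == 0 ||
        !all(vapply(records, is.data.frame, logical(1)))) {
      stop("records must be a data.frame or a nonempty list of data.frames")
    }
    schemas <- lapply(records, names)
    if (!all(vapply(schemas, identical, logical(1), schemas[[1]]))) {
      stop("records have mixed schemas")
    }
    records <- do.call(rbind, records)
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}
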
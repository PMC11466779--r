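#' Genomic intervals and on-disk formats
#'
#' All intervals in `triomics` are plain data frames with columns
#' `chrom` (character), `start`, `end` (0-based half-open, BED
#' convention) and optionally `name` and `score`. Overlap queries are
#' delegated to GenomicRanges; the 0-based half-open to 1-based closed
#' conversion happens only inside [as_granges()].
#'
#' @name intervals
NULL

#' Construct an interval data frame
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors, 0-based half-open.
#' @param name optional identifiers.
#' @param score optional numeric scores.
#' @return data.frame with validated interval columns.
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  validate_intervals(df)
  df
}

#' Validate an interval data frame
#'
#' Checks the 0 <= start < end invariant and integral coordinates.
#'
#' @param df interval data frame.
#' @param where label used in error messages (e.g. a file name).
#' @return the input, invisibly.
#' @export
validate_intervals <- function(df, where = "intervals") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(where, ": missing columns ", paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end) ||
      any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop(where, ": non-integer coordinate")
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop(where, ": invalid interval (start >= end or start < 0) at row ",
         bad[1])
  invisible(df)
}

#' Sort intervals by (chrom, start, end)
#' @param df interval data frame.
#' @return sorted data frame, row names dropped.
#' @export
sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Convert 0-based half-open intervals to a GRanges (1-based closed).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read a BED / narrowPeak file
#'
#' Accepts >= 3 tab-separated columns; column 4 becomes `name` and
#' column 5 `score` when present (narrowPeak extra columns beyond 5
#' are ignored). Lines starting with `#` or `track` are skipped.
#' Coordinates are kept in BED convention (0-based half-open).
#'
#' @param path file path.
#' @return sorted interval data frame.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#|^track|^browser|^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(intervals(character(), integer(), integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3))
    stop(path, ": line ", lineno[which(ncol < 3)[1]], ": fewer than 3 columns")
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) |
               start != floor(start) | end != floor(end))
  if (length(bad))
    stop(path, ": line ", lineno[bad[1]], ": non-integer coordinate")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop(path, ": line ", lineno[bad[1]], ": start >= end")
  df <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                   start = start, end = end, stringsAsFactors = FALSE)
  if (all(ncol >= 4))
    df$name <- vapply(parts, `[[`, "", 4L)
  if (all(ncol >= 5))
    df$score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L)))
  sort_intervals(df)
}

#' Write intervals as BED
#'
#' Writes tab-separated BED with a `#`-prefixed header line.
#'
#' @param df interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, where = path)
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(df)) {
    out <- df[, cols, drop = FALSE]
    out$start <- format(out$start, scientific = FALSE, trim = TRUE)
    out$end <- format(out$end, scientific = FALSE, trim = TRUE)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read per-sample chromatin loops from a BEDPE-like file
#'
#' Expects >= 7 tab-separated columns: chrom1, start1, end1, chrom2,
#' start2, end2, strength, and an optional 8th loop id column. Anchors
#' are stored canonically ordered so that (chrom1, start1) <=
#' (chrom2, start2) lexicographically; a missing loop id is
#' synthesized as `"chrom1:start1-end1|chrom2:start2-end2"` from the
#' canonical anchors.
#'
#' @param path file path.
#' @return data.frame with columns chrom1, start1, end1, chrom2,
#'   start2, end2, strength, loop_id.
#' @export
read_bedpe_loops <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#|^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom1 = character(), start1 = numeric(),
                      end1 = numeric(), chrom2 = character(),
                      start2 = numeric(), end2 = numeric(),
                      strength = numeric(), loop_id = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 7))
    stop(path, ": line ", lineno[which(ncol < 7)[1]], ": fewer than 7 columns")
  num <- function(k) suppressWarnings(as.numeric(vapply(parts, `[[`, "", k)))
  df <- data.frame(chrom1 = vapply(parts, `[[`, "", 1L),
                   start1 = num(2L), end1 = num(3L),
                   chrom2 = vapply(parts, `[[`, "", 4L),
                   start2 = num(5L), end2 = num(6L),
                   strength = num(7L), stringsAsFactors = FALSE)
  for (side in c(1, 2)) {
    s <- df[[paste0("start", side)]]; e <- df[[paste0("end", side)]]
    bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
    if (length(bad))
      stop(path, ": line ", lineno[bad[1]], ": non-integer coordinate")
    bad <- which(s < 0 | s >= e)
    if (length(bad))
      stop(path, ": line ", lineno[bad[1]], ": start >= end")
  }
  if (anyNA(df$strength))
    stop(path, ": line ", lineno[which(is.na(df$strength))[1]],
         ": non-numeric strength")
  if (any(df$strength < 0))
    stop(path, ": line ", lineno[which(df$strength < 0)[1]],
         ": negative loop strength")
  # canonical anchor order: (chrom, start) lexicographic
  flip <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$start2 < df$start1)
  if (any(flip)) {
    tmp <- df[flip, c("chrom1", "start1", "end1")]
    df[flip, c("chrom1", "start1", "end1")] <-
      df[flip, c("chrom2", "start2", "end2")]
    df[flip, c("chrom2", "start2", "end2")] <- tmp
  }
  if (any(ncol >= 8)) {
    df$loop_id <- vapply(parts, function(p)
      if (length(p) >= 8) p[[8]] else NA_character_, "")
  } else df$loop_id <- NA_character_
  auto <- is.na(df$loop_id) | df$loop_id == ""
  df$loop_id[auto] <- sprintf("%s:%d-%d|%s:%d-%d",
    df$chrom1[auto], df$start1[auto], df$end1[auto],
    df$chrom2[auto], df$start2[auto], df$end2[auto])
  dup <- duplicated(df$loop_id)
  if (any(dup))
    stop(path, ": duplicate loop_id '", df$loop_id[which(dup)[1]], "'")
  rownames(df) <- NULL
  df
}

#' Write loops as BEDPE
#' @param df loop data frame as returned by [read_bedpe_loops()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe_loops <- function(df, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "strength", "loop_id")
  stopifnot(all(cols %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(df)) {
    out <- df[, cols, drop = FALSE]
    for (k in c("start1", "end1", "start2", "end2"))
      out[[k]] <- format(out[[k]], scientific = FALSE, trim = TRUE)
    out$strength <- sprintf("%.17g", out$strength)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' 6-column BED-like TSV: chrom, start, end, gene_id, symbol, strand.
#' The transcription start site is derived from the body and strand
#' (`start` on +, `end - 1` on -).
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end, gene_id, symbol,
#'   strand, tss.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop(path, ": expected 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "gene_id", "symbol", "strand")
  df <- df[, 1:6]
  validate_intervals(df, where = path)
  if (!all(df$strand %in% c("+", "-")))
    stop(path, ": strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicate gene_id")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  rownames(df) <- NULL
  df
}

#' Read a two-column chromosome sizes table
#' @param path file path (chrom \\t length).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Find overlapping interval pairs
#'
#' Returns all index pairs (i, j) such that interval i of `a` and
#' interval j of `b` lie on the same chromosome (exact string match,
#' no "chr" aliasing) and share at least `min_bp` bases, i.e.
#' `min(end_i, end_j) - max(start_i, start_j) >= min_bp`.
#'
#' @param a,b interval data frames.
#' @param min_bp minimum overlap width in bases (default 1: any
#'   overlap counts).
#' @return data.frame with integer columns `a` and `b`.
#' @export
overlap_pairs <- function(a, b, min_bp = 1L) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  stopifnot(min_bp >= 1)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(a = integer(), b = integer()))
  if (length(intersect(unique(a$chrom), unique(b$chrom))) == 0)
    warning("inputs share no chromosome names; check naming conventions")
  # seqlevel bookkeeping is ours (warning above), not GRanges'
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                minoverlap = as.integer(min_bp)))
  data.frame(a = S4Vectors::queryHits(hits), b = S4Vectors::subjectHits(hits))
}

#' Whole-peak set subtraction
#'
#' Returns the intervals of `a` that have no overlapping interval in
#' `b`. Peaks are removed whole, never trimmed at base-pair level.
#'
#' @param a,b interval data frames.
#' @param min_bp minimum overlap that triggers removal.
#' @return subset of `a`.
#' @export
subtract_peaks <- function(a, b, min_bp = 1L) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  drop <- unique(overlap_pairs(a, b, min_bp = min_bp)$a)
  out <- a[setdiff(seq_len(nrow(a)), drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}
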
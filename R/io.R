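#' Read genomic features from standard interval formats
#'
#' Parses BED, ENCODE narrowPeak, RepeatMasker `.out`, or a generic TSV
#' with header into an interval data.frame on the package's single internal
#' convention: 0-based half-open coordinates. BED and narrowPeak are
#' already half-open and pass through; RepeatMasker `.out` is 1-based
#' inclusive and is shifted on read. Readers are gzip-transparent.
#'
#' Column mapping by format:
#' \describe{
#'   \item{bed}{chrom, start, end, then optional name, score, strand. The
#'     name column is returned as both `name` and `family` (TE BED files
#'     conventionally put the repeat family there).}
#'   \item{narrowPeak}{BED6 plus signalValue, pValue, qValue, summit; the
#'     signalValue column is returned as `signal`.}
#'   \item{repeatmasker_out}{the standard 15-column RepeatMasker table;
#'     returns `family` (repeat name), `class_family`, `divergence`, and
#'     strand with `C` mapped to `-`.}
#'   \item{tsv}{header-driven; must contain chrom, start, end.}
#' }
#'
#' @param path file path (optionally gzipped).
#' @param format one of `"bed"`, `"narrowPeak"`, `"repeatmasker_out"`,
#'   `"tsv"`.
#' @return data.frame of intervals in input order, with an `id` column
#'   (`<basename>_<row>` for formats without one).
#' @export
read_intervals <- function(path,
                           format = c("bed", "narrowPeak",
                                      "repeatmasker_out", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "repeatmasker_out") {
    # drop the two header lines + blank separator if present
    hdr <- grepl("^\\s*(SW|score|bit)", lines)
    lines <- lines[!hdr]
  }
  if (!length(lines)) {
    warning("empty file: ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  out <- switch(format,
    bed = .parse_bed(lines, path),
    narrowPeak = .parse_narrowpeak(lines, path),
    repeatmasker_out = .parse_rmout(lines, path),
    tsv = .parse_tsv(lines, path)
  )
  if (!"id" %in% names(out))
    out$id <- paste0(sub("\\.gz$", "", basename(path)), "_",
                     seq_len(nrow(out)))
  validate_intervals(out, path)
  out
}

.split_fields <- function(lines, sep = "\t") strsplit(lines, sep, fixed = TRUE)

.coord_check <- function(start, end, lineno, path) {
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed coordinates in ", path, " at line ", lineno[bad[1]])
}

.parse_bed <- function(lines, path) {
  f <- .split_fields(lines)
  n <- lengths(f)
  if (any(n < 3))
    stop("malformed BED line ", which(n < 3)[1], " in ", path,
         ": fewer than 3 fields")
  start <- suppressWarnings(as.integer(vapply(f, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(f, `[`, "", 3)))
  .coord_check(start, end, seq_along(lines), path)
  out <- data.frame(chrom = vapply(f, `[`, "", 1), start = start,
                    end = end, stringsAsFactors = FALSE)
  if (all(n >= 4)) {
    out$name <- vapply(f, `[`, "", 4)
    out$family <- out$name
  }
  if (all(n >= 5))
    out$score <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5)))
  if (all(n >= 6)) out$strand <- vapply(f, `[`, "", 6)
  out
}

.parse_narrowpeak <- function(lines, path) {
  f <- .split_fields(lines)
  n <- lengths(f)
  if (any(n < 10))
    stop("malformed narrowPeak line ", which(n < 10)[1], " in ", path,
         ": expected 10 fields")
  start <- suppressWarnings(as.integer(vapply(f, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(f, `[`, "", 3)))
  .coord_check(start, end, seq_along(lines), path)
  data.frame(chrom = vapply(f, `[`, "", 1), start = start, end = end,
             name = vapply(f, `[`, "", 4),
             strand = vapply(f, `[`, "", 6),
             signal = as.numeric(vapply(f, `[`, "", 7)),
             stringsAsFactors = FALSE)
}

.parse_rmout <- function(lines, path) {
  f <- strsplit(trimws(lines), "\\s+")
  n <- lengths(f)
  if (any(n < 11))
    stop("malformed RepeatMasker line ", which(n < 11)[1], " in ", path)
  begin <- suppressWarnings(as.integer(vapply(f, `[`, "", 6)))
  end <- suppressWarnings(as.integer(vapply(f, `[`, "", 7)))
  .coord_check(begin, end, seq_along(lines), path)
  strand <- vapply(f, `[`, "", 9)
  strand[strand == "C"] <- "-"
  data.frame(chrom = vapply(f, `[`, "", 5),
             start = begin - 1L,  # 1-based inclusive -> 0-based half-open
             end = end,
             strand = strand,
             family = vapply(f, `[`, "", 10),
             class_family = vapply(f, `[`, "", 11),
             divergence = suppressWarnings(
               as.numeric(vapply(f, `[`, "", 2))),
             stringsAsFactors = FALSE)
}

.parse_tsv <- function(lines, path) {
  out <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(out)))
    stop("TSV ", path, " lacks chrom/start/end header")
  out
}

#' Write an interval table as BED
#'
#' Emits tab-separated, newline-terminated BED records (0-based half-open,
#' unchanged from the internal convention). Writes name/score/strand
#' columns when present, padding with BED conventions (`.`/`0`) so the
#' column count is consistent.
#'
#' @param x interval data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "x")
  name <- if ("family" %in% names(x)) x$family
          else if ("name" %in% names(x)) x$name
          else if ("id" %in% names(x)) x$id else NULL
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(name) || "strand" %in% names(x)) {
    cols <- c(cols, list(if (is.null(name)) "." else name,
                         if ("score" %in% names(x)) x$score else 0L,
                         if ("strand" %in% names(x)) x$strand else "."))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased; in nucleotide mode `U` is transcribed to `T`
#' so RNA motifs can be scanned on the DNA alphabet.
#'
#' @param path FASTA file (optionally gzipped).
#' @param mode `"nucleotide"` (default) or `"protein"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  ids <- sub("\\s.*$", "", ids)  # id = first token of header
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  if (mode == "nucleotide") seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), path)
  invisible(path)
}
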
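#' Validate a genomic interval table
#'
#' Interval tables are plain data frames with at least `chrom`, `start`,
#' `end` columns (0-based half-open coordinates) and optionally `strand`
#' (one of `+`, `-`, `.`). All package analyses use this single coordinate
#' convention; format readers convert on input.
#'
#' @param x data.frame with columns chrom, start, end (and optionally strand).
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x))
    stop(what, " must be a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(is.na(x$start) | is.na(x$end)))
      stop(what, ": NA coordinates")
    if (any(x$start < 0))
      stop(what, ": negative start coordinate")
    if (any(x$end <= x$start))
      stop(what, ": end must exceed start (0-based half-open)")
    if (any(!nzchar(as.character(x$chrom))))
      stop(what, ": empty chromosome name")
    if ("strand" %in% names(x) &&
        !all(x$strand %in% c("+", "-", ".")))
      stop(what, ": strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

# Internal: interval data.frame -> GRanges (shifts to 1-based closed).
.as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[s == "."] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Overlap join between two interval sets
#'
#' Reports every pair of intervals from `a` and `b` that overlap by at
#' least one bp, optionally requiring the overlap to cover a minimum
#' fraction of the `a` interval. With `min_fraction_of_a = 0` this is the
#' classic bedtools-style any-overlap intersection; with 0.7 it reproduces
#' the stricter rule that 70% of a peak must be covered, read as fraction
#' of the first argument. Pass peaks as `a` for fraction-of-peak, or TEs
#' as `a` for fraction-of-TE.
#'
#' @param a,b interval data.frames (chrom, start, end, ...).
#' @param min_fraction_of_a required overlap as a fraction of the `a`
#'   interval length, in `[0, 1]`. Default 0 (any overlap).
#' @return data.frame with columns `a_index`, `b_index`, `overlap_bp`,
#'   ordered by `a_index` then `b_index`. Empty inputs give zero rows.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 150, end = 250)
#' b <- data.frame(chrom = "chr1", start = 100, end = 200)
#' overlap_join(a, b)                        # 50 bp overlap
#' overlap_join(a, b, min_fraction_of_a = 0.7)  # dropped: 50/100 < 0.7
#' @export
overlap_join <- function(a, b, min_fraction_of_a = 0) {
  validate_intervals(a, "a")
  validate_intervals(b, "b")
  stopifnot(length(min_fraction_of_a) == 1,
            min_fraction_of_a >= 0, min_fraction_of_a <= 1)
  empty <- data.frame(a_index = integer(), b_index = integer(),
                      overlap_bp = integer())
  if (!nrow(a) || !nrow(b)) return(empty)
  ga <- .as_granges(a)
  gb <- .as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L,
                                      ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  keep <- ov >= 1 & ov / (a$end[ai] - a$start[ai]) >= min_fraction_of_a
  out <- data.frame(a_index = ai[keep], b_index = bi[keep],
                    overlap_bp = as.integer(ov[keep]))
  out[order(out$a_index, out$b_index), , drop = FALSE]
}

#' Distance from intervals to the nearest anchor point
#'
#' For each query interval, finds the nearest target anchor point (for
#' example a set of gene 3' termini) on the same chromosome. An anchor
#' lying inside or abutting the half-open interval (including the `end`
#' coordinate itself) is at distance 0. Ties are broken by the smaller
#' anchor coordinate, then lexicographically by `target_id`.
#'
#' Queries on chromosomes carrying no anchor are dropped with a warning;
#' repeat annotations routinely include scaffolds absent from gene models.
#'
#' @param query interval data.frame; an `id` column is carried through
#'   (defaults to row number).
#' @param targets data.frame with columns `target_id`, `chrom`, `pos`
#'   (anchor coordinate on the 0-based scale).
#' @return data.frame with columns `query_id`, `target_id`, `distance_bp`,
#'   one row per retained query, in query order.
#' @export
closest_distance <- function(query, targets) {
  validate_intervals(query, "query")
  if (!is.data.frame(targets) ||
      !all(c("target_id", "chrom", "pos") %in% names(targets)))
    stop("targets needs columns target_id, chrom, pos")
  if (!nrow(targets)) stop("empty target set")
  qid <- if ("id" %in% names(query)) as.character(query$id)
         else as.character(seq_len(nrow(query)))
  out <- vector("list", nrow(query))
  tg <- split(targets, as.character(targets$chrom))
  dropped <- character()
  for (i in seq_len(nrow(query))) {
    ch <- as.character(query$chrom[i])
    t <- tg[[ch]]
    if (is.null(t)) {
      dropped <- c(dropped, ch)
      next
    }
    # distance from anchor p to half-open [s, e): 0 when s <= p <= e
    d <- pmax(0, query$start[i] - t$pos, t$pos - query$end[i])
    dmin <- min(d)
    cand <- t[d == dmin, , drop = FALSE]
    cand <- cand[order(cand$pos, as.character(cand$target_id)), ,
                 drop = FALSE]
    out[[i]] <- data.frame(query_id = qid[i],
                           target_id = as.character(cand$target_id[1]),
                           distance_bp = dmin,
                           stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("no anchors on chromosome(s): ",
            paste(unique(dropped), collapse = ", "),
            "; queries there skipped")
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(query_id = character(), target_id = character(),
                      distance_bp = numeric()))
  do.call(rbind, out)
}
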
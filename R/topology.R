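#' Hydrophobicity scales
#'
#' `"kd"` is the Kyte-Doolittle hydropathy scale; `"hw"` is the
#' Hopp-Woods hydrophilicity scale negated so that, on both scales,
#' larger means more hydrophobic. Unknown residues (`X`) score 0.
#'
#' @param scale `"kd"` (default) or `"hw"`.
#' @return named numeric vector over the 20-letter alphabet.
#' @export
hydropathy_scale <- function(scale = c("kd", "hw")) {
  scale <- match.arg(scale)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  hw <- c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2,
          E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0,
          M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4,
          Y = -2.3, V = -1.5)
  if (scale == "kd") kd else -hw
}

#' Sliding-window hydropathy profile
#'
#' Mean scale value over a window of `window` residues, reported at each
#' center residue; the profile has `length(seq) - window + 1` entries.
#'
#' @param protein_seq amino-acid string (20-letter alphabet plus `X`).
#' @param scale `"kd"` or `"hw"`, or a named numeric vector.
#' @param window odd window size, default 19.
#' @return object of class `hydropathy_profile`: list(sequence_id,
#'   window, scores, offset) where `offset = (window-1)/2` maps profile
#'   index i (1-based) to residue `offset + i - 1` (0-based).
#' @param sequence_id label, default "protein".
#' @export
hydropathy_profile <- function(protein_seq, scale = "kd", window = 19,
                               sequence_id = "protein") {
  if (window %% 2 == 0) stop("window must be odd")
  sc <- if (is.character(scale)) hydropathy_scale(scale) else scale
  chars <- strsplit(toupper(protein_seq), "")[[1]]
  if (window > length(chars)) stop("window exceeds sequence length")
  bad <- setdiff(unique(chars), c(names(sc), "X"))
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  v <- unname(sc[chars])
  v[is.na(v)] <- 0  # X
  scores <- as.numeric(stats::filter(v, rep(1 / window, window),
                                     sides = 2))
  scores <- scores[!is.na(scores)]
  structure(list(sequence_id = sequence_id, window = window,
                 scores = scores, offset = (window - 1L) %/% 2L),
            class = "hydropathy_profile")
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Finds maximal runs of window-center scores at or above `threshold`,
#' maps each run back to the residue span its windows cover
#' (`[first_center - (w-1)/2, last_center + (w-1)/2 + 1)`, 0-based
#' half-open), merges overlapping spans, and keeps spans of at least
#' `min_len` residues. Defaults (threshold 1.6, window 19 upstream,
#' min_len 15) follow classical hydropathy-based membrane-segment
#' calling.
#'
#' @param profile a `hydropathy_profile`.
#' @param threshold score threshold, default 1.6.
#' @param min_len minimum segment span in residues, default 15.
#' @return data.frame (start, end, peak_score), disjoint and sorted;
#'   zero rows when nothing qualifies.
#' @export
call_tm_segments <- function(profile, threshold = 1.6, min_len = 15) {
  stopifnot(inherits(profile, "hydropathy_profile"))
  s <- profile$scores
  if (!length(s)) stop("empty profile")
  above <- s >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- data.frame(start = integer(), end = integer(),
                     peak_score = numeric())
  h <- profile$offset
  for (i in which(r$values)) {
    # profile index j covers residues [h + j - 1 - h, h + j - 1 + h]
    res_start <- starts[i] - 1L
    res_end <- ends[i] + 2L * h
    segs <- rbind(segs, data.frame(
      start = res_start, end = res_end,
      peak_score = max(s[starts[i]:ends[i]])))
  }
  if (!nrow(segs)) return(segs)
  segs <- segs[order(segs$start), , drop = FALSE]
  merged <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1]) {
    last <- nrow(merged)
    if (segs$start[i] < merged$end[last]) {
      merged$end[last] <- max(merged$end[last], segs$end[i])
      merged$peak_score[last] <- max(merged$peak_score[last],
                                     segs$peak_score[i])
    } else merged <- rbind(merged, segs[i, ])
  }
  out <- merged[merged$end - merged$start >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare the topology of two protein isoforms
#'
#' Intended for isoform pairs produced by alternative polyadenylation of
#' one locus: both sequences must share a common prefix of at least half
#' the shorter sequence. Each isoform is profiled and segment-called;
#' the C-terminal transmembrane flag is true iff a called segment ends
#' within the final 40 residues. `differing_tail_length` is the length
#' difference after the longest common prefix.
#'
#' @param seqA,seqB amino-acid strings.
#' @param scale,window,threshold,min_len passed to the profile and
#'   segment caller.
#' @return list (A_has_Cterm_TM, B_has_Cterm_TM, differing_tail_length,
#'   common_prefix, segments_A, segments_B).
#' @export
compare_isoform_topology <- function(seqA, seqB, scale = "kd",
                                     window = 19, threshold = 1.6,
                                     min_len = 15) {
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  nmin <- min(length(a), length(b))
  same <- a[seq_len(nmin)] == b[seq_len(nmin)]
  prefix <- if (all(same)) nmin else which(!same)[1] - 1L
  if (prefix < 0.5 * nmin)
    stop("sequences share a prefix of only ", prefix,
         " residues; not isoforms of one locus")
  cterm_tm <- function(seq) {
    p <- hydropathy_profile(seq, scale, window)
    seg <- call_tm_segments(p, threshold, min_len)
    list(flag = nrow(seg) > 0 &&
           any(seg$end >= nchar(seq) - 40), segments = seg)
  }
  ra <- cterm_tm(seqA); rb <- cterm_tm(seqB)
  list(A_has_Cterm_TM = ra$flag, B_has_Cterm_TM = rb$flag,
       differing_tail_length = abs(length(a) - length(b)),
       tail_A = length(a) - prefix, tail_B = length(b) - prefix,
       common_prefix = prefix,
       segments_A = ra$segments, segments_B = rb$segments)
}
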
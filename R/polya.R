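#' Extract the sequence window around a transcript's polyA site
#'
#' Takes the `w`-bp window centred on the polyadenylation site
#' (`[site - w/2, site + w/2)` in genomic coordinates, clipped at
#' chromosome ends). For minus-strand transcripts the window is
#' reverse-complemented so it reads in the transcript's sense direction;
#' `site_offset` is the polyA site's 0-based position within the
#' returned sequence.
#'
#' @param genome_sequences named character vector of chromosome
#'   sequences.
#' @param transcript a [transcript_model()] with `polya_site` set.
#' @param w window size (even), default 200.
#' @return object of class `polya_window`: list(source_id, sequence,
#'   site_offset, chrom, g_start, g_end, strand).
#' @export
extract_polya_window <- function(genome_sequences, transcript, w = 200) {
  stopifnot(w %% 2 == 0)
  if (is.null(transcript$polya_site) || is.na(transcript$polya_site))
    stop("transcript ", transcript$transcript_id, " has no polya_site")
  chrom <- transcript$chrom
  if (!chrom %in% names(genome_sequences))
    stop("chromosome ", chrom, " absent from genome sequences")
  L <- nchar(genome_sequences[[chrom]])
  site <- transcript$polya_site
  g_start <- max(0L, site - w %/% 2L)
  g_end <- min(L, site + w %/% 2L)
  seq <- substr(genome_sequences[[chrom]], g_start + 1L, g_end)
  seq <- chartr("U", "T", toupper(seq))
  if (transcript$strand == "-") {
    seq <- revcomp(seq)
    offset <- g_end - site
  } else {
    offset <- site - g_start
  }
  structure(list(source_id = transcript$transcript_id, sequence = seq,
                 site_offset = offset, chrom = chrom, g_start = g_start,
                 g_end = g_end, strand = transcript$strand),
            class = "polya_window")
}

#' Reverse complement of a DNA string
#' @param seq DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq)))
}

#' Align an instance window to its family consensus
#'
#' Global alignment with free end gaps (match +2, mismatch -2, gap open
#' -5, gap extend -1) between the window and the consensus, yielding a
#' position-to-position mapping over the matched/mismatched columns
#' (gapped columns are omitted, so the mapping is strictly increasing in
#' both coordinates). Positional annotations such as a planted hexamer
#' can be lifted through the mapping with [lift_to_consensus()].
#'
#' @param window a `polya_window` or a plain character sequence.
#' @param consensus_seq consensus DNA string.
#' @param min_identity identity floor, default 0.5; below it the mapping
#'   is returned flagged `low_confidence`, not an error.
#' @param window_id id used when `window` is a bare string.
#' @return object of class `consensus_mapping`: list(window_id, pairs
#'   (data.frame window_pos, consensus_pos, match — 0-based), identity,
#'   consensus_region (0-based half-open c(start, end)),
#'   low_confidence).
#' @export
align_to_consensus <- function(window, consensus_seq,
                               min_identity = 0.5,
                               window_id = "window") {
  seq <- if (inherits(window, "polya_window")) window$sequence
         else as.character(window)
  id <- if (inherits(window, "polya_window")) window$source_id
        else window_id
  if (!nchar(seq) || !nchar(consensus_seq))
    stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                  mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), Biostrings::DNAString(consensus_seq),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  wp <- Biostrings::start(Biostrings::pattern(al)) - 1L  # 0-based
  cp <- Biostrings::start(Biostrings::subject(al)) - 1L
  wpos <- cpos <- match <- integer(0)
  wi <- wp; ci <- cp
  for (k in seq_along(pa)) {
    pg <- pa[k] == "-"; sg <- sa[k] == "-"
    if (!pg && !sg) {
      wpos <- c(wpos, wi); cpos <- c(cpos, ci)
      match <- c(match, pa[k] == sa[k])
    }
    if (!pg) wi <- wi + 1L
    if (!sg) ci <- ci + 1L
  }
  identity <- if (length(match)) mean(match) else 0
  structure(list(
    window_id = id,
    pairs = data.frame(window_pos = wpos, consensus_pos = cpos,
                       match = as.logical(match)),
    identity = identity,
    consensus_region = if (length(cpos)) c(min(cpos), max(cpos) + 1L)
                       else c(NA_integer_, NA_integer_),
    low_confidence = identity < min_identity),
    class = "consensus_mapping")
}

#' Lift window positions onto consensus coordinates
#'
#' @param mapping a `consensus_mapping`.
#' @param positions 0-based positions on the window.
#' @return 0-based consensus positions (NA where the position falls in a
#'   gapped column).
#' @export
lift_to_consensus <- function(mapping, positions) {
  stopifnot(inherits(mapping, "consensus_mapping"))
  idx <- match(positions, mapping$pairs$window_pos)
  mapping$pairs$consensus_pos[idx]
}

#' The canonical polyadenylation-signal hexamer set
#'
#' `core_pas_motif()` is the single canonical AAUAAA signal (scanned as
#' `AATAAA` on the DNA alphabet); `extended_pas_motifs()` adds the
#' common single-substitution variants, reported separately when used.
#'
#' @return character vector of DNA hexamers.
#' @export
core_pas_motif <- function() "AATAAA"

#' @rdname core_pas_motif
#' @export
extended_pas_motifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Scan sequences for polyA-signal hexamers
#'
#' Reports every occurrence (overlapping occurrences included) of each
#' motif in each sequence; positions are 0-based on the given sequence.
#' RNA motifs are transcribed to DNA on input. With
#' `strand_mode = "both"` the reverse complement is scanned too.
#'
#' @param sequences named character vector (or single string).
#' @param motif_set DNA hexamers, default [core_pas_motif()].
#' @param strand_mode `"given"` (default) or `"both"`.
#' @return data.frame (sequence_id, position, hexamer, is_core, strand).
#' @export
scan_polya_hexamers <- function(sequences, motif_set = core_pas_motif(),
                                strand_mode = c("given", "both")) {
  strand_mode <- match.arg(strand_mode)
  if (!length(motif_set)) stop("motif set is empty")
  motif_set <- chartr("U", "T", toupper(motif_set))
  if (is.null(names(sequences)))
    names(sequences) <- if (length(sequences) == 1) "seq"
                        else paste0("seq", seq_along(sequences))
  rows <- list()
  scan1 <- function(id, seq, strand) {
    seq <- chartr("U", "T", toupper(seq))
    for (m in motif_set) {
      hits <- Biostrings::matchPattern(m, Biostrings::DNAString(seq))
      if (length(hits))
        rows[[length(rows) + 1]] <<- data.frame(
          sequence_id = id,
          position = Biostrings::start(hits) - 1L,
          hexamer = m, is_core = m == "AATAAA", strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(sequences)) {
    scan1(names(sequences)[i], sequences[[i]], "+")
    if (strand_mode == "both")
      scan1(names(sequences)[i], revcomp(sequences[[i]]), "-")
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(), position = integer(),
                      hexamer = character(), is_core = logical(),
                      strand = character()))
  out <- do.call(rbind, rows)
  out[order(out$sequence_id, out$position), , drop = FALSE]
}

#' Paired test of motif co-occurrence: instances vs consensus
#'
#' For each instance window, forms the pair (motif count in the window,
#' motif count in the consensus region its alignment covers) and applies
#' a paired t-test to the differences: `t = mean(d) / (sd(d)/sqrt(n))`
#' with `df = n - 1` (n-1 denominator in the sd). A signal present in
#' the instances but absent from the consensus — the signature of a
#' motif gained by the repeat copies at one locus — yields positive
#' differences. Counts (not presence flags) are the default paired
#' value; with 200-nt windows they are almost always 0/1 and keep the
#' test well defined. When every difference is zero the statistic is
#' undefined and p = 1 is returned with a warning.
#'
#' @param windows named character vector of instance windows (or list of
#'   `polya_window`).
#' @param mappings list of `consensus_mapping`, parallel to `windows`.
#' @param consensus_seq the consensus DNA string.
#' @param motif motif scanned on both sides, default [core_pas_motif()].
#' @param mode `"count"` (default) or `"presence"`.
#' @return list (pairs data.frame, t, df, p).
#' @export
cooccurrence_paired_test <- function(windows, mappings, consensus_seq,
                                     motif = core_pas_motif(),
                                     mode = c("count", "presence")) {
  mode <- match.arg(mode)
  if (inherits(windows, "polya_window")) windows <- list(windows)
  seqs <- if (is.list(windows))
    stats::setNames(vapply(windows, function(w)
      if (inherits(w, "polya_window")) w$sequence else w, ""),
      vapply(windows, function(w)
        if (inherits(w, "polya_window")) w$source_id else "", ""))
  else windows
  n <- length(seqs)
  if (n < 3) stop("need >= 3 windows with mappings")
  stopifnot(length(mappings) == n)
  count_in <- function(seq) {
    k <- length(Biostrings::start(Biostrings::matchPattern(
      motif, Biostrings::DNAString(seq))))
    if (mode == "presence") as.integer(k > 0) else k
  }
  wcount <- vapply(seqs, count_in, 0L)
  ccount <- vapply(mappings, function(m) {
    r <- m$consensus_region
    if (any(is.na(r))) return(0L)
    count_in(substr(consensus_seq, r[1] + 1L, r[2]))
  }, 0L)
  d <- wcount - ccount
  pairs <- data.frame(id = names(seqs), window_count = unname(wcount),
                      consensus_count = unname(ccount),
                      stringsAsFactors = FALSE)
  if (all(d == 0)) {
    warning("all paired differences are zero; t undefined, p = 1")
    return(list(pairs = pairs, t = NA_real_, df = n - 1, p = 1))
  }
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(pairs = pairs, t = t_stat, df = n - 1, p = p)
}

#' Group transcript isoforms by terminal-exon TE overlap
#'
#' Intersects each transcript's terminal (3'-most) exon with the copies
#' of one repeat family and labels the transcript by which copy it
#' overlaps, copies being ranked proximal-to-distal along the gene's
#' 5'->3' direction. Transcripts overlapping no copy get `"no-TE"` (the
#' membrane-isoform pattern, whose terminal exon stops short of the
#' repeat). A terminal exon overlapping two copies is labeled by the
#' larger overlap, with a message.
#'
#' @param transcripts list of [transcript_model()] (one gene's isoforms,
#'   all on one strand).
#' @param te_instances TE interval data.frame with `family`, `id`.
#' @param family_filter optional family name(s) to retain.
#' @param labels optional label per copy rank; default `"TE-proximal"`
#'   for the first copy, `"TE-distal"` for the last, `"TE-<r>"` between
#'   (label semantics are configuration, not fixed biology).
#' @return data.frame (transcript_id, group, te_id).
#' @export
classify_isoform_groups <- function(transcripts, te_instances,
                                    family_filter = NULL,
                                    labels = NULL) {
  stopifnot(length(transcripts) >= 1)
  te <- te_instances
  if (!is.null(family_filter))
    te <- te[te$family %in% family_filter, , drop = FALSE]
  strand <- transcripts[[1]]$strand
  chrom <- transcripts[[1]]$chrom
  te <- te[as.character(te$chrom) == chrom, , drop = FALSE]
  # rank copies along the transcription direction
  ord <- if (strand == "+") order(te$start) else order(-te$end)
  te <- te[ord, , drop = FALSE]
  K <- nrow(te)
  if (is.null(labels)) {
    labels <- if (K == 0) character() else if (K == 1) "TE-proximal"
    else c("TE-proximal",
           if (K > 2) paste0("TE-", seq(2, K - 1)) else NULL,
           "TE-distal")
  }
  if (K && length(labels) != K)
    stop("labels must have one entry per retained TE copy (", K, ")")
  out <- lapply(transcripts, function(tx) {
    ex <- tx$exons
    term <- if (strand == "+") ex[which.max(ex$end), ]
            else ex[which.min(ex$start), ]
    if (!K)
      return(data.frame(transcript_id = tx$transcript_id,
                        group = "no-TE", te_id = NA_character_,
                        stringsAsFactors = FALSE))
    ov <- pmin(term$end, te$end) - pmax(term$start, te$start)
    hit <- which(ov > 0)
    if (!length(hit))
      return(data.frame(transcript_id = tx$transcript_id,
                        group = "no-TE", te_id = NA_character_,
                        stringsAsFactors = FALSE))
    if (length(hit) > 1) {
      message("terminal exon of ", tx$transcript_id, " overlaps ",
              length(hit), " copies; using the largest overlap")
      hit <- hit[which.max(ov[hit])]
    }
    data.frame(transcript_id = tx$transcript_id, group = labels[hit],
               te_id = as.character(te$id[hit]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
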
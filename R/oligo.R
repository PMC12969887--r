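#' Best ungapped local alignment between two nucleotide sequences
#'
#' Exhaustively scans every diagonal of the query x target comparison
#' (and of the query against the reverse complement of the target) for
#' the maximal-scoring ungapped segment pair under
#' `score = reward * matches + penalty * mismatches`. The score is never
#' negative (the empty segment scores 0). This is the alignment model
#' under which a short knockdown oligo's on- and off-target matches are
#' compared.
#'
#' @param query,target nucleotide strings (`U` transcribed to `T`).
#' @param reward match reward (> 0), default +1.
#' @param penalty mismatch penalty (< 0), default -3.
#' @return list (score, q_start, q_end, t_start, t_end — 0-based
#'   half-open on the given strands, strand, matches, match_len,
#'   identity).
#' @export
best_ungapped_hit <- function(query, target, reward = 1, penalty = -3) {
  stopifnot(reward > 0, penalty < 0)
  query <- chartr("U", "T", toupper(query))
  target <- chartr("U", "T", toupper(target))
  if (!nchar(query) || !nchar(target)) stop("empty sequence")
  best <- list(score = 0, q_start = 0L, q_end = 0L, t_start = 0L,
               t_end = 0L, strand = "+", matches = 0L, match_len = 0L,
               identity = NA_real_)
  q <- strsplit(query, "")[[1]]
  for (strand in c("+", "-")) {
    tseq <- if (strand == "+") target else revcomp(target)
    t <- strsplit(tseq, "")[[1]]
    n <- length(q); m <- length(t)
    for (d in seq(-(n - 1L), m - 1L)) {
      i0 <- max(1L, 1L - d); i1 <- min(n, m - d)
      if (i0 > i1) next
      idx <- i0:i1
      sc <- ifelse(q[idx] == t[idx + d], reward, penalty)
      # Kadane with segment tracking
      run <- 0; run_start <- 1L; run_matches <- 0L; run_len <- 0L
      for (k in seq_along(sc)) {
        if (run <= 0) {
          run <- sc[k]; run_start <- k
          run_matches <- as.integer(sc[k] > 0); run_len <- 1L
        } else {
          run <- run + sc[k]
          run_matches <- run_matches + as.integer(sc[k] > 0)
          run_len <- run_len + 1L
        }
        if (run > best$score ||
            (run == best$score && strand == "+" &&
             best$strand == "-")) {
          qs <- idx[run_start]; qe <- idx[k]
          best <- list(score = run, q_start = qs - 1L, q_end = qe,
                       t_start = qs + d - 1L, t_end = qe + d,
                       strand = strand,
                       matches = run_matches, match_len = run_len,
                       identity = run_matches / run_len)
        }
        if (run < 0) run <- 0
      }
    }
  }
  best
}

#' Karlin-Altschul bit score
#'
#' Converts an ungapped raw alignment score to a normalized bit score:
#' `bits = (lambda * S - ln K) / ln 2`. The defaults `lambda = 1.374`
#' and `K = 0.711` are the standard ungapped Karlin-Altschul parameters
#' for +1/-3 nucleotide scoring; under them a 21-match perfect hit
#' scores 42.1 bits and a 15-match run 30.2 bits.
#'
#' @param S raw score.
#' @param lambda scale parameter (> 0).
#' @param K search-space constant (> 0).
#' @return bit score (unrounded; report to one decimal in tables).
#' @export
karlin_altschul_bits <- function(S, lambda = 1.374, K = 0.711) {
  stopifnot(lambda > 0, K > 0)
  (lambda * S - log(K)) / log(2)
}

#' Oligo specificity report against a transcript set
#'
#' Scores the query oligo against every target with
#' [best_ungapped_hit()], converts raw scores to bits, and ranks targets
#' by bits (descending, ties by target id). The `specific` flag is true
#' when the top hit exceeds the runner-up by at least `margin` bits
#' (NA with a single target).
#'
#' @param query oligo nucleotide string.
#' @param targets named character vector of target sequences.
#' @param reward,penalty scoring, default +1/-3.
#' @param lambda,K Karlin-Altschul parameters, default 1.374 / 0.711.
#' @param margin bit-score margin for the specificity flag, default 5.
#' @return list with `table` (data.frame target, score, bits — one
#'   decimal, identity, strand, rank) and `specific`.
#' @export
specificity_report <- function(query, targets, reward = 1,
                               penalty = -3, lambda = 1.374, K = 0.711,
                               margin = 5) {
  if (!nchar(query)) stop("empty query")
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  rows <- lapply(names(targets), function(id) {
    h <- best_ungapped_hit(query, targets[[id]], reward, penalty)
    data.frame(target = id, score = h$score,
               bits = round(karlin_altschul_bits(h$score, lambda, K),
                            1),
               identity = h$identity, strand = h$strand,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$bits, tab$target), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  specific <- if (nrow(tab) < 2) NA
              else (tab$bits[1] - tab$bits[2]) >= margin
  list(table = tab, specific = specific)
}
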
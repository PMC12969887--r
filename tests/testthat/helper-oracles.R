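# Independent brute-force oracles used to validate the package's
# optimized implementations. These deliberately use naive algorithms.

# All-vs-all interval overlap scan.
brute_overlap <- function(a, b, min_fraction_of_a = 0) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (as.character(a$chrom[i]) != as.character(b$chrom[j])) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1 && ov / (a$end[i] - a$start[i]) >= min_fraction_of_a)
      rows[[length(rows) + 1]] <- data.frame(a_index = i, b_index = j,
                                             overlap_bp = ov)
  }
  if (!length(rows))
    return(data.frame(a_index = integer(), b_index = integer(),
                      overlap_bp = integer()))
  out <- do.call(rbind, rows)
  out[order(out$a_index, out$b_index), ]
}

# Exhaustive nearest-anchor search (same tie rule as the contract).
brute_closest <- function(query, targets) {
  res <- list()
  for (i in seq_len(nrow(query))) {
    t <- targets[as.character(targets$chrom) ==
                   as.character(query$chrom[i]), , drop = FALSE]
    if (!nrow(t)) next
    d <- pmax(0, query$start[i] - t$pos, t$pos - query$end[i])
    t <- t[d == min(d), , drop = FALSE]
    t <- t[order(t$pos, as.character(t$target_id)), , drop = FALSE]
    res[[length(res) + 1]] <- data.frame(
      query_id = as.character(i), target_id = as.character(t$target_id[1]),
      distance_bp = min(d), stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

# From-scratch Benjamini-Hochberg.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n); out[o] <- adj
  out
}

# Prefix-sum scan of every (start, end) segment on every diagonal and
# both strands: a different algorithm from the Kadane-style scanner.
brute_ungapped <- function(query, target, reward = 1, penalty = -3) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- 0
  q <- strsplit(toupper(query), "")[[1]]
  for (tgt in c(toupper(target), rc(toupper(target)))) {
    t <- strsplit(tgt, "")[[1]]
    n <- length(q); m <- length(t)
    for (d in seq(-(n - 1L), m - 1L)) {
      i0 <- max(1L, 1L - d); i1 <- min(n, m - d)
      if (i0 > i1) next
      sc <- ifelse(q[i0:i1] == t[(i0:i1) + d], reward, penalty)
      cs <- c(0, cumsum(sc))
      for (s in seq_along(sc)) for (e in s:length(sc))
        best <- max(best, cs[e + 1] - cs[s])
    }
  }
  best
}

# Sliding-window string comparison motif scan.
brute_motif_scan <- function(seq, motif) {
  L <- nchar(seq); k <- nchar(motif)
  pos <- integer()
  if (L >= k) for (i in 0:(L - k))
    if (substr(seq, i + 1, i + k) == motif) pos <- c(pos, i)
  pos
}

# Exact Mann-Whitney two-sided p via an independent enumeration based on
# rank sums rather than pairwise comparisons.
brute_mw <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  r <- rank(v)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Closed-form Fisher combination for an even number of degrees of
# freedom: p = exp(-X/2) * sum_{j<k} (X/2)^j / j!
closed_form_fisher <- function(pvals) {
  X <- -2 * sum(log(pvals))
  k <- length(pvals)
  exp(-X / 2) * sum((X / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Fabricate a family_enrichment-like table for matrix assembly tests.
fake_table <- function(dataset, families, adj_p) {
  t <- data.frame(family = families, adj_p = adj_p, p = adj_p,
                  stringsAsFactors = FALSE)
  attr(t, "dataset") <- dataset
  t
}

# Small deterministic gene fixture: one gene, two exons.
make_gene <- function(id = "g1", chrom = "chr1", strand = "+",
                      exons = data.frame(start = c(100, 300),
                                         end = c(200, 400))) {
  gene_model(id, chrom, strand,
             list(transcript_model(paste0(id, ".t1"), chrom, strand,
                                   exons)))
}
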
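#' Default PSG-array locus window
#'
#' The tandem PSG gene cluster on chr19q13 used in documentation
#' examples (chr19:43,203,459-43,802,656). Every analysis takes the
#' window as a parameter; this is only a convenience constant.
#'
#' @return one-row interval data.frame.
#' @export
psg_locus_window <- function() {
  data.frame(chrom = "chr19", start = 43203459L, end = 43802656L)
}

#' Distance from TE instances to the nearest gene 3' terminus
#'
#' For each retained TE instance, computes the distance to the nearest
#' strand-aware gene 3' end (via [closest_distance()]; an instance
#' overlapping or abutting the terminus is at distance 0) and flags
#' instances closer than `threshold_bp`. The output is sorted ascending
#' by distance — the ordering used to ask whether a family sits at gene
#' 3' ends anywhere beyond one locus. A TSS mode is available for
#' completeness.
#'
#' @param te_instances TE interval data.frame with `family` and `id`.
#' @param genes list of [gene_model()] objects.
#' @param family_filter optional family name(s) to retain.
#' @param threshold_bp proximity threshold, default 50.
#' @param anchor `"end3"` (default) or `"tss"`.
#' @return data.frame (te_id, family, nearest_gene, distance_bp,
#'   proximal) sorted by ascending distance.
#' @export
gene_end_proximity <- function(te_instances, genes, family_filter = NULL,
                               threshold_bp = 50, anchor = c("end3",
                                                             "tss")) {
  anchor <- match.arg(anchor)
  if (!length(genes)) stop("no genes supplied")
  te <- te_instances
  if (!is.null(family_filter))
    te <- te[te$family %in% family_filter, , drop = FALSE]
  targets <- data.frame(
    target_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    pos = vapply(genes, function(g) as.numeric(g[[anchor]]), 0),
    stringsAsFactors = FALSE)
  cd <- closest_distance(te, targets)
  fam <- stats::setNames(as.character(te$family), as.character(te$id))
  out <- data.frame(te_id = cd$query_id, family = fam[cd$query_id],
                    nearest_gene = cd$target_id,
                    distance_bp = cd$distance_bp,
                    proximal = cd$distance_bp < threshold_bp,
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance_bp, out$te_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter structural-variant records by size and region
#'
#' Keeps records of at least `min_size_bp` that overlap the region by at
#' least 1 bp. Idempotent.
#'
#' @param records CNV/SV data.frame (chrom, start, end, plus metadata;
#'   a `size` column is recomputed as end - start if absent).
#' @param min_size_bp minimum size, default 1000.
#' @param region one-row interval data.frame.
#' @return filtered data.frame.
#' @export
filter_sv <- function(records, min_size_bp = 1000, region) {
  validate_intervals(region, "region")
  if (!nrow(records)) return(records)
  if (!"size" %in% names(records))
    records$size <- records$end - records$start
  keep <- records$size >= min_size_bp &
    as.character(records$chrom) == as.character(region$chrom[1]) &
    records$start < region$end[1] & records$end > region$start[1]
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loss:gain copy-number ratio per group
#'
#' Counts loss and gain events per group and normalizes the ratio so the
#' smaller side is 1, printed to one decimal (e.g. `12:1`, `2.8:1`,
#' `1:1.9`). A zero denominator is reported as-is (e.g. `5:0`).
#'
#' @param records CNV data.frame with `type` in `{loss, gain}`.
#' @param grouping column name holding the group label, default
#'   `"group"`.
#' @return data.frame (group, n_loss, n_gain, ratio).
#' @export
locus_cnv_ratio <- function(records, grouping = "group") {
  if (!grouping %in% names(records))
    stop("no column named ", grouping)
  fmt <- function(x) {
    r <- round(x, 1)
    if (abs(r - round(r)) < 1e-9) format(round(r)) else format(r)
  }
  groups <- unique(as.character(records[[grouping]]))
  out <- lapply(groups, function(g) {
    sub <- records[records[[grouping]] == g, , drop = FALSE]
    L <- sum(sub$type == "loss"); G <- sum(sub$type == "gain")
    ratio <- if (L >= G) {
      if (G == 0) paste0(L, ":0") else paste0(fmt(L / G), ":1")
    } else {
      if (L == 0) paste0("0:", G) else paste0("1:", fmt(G / L))
    }
    data.frame(group = g, n_loss = L, n_gain = G, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Internal: exact two-sided Mann-Whitney p by full enumeration of
# group-label assignments (handles ties; feasible for combined n <= 16).
.mw_exact <- function(x, y) {
  v <- c(x, y); n1 <- length(x); n <- length(v)
  ustat <- function(idx) {
    a <- v[idx]; b <- v[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, ustat)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(lo, hi)),
       p_one_sided = min(lo, hi))
}

#' Mann-Whitney locus CNV burden test
#'
#' Compares a per-sample copy-number burden statistic between two groups
#' with the Mann-Whitney U test. The default statistic is the number of
#' gain (duplication) records per sample; `"gain_bp"` sums gained bp
#' instead. Samples with no events count as 0, so the full sample roster
#' is required. For combined n <= 16 the two-sided p is exact by full
#' enumeration of group labelings; above that, the normal approximation
#' with tie correction is used.
#'
#' @param records CNV data.frame (already filtered, e.g. by
#'   [filter_sv()]).
#' @param samples roster data.frame (sample, group); exactly two groups,
#'   each with at least 2 samples.
#' @param statistic `"duplication_count"` (default) or `"gain_bp"`.
#' @return list (U, p, method, per_sample) where `per_sample` holds the
#'   statistic values.
#' @export
cnv_burden_test <- function(records, samples,
                            statistic = c("duplication_count",
                                          "gain_bp")) {
  statistic <- match.arg(statistic)
  groups <- unique(as.character(samples$group))
  if (length(groups) != 2) stop("need exactly two groups")
  if (any(table(samples$group) < 2))
    stop("each group needs >= 2 samples")
  gains <- records[records$type == "gain", , drop = FALSE]
  val <- stats::setNames(numeric(nrow(samples)),
                         as.character(samples$sample))
  if (nrow(gains)) {
    contrib <- if (statistic == "duplication_count")
      rep(1, nrow(gains)) else gains$end - gains$start
    agg <- tapply(contrib, as.character(gains$sample), sum)
    common <- intersect(names(agg), names(val))
    val[common] <- agg[common]
  }
  x <- val[samples$group == groups[1]]
  y <- val[samples$group == groups[2]]
  if (length(unique(c(x, y))) == 1) {
    warning("all burden values identical; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1,
                method = "degenerate",
                per_sample = data.frame(sample = names(val),
                                        group = samples$group,
                                        value = unname(val))))
  }
  if (length(x) + length(y) <= 16) {
    ex <- .mw_exact(x, y)
    U <- ex$U; p <- ex$p; method <- "exact enumeration"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    U <- unname(wt$statistic); p <- wt$p.value
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, method = method,
       per_sample = data.frame(sample = names(val),
                               group = samples$group,
                               value = unname(val),
                               stringsAsFactors = FALSE))
}
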
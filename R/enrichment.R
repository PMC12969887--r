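#' Per-family enrichment of a peak set within TE instances
#'
#' For one peak dataset, counts for every repeat family how many of its
#' instances are overlapped by at least one qualifying peak, and tests
#' enrichment against an all-other-TE-instances background with a
#' one-sided Fisher's exact test on the 2x2 table
#' (family overlapped / not vs background overlapped / not).
#' P-values are Benjamini-Hochberg adjusted across the tested families.
#'
#' The counting unit is the TE instance, not the peak: family sizes span
#' orders of magnitude and instance counting keeps families comparable.
#' A peak qualifies under `overlap_mode = "any"` with any 1-bp overlap,
#' or under `"fraction"` when the overlap covers at least `min_fraction`
#' of the peak (fraction-of-TE is available via `fraction_of = "te"`).
#' Families with fewer than `min_instances` copies are reported with
#' `tested = FALSE` and NA p-values.
#'
#' @param peaks peak data.frame (one dataset).
#' @param te_instances TE interval data.frame with a `family` column.
#' @param overlap_mode `"any"` or `"fraction"`.
#' @param min_fraction overlap fraction required in fraction mode
#'   (default 0.7).
#' @param fraction_of `"peak"` (default) or `"te"`: which feature's
#'   length the fraction is measured against.
#' @param min_instances minimum family size to test, default 10.
#' @param blacklist optional interval data.frame; peaks overlapping it
#'   are removed before testing (ENCODE-blacklist-style exclusion).
#' @return data.frame of class `family_enrichment` with columns family,
#'   n_instances, n_overlapped, n_background_instances,
#'   n_background_overlapped, fold, p, adj_p, tested; plus attribute
#'   `dataset`.
#' @export
family_enrichment <- function(peaks, te_instances,
                              overlap_mode = c("any", "fraction"),
                              min_fraction = 0.7,
                              fraction_of = c("peak", "te"),
                              min_instances = 10,
                              blacklist = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  fraction_of <- match.arg(fraction_of)
  if (!"family" %in% names(te_instances))
    stop("te_instances needs a family column")
  if ("dataset" %in% names(peaks) &&
      length(unique(peaks$dataset)) > 1)
    stop("peaks must come from a single dataset")
  dataset <- if ("dataset" %in% names(peaks) && nrow(peaks))
    peaks$dataset[1] else NA_character_
  if (!is.null(blacklist) && nrow(peaks)) {
    bad <- unique(overlap_join(peaks, blacklist)$a_index)
    if (length(bad)) peaks <- peaks[-bad, , drop = FALSE]
  }
  f <- if (overlap_mode == "any") 0 else min_fraction
  hits <- if (fraction_of == "peak")
    overlap_join(peaks, te_instances, min_fraction_of_a = f)
  else {
    h <- overlap_join(te_instances, peaks, min_fraction_of_a = f)
    data.frame(a_index = h$b_index, b_index = h$a_index,
               overlap_bp = h$overlap_bp)
  }
  overlapped <- logical(nrow(te_instances))
  overlapped[unique(hits$b_index)] <- TRUE

  fams <- sort(unique(as.character(te_instances$family)))
  n_inst <- table(factor(te_instances$family, levels = fams))
  n_ov <- tapply(overlapped, factor(te_instances$family, levels = fams),
                 sum)
  n_ov[is.na(n_ov)] <- 0
  tot <- nrow(te_instances)
  tot_ov <- sum(overlapped)
  res <- data.frame(
    family = fams,
    n_instances = as.integer(n_inst),
    n_overlapped = as.integer(n_ov),
    n_background_instances = tot - as.integer(n_inst),
    n_background_overlapped = tot_ov - as.integer(n_ov),
    stringsAsFactors = FALSE)
  res$tested <- res$n_instances >= min_instances
  if (!any(res$tested)) stop("zero families meet min_instances = ",
                             min_instances)
  rate_fam <- res$n_overlapped / res$n_instances
  rate_bg <- res$n_background_overlapped / res$n_background_instances
  res$fold <- rate_fam / rate_bg
  res$p <- NA_real_
  for (i in which(res$tested)) {
    tab <- matrix(c(res$n_overlapped[i],
                    res$n_instances[i] - res$n_overlapped[i],
                    res$n_background_overlapped[i],
                    res$n_background_instances[i] -
                      res$n_background_overlapped[i]), nrow = 2)
    res$p[i] <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  res$adj_p <- NA_real_
  res$adj_p[res$tested] <- stats::p.adjust(res$p[res$tested],
                                           method = "BH")
  attr(res, "dataset") <- dataset
  class(res) <- c("family_enrichment", "data.frame")
  res
}

#' Assemble per-dataset enrichment tables into a matrix
#'
#' Rows are the union of families across datasets, columns the datasets,
#' values `-log10(adjusted p)` capped at 300; untested or absent cells
#' are 0. A family belongs to the significant subset iff its adjusted p
#' is below `alpha` in at least one dataset.
#'
#' @param tables named list of [family_enrichment()] results, or an
#'   unnamed list whose elements carry a `dataset` attribute.
#' @param alpha significance level, default 0.05.
#' @param cap cap on `-log10(adj_p)`, default 300.
#' @return object of class `enrichment_matrix`: list with `values`
#'   (numeric matrix), `significant` (logical matrix), `alpha`,
#'   `significant_families` (character).
#' @export
build_enrichment_matrix <- function(tables, alpha = 0.05, cap = 300) {
  if (length(tables) < 2) stop("need at least 2 datasets")
  nm <- names(tables)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(tables, attr, "", "dataset")
  if (anyDuplicated(nm))
    stop("duplicated dataset name: ", nm[duplicated(nm)][1])
  fams <- sort(unique(unlist(lapply(tables, `[[`, "family"))))
  values <- matrix(0, length(fams), length(tables),
                   dimnames = list(fams, nm))
  sig <- matrix(FALSE, length(fams), length(tables),
                dimnames = list(fams, nm))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    ok <- !is.na(t$adj_p)
    v <- pmin(-log10(t$adj_p[ok]), cap)
    values[t$family[ok], j] <- v
    sig[t$family[ok], j] <- t$adj_p[ok] < alpha
  }
  structure(list(values = values, significant = sig, alpha = alpha,
                 significant_families = fams[rowSums(sig) > 0]),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d families x %d datasets (alpha=%g)\n",
              nrow(x$values), ncol(x$values), x$alpha))
  cat(sprintf("  significant in >=1 dataset: %d families\n",
              length(x$significant_families)))
  invisible(x)
}

#' Subset an enrichment matrix to its significant families
#' @param x `enrichment_matrix`.
#' @return `enrichment_matrix` restricted to families significant in at
#'   least one dataset.
#' @export
significant_subset <- function(x) {
  stopifnot(inherits(x, "enrichment_matrix"))
  keep <- x$significant_families
  structure(list(values = x$values[keep, , drop = FALSE],
                 significant = x$significant[keep, , drop = FALSE],
                 alpha = x$alpha, significant_families = keep),
            class = "enrichment_matrix")
}

#' K-means clustering of enrichment profiles
#'
#' Clusters the family rows of the `-log10(adj_p)` matrix with k-means
#' (multiple restarts, fixed seed). Labels are renumbered canonically by
#' descending cluster mean so the labelling is reproducible.
#'
#' @param x `enrichment_matrix`.
#' @param k number of clusters (`2 <= k <=` number of rows).
#' @param seed integer seed.
#' @param n_init number of random restarts, default 10.
#' @return named integer vector: family -> cluster label (1 = highest
#'   mean enrichment).
#' @export
cluster_enrichment <- function(x, k, seed = 1, n_init = 10) {
  stopifnot(inherits(x, "enrichment_matrix"), k >= 2)
  m <- x$values
  if (k > nrow(m)) stop("k exceeds the number of families")
  set.seed(seed)
  if (k == nrow(m)) {
    # degenerate limit: every family its own cluster
    km <- list(cluster = stats::setNames(seq_len(nrow(m)),
                                         rownames(m)))
  } else {
    km <- stats::kmeans(m, centers = k, nstart = n_init)
  }
  means <- tapply(rowMeans(m), km$cluster, mean)
  relabel <- stats::setNames(rank(-means, ties.method = "first"),
                             names(means))
  out <- as.integer(relabel[as.character(km$cluster)])
  stats::setNames(out, rownames(m))
}

#' Spearman rank correlation between datasets
#'
#' Correlates the `-log10(adj_p)` columns of the matrix pairwise with
#' Spearman's rank correlation (average ranks for ties). A constant
#' column yields NA against every other column rather than an error;
#' the diagonal is 1.
#'
#' @param x `enrichment_matrix`.
#' @return symmetric dataset-by-dataset correlation matrix.
#' @export
dataset_correlation <- function(x) {
  stopifnot(inherits(x, "enrichment_matrix"))
  m <- x$values
  if (ncol(m) < 2 || nrow(m) < 3)
    stop("need >= 2 datasets and >= 3 families")
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Co-occupancy of two factors over significant families
#'
#' Set algebra on the significance flags: families significant for
#' `factorA` only, `factorB` only, or both; plus the fraction of shared
#' families classified as enhancer-like under `rule_config`
#' (NA when no family is shared).
#'
#' @param x `enrichment_matrix`.
#' @param factorA,factorB dataset names.
#' @param rule_config rule configuration for
#'   [classify_family_activity()]; used to classify the shared families.
#' @param alpha significance level; default the matrix's own.
#' @return list with `A_only`, `B_only`, `shared` (counts),
#'   `shared_families`, `shared_enhancer_fraction`.
#' @export
cooccupancy_summary <- function(x, factorA, factorB,
                                rule_config = default_activity_rules(),
                                alpha = NULL) {
  stopifnot(inherits(x, "enrichment_matrix"))
  for (d in c(factorA, factorB))
    if (!d %in% colnames(x$values)) stop("missing dataset: ", d)
  sig <- .sig_at(x, alpha)
  a <- rownames(sig)[sig[, factorA]]
  b <- rownames(sig)[sig[, factorB]]
  shared <- intersect(a, b)
  frac <- NA_real_
  if (length(shared)) {
    lab <- classify_family_activity(x, rule_config, alpha)
    frac <- mean(lab[shared] == "enhancer-like")
  }
  list(A_only = length(setdiff(a, b)), B_only = length(setdiff(b, a)),
       shared = length(shared), shared_families = shared,
       shared_enhancer_fraction = frac)
}

# Internal: significance flags, optionally re-thresholded from values.
.sig_at <- function(x, alpha) {
  if (is.null(alpha) || alpha == x$alpha) return(x$significant)
  x$values > -log10(alpha)
}

#' Default promoter/enhancer activity rule configuration
#'
#' Dataset roles used by [classify_family_activity()]: which columns of
#' the enrichment matrix act as promoter mark, pioneer factor, enhancer
#' marks, enhancer cofactors, and repressive mark.
#'
#' @param promoter_marks,pioneer,enhancer_marks,enhancer_cofactors,repressive
#'   character vectors of dataset names.
#' @return named list.
#' @export
default_activity_rules <- function(promoter_marks = "H3K4me3",
                                   pioneer = "TFAP2C",
                                   enhancer_marks = c("H3K4me1",
                                                      "H3K27ac"),
                                   enhancer_cofactors = c("P300", "MED1"),
                                   repressive = "H3K9me3") {
  list(promoter_marks = promoter_marks, pioneer = pioneer,
       enhancer_marks = enhancer_marks,
       enhancer_cofactors = enhancer_cofactors, repressive = repressive)
}

#' Classify family regulatory activity from enrichment signatures
#'
#' Applies the signature rules, with precedence promoter > enhancer >
#' repressed:
#' \itemize{
#'   \item promoter-like: significant for a promoter mark AND the
#'     designated pioneer factor;
#'   \item enhancer-like: significant for an enhancer mark AND an
#'     enhancer cofactor;
#'   \item repressed: significant for the repressive mark and neither of
#'     the above;
#'   \item unclassified otherwise.
#' }
#' Datasets named by the rules must exist in the matrix.
#'
#' @param x `enrichment_matrix`.
#' @param rule_config see [default_activity_rules()].
#' @param alpha significance level; default the matrix's own.
#' @return named character vector: family -> label.
#' @export
classify_family_activity <- function(x,
                                     rule_config =
                                       default_activity_rules(),
                                     alpha = NULL) {
  stopifnot(inherits(x, "enrichment_matrix"))
  need <- unlist(rule_config)
  absent <- setdiff(need, colnames(x$values))
  if (length(absent))
    stop("rule references absent dataset(s): ",
         paste(absent, collapse = ", "))
  sig <- .sig_at(x, alpha)
  any_sig <- function(cols) if (!length(cols)) rep(FALSE, nrow(sig))
    else rowSums(sig[, cols, drop = FALSE]) > 0
  prom <- any_sig(rule_config$promoter_marks) &
    any_sig(rule_config$pioneer)
  enh <- any_sig(rule_config$enhancer_marks) &
    any_sig(rule_config$enhancer_cofactors)
  rep_ <- any_sig(rule_config$repressive)
  lab <- rep("unclassified", nrow(sig))
  lab[rep_] <- "repressed"
  lab[enh] <- "enhancer-like"
  lab[prom] <- "promoter-like"
  stats::setNames(lab, rownames(sig))
}

#' Shortlist candidate regulatory families
#'
#' Families significant for every required dataset and carrying an
#' allowed activity label, ranked by summed `-log10(adj_p)` over the
#' required datasets, ties broken lexicographically by family name.
#'
#' @param x `enrichment_matrix`.
#' @param required character vector of dataset names a candidate must be
#'   significant in (e.g. two TFs plus the pioneer factor).
#' @param allowed_labels activity labels accepted, default
#'   promoter-like and enhancer-like.
#' @param rule_config see [default_activity_rules()].
#' @param alpha significance level; default the matrix's own.
#' @return data.frame (family, score, label, rank), possibly empty.
#' @export
shortlist_candidates <- function(x, required,
                                 allowed_labels = c("promoter-like",
                                                    "enhancer-like"),
                                 rule_config = default_activity_rules(),
                                 alpha = NULL) {
  stopifnot(inherits(x, "enrichment_matrix"))
  absent <- setdiff(required, colnames(x$values))
  if (length(absent))
    stop("missing dataset: ", paste(absent, collapse = ", "))
  sig <- .sig_at(x, alpha)
  ok <- rowSums(sig[, required, drop = FALSE]) == length(required)
  lab <- classify_family_activity(x, rule_config, alpha)
  ok <- ok & lab %in% allowed_labels
  fams <- rownames(sig)[ok]
  if (!length(fams))
    return(data.frame(family = character(), score = numeric(),
                      label = character(), rank = integer()))
  score <- rowSums(x$values[fams, required, drop = FALSE])
  ord <- order(-score, fams)
  data.frame(family = fams[ord], score = unname(score[ord]),
             label = unname(lab[fams][ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
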
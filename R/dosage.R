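#' Z-standardize a per-sample vector
#'
#' `(observed - sample mean) / sample sd`, with the n-1 denominator in
#' the sd. Idempotent: z-scoring a z-scored vector changes nothing.
#'
#' @param values numeric vector, length >= 2.
#' @return standardized vector (mean 0, sd 1).
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("zero standard deviation")
  (values - mean(values)) / s
}

#' log2 preprocessing of a raw expression matrix
#'
#' `log2(x + offset)`; the offset defaults to 1 for TPM-like input and
#' can be set to 0 when values are already strictly positive powers of
#' two of a latent scale.
#'
#' @param raw genes x samples matrix of non-negative values.
#' @param offset pseudo-count, default 1.
#' @return log2-scale matrix.
#' @export
preprocess_expression <- function(raw, offset = 1) {
  if (any(raw < 0)) stop("raw expression must be non-negative")
  log2(raw + offset)
}

#' Combined two-TF dosage correlation with a target gene
#'
#' The dosage statistic: each TF's per-sample log2 expression is
#' converted to Z scores (so TFs expressed at different absolute levels
#' are comparable), the two Z vectors are summed per sample, and the sum
#' is correlated with the target gene's expression (Pearson).
#' Individual TF-target correlations are reported alongside. Two-sided
#' p-values use the t transform `t = r * sqrt((n-2)/(1-r^2))` with
#' `df = n - 2`; at `|r| = 1` the p-value is reported as 0.
#'
#' @param matrix genes x samples numeric matrix on the log2 scale.
#' @param tf1,tf2,target row names of the two TFs and the target gene.
#' @return list (n, r_tf1, p_tf1, r_tf2, p_tf2, r_combined, p_combined,
#'   dosage — the per-sample summed Z vector).
#' @export
combined_dosage_correlation <- function(matrix, tf1, tf2, target) {
  for (g in c(tf1, tf2, target))
    if (!g %in% rownames(matrix)) stop("gene absent from matrix: ", g)
  n <- ncol(matrix)
  if (n < 4) stop("need >= 4 samples")
  z1 <- zscore(matrix[tf1, ])
  z2 <- zscore(matrix[tf2, ])
  y <- matrix[target, ]
  r_p <- function(x) {
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0
    else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
    c(r = r, p = p)
  }
  a <- r_p(z1); b <- r_p(z2); comb <- r_p(z1 + z2)
  list(n = n, r_tf1 = unname(a["r"]), p_tf1 = unname(a["p"]),
       r_tf2 = unname(b["r"]), p_tf2 = unname(b["p"]),
       r_combined = unname(comb["r"]), p_combined = unname(comb["p"]),
       dosage = z1 + z2)
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values via `X = -2 * sum(log(p))`, referred
#' to the upper tail of a chi-square distribution with 2k degrees of
#' freedom.
#'
#' @param pvals numeric vector of p-values, each in (0, 1].
#' @return combined p-value.
#' @export
fishers_combined <- function(pvals) {
  if (!length(pvals) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(pvals))
  stats::pchisq(X, df = 2 * length(pvals), lower.tail = FALSE)
}
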
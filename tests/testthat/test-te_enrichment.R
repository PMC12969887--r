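# tiny deterministic fixture: 2 families x 2 instances, one dataset
tiny_te <- data.frame(chrom = "chr1",
                      start = c(10, 1010, 5000, 6000),
                      end = c(60, 1060, 5050, 6050),
                      family = rep(c("A", "B"), each = 2))
tiny_pk <- data.frame(chrom = "chr1", start = c(0, 1000),
                      end = c(100, 1100), dataset = "D1")

test_that("Fisher's exact enrichment matches the hypergeometric tail", {
  t <- family_enrichment(tiny_pk, tiny_te, min_instances = 2)
  # family A 2/2 overlapped vs background 0/2: one-sided p = 1/6
  expect_equal(t$p[t$family == "A"], 1 / 6, tolerance = 1e-12)
  expect_equal(t$n_overlapped[t$family == "A"], 2L)
  expect_equal(t$n_background_overlapped[t$family == "A"], 0L)
})

test_that("small families are reported untested; all-small errors", {
  expect_error(family_enrichment(tiny_pk, tiny_te, min_instances = 10),
               "min_instances")
  t2 <- family_enrichment(
    tiny_pk, rbind(tiny_te,
                   data.frame(chrom = "chr1", start = 9000, end = 9050,
                              family = "C")), min_instances = 2)
  expect_false(t2$tested[t2$family == "C"])
  expect_true(is.na(t2$adj_p[t2$family == "C"]))
})

test_that("any-overlap mode equals fraction mode with f = 0 exactly", {
  set.seed(9)
  genome <- c(chr1 = 5e5)
  te <- simulate_te_annotation(genome, 5, 30, seed = 9)
  pk <- simulate_peakset(te$instances, genome, "D", 400, seed = 9)
  a <- family_enrichment(pk, te$instances, overlap_mode = "any")
  b <- family_enrichment(pk, te$instances, overlap_mode = "fraction",
                         min_fraction = 0)
  expect_equal(a$p, b$p)
  expect_equal(a$n_overlapped, b$n_overlapped)
})

test_that("BH adjustment matches a from-scratch implementation", {
  set.seed(21)
  for (rep in 1:5) {
    p <- runif(30)^2
    expect_equal(stats::p.adjust(p, "BH"), brute_bh(p),
                 tolerance = 1e-12)
  }
  # and on a real enrichment table: monotone in p, adj_p >= p
  genome <- c(chr1 = 5e5)
  te <- simulate_te_annotation(genome, 8, 25, seed = 10)
  pk <- simulate_peakset(te$instances, genome, "D", 400,
                         enrichment = c(FAM02 = 6), seed = 10)
  t <- family_enrichment(pk, te$instances)
  expect_true(all(t$adj_p >= t$p - 1e-12, na.rm = TRUE))
  o <- order(t$p)
  expect_true(all(diff(t$adj_p[o]) >= -1e-12))
  expect_equal(t$adj_p[!is.na(t$p)], brute_bh(t$p[!is.na(t$p)]),
               tolerance = 1e-12)
})

test_that("matrix assembly unions families and flags significance", {
  tabs <- list(D1 = fake_table("D1", c("f1", "f2"), c(0.01, 0.2)),
               D2 = fake_table("D2", c("f2", "f3"), c(0.3, 0.001)))
  m <- build_enrichment_matrix(tabs)
  expect_equal(rownames(m$values), c("f1", "f2", "f3"))
  expect_equal(m$values["f1", "D2"], 0)  # missing cell
  expect_equal(m$values["f3", "D2"], 3, tolerance = 1e-9)
  expect_setequal(m$significant_families, c("f1", "f3"))
  expect_error(build_enrichment_matrix(list(D1 = tabs$D1,
                                            D1 = tabs$D1)),
               "duplicated dataset")
  expect_error(build_enrichment_matrix(tabs["D1"]), "2 datasets")
})

test_that("planted enrichment is recovered as the significant subset", {
  genome <- c(chr1 = 2e6, chr2 = 2e6)
  te <- simulate_te_annotation(genome, 12, 60, seed = 12)
  planted <- c("FAM02", "FAM05", "FAM09")
  tabs <- lapply(1:2, function(i) {
    pk <- simulate_peakset(te$instances, genome, paste0("D", i), 1200,
                           enrichment = stats::setNames(c(8, 8, 8),
                                                        planted),
                           seed = child_seed(12, "peaks", i))
    family_enrichment(pk, te$instances)
  })
  names(tabs) <- c("D1", "D2")
  m <- build_enrichment_matrix(tabs)
  expect_setequal(m$significant_families, planted)
})

test_that("k-means clustering recovers separable groups, deterministically", {
  set.seed(99)
  v <- rbind(matrix(10 + rnorm(10, sd = .1), 5, 2),
             matrix(5 + rnorm(10, sd = .1), 5, 2),
             matrix(0 + abs(rnorm(10, sd = .1)), 5, 2))
  rownames(v) <- sprintf("f%02d", 1:15)
  m <- structure(list(values = v, significant = v > 2, alpha = 0.05,
                      significant_families = rownames(v)),
                 class = "enrichment_matrix")
  cl <- cluster_enrichment(m, 3, seed = 1)
  expect_equal(unname(cl), rep(1:3, each = 5))  # canonical labels
  expect_identical(cl, cluster_enrichment(m, 3, seed = 1))
  expect_error(cluster_enrichment(m, 16, seed = 1), "exceeds")
  # k = rows: each row its own cluster
  expect_equal(sort(unname(cluster_enrichment(m, 15, seed = 1))), 1:15)
})

test_that("dataset correlation is Spearman with tie-average ranks", {
  set.seed(13)
  v <- matrix(runif(100), 20, 5,
              dimnames = list(sprintf("f%02d", 1:20),
                              sprintf("D%d", 1:5)))
  m <- structure(list(values = v, significant = v > 2, alpha = 0.05,
                      significant_families = character()),
                 class = "enrichment_matrix")
  rho <- dataset_correlation(m)
  # definitional oracle: rank then Pearson
  want <- stats::cor(apply(v, 2, rank))
  expect_equal(rho, want, tolerance = 1e-12)
  dup <- m; dup$values <- cbind(v, D6 = v[, 1])
  expect_equal(dataset_correlation(dup)["D1", "D6"], 1)
  rev <- m; rev$values <- cbind(v[, 1:2], D3 = -v[, 1])
  expect_equal(dataset_correlation(rev)["D1", "D3"], -1)
  const <- m; const$values <- cbind(v[, 1:2], D3 = rep(1, 20))
  expect_true(is.na(dataset_correlation(const)["D1", "D3"]))
})

test_that("co-occupancy counts are set algebra on significance flags", {
  v <- matrix(0, 3, 5, dimnames = list(
    c("f1", "f2", "f3"), c("A", "B", "H3K4me1", "P300", "H3K4me3")))
  sig <- v > 0
  sig[c("f1", "f2"), "A"] <- TRUE
  sig[c("f2", "f3"), "B"] <- TRUE
  sig["f2", c("H3K4me1", "P300")] <- TRUE
  m <- structure(list(values = (sig) * 5, significant = sig,
                      alpha = 0.05, significant_families = rownames(v)),
                 class = "enrichment_matrix")
  rules <- default_activity_rules(promoter_marks = "H3K4me3",
                                  pioneer = "B",
                                  enhancer_marks = "H3K4me1",
                                  enhancer_cofactors = "P300",
                                  repressive = "H3K4me3")
  co <- cooccupancy_summary(m, "A", "B", rules)
  expect_equal(co$A_only, 1)
  expect_equal(co$B_only, 1)
  expect_equal(co$shared, 1)
  expect_equal(co$shared_enhancer_fraction, 1)  # f2 is enhancer-like
  expect_error(cooccupancy_summary(m, "A", "NOPE", rules),
               "missing dataset: NOPE")
  none <- m; none$significant[, "B"] <- FALSE
  expect_true(is.na(cooccupancy_summary(none, "A", "B",
                                        rules)$shared_enhancer_fraction))
})

test_that("activity classification follows the signature precedence", {
  ds <- c("H3K4me3", "TFAP2C", "H3K4me1", "H3K27ac", "P300", "MED1",
          "H3K9me3")
  sig <- matrix(FALSE, 4, 7, dimnames = list(
    c("prom", "enh", "repr", "both"), ds))
  sig["prom", c("H3K4me3", "TFAP2C")] <- TRUE
  sig["enh", c("H3K4me1", "P300")] <- TRUE
  sig["repr", "H3K9me3"] <- TRUE
  sig["both", c("H3K4me3", "TFAP2C", "H3K4me1", "P300",
                "H3K9me3")] <- TRUE
  m <- structure(list(values = sig * 4, significant = sig, alpha = 0.05,
                      significant_families = rownames(sig)),
                 class = "enrichment_matrix")
  lab <- classify_family_activity(m)
  expect_equal(unname(lab[c("prom", "enh", "repr")]),
               c("promoter-like", "enhancer-like", "repressed"))
  expect_equal(unname(lab["both"]), "promoter-like")  # precedence
  expect_error(classify_family_activity(
    m, default_activity_rules(pioneer = "GHOST")), "GHOST")
})

test_that("shortlisting requires all datasets and ranks by summed score", {
  ds <- c("GATA3", "DLX5", "TFAP2C", "H3K4me3", "H3K4me1", "P300",
          "H3K9me3")
  sig <- matrix(FALSE, 3, 7, dimnames = list(c("fa", "fb", "fc"), ds))
  sig[c("fa", "fb"), c("GATA3", "DLX5", "TFAP2C", "H3K4me3")] <- TRUE
  sig["fc", "GATA3"] <- TRUE
  vals <- sig * 4  # equal scores -> lexicographic tie-break
  m <- structure(list(values = vals, significant = sig, alpha = 0.05,
                      significant_families = rownames(sig)),
                 class = "enrichment_matrix")
  rules <- default_activity_rules(enhancer_marks = "H3K4me1",
                                  enhancer_cofactors = "P300")
  sl <- shortlist_candidates(m, c("GATA3", "DLX5", "TFAP2C"),
                             rule_config = rules)
  expect_equal(sl$family, c("fa", "fb"))
  expect_equal(sl$rank, 1:2)
  empty <- shortlist_candidates(m, c("GATA3", "DLX5", "TFAP2C"),
                                allowed_labels = "repressed",
                                rule_config = rules)
  expect_equal(nrow(empty), 0)
})

test_that("null peak sets keep the family false-positive rate near alpha", {
  genome <- c(chr1 = 1e6)
  te <- simulate_te_annotation(genome, 15, 30, seed = 30)
  fp <- vapply(1:10, function(s) {
    pk <- simulate_peakset(te$instances, genome, "null", 600,
                           seed = child_seed(30, "peaks", s))
    t <- family_enrichment(pk, te$instances)
    mean(t$adj_p < 0.05, na.rm = TRUE)
  }, 0)
  se <- stats::sd(fp) / sqrt(length(fp))
  expect_lte(mean(fp), 0.05 + 2 * max(se, 0.01))
})
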
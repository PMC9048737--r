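sig_ab <- list(enriched_in_case = c("A", "B"),
               enriched_in_control = c("C", "D"))

test_that("dysbiosis index computes the abundance-ratio formula", {
  rel <- matrix(c(0.15, 0.05, 0.06, 0.04, 0.7,
                  0.10, 0.10, 0.15, 0.05, 0.6,
                  0.20, 0.00, 0.00, 0.00, 0.8),
                nrow = 5,
                dimnames = list(c("A", "B", "C", "D", "E"),
                                c("s1", "s2", "s3")))
  di <- dysbiosis_index(rel, sig_ab)
  expect_equal(di$di[1], 0.2 / 0.1, tolerance = 1e-4)
  expect_equal(di$di[2], 1.0, tolerance = 1e-4)
  # zero denominator: pseudocount keeps it finite
  expect_equal(di$di[3], (0.2 + 1e-6) / 1e-6, tolerance = 1e-6)
  expect_true(all(is.finite(di$di) & di$di > 0))
  expect_equal(di$log10_di, log10(di$di))
})

test_that("dysbiosis index is scale-free and inverts with the signature", {
  set.seed(4)
  m <- matrix(rpois(4 * 6, 20) + 1, nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:6)))
  rel <- relative_abundance(m)
  di1 <- dysbiosis_index(rel, sig_ab)
  m2 <- m
  m2[, 3] <- m2[, 3] * 17  # rescale one sample's counts
  di2 <- dysbiosis_index(relative_abundance(m2), sig_ab)
  expect_equal(di1$di, di2$di)

  swapped <- list(enriched_in_case = sig_ab$enriched_in_control,
                  enriched_in_control = sig_ab$enriched_in_case)
  di3 <- dysbiosis_index(rel, swapped)
  expect_equal(di3$di, 1 / di1$di, tolerance = 1e-4)

  expect_warning(
    dysbiosis_index(rel, list(enriched_in_case = c("A", "ZZ"),
                              enriched_in_control = "C")),
    "absent.*ZZ")
  expect_error(dysbiosis_index(rel, list(enriched_in_case = character(),
                                         enriched_in_control = "C")),
               "both sides")
})

test_that("group tests reproduce their textbook statistics", {
  sex <- rbind(M = c(7, 14, 16), F = c(5, 4, 4))
  chi <- group_tests(test = "chisq", table = sex)
  expect_equal(chi$statistic, 2.039, tolerance = 1e-3)
  expect_equal(chi$p_value, 0.361, tolerance = 1e-3)

  w <- group_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                   test = "wilcoxon")
  expect_equal(w$p_value, 0.1)

  a <- group_tests(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3),
                   test = "anova")
  expect_equal(a$statistic, 1.5)

  k <- group_tests(1:9, rep(c("a", "b", "c"), each = 3), test = "kruskal")
  expect_equal(k$statistic, 7.2)
  expect_error(group_tests(1:4, c("a", "a", "a", "a"), test = "wilcoxon"),
               "group")
})

test_that("wilcoxon normal approximation tracks the exact small-n p", {
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:100, 8)
    y <- sample(1:100, 7) + sample(0:20, 1)
    p_exact <- group_tests(c(x, y), rep(c("a", "b"), c(8, 7)),
                           test = "wilcoxon")$p_value
    p_approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.06)
  }
})

test_that("roc_auc equals the Mann-Whitney concordance with ties at half", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       rep(c("n", "p"), each = 3), "p")$auc, 1.0)
  r <- roc_auc(c(0.1, 0.2, 0.3, 0.25, 0.4, 0.5),
               rep(c("n", "p"), each = 3), "p")
  expect_equal(r$auc, 8 / 9)
  expect_equal(roc_auc(rep(1, 6), rep(c("n", "p"), each = 3), "p")$auc, 0.5)

  # concordance identity against wilcox U, and curve monotonicity
  set.seed(11)
  sc <- c(rnorm(12), rnorm(10, 1))
  lb <- rep(c("n", "p"), c(12, 10))
  r2 <- roc_auc(sc, lb, "p")
  U <- stats::wilcox.test(sc[lb == "p"], sc[lb == "n"])$statistic
  expect_equal(r2$auc, unname(U) / (12 * 10), tolerance = 1e-12)
  expect_true(all(diff(r2$sensitivity) >= 0))
  expect_true(all(diff(r2$specificity) <= 0))
  expect_error(roc_auc(1:3, c("p", "p", "p"), "p"), "both classes")

  skip_if_not_installed("pROC")
  pr <- pROC::roc(lb, sc, levels = c("n", "p"), direction = "<",
                  quiet = TRUE)
  expect_equal(r2$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("the composition classifier separates planted cohorts", {
  sim <- simulate_counts(simulation_config(seed = 5))
  rel <- relative_abundance(sim$counts)
  fit <- fit_dysbiosis(sim$counts, sim$metadata, seed = 5)
  genera <- c(fit$signature$enriched_in_case,
              fit$signature$enriched_in_control)
  sel <- sim$metadata$group %in% c("FRI", "HC")
  mv <- suppressMessages(
    multivariate_auc(rel[, sel], sim$metadata$group[sel], positive = "FRI",
                     genera = genera))
  expect_gte(mv$auc, 0.9)

  # an uninformative genus barely moves the AUC
  mv2 <- suppressMessages(
    multivariate_auc(rel[, sel], sim$metadata$group[sel], positive = "FRI",
                     genera = c(genera, "genus_100")))
  expect_lt(abs(mv2$auc - mv$auc), 0.05)
})

test_that("the composition classifier is null-calibrated under permutation", {
  sim <- simulate_counts(simulation_config(seed = 5))
  rel <- relative_abundance(sim$counts)
  fit <- fit_dysbiosis(sim$counts, sim$metadata, seed = 5)
  genera <- c(fit$signature$enriched_in_case,
              fit$signature$enriched_in_control)
  sel <- sim$metadata$group %in% c("FRI", "HC")
  rels <- rel[, sel]
  set.seed(123)
  aucs <- replicate(60, {
    suppressMessages(
      multivariate_auc(rels, sample(sim$metadata$group[sel]),
                       positive = "FRI", genera = genera)$auc)
  })
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("logistic odds ratios match the 2x2 cross-product and invert", {
  md <- data.frame(sample_id = paste0("s", 1:40),
                   group = rep(c("FRI", "FH"), each = 20),
                   marker = c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15)))
  or <- odds_ratios(md, "marker")
  expect_equal(or$or, (10 * 15) / (10 * 5), tolerance = 1e-6)

  md2 <- md
  md2$group <- ifelse(md$group == "FRI", "FH", "FRI")
  or2 <- odds_ratios(md2, "marker")
  expect_equal(or2$or, 1 / or$or, tolerance = 1e-9)
  expect_error(odds_ratios(md, "absent"), "not found")
  md$marker <- 1
  expect_error(odds_ratios(md, "marker"), "constant")
})

test_that("odds-ratio confidence intervals cover the null at ~95%", {
  set.seed(14)
  cover <- replicate(200, {
    n <- 500
    md <- data.frame(sample_id = paste0("s", 1:n),
                     group = sample(rep(c("FRI", "FH"), each = n / 2)),
                     m = rnorm(n))
    or <- odds_ratios(md, "m")
    or$ci_lo <= 1 && 1 <= or$ci_hi
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("spearman associations recover monotone and copula links", {
  rel <- rbind(up = 1:8 / 10, down = 8:1 / 10, flat = rep(0.1, 8))
  colnames(rel) <- paste0("s", 1:8)
  md <- data.frame(sample_id = paste0("s", 1:8), m = (1:8)^2)
  res <- marker_taxon_correlations(rel, md, "m")
  expect_equal(res$rho[res$taxon == "up"], 1)
  expect_equal(res$rho[res$taxon == "down"], -1)
  expect_true(is.na(res$rho[res$taxon == "flat"]))
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"))

  # generator's copula hits the target within tolerance at n = 50
  cfg <- simulation_config(
    n_per_group = c(FRI = 50L),
    planted_effects = data.frame(taxon = "Escherichia", group = "FRI",
                                 log2fc = 0),
    marker_links = data.frame(marker = "CRP", taxon = "Escherichia",
                              rho = 0.6),
    richness_deficit_frac = 0, seed = 2)
  sim <- simulate_counts(cfg)
  rel2 <- relative_abundance(sim$counts)
  res2 <- marker_taxon_correlations(rel2, sim$metadata, "CRP",
                                    taxa = "Escherichia")
  expect_equal(res2$rho, 0.6, tolerance = 0.2)
  expect_gt(res2$rho, 0)
})
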
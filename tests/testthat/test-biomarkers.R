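test_that("kruskal-wallis screen matches the rank formula and handles ties", {
  rel <- rbind(t1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
               t2 = rep(1, 9))
  colnames(rel) <- paste0("s", 1:9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis_screen(rel, g)
  expect_equal(res$H[res$taxon == "t1"], 7.2)
  expect_equal(res$H[res$taxon == "t2"], 0)
  expect_equal(res$p[res$taxon == "t2"], 1)

  # heavy ties: tie-corrected H equals the explicit rank formula
  x <- c(1, 1, 2, 2, 2, 3, 3, 1, 2)
  r <- rank(x)
  n <- 9
  H_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  H_tie <- H_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  res2 <- kruskal_wallis_screen(rbind(tx = x), g)
  expect_equal(res2$H, H_tie, tolerance = 1e-12)
})

test_that("kruskal-wallis p is calibrated against exhaustive permutation", {
  # with n = 9 and distinct values, the permutation null of H is exact;
  # the chi-square p must sit inside the attainable permutation range
  x <- c(3, 9, 4, 1, 8, 2, 7, 5, 6)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis_screen(rbind(tx = x), g)
  perms <- NULL
  idx <- utils::combn(9, 3)
  h_of <- function(gp) kruskal_wallis_screen(rbind(tx = x), gp)$H
  h_all <- c()
  for (i in seq_len(ncol(idx))) {
    rest <- setdiff(1:9, idx[, i])
    idx2 <- utils::combn(rest, 3)
    for (j in seq_len(ncol(idx2))) {
      gp <- character(9)
      gp[idx[, i]] <- "a"
      gp[idx2[, j]] <- "b"
      gp[gp == ""] <- "c"
      h_all <- c(h_all, h_of(gp))
    }
  }
  p_exact <- mean(h_all >= res$H - 1e-12)
  # chi-square reference is approximate at n = 9; require agreement to 0.1
  expect_lt(abs(res$p - p_exact), 0.1)
})

test_that("lda effect sizes recover a planted enrichment with the right sign", {
  cfg <- simulation_config(
    planted_effects = data.frame(taxon = "Escherichia", group = "FRI",
                                 log2fc = log2(10)),
    richness_deficit_frac = 0, seed = 3)
  sim <- simulate_counts(cfg)
  rel <- relative_abundance(sim$counts)
  relf <- abundance_prevalence_filter(rel)
  sc <- lda_effect_size(relf, sim$metadata$group, seed = 3)
  scored <- sc[!is.na(sc$lda_score), ]
  top <- scored$taxon[which.max(abs(scored$lda_score))]
  expect_equal(top, "Escherichia")
  esc <- sc[sc$taxon == "Escherichia", ]
  expect_equal(esc$enriched_group, "FRI")
  expect_gt(esc$lda_score, 0)
  expect_true(esc$passed)
})

test_that("lda scoring is screened, seeded and monotone", {
  sim <- simulate_counts(simulation_config(seed = 9))
  rel <- abundance_prevalence_filter(relative_abundance(sim$counts))
  g <- sim$metadata$group
  a <- lda_effect_size(rel, g, seed = 21)
  b <- lda_effect_size(rel, g, seed = 21)
  expect_identical(a, b)  # seeded determinism

  # screen-then-score: KW failures never pass
  expect_true(all(is.na(a$lda_score[a$kw_p >= 0.05])))
  expect_false(any(a$passed[a$kw_p >= 0.05]))

  # doubling a passing feature's group contrast never lowers its |score|
  pass_tx <- a$taxon[which(a$passed)[1]]
  boosted <- rel
  in_en <- g == a$enriched_group[a$taxon == pass_tx]
  boosted[pass_tx, in_en] <- boosted[pass_tx, in_en] * 2
  b2 <- lda_effect_size(boosted, g, seed = 21)
  expect_gte(abs(b2$lda_score[b2$taxon == pass_tx]),
             abs(a$lda_score[a$taxon == pass_tx]))
})

test_that("the NB GLM flags a planted fold change and skips empty genera", {
  cfg <- simulation_config(
    planted_effects = data.frame(taxon = "Escherichia", group = "FRI",
                                 log2fc = 2),
    richness_deficit_frac = 0, seed = 13)
  sim <- simulate_counts(cfg)
  res <- glm_differential(sim$counts, sim$metadata, comparison = "FRI-vs-HC")
  esc <- res[res$taxon == "Escherichia", ]
  expect_lt(esc$p, 0.05)
  expect_gt(esc$estimate, 0)

  cts <- sim$counts[1:5, ]
  dead <- rownames(cts)[1]
  cts[dead, ] <- 0L
  cts <- rbind(cts, keepalive = as.integer(sim$metadata$library_size -
                                             colSums(cts)))
  expect_message(
    out <- glm_differential(cts, sim$metadata, comparison = "FRI-vs-FH"),
    paste0("all-zero genus ", dead))
  expect_false(dead %in% out$taxon)
})

test_that("signatures assemble correctly in all three modes", {
  # manual: the shipped 14-genus fracture-infection signature
  sig14 <- read_signature()
  sim <- simulate_counts(simulation_config(seed = 5))
  rel <- relative_abundance(sim$counts)
  sig <- build_signature(rel, sim$metadata$group, mode = "manual",
                         manual = sig14)
  expect_length(sig$enriched_in_case, 4L)
  expect_length(sig$enriched_in_control, 10L)
  expect_length(intersect(sig$enriched_in_case, sig$enriched_in_control), 0)

  # lefse: partition by enriched group
  relf <- abundance_prevalence_filter(rel)
  sc <- lda_effect_size(relf, sim$metadata$group, seed = 5)
  sl <- build_signature(relf, sim$metadata$group, mode = "lefse", lefse = sc)
  expect_true(all(sim$truth$true_enriched %in% sl$enriched_in_case))

  # glm-union: duplicates collapse, direction from group means
  fake <- data.frame(taxon = c("Escherichia", "Escherichia", "Roseburia"),
                     comparison = c("FRI-vs-HC", "FRI-vs-FH", "FRI-vs-HC"),
                     estimate = c(1, 1, -1), z = c(3, 3, -3),
                     p = c(0.01, 0.02, 0.01))
  su <- build_signature(rel, sim$metadata$group, mode = "glm-union",
                        glm_results = fake)
  expect_equal(su$enriched_in_case, "Escherichia")  # appears once
  expect_equal(su$enriched_in_control, "Roseburia")

  expect_error(build_signature(rel, sim$metadata$group, mode = "manual",
                               manual = list(enriched_in_case = "Escherichia",
                                             enriched_in_control = character())),
               "relax")
})

test_that("glm-union assigns every strongly planted genus to the true side", {
  agree <- sapply(1:3, function(s) {
    sim <- simulate_counts(simulation_config(seed = s))
    fit <- suppressMessages(
      fit_dysbiosis(sim$counts, sim$metadata, method = "glm-union",
                    seed = s))
    sig <- fit$signature
    up_ok <- sim$truth$true_enriched %in% sig$enriched_in_case
    planted_dep <- default_planted_effects()$taxon[
      default_planted_effects()$log2fc < 0]
    found_dep <- intersect(planted_dep,
                           c(sig$enriched_in_case, sig$enriched_in_control))
    dn_ok <- found_dep %in% sig$enriched_in_control
    all(up_ok) && all(dn_ok)
  })
  expect_gte(sum(agree), 2)

  # lefse and glm-union agree on direction for genera both select
  sim <- simulate_counts(simulation_config(seed = 2))
  f1 <- fit_dysbiosis(sim$counts, sim$metadata, method = "lefse", seed = 2)
  f2 <- suppressMessages(
    fit_dysbiosis(sim$counts, sim$metadata, method = "glm-union", seed = 2))
  both_up <- intersect(f1$signature$enriched_in_case,
                       c(f2$signature$enriched_in_case,
                         f2$signature$enriched_in_control))
  expect_true(all(both_up %in% f2$signature$enriched_in_case))
})
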
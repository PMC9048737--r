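# The dysbiosis index and the evaluation layer: rank tests, ROC/AUC,
# logistic odds ratios and marker-taxon rank correlations.

#' Dysbiosis index per sample
#'
#' DI = (sum of relative abundances over case-enriched genera + pseudocount)
#' / (sum over control-enriched genera + pseudocount). The symmetric
#' pseudocount (default 1e-6) keeps DI finite and positive when one side of
#' the signature carries no mass, and preserves the inversion property
#' (swapping the signature sides maps DI to 1/DI up to the pseudocount).
#' Signature genera absent from the table contribute 0, with a warning.
#'
#' @param rel taxa x samples relative-abundance matrix.
#' @param signature a `signature_set` (or list with `enriched_in_case`,
#'   `enriched_in_control`).
#' @param pseudocount added to numerator and denominator.
#' @param log10 also return log10(DI).
#' @return data.frame: sample_id, di (and log10_di).
#' @export
dysbiosis_index <- function(rel, signature, pseudocount = 1e-6,
                            log10 = TRUE) {
  up <- signature$enriched_in_case
  down <- signature$enriched_in_control
  if (!length(up) || !length(down))
    stop("signature must have genera on both sides")
  miss <- setdiff(c(up, down), rownames(rel))
  if (length(miss))
    warning("signature genera absent from table (contributing 0): ",
            paste(miss, collapse = ", "))
  num <- colSums(rel[intersect(up, rownames(rel)), , drop = FALSE])
  den <- colSums(rel[intersect(down, rownames(rel)), , drop = FALSE])
  di <- (num + pseudocount) / (den + pseudocount)
  out <- data.frame(sample_id = colnames(rel), di = as.numeric(di),
                    stringsAsFactors = FALSE)
  if (log10) out$log10_di <- log10(out$di)
  out
}

#' Group-difference tests
#'
#' Dispatches the study's univariate tests: Wilcoxon rank sum for two
#' groups (exact enumeration when both groups have n <= 10 and no ties,
#' normal approximation with tie correction otherwise), one-way ANOVA or
#' Kruskal-Wallis for three or more, and Pearson chi-square (no continuity
#' correction) on a contingency table.
#'
#' @param values numeric vector (or, for `test = "chisq"`, a contingency
#'   matrix passed via `table`).
#' @param groups group label per value.
#' @param test "wilcoxon", "anova", "kruskal" or "chisq".
#' @param table contingency matrix for the chi-square test.
#' @return list: statistic, p_value, test.
#' @export
group_tests <- function(values = NULL, groups = NULL,
                        test = c("wilcoxon", "anova", "kruskal", "chisq"),
                        table = NULL) {
  test <- match.arg(test)
  if (test == "chisq") {
    if (is.null(table)) stop("chisq test needs a contingency matrix")
    ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test = "chisq"))
  }
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) stop("empty group")
  if (test == "wilcoxon") {
    if (nlevels(groups) != 2) stop("wilcoxon needs exactly 2 groups")
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    exact <- length(x) <= 10 && length(y) <= 10
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                test = "wilcoxon"))
  }
  if (test == "anova") {
    fit <- stats::aov(values ~ groups)
    sm <- summary(fit)[[1]]
    return(list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
                test = "anova"))
  }
  ht <- stats::kruskal.test(values, groups)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       test = "kruskal")
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; sensitivity/specificity at each
#' cut, AUC by trapezoid. Ties count one half, so the AUC equals the
#' Mann-Whitney concordance probability U / (n1 * n0).
#'
#' @param scores numeric score per sample (higher = more case-like).
#' @param labels class label per sample.
#' @param positive the case label.
#' @return list of class `roc_result`: thresholds, sensitivity,
#'   specificity, auc.
#' @export
roc_auc <- function(scores, labels, positive) {
  is_pos <- labels == positive
  if (!any(is_pos) || all(is_pos)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!is_pos] < t), numeric(1))
  x <- scores[is_pos]
  y <- scores[!is_pos]
  conc <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = mean(conc)),
            class = "roc_result")
}

# ridge-penalised logistic scores via glmnet, used when plain ML fails
ridge_logistic_loo <- function(X, y, lambda = 1e-3) {
  vapply(seq_along(y), function(i) {
    fit <- glmnet::glmnet(X[-i, , drop = FALSE], y[-i], family = "binomial",
                          alpha = 0, lambda = lambda)
    as.numeric(stats::predict(fit, X[i, , drop = FALSE], type = "response"))
  }, numeric(1))
}

#' Multivariate (composition-based) cross-validated AUC
#'
#' Logistic regression on log-transformed signature-genus relative
#' abundances, scored by leave-one-out cross-validation and fed to
#' [roc_auc()]. If any training fold fails to converge (separation), the
#' whole model falls back to a ridge-penalised logistic fit (glmnet,
#' lambda 1e-3), with a message. Deterministic given its inputs;
#' `resubstitution = TRUE` skips cross-validation for comparison.
#'
#' @param rel taxa x samples relative-abundance matrix restricted (by the
#'   caller or via `genera`) to the signature genera.
#' @param labels class label per sample.
#' @param positive the case label.
#' @param genera optional subset of rownames to use.
#' @param pseudocount added before the log transform.
#' @param resubstitution score on the training fit instead of LOO.
#' @return `roc_result` with an extra `scores` element.
#' @export
multivariate_auc <- function(rel, labels, positive, genera = NULL,
                             pseudocount = 1e-6, resubstitution = FALSE) {
  if (!is.null(genera))
    rel <- rel[intersect(genera, rownames(rel)), , drop = FALSE]
  if (min(table(labels)) < 5) stop("need >= 5 samples per class")
  X <- t(log(rel + pseudocount))
  y <- as.integer(labels == positive)
  fit_scores <- function(train, test) {
    dat <- data.frame(y = y[train], X[train, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                       family = stats::binomial()))
    if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 50, na.rm = TRUE))
      return(NULL)
    newd <- data.frame(X[test, , drop = FALSE])
    suppressWarnings(stats::predict(fit, newdata = newd, type = "response"))
  }
  n <- length(y)
  if (resubstitution) {
    scores <- fit_scores(seq_len(n), seq_len(n))
    if (is.null(scores)) {
      message("multivariate_auc: separation; using ridge-penalised fit")
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = 1e-3)
      scores <- as.numeric(stats::predict(fit, X, type = "response"))
    }
  } else {
    scores <- rep(NA_real_, n)
    ok <- TRUE
    for (i in seq_len(n)) {
      s <- fit_scores(setdiff(seq_len(n), i), i)
      if (is.null(s)) { ok <- FALSE; break }
      scores[i] <- s
    }
    if (!ok) {
      message("multivariate_auc: separation; using ridge-penalised LOO fit")
      scores <- ridge_logistic_loo(X, y)
    }
  }
  res <- roc_auc(scores, labels, positive)
  res$scores <- scores
  res
}

#' Univariate logistic odds ratios for serum markers
#'
#' Per marker, a univariate logistic fit of case status on the standardized
#' marker, with Wald 95% confidence intervals. Binary 0/1 markers are used
#' unstandardized, so the OR matches the 2x2 cross-product ratio. Perfect
#' separation triggers a ridge-penalised fallback, flagged in the output.
#'
#' @param metadata data.frame with `group` and the marker columns.
#' @param markers marker column names.
#' @param case,control the two labels compared (rows restricted to them).
#' @return data.frame: marker, or, ci_lo, ci_hi, p, penalized.
#' @export
odds_ratios <- function(metadata, markers, case = "FRI", control = "FH") {
  md <- metadata[metadata$group %in% c(case, control), , drop = FALSE]
  y <- as.integer(md$group == case)
  res <- lapply(markers, function(m) {
    x <- md[[m]]
    if (is.null(x)) stop("marker not found: ", m)
    if (length(unique(x)) < 2) stop("marker is constant: ", m)
    binary <- all(x %in% c(0, 1))
    if (!binary) x <- as.numeric(scale(x))
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    penal <- FALSE
    if (!fit$converged || abs(cf["x", "Estimate"]) > 25) {
      penal <- TRUE
      Xm <- cbind(x, 0)  # glmnet needs >= 2 columns; second is inert
      rfit <- glmnet::glmnet(Xm, y, family = "binomial", alpha = 0,
                             lambda = 1e-2)
      b <- as.numeric(stats::coef(rfit))[2]
      cf <- matrix(c(b, NA, NA, NA), nrow = 1,
                   dimnames = list("x", c("Estimate", "Std. Error",
                                          "z value", "Pr(>|z|)")))
      cf <- rbind("(Intercept)" = NA, cf)
    }
    b <- cf["x", "Estimate"]
    se <- cf["x", "Std. Error"]
    data.frame(marker = m, or = exp(b),
               ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
               p = cf["x", "Pr(>|z|)"], penalized = penal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spearman correlations between serum markers and taxa
#'
#' Tie-corrected Spearman rho and p per (marker, taxon) pair, with
#' Benjamini-Hochberg adjustment across the whole grid. Constant vectors
#' yield NA rho (reported, not dropped).
#'
#' @param rel taxa x samples abundance matrix.
#' @param metadata data.frame holding the marker columns, rows matching
#'   table samples by `sample_id`.
#' @param markers marker column names.
#' @param taxa taxa to test (default all rows).
#' @return data.frame: marker, taxon, rho, p, p_adj.
#' @export
marker_taxon_correlations <- function(rel, metadata, markers,
                                      taxa = rownames(rel)) {
  md <- metadata[match(colnames(rel), metadata$sample_id), , drop = FALSE]
  if (ncol(rel) < 4) stop("need >= 4 paired observations")
  grid <- expand.grid(marker = markers, taxon = taxa,
                      stringsAsFactors = FALSE)
  res <- mapply(function(m, tx) {
    x <- md[[m]]
    yv <- rel[tx, ]
    if (length(unique(x)) < 2 || length(unique(yv)) < 2)
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(x, yv, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }, grid$marker, grid$taxon)
  grid$rho <- res[1, ]
  grid$p <- res[2, ]
  grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  grid
}
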
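# fit_dysbiosis(): the package's central estimator. Fits an enriched /
# depleted genus signature on a labelled cohort and scores every sample
# with the dysbiosis index; returns a classed object with the usual
# modelling methods.

#' Fit a dysbiosis signature and index to a case-control cohort
#'
#' Pipeline: (optionally) collapse the count table to a taxonomic rank,
#' convert to relative abundances, apply the abundance/prevalence filter,
#' discover the signature (LEfSe-style LDA effect sizes, the union of
#' covariate-adjusted GLM comparisons, or a user-supplied list), score
#' every sample with the dysbiosis index, and evaluate discrimination
#' (rank tests and ROC/AUC of the index, plus a cross-validated logistic
#' model on the signature composition).
#'
#' @param counts taxa x samples count matrix.
#' @param metadata data.frame with sample_id, group, age, sex (and any
#'   marker columns).
#' @param taxonomy optional named lineage vector; when given, counts are
#'   collapsed to `rank` first.
#' @param tree optional rooted phylogeny; when given, per-sample Shannon
#'   and Faith's PD are also computed.
#' @param rank collapse rank (default genus).
#' @param method signature discovery mode: "lefse", "glm-union" or
#'   "manual".
#' @param manual_signature list with `enriched_in_case` /
#'   `enriched_in_control` (method = "manual").
#' @param case case group label; remaining groups are the controls.
#' @param min_rel,min_prev abundance/prevalence filter thresholds.
#' @param alpha significance level for the screens.
#' @param lda_threshold absolute LDA score needed to pass.
#' @param n_boot LDA bootstrap count.
#' @param pseudocount dysbiosis-index pseudocount.
#' @param seed integer seed for the seeded stages.
#' @return an object of class `dysbiosis_fit`.
#' @seealso [predict.dysbiosis_fit()], [summary.dysbiosis_fit()]
#' @export
fit_dysbiosis <- function(counts, metadata, taxonomy = NULL, tree = NULL,
                          rank = "genus",
                          method = c("lefse", "glm-union", "manual"),
                          manual_signature = NULL, case = "FRI",
                          min_rel = 1e-4, min_prev = 0.2, alpha = 0.05,
                          lda_threshold = 2.0, n_boot = 30L,
                          pseudocount = 1e-6, seed = 1L) {
  method <- match.arg(method)
  validate_feature_table(counts)
  check_ids(counts, metadata = metadata, taxonomy = taxonomy, tree = tree)
  if (!is.null(taxonomy))
    counts <- collapse_to_rank(counts, taxonomy, rank = rank)
  md <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  groups <- md$group
  if (!case %in% groups) stop("case group '", case, "' absent from data")
  rel <- relative_abundance(counts)
  rel_f <- abundance_prevalence_filter(rel, min_rel = min_rel,
                                       min_prev = min_prev)

  scores <- NULL
  glm_res <- NULL
  if (method == "lefse") {
    scores <- lda_effect_size(rel_f, groups, alpha = alpha,
                              lda_threshold = lda_threshold,
                              n_boot = n_boot, seed = seed, case = case)
    signature <- build_signature(rel_f, groups, mode = "lefse",
                                 lefse = scores, case = case)
  } else if (method == "glm-union") {
    cf <- counts[rownames(rel_f), , drop = FALSE]
    comps <- c("FRI-vs-FH-vs-HC", "FRI-vs-HC", "FRI-vs-FH")
    comps <- comps[vapply(comps, function(cc)
      all(strsplit(cc, "-vs-")[[1]] %in% groups), logical(1))]
    glm_res <- do.call(rbind, lapply(comps, function(cc)
      glm_differential(cf, md, comparison = cc)))
    signature <- build_signature(rel_f, groups, mode = "glm-union",
                                 glm_results = glm_res, case = case,
                                 alpha = alpha)
  } else {
    signature <- build_signature(rel, groups, mode = "manual",
                                 manual = manual_signature, case = case)
  }

  di <- dysbiosis_index(rel, signature, pseudocount = pseudocount)
  di$group <- groups

  controls <- setdiff(unique(groups), case)
  tests <- list()
  rocs <- list()
  for (ctl in controls) {
    sel <- groups %in% c(case, ctl)
    key <- paste0(case, "_vs_", ctl)
    tests[[key]] <- group_tests(di$di[sel], groups[sel], test = "wilcoxon")
    rocs[[key]] <- roc_auc(di$di[sel], groups[sel], positive = case)
  }
  if (length(controls) >= 2) {
    sel <- groups %in% controls
    tests[[paste(controls, collapse = "_vs_")]] <-
      group_tests(di$di[sel], groups[sel], test = "wilcoxon")
    tests[["all_groups"]] <- group_tests(di$di, groups, test = "kruskal")
  }

  alpha_div <- NULL
  if (!is.null(tree)) {
    alpha_div <- data.frame(
      sample_id = colnames(counts), group = groups,
      shannon = apply(counts, 2, shannon),
      faith_pd = apply(counts, 2, faith_pd, tree = tree),
      stringsAsFactors = FALSE)
  }

  structure(list(call = match.call(), method = method, case = case,
                 signature = signature, scores = scores,
                 glm_results = glm_res, di = di, tests = tests, roc = rocs,
                 alpha_diversity = alpha_div, rel = rel, groups = groups,
                 params = list(min_rel = min_rel, min_prev = min_prev,
                               alpha = alpha, lda_threshold = lda_threshold,
                               pseudocount = pseudocount, seed = seed)),
            class = "dysbiosis_fit")
}

#' @export
print.dysbiosis_fit <- function(x, ...) {
  cat("Dysbiosis signature fit (", x$method, ")\n", sep = "")
  cat("  case group: ", x$case, "; samples: ", nrow(x$di), "\n", sep = "")
  cat("  signature: ", length(x$signature$enriched_in_case),
      " case-enriched / ", length(x$signature$enriched_in_control),
      " control-enriched genera\n", sep = "")
  for (k in names(x$roc))
    cat(sprintf("  AUC(DI) %s: %.3f\n", k, x$roc[[k]]$auc))
  invisible(x)
}

#' Summarise a dysbiosis fit
#'
#' Median dysbiosis index per group, the signature genera, rank-test
#' p-values, and AUCs.
#' @param object a `dysbiosis_fit`.
#' @param ... unused.
#' @export
summary.dysbiosis_fit <- function(object, ...) {
  med <- tapply(object$di$di, object$di$group, stats::median)
  out <- list(method = object$method, case = object$case,
              signature = object$signature, median_di = med,
              tests = vapply(object$tests, `[[`, numeric(1), "p_value"),
              auc = vapply(object$roc, `[[`, numeric(1), "auc"))
  class(out) <- "summary.dysbiosis_fit"
  out
}

#' @export
print.summary.dysbiosis_fit <- function(x, ...) {
  cat("Dysbiosis fit summary (", x$method, ", case = ", x$case, ")\n",
      sep = "")
  cat("case-enriched: ", paste(x$signature$enriched_in_case,
                               collapse = ", "), "\n", sep = "")
  cat("control-enriched: ", paste(x$signature$enriched_in_control,
                                  collapse = ", "), "\n", sep = "")
  cat("median DI by group:\n")
  print(round(x$median_di, 3))
  cat("rank-test p-values:\n")
  print(signif(x$tests, 3))
  cat("AUC of the index:\n")
  print(round(x$auc, 3))
  invisible(x)
}

#' Signature directions as coefficients
#'
#' +1 for case-enriched genera, -1 for control-enriched.
#' @param object a `dysbiosis_fit`.
#' @param ... unused.
#' @export
coef.dysbiosis_fit <- function(object, ...) {
  s <- object$signature
  stats::setNames(c(rep(1, length(s$enriched_in_case)),
                    rep(-1, length(s$enriched_in_control))),
                  c(s$enriched_in_case, s$enriched_in_control))
}

#' Dysbiosis index for new samples
#'
#' @param object a `dysbiosis_fit`.
#' @param newdata taxa x samples count (or relative-abundance) matrix at
#'   the rank the model was fitted on.
#' @param type "di" or "log10_di".
#' @param ... unused.
#' @return named numeric vector of index values.
#' @export
predict.dysbiosis_fit <- function(object, newdata,
                                  type = c("di", "log10_di"), ...) {
  type <- match.arg(type)
  if (max(abs(colSums(newdata) - 1)) > 1e-6)
    newdata <- relative_abundance(newdata)
  di <- dysbiosis_index(newdata, object$signature,
                        pseudocount = object$params$pseudocount)
  stats::setNames(if (type == "di") di$di else di$log10_di, di$sample_id)
}

#' @export
fitted.dysbiosis_fit <- function(object, ...) {
  stats::setNames(object$di$di, object$di$sample_id)
}

#' Plot a dysbiosis fit
#'
#' Left: log10 dysbiosis index by group. Right: ROC curves of the index
#' for the case against each control group.
#' @param x a `dysbiosis_fit`.
#' @param ... passed to [boxplot()].
#' @export
plot.dysbiosis_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(log10_di ~ group, data = x$di,
                    ylab = "log10 dysbiosis index", xlab = "", ...)
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "grey",
                 xlab = "1 - specificity", ylab = "sensitivity")
  cols <- seq_along(x$roc) + 1
  for (i in seq_along(x$roc)) {
    r <- x$roc[[i]]
    graphics::lines(1 - r$specificity, r$sensitivity, col = cols[i])
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.2f)", names(x$roc),
                                    vapply(x$roc, `[[`, numeric(1), "auc")),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
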
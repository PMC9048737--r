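# Signature discovery: Kruskal-Wallis screening, LEfSe-style linear
# discriminant effect sizes, and covariate-adjusted negative-binomial GLMs.

#' Kruskal-Wallis screen across taxa
#'
#' Tie-corrected H and chi-square p-value per taxon (via
#' [stats::kruskal.test()]). A taxon constant across all samples gets
#' H = 0, p = 1 rather than an error.
#'
#' @param rel taxa x samples abundance matrix.
#' @param groups group label per sample (>= 2 groups).
#' @param alpha screening level; `pass` is `p < alpha`.
#' @return data.frame: taxon, H, p, pass.
#' @export
kruskal_wallis_screen <- function(rel, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  res <- t(apply(rel, 1, function(x) {
    if (max(x) == min(x)) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(x, groups)
    c(H = unname(kt$statistic), p = kt$p.value)
  }))
  ids <- rownames(rel)
  if (is.null(ids)) ids <- paste0("taxon_", seq_len(nrow(rel)))
  data.frame(taxon = ids, H = res[, "H"], p = res[, "p"],
             pass = res[, "p"] < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

# ridge-regularised pooled-covariance discriminant direction, unit L2 norm;
# the ridge constant lambda = max(1e-6 * mean diag, 1e-8) is always added
lda_direction <- function(X1, X0) {
  m1 <- colMeans(X1)
  m0 <- colMeans(X0)
  n1 <- nrow(X1)
  n0 <- nrow(X0)
  Sw <- (stats::cov(X1) * (n1 - 1) + stats::cov(X0) * (n0 - 1)) / (n1 + n0 - 2)
  lam <- max(1e-6 * mean(diag(Sw)), 1e-8)
  p <- ncol(Sw)
  w <- NULL
  repeat {
    w <- tryCatch(solve(Sw + diag(lam, p), m1 - m0), error = function(e) NULL)
    if (!is.null(w)) break
    lam <- lam * 10
  }
  nw <- sqrt(sum(w^2))
  if (nw > 0) w <- w / nw
  list(w = w, m1 = m1, m0 = m0)
}

#' LEfSe-style LDA effect sizes
#'
#' Features passing the Kruskal-Wallis screen are scored with a linear
#' discriminant effect size, following the published LEfSe recipe: relative
#' abundances rescaled by 1e6; 30 seeded subsamples of 2/3 of each class;
#' one-vs-rest discriminants for multi-class designs, each feature scored
#' under its enriched class (the class with the largest mean); per
#' bootstrap the feature's effect is
#' `0.5 * (|between-class mean difference| + |w_f * (w . (m1 - m0))|)`
#' with `w` the ridge-regularised pooled-covariance discriminant direction
#' (unit L2 norm); the score is `log10(1 + mean bootstrap effect)`, signed
#' positive when the feature is enriched in `case` and negative otherwise.
#'
#' @param rel taxa x samples relative-abundance matrix.
#' @param groups group label per sample; >= 2 groups of >= 3 samples each.
#' @param alpha Kruskal-Wallis screening level.
#' @param lda_threshold absolute score needed to pass (LEfSe convention 2.0).
#' @param n_boot number of bootstrap subsamples.
#' @param subsample_frac fraction of each class drawn per bootstrap.
#' @param seed integer seed.
#' @param case group treated as the positive direction (default FRI when
#'   present, else the first level).
#' @return data.frame: taxon, kw_H, kw_p, lda_score, enriched_group, passed.
#'   Features failing the screen keep NA scores and `passed = FALSE`.
#' @export
lda_effect_size <- function(rel, groups, alpha = 0.05, lda_threshold = 2.0,
                            n_boot = 30L, subsample_frac = 2 / 3, seed = 1L,
                            case = NULL) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 3))
    stop("need >= 2 groups with >= 3 samples each")
  if (is.null(case))
    case <- if ("FRI" %in% names(tab)) "FRI" else names(tab)[1]
  kw <- kruskal_wallis_screen(rel, groups, alpha = alpha)
  out <- data.frame(taxon = kw$taxon, kw_H = kw$H, kw_p = kw$p,
                    lda_score = NA_real_, enriched_group = NA_character_,
                    passed = FALSE, stringsAsFactors = FALSE)
  keep <- which(kw$pass)
  if (!length(keep)) return(out)

  X <- t(rel[keep, , drop = FALSE]) * 1e6   # samples x features, LEfSe scale
  feats <- colnames(X)
  grp_means <- vapply(names(tab), function(g)
    colMeans(X[groups == g, , drop = FALSE]), numeric(length(feats)))
  if (length(feats) == 1) grp_means <- matrix(grp_means, nrow = 1,
                                              dimnames = list(feats, names(tab)))
  enriched <- colnames(grp_means)[max.col(grp_means, ties.method = "first")]
  names(enriched) <- feats

  set.seed(seed)
  classes <- unique(enriched)
  eff_sum <- matrix(0, nrow = length(feats), ncol = length(classes),
                    dimnames = list(feats, classes))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(names(tab), function(g) {
      ig <- which(groups == g)
      sample(ig, max(2, ceiling(subsample_frac * length(ig))))
    }))
    gb <- groups[idx]
    Xb <- X[idx, , drop = FALSE]
    for (cl in classes) {
      ld <- lda_direction(Xb[gb == cl, , drop = FALSE],
                          Xb[gb != cl, , drop = FALSE])
      d <- sum(ld$w * (ld$m1 - ld$m0))
      eff_sum[, cl] <- eff_sum[, cl] +
        0.5 * (abs(ld$m1 - ld$m0) + abs(ld$w * d))
    }
  }
  eff <- eff_sum / n_boot
  score <- log10(1 + eff[cbind(feats, enriched[feats])])
  sgn <- ifelse(enriched == case, 1, -1)
  out$lda_score[keep] <- sgn * score
  out$enriched_group[keep] <- enriched
  out$passed[keep] <- abs(score) >= lda_threshold
  out
}

#' Covariate-adjusted differential abundance by negative-binomial GLM
#'
#' Per genus, fits counts ~ group + age + sex with a log(sample total)
#' offset, negative-binomial family with ML dispersion ([MASS::glm.nb()]);
#' on non-convergence the dispersion falls back to method-of-moments
#' ([MASS::theta.mm()]) inside a fixed-theta NB fit. The reported Wald z
#' and two-sided p are for the FRI contrast (in the three-group comparison,
#' the FRI coefficient against the HC reference). Alternative families
#' (`poisson`, `binomial` on presence/absence) are available for
#' sensitivity checks. Genera with all-zero counts within the compared
#' groups are skipped with a message.
#'
#' @param counts taxa x samples count matrix (genus level).
#' @param metadata data.frame with sample_id, group, age, sex.
#' @param comparison one of "FRI-vs-FH-vs-HC", "FRI-vs-HC", "FRI-vs-FH".
#' @param family "negbin" (default), "poisson" or "binomial".
#' @return data.frame: taxon, comparison, estimate, z, p.
#' @export
glm_differential <- function(counts, metadata,
                             comparison = c("FRI-vs-FH-vs-HC", "FRI-vs-HC",
                                            "FRI-vs-FH"),
                             family = c("negbin", "poisson", "binomial")) {
  comparison <- match.arg(comparison)
  family <- match.arg(family)
  check_ids(counts, metadata = metadata)
  want <- strsplit(comparison, "-vs-", fixed = TRUE)[[1]]
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  sel <- md$group %in% want
  md <- md[sel, , drop = FALSE]
  sub <- counts[, sel, drop = FALSE]
  if (!all(want %in% md$group))
    stop("comparison groups missing from data: ",
         paste(setdiff(want, md$group), collapse = ", "))
  if (!all(c("age", "sex") %in% names(md)))
    stop("metadata must provide age and sex")
  ref <- if ("HC" %in% want) "HC" else setdiff(want, "FRI")[1]
  md$group <- stats::relevel(factor(md$group, levels = want), ref = ref)
  offs <- log(colSums(sub))
  covs <- c("group",
            if (length(unique(md$age)) > 1) "age",
            if (length(unique(md$sex)) > 1) "sex")
  fml <- stats::as.formula(paste("y ~", paste(covs, collapse = " + ")))
  res <- lapply(rownames(sub), function(tx) {
    y <- sub[tx, ]
    if (all(y == 0)) {
      message("glm_differential: skipping all-zero genus ", tx)
      return(NULL)
    }
    dat <- cbind(data.frame(y = as.numeric(y)), md)
    fit <- switch(family,
      negbin = tryCatch(
        suppressWarnings(MASS::glm.nb(stats::update(fml, . ~ . + offset(offs)),
                                      data = dat)),
        error = function(e) {
          pfit <- suppressWarnings(stats::glm(fml, data = dat,
                                              family = stats::poisson(),
                                              offset = offs))
          th <- tryCatch(
            MASS::theta.mm(dat$y, stats::fitted(pfit),
                           stats::df.residual(pfit)),
            error = function(e2) 1)
          if (!is.finite(th)) th <- 1
          th <- min(max(th, 1e-2), 1e6)  # keep the IRLS numerically sane
          tryCatch(
            suppressWarnings(stats::glm(fml, data = dat,
                                        family = MASS::negative.binomial(th),
                                        offset = offs)),
            error = function(e3) pfit)
        }),
      poisson = suppressWarnings(stats::glm(fml, data = dat,
                                            family = stats::poisson(),
                                            offset = offs)),
      binomial = suppressWarnings(stats::glm(
        stats::as.formula(paste("I(y > 0) ~", paste(covs, collapse = " + "))),
        data = dat, family = stats::binomial())))
    cf <- summary(fit)$coefficients
    row <- "groupFRI"
    if (!row %in% rownames(cf)) return(NULL)
    z <- cf[row, "Estimate"] / cf[row, "Std. Error"]
    data.frame(taxon = tx, comparison = comparison,
               estimate = cf[row, "Estimate"], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(taxon = character(), comparison = character(),
                      estimate = numeric(), z = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build an enriched/depleted genus signature
#'
#' Three modes. `lefse`: genera passing the LDA-score threshold, partitioned
#' by their enriched group. `glm-union`: the union of genera with p < alpha
#' over the three group comparisons, each assigned to the case side iff its
#' mean relative abundance is higher in `case` than in the pooled controls
#' (ties go to the control side, with a warning). `manual`: user-provided
#' sets validated against the table.
#'
#' @param rel taxa x samples relative-abundance matrix.
#' @param groups group label per sample.
#' @param mode "lefse", "glm-union" or "manual".
#' @param lefse output of [lda_effect_size()] (lefse mode).
#' @param glm_results row-bound outputs of [glm_differential()] across the
#'   comparisons (glm-union mode).
#' @param manual list with `enriched_in_case`, `enriched_in_control`
#'   (manual mode).
#' @param case the case group label.
#' @param alpha p threshold for glm-union membership.
#' @return list of class `signature_set`: `enriched_in_case`,
#'   `enriched_in_control`, `provenance`.
#' @export
build_signature <- function(rel, groups,
                            mode = c("lefse", "glm-union", "manual"),
                            lefse = NULL, glm_results = NULL, manual = NULL,
                            case = "FRI", alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "lefse") {
    if (is.null(lefse)) stop("lefse scores required for lefse mode")
    sel <- lefse[lefse$passed, , drop = FALSE]
    up <- sel$taxon[sel$enriched_group == case]
    down <- sel$taxon[sel$enriched_group != case]
  } else if (mode == "glm-union") {
    if (is.null(glm_results)) stop("glm results required for glm-union mode")
    union_tx <- unique(glm_results$taxon[glm_results$p < alpha])
    union_tx <- intersect(union_tx, rownames(rel))
    if (!length(union_tx))
      stop("no genus significant in any comparison; relax alpha")
    in_case <- groups == case
    mu_case <- rowMeans(rel[union_tx, in_case, drop = FALSE])
    mu_ctrl <- rowMeans(rel[union_tx, !in_case, drop = FALSE])
    ties <- union_tx[mu_case == mu_ctrl]
    if (length(ties))
      warning("equal group means; assigning to control side: ",
              paste(ties, collapse = ", "))
    up <- union_tx[mu_case > mu_ctrl]
    down <- union_tx[mu_case <= mu_ctrl]
  } else {
    if (is.null(manual) ||
        !all(c("enriched_in_case", "enriched_in_control") %in% names(manual)))
      stop("manual mode needs enriched_in_case and enriched_in_control")
    up <- manual$enriched_in_case
    down <- manual$enriched_in_control
    miss <- setdiff(c(up, down), rownames(rel))
    if (length(miss))
      warning("signature genera absent from table: ",
              paste(miss, collapse = ", "))
  }
  if (length(intersect(up, down)))
    stop("signature sides overlap: ", paste(intersect(up, down),
                                            collapse = ", "))
  if (!length(up) || !length(down))
    stop("empty signature side (case: ", length(up), ", control: ",
         length(down), "); relax the selection thresholds")
  structure(list(enriched_in_case = sort(unique(up)),
                 enriched_in_control = sort(unique(down)),
                 provenance = mode),
            class = "signature_set")
}

#' Load a signature from a two-column TSV (genus, side)
#'
#' `side` is `case` or `control`. The package ships
#' `inst/extdata/signature_fri14.tsv`, a 14-genus fracture-related-infection
#' signature (4 case-enriched, 10 control-enriched).
#'
#' @param path TSV path; default the shipped 14-genus signature.
#' @return list with `enriched_in_case`, `enriched_in_control`.
#' @export
read_signature <- function(path = system.file("extdata",
                                              "signature_fri14.tsv",
                                              package = "dysbiome")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("genus", "side") %in% names(df)),
            all(df$side %in% c("case", "control")))
  list(enriched_in_case = df$genus[df$side == "case"],
       enriched_in_control = df$genus[df$side == "control"])
}
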
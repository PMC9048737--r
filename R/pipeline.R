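# End-to-end orchestration: simulate (or load) -> filter -> diversity ->
# biomarkers -> dysbiosis -> evaluation, with every intermediate written
# to disk and a checksum manifest for reproducibility.

write_tsv <- function(df, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    df <- data.frame(stats::setNames(list(rownames(df)), rownames_col), df,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the whole analysis pipeline on a simulated or on-disk cohort
#'
#' Stages, in dependency order: simulate (or read) the dataset; collapse /
#' normalise / filter the table; alpha diversity (Shannon, Faith's PD),
#' unweighted-UniFrac distances, PCoA and PERMANOVA; LEfSe-style signature
#' discovery via [fit_dysbiosis()]; dysbiosis index, rank tests and AUCs;
#' serum-marker odds ratios and marker-taxon Spearman correlations when
#' marker columns are present. Every artifact is written under `out_dir`
#' as TSV/Newick/JSON, and `manifest.json` records the configuration hash,
#' the seed and an MD5 checksum per file; a rerun with the same
#' configuration is bit-identical.
#'
#' @param config a [simulation_config()] (simulated cohort), or a named
#'   list of paths with elements `counts`, `metadata`, `tree`, `taxonomy`
#'   (on-disk cohort).
#' @param out_dir output directory.
#' @param method signature discovery mode passed to [fit_dysbiosis()].
#' @param n_permutations PERMANOVA permutations.
#' @param seed seed for the seeded analysis stages (the simulation stage
#'   uses the seed inside `config`).
#' @return invisibly, a list: `fit` (the `dysbiosis_fit`), `permanova`,
#'   `pcoa`, `manifest` (named md5 vector), `paths`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         method = "lefse", n_permutations = 999,
                         seed = 1L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  t0 <- Sys.time()
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s (%.1fs)", stage, paste0(...),
                    as.numeric(Sys.time() - t0, units = "secs")))

  if (inherits(config, "sim_config")) {
    sim <- simulate_counts(config)
    counts <- sim$counts; metadata <- sim$metadata
    tree <- sim$tree; taxonomy <- sim$taxonomy
    log_stage("simulate", "seed ", config$seed, ", ",
              ncol(counts), " samples x ", nrow(counts), " taxa")
  } else {
    counts <- read_table(config$counts)
    metadata <- read_metadata(config$metadata)
    tree <- read_tree(config$tree)
    taxonomy <- read_taxonomy(config$taxonomy)
    log_stage("load", "read 4 input files")
  }
  paths <- write_dataset(counts, metadata, tree, taxonomy, out_dir)

  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  groups <- md$group
  rel <- relative_abundance(counts)

  # diversity
  alpha <- data.frame(sample_id = colnames(counts), group = groups,
                      shannon = apply(counts, 2, shannon),
                      faith_pd = apply(counts, 2, faith_pd, tree = tree),
                      stringsAsFactors = FALSE)
  paths["alpha_diversity"] <- write_tsv(alpha,
                                        file.path(out_dir,
                                                  "alpha_diversity.tsv"))
  dm <- pairwise_distances(rel, tree, weighted = FALSE)
  paths["distance_matrix"] <- write_tsv(as.data.frame(dm),
                                        file.path(out_dir,
                                                  "unweighted_unifrac.tsv"),
                                        rownames_col = "sample_id")
  ord <- pcoa(dm)
  co <- as.data.frame(ord$coordinates)
  names(co) <- paste0("PCo", seq_len(ncol(co)))
  paths["pcoa"] <- write_tsv(co, file.path(out_dir, "pcoa_coordinates.tsv"),
                             rownames_col = "sample_id")
  paths["pcoa_eigenvalues"] <- write_tsv(
    data.frame(axis = seq_along(ord$eigenvalues),
               eigenvalue = ord$eigenvalues,
               prop_explained = ord$prop_explained),
    file.path(out_dir, "pcoa_eigenvalues.tsv"))
  pmv <- permanova(dm, groups, n_permutations = n_permutations, seed = seed)
  log_stage("diversity", sprintf("PERMANOVA F = %.2f, p = %.4f",
                                 pmv$pseudo_F, pmv$p_value))

  # biomarkers + dysbiosis via the fit object
  fit <- fit_dysbiosis(counts, md, tree = tree, method = method, seed = seed)
  if (!is.null(fit$scores))
    paths["biomarkers"] <- write_tsv(fit$scores,
                                     file.path(out_dir, "lda_scores.tsv"))
  if (!is.null(fit$glm_results))
    paths["glm"] <- write_tsv(fit$glm_results,
                              file.path(out_dir, "glm_results.tsv"))
  paths["signature"] <- write_tsv(
    data.frame(genus = c(fit$signature$enriched_in_case,
                         fit$signature$enriched_in_control),
               side = c(rep("case", length(fit$signature$enriched_in_case)),
                        rep("control",
                            length(fit$signature$enriched_in_control)))),
    file.path(out_dir, "signature.tsv"))
  paths["dysbiosis_index"] <- write_tsv(fit$di,
                                        file.path(out_dir,
                                                  "dysbiosis_index.tsv"))
  log_stage("dysbiosis", length(fit$signature$enriched_in_case), "+",
            length(fit$signature$enriched_in_control), " signature genera")

  # evaluation
  summary_stats <- list(
    permanova = list(pseudo_F = pmv$pseudo_F, p_value = pmv$p_value,
                     R2 = pmv$R2, n_permutations = n_permutations),
    dysbiosis_tests = lapply(fit$tests, function(t)
      list(statistic = t$statistic, p_value = t$p_value, test = t$test)),
    auc_di = lapply(fit$roc, `[[`, "auc"))
  marker_cols <- intersect(names(md), names(MARKER_LOG_MEAN))
  if (length(marker_cols) >= 1 && all(c("FRI", "FH") %in% groups)) {
    ors <- odds_ratios(md, marker_cols)
    paths["odds_ratios"] <- write_tsv(ors,
                                      file.path(out_dir, "odds_ratios.tsv"))
    cors <- marker_taxon_correlations(
      rel, md, marker_cols,
      taxa = c(fit$signature$enriched_in_case,
               fit$signature$enriched_in_control))
    paths["correlations"] <- write_tsv(
      cors, file.path(out_dir, "marker_taxon_correlations.tsv"))
  }
  for (k in names(fit$roc)) {
    r <- fit$roc[[k]]
    paths[paste0("roc_", k)] <- write_tsv(
      data.frame(threshold = r$thresholds, sensitivity = r$sensitivity,
                 specificity = r$specificity),
      file.path(out_dir, paste0("roc_", k, ".tsv")))
  }
  paths["summary"] <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary_stats, paths[["summary"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("evaluate", "wrote run_summary.json")

  # manifest: config hash, seed, checksum per artifact
  cfg_file <- file.path(out_dir, "config.json")
  cfg_list <- if (inherits(config, "sim_config")) unclass(config) else config
  jsonlite::write_json(cfg_list, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  paths["config"] <- cfg_file
  sums <- tools::md5sum(unname(paths))
  names(sums) <- names(paths)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                   seed = seed,
                   files = lapply(names(paths), function(k)
                     list(name = k, file = basename(paths[[k]]),
                          md5 = unname(sums[[k]]))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("manifest", length(paths), " artifacts")

  invisible(list(fit = fit, permanova = pmv, pcoa = ord,
                 alpha_diversity = alpha, manifest = sums, paths = paths))
}
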
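# Synthetic case-control cohort generator: Dirichlet-multinomial counts with
# planted group effects, a random phylogeny, and serum markers linked to
# planted genera through a Gaussian copula on ranks.

#' Simulate a rooted phylogeny for synthetic taxa
#'
#' Coalescent topology (via [ape::rcoal()]) with independent exponential
#' branch lengths, so every edge is strictly positive. Deterministic given
#' `seed`.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @param labels optional leaf labels (length `n_taxa`, unique); default
#'   `taxon_001`, `taxon_002`, ...
#' @return a rooted binary [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, labels = NULL) {
  if (!is.numeric(n_taxa) || n_taxa < 2)
    stop("n_taxa must be >= 2")
  n_taxa <- as.integer(n_taxa)
  if (is.null(labels))
    labels <- sprintf("taxon_%03d", seq_len(n_taxa))
  if (length(labels) != n_taxa || anyDuplicated(labels))
    stop("labels must be ", n_taxa, " unique strings")
  set.seed(seed)
  tree <- ape::rcoal(n_taxa, tip.label = labels)
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 5) + 1e-3
  tree
}

#' Simulation configuration for a study-like cohort
#'
#' Defaults encode the study conditions the package is designed around:
#' three groups of 20 (FRI), 18 (FH) and 12 (HC) samples; 120 genera; four
#' case-enriched genera planted at +3 log2 fold change in FRI and ten
#' control-enriched genera at -3; a 15% richness deficit in the FRI-like
#' group; serum inflammatory markers rank-linked to planted genera.
#'
#' @param n_per_group named integer vector over groups FRI/FH/HC.
#' @param n_taxa number of genera simulated.
#' @param library_size_mean,library_size_dispersion negative-binomial mean
#'   and size for per-sample sequencing depth.
#' @param base_concentration scale of the per-taxon Dirichlet concentration;
#'   the total concentration is `base_concentration * n_taxa` (smaller =
#'   more overdispersion between replicate samples).
#' @param planted_effects data.frame with columns `taxon`, `group`,
#'   `log2fc`: the group's Dirichlet concentration for that taxon is
#'   multiplied by `2^log2fc`.
#' @param richness_deficit_frac fraction of non-planted taxa zeroed out in
#'   the FRI group, in [0, 1).
#' @param marker_links data.frame with columns `marker`, `taxon`, `rho`:
#'   target Spearman correlation (sign and magnitude, |rho| < 1) between
#'   the marker and the taxon's relative abundance.
#' @param seed integer seed; fully determines all outputs.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_per_group = c(FRI = 20L, FH = 18L, HC = 12L),
                              n_taxa = 120L,
                              library_size_mean = 2e4,
                              library_size_dispersion = 10,
                              base_concentration = 0.5,
                              planted_effects = default_planted_effects(),
                              richness_deficit_frac = 0.15,
                              marker_links = default_marker_links(),
                              seed = 1L) {
  stopifnot(all(names(n_per_group) %in% GROUP_LEVELS),
            n_taxa >= 2, library_size_mean > 0,
            library_size_dispersion > 0, base_concentration > 0,
            richness_deficit_frac >= 0, richness_deficit_frac < 1)
  if (nrow(planted_effects)) {
    stopifnot(all(c("taxon", "group", "log2fc") %in% names(planted_effects)))
    if (any(!is.finite(planted_effects$log2fc)))
      stop("planted log2 fold changes must be finite")
    bad <- setdiff(planted_effects$group, GROUP_LEVELS)
    if (length(bad)) stop("unknown group(s) in planted_effects: ",
                          paste(bad, collapse = ", "))
  }
  if (nrow(marker_links)) {
    stopifnot(all(c("marker", "taxon", "rho") %in% names(marker_links)))
    if (any(abs(marker_links$rho) >= 1))
      stop("marker link |rho| must be < 1")
  }
  structure(list(n_per_group = n_per_group, n_taxa = as.integer(n_taxa),
                 library_size_mean = library_size_mean,
                 library_size_dispersion = library_size_dispersion,
                 base_concentration = base_concentration,
                 planted_effects = planted_effects,
                 richness_deficit_frac = richness_deficit_frac,
                 marker_links = marker_links,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Named genera planted by default
#'
#' Four FRI-enriched genera (+3 log2FC) and ten control-enriched genera
#' (-3 log2FC in FRI), mirroring the enrichment structure of a
#' fracture-related-infection gut cohort.
#' @param enriched_log2fc,depleted_log2fc log2 fold changes applied to the
#'   FRI group's Dirichlet concentrations.
#' @export
default_planted_effects <- function(enriched_log2fc = 3, depleted_log2fc = -3) {
  enr <- c("Escherichia", "Streptococcus", "Veillonella", "Actinomyces")
  dep <- c("Roseburia", "Parabacteroides", "Desulfovibrio", "Blautia",
           "Coprococcus", "Prevotella", "SMB53", "Phascolarctobacterium",
           "Dialister", "Anaerostipes")
  data.frame(taxon = c(enr, dep),
             group = "FRI",
             log2fc = c(rep(enriched_log2fc, length(enr)),
                        rep(depleted_log2fc, length(dep))),
             stringsAsFactors = FALSE)
}

#' Default serum-marker / taxon rank-correlation targets
#' @export
default_marker_links <- function() {
  data.frame(
    marker = c("NEU", "ESR", "CRP", "SAA", "WBC", "IL6"),
    taxon  = c("Escherichia", "Escherichia", "Escherichia", "Streptococcus",
               "Roseburia", "Blautia"),
    rho    = c(0.45, 0.55, 0.60, 0.50, -0.35, -0.45),
    stringsAsFactors = FALSE)
}

#' Default taxon labels for a simulated cohort
#'
#' The planted genera keep their genus names; the remainder are anonymous
#' `genus_###` fillers.
#' @param n_taxa total number of genera.
#' @export
default_taxon_labels <- function(n_taxa = 120L) {
  named <- default_planted_effects()$taxon
  if (n_taxa < length(named))
    stop("n_taxa smaller than the number of named planted genera")
  c(named, sprintf("genus_%03d", seq_len(n_taxa - length(named))))
}

# log-scale location used to synthesise each marker's plausible range
MARKER_LOG_MEAN <- c(NEU = log(65), ESR = log(30), CRP = log(20),
                     SAA = log(30), WBC = log(8), IL6 = log(10))

#' Simulate counts, metadata and ground truth for a cohort
#'
#' Per sample: a Dirichlet-multinomial draw whose group-specific
#' concentration vector is the base concentration times `2^log2fc` for
#' planted (taxon, group) pairs, with a `richness_deficit_frac` share of
#' non-planted taxa set to zero concentration in the FRI group; library
#' sizes are negative-binomial. Metadata carries age (uniform 18-70), sex
#' (Bernoulli at the cohort's 37:13 male:female ratio), a sinus/pus flag for
#' FRI samples, and serum markers produced as rank-preserving noisy
#' transforms (Gaussian copula) of linked planted-taxon relative abundances.
#'
#' @param config a [simulation_config()].
#' @param tree phylogeny whose tips contain all simulated taxa; default
#'   simulated from the config.
#' @return list with `counts` (taxa x samples integer matrix), `metadata`
#'   (data.frame), `taxonomy` (named lineage vector), `tree`, and `truth`
#'   (list: `true_enriched`, `true_depleted`, `marker_signs`).
#' @export
simulate_counts <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  labels <- default_taxon_labels(config$n_taxa)
  if (is.null(tree))
    tree <- simulate_tree(config$n_taxa, seed = config$seed + 1000L,
                          labels = labels)
  else
    labels <- intersect(tree$tip.label, labels)
  pe <- config$planted_effects
  if (nrow(pe)) {
    miss <- setdiff(pe$taxon, tree$tip.label)
    if (length(miss))
      stop("planted taxa absent from tree: ", paste(miss, collapse = ", "))
    miss2 <- setdiff(pe$taxon, labels)
    if (length(miss2))
      stop("planted taxa absent from table: ", paste(miss2, collapse = ", "))
  }
  set.seed(config$seed)
  n_taxa <- length(labels)
  planted <- unique(pe$taxon)
  w <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = 1.5)
  names(w) <- labels
  # planted genera drawn from the abundant range so effects act on real mass
  if (length(planted))
    w[planted] <- stats::rlnorm(length(planted), meanlog = 1.2, sdlog = 0.6)
  alpha0 <- config$base_concentration * n_taxa * w / sum(w)

  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  sample_ids <- unlist(lapply(names(config$n_per_group), function(g)
    sprintf("%s_%02d", g, seq_len(config$n_per_group[[g]]))))
  n <- length(groups)

  # group-specific concentration vectors
  alpha_by_group <- lapply(names(config$n_per_group), function(g) {
    a <- alpha0
    rows <- pe[pe$group == g, , drop = FALSE]
    if (nrow(rows)) a[rows$taxon] <- a[rows$taxon] * 2^rows$log2fc
    a
  })
  names(alpha_by_group) <- names(config$n_per_group)
  dropped <- character(0)
  if ("FRI" %in% names(alpha_by_group) && config$richness_deficit_frac > 0) {
    cand <- setdiff(labels, planted)
    k <- floor(config$richness_deficit_frac * length(cand))
    dropped <- sample(cand, k)
    alpha_by_group[["FRI"]][dropped] <- 0
  }

  lib <- as.integer(pmax(stats::rnbinom(n, mu = config$library_size_mean,
                                        size = config$library_size_dispersion),
                         1000L))
  counts <- matrix(0L, nrow = n_taxa, ncol = n,
                   dimnames = list(labels, sample_ids))
  for (j in seq_len(n)) {
    a <- alpha_by_group[[groups[j]]]
    g <- numeric(n_taxa)
    pos <- a > 0
    g[pos] <- stats::rgamma(sum(pos), shape = a[pos], rate = 1)
    p <- g / sum(g)
    counts[, j] <- stats::rmultinom(1, size = lib[j], prob = p)[, 1]
  }

  age <- as.integer(round(stats::runif(n, 18, 70)))
  sex <- ifelse(stats::runif(n) < 37 / 50, "M", "F")
  sinus_pus <- ifelse(groups == "FRI",
                      ifelse(stats::runif(n) < 16 / 20, "yes", "no"),
                      "n/a")
  metadata <- data.frame(sample_id = sample_ids, group = groups,
                         age = age, sex = sex, sinus_pus = sinus_pus,
                         library_size = lib, stringsAsFactors = FALSE)

  rel <- sweep(counts, 2, colSums(counts), "/")
  ml <- config$marker_links
  for (m in unique(ml$marker)) {
    rows <- ml[ml$marker == m, , drop = FALSE]
    z <- rowMeans(vapply(seq_len(nrow(rows)), function(i) {
      r <- rel[rows$taxon[i], ]
      zt <- stats::qnorm((rank(r, ties.method = "average") - 0.5) / n)
      rho_z <- 2 * sin(pi * rows$rho[i] / 6)  # Spearman -> Pearson on latent
      rho_z * zt
    }, numeric(n)))
    load2 <- mean((2 * sin(pi * rows$rho / 6))^2)
    z <- z + sqrt(max(0, 1 - load2)) * stats::rnorm(n)
    mu <- if (m %in% names(MARKER_LOG_MEAN)) MARKER_LOG_MEAN[[m]] else log(10)
    metadata[[m]] <- round(exp(mu + 0.6 * z), 2)
  }

  enr <- pe$taxon[pe$group == "FRI" & pe$log2fc > 0]
  # taxa zeroed out in FRI are depleted there by construction
  dep <- c(pe$taxon[pe$group == "FRI" & pe$log2fc < 0], dropped)
  marker_signs <- if (nrow(ml))
    stats::setNames(sign(ml$rho), paste(ml$marker, ml$taxon, sep = ":"))
  else stats::setNames(numeric(0), character(0))
  truth <- list(true_enriched = unique(enr), true_depleted = unique(dep),
                marker_signs = marker_signs)
  stopifnot(length(intersect(truth$true_enriched, truth$true_depleted)) == 0)

  list(counts = counts, metadata = metadata,
       taxonomy = default_lineages(labels), tree = tree, truth = truth)
}

# Curated lineages for the named gut genera; fillers get a rotating phylum.
default_lineages <- function(taxon_ids) {
  known <- list(
    Escherichia = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                    "Enterobacteriales", "Enterobacteriaceae"),
    Streptococcus = c("Bacteria", "Firmicutes", "Bacilli", "Lactobacillales",
                      "Streptococcaceae"),
    Veillonella = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                    "Veillonellaceae"),
    Dialister = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                  "Veillonellaceae"),
    Phascolarctobacterium = c("Bacteria", "Firmicutes", "Clostridia",
                              "Clostridiales", "Veillonellaceae"),
    Actinomyces = c("Bacteria", "Actinobacteria", "Actinobacteria",
                    "Actinomycetales", "Actinomycetaceae"),
    Roseburia = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                  "Lachnospiraceae"),
    Blautia = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                "Lachnospiraceae"),
    Coprococcus = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                    "Lachnospiraceae"),
    Anaerostipes = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                     "Lachnospiraceae"),
    SMB53 = c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
              "Clostridiaceae"),
    Parabacteroides = c("Bacteria", "Bacteroidetes", "Bacteroidia",
                        "Bacteroidales", "Porphyromonadaceae"),
    Prevotella = c("Bacteria", "Bacteroidetes", "Bacteroidia", "Bacteroidales",
                   "Prevotellaceae"),
    Desulfovibrio = c("Bacteria", "Proteobacteria", "Deltaproteobacteria",
                      "Desulfovibrionales", "Desulfovibrionaceae"))
  filler_phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                    "Actinobacteria")
  out <- character(length(taxon_ids))
  fi <- 0L
  for (i in seq_along(taxon_ids)) {
    id <- taxon_ids[i]
    if (id %in% names(known)) {
      up <- known[[id]]
    } else {
      fi <- fi + 1L
      ph <- filler_phyla[(fi - 1L) %% length(filler_phyla) + 1L]
      up <- c("Bacteria", ph, paste0(ph, "_class"), paste0(ph, "_order"),
              paste0(ph, "_family"))
    }
    out[i] <- paste0("k__", up[1], ";p__", up[2], ";c__", up[3],
                     ";o__", up[4], ";f__", up[5], ";g__", id)
  }
  stats::setNames(out, taxon_ids)
}

#' Write a simulated dataset to disk
#'
#' Writes counts, metadata and taxonomy TSVs plus a Newick tree; the files
#' round-trip exactly through [read_table()], [read_metadata()],
#' [read_taxonomy()] and [read_tree()].
#'
#' @param counts,metadata,tree,taxonomy dataset components with consistent
#'   identifiers.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the four file paths (the manifest).
#' @export
write_dataset <- function(counts, metadata, tree, taxonomy, out_dir) {
  check_ids(counts, metadata = metadata, taxonomy = taxonomy, tree = tree)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"))
  write_table(counts, paths[["counts"]])
  write_metadata(metadata, paths[["metadata"]])
  ape::write.tree(tree, paths[["tree"]])
  write_taxonomy(taxonomy, paths[["taxonomy"]])
  paths
}
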
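# Alpha and beta diversity on a fixed rooted phylogeny.
#
# UniFrac and Faith's PD are computed from an edge-by-tip incidence matrix
# built once per tree: entry (e, j) is TRUE when tip j descends from the
# child node of edge e, so an edge's "mass" for a sample is the summed
# relative abundance of its descendant tips.

#' Shannon diversity of one sample
#'
#' H = -sum p_i log_base(p_i) over taxa with nonzero counts. Base 2 by
#' default (bits), the common amplicon-pipeline convention.
#'
#' @param x non-negative count (or abundance) vector, not all zero.
#' @param base logarithm base.
#' @return Shannon entropy.
#' @export
shannon <- function(x, base = 2) {
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative")
  s <- sum(x)
  if (s == 0) stop("all-zero sample")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

# edge-by-tip incidence: M[e, j] TRUE iff tip j descends from edge e's child
edge_tip_incidence <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nrow = nnode, ncol = ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    chi <- tree$edge[e, 2]
    below[par, ] <- below[par, ] | below[chi, ]
  }
  M <- below[tree$edge[, 2], , drop = FALSE]
  colnames(M) <- tree$tip.label
  list(incidence = M, lengths = tree$edge.length)
}

check_taxa_in_tree <- function(taxa, tree) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss))
    stop("taxa absent from tree: ", paste(miss, collapse = ", "))
}

#' Faith's phylogenetic diversity (whole tree)
#'
#' Total branch length of the union of root-to-leaf paths of the taxa
#' present in the sample; edges on the path to the root are included
#' (the "whole tree" reading of the index). An empty sample scores 0.
#'
#' @param x named count vector (names are tree tips).
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(x, tree) {
  if (is.null(names(x))) stop("sample counts must be named by taxon")
  check_taxa_in_tree(names(x), tree)
  present <- names(x)[x > 0]
  if (!length(present)) return(0)
  et <- edge_tip_incidence(tree)
  on_path <- rowSums(et$incidence[, present, drop = FALSE]) > 0
  sum(et$lengths[on_path])
}

#' UniFrac distance between two samples
#'
#' Unweighted: branch length unique to one sample's descendant tip set over
#' the branch length of the union. Weighted: sum over edges of
#' `length * |p_A - p_B|` with p the descendant relative-abundance mass;
#' when `normalized`, divided by `sum length * (p_A + p_B)` so the result is
#' bounded in [0, 1].
#'
#' @param a,b named non-negative vectors (same taxon set of tree tips),
#'   each with positive total.
#' @param tree rooted phylogeny covering the taxa.
#' @param weighted use abundance-weighted UniFrac.
#' @param normalized normalize weighted UniFrac (ignored when unweighted).
#' @return distance (in [0, 1] for unweighted and normalized-weighted).
#' @export
unifrac <- function(a, b, tree, weighted = FALSE, normalized = TRUE) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("sample counts must be named by taxon")
  check_taxa_in_tree(union(names(a), names(b)), tree)
  if (sum(a) == 0 || sum(b) == 0) stop("empty sample")
  et <- edge_tip_incidence(tree)
  unifrac_from_incidence(a, b, et, weighted = weighted,
                         normalized = normalized)
}

unifrac_from_incidence <- function(a, b, et, weighted = FALSE,
                                   normalized = TRUE) {
  M <- et$incidence
  len <- et$lengths
  pa <- as.numeric(M[, names(a), drop = FALSE] %*% (a / sum(a)))
  pb <- as.numeric(M[, names(b), drop = FALSE] %*% (b / sum(b)))
  if (weighted) {
    num <- sum(len * abs(pa - pb))
    if (!normalized) return(num)
    den <- sum(len * (pa + pb))
    return(if (den == 0) 0 else num / den)
  }
  ina <- pa > 0
  inb <- pb > 0
  uni <- sum(len[xor(ina, inb)])
  tot <- sum(len[ina | inb])
  if (tot == 0) 0 else uni / tot
}

#' All-pairs UniFrac distance matrix
#'
#' @param rel relative-abundance (or count) matrix, taxa x samples.
#' @param tree rooted phylogeny covering the table taxa.
#' @param weighted,normalized as in [unifrac()].
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
pairwise_distances <- function(rel, tree, weighted = FALSE,
                               normalized = TRUE) {
  check_taxa_in_tree(rownames(rel), tree)
  if (any(colSums(rel) == 0)) stop("empty sample")
  et <- edge_tip_incidence(tree)
  n <- ncol(rel)
  D <- matrix(0, n, n, dimnames = list(colnames(rel), colnames(rel)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- unifrac_from_incidence(rel[, i], rel[, j], et,
                                  weighted = weighted,
                                  normalized = normalized)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Principal coordinates analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition (via
#' [stats::cmdscale()]). Negative eigenvalues are reported but excluded
#' from the proportion explained; no correction is applied by default,
#' `correction = "cailliez"` requests the additive constant.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @param correction "none" or "cailliez".
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (non-increasing, full spectrum), `prop_explained`
#'   (over positive eigenvalues).
#' @export
pcoa <- function(dm, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- as.matrix(dm)
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  n <- nrow(dm)
  # negative eigenvalues are expected for non-Euclidean distances;
  # cmdscale's note about them is not actionable here
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE,
                    add = correction == "cailliez"))
  eig <- fit$eig
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  prop <- numeric(length(eig))
  if (any(pos)) prop[pos] <- eig[pos] / sum(eig[pos])
  pts <- fit$points
  rownames(pts) <- rownames(dm)
  structure(list(coordinates = pts, eigenvalues = eig,
                 prop_explained = prop),
            class = "pcoa_result")
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: pseudo-F from
#' the distance-based partition of sums of squares
#' (SS_total = sum of squared distances / N, SS_within summed per group),
#' with a label-permutation p-value using the +1 convention in numerator
#' and denominator.
#'
#' @param dm symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `permanova_result`: `pseudo_F`, `p_value`, `R2`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(dm, groups, n_permutations = 999, seed = 1L) {
  dm <- as.matrix(dm)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm))
    stop("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  D2 <- dm^2
  N <- nrow(dm)
  a <- length(tab)
  sst <- sum(D2[upper.tri(D2)]) / N
  ss_within <- function(g) {
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      sub <- D2[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ssw
  }
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((sst - ssw) / (a - 1)) / (ssw / (N - a))
  }
  f_obs <- f_stat(groups)
  set.seed(seed)
  n_ge <- 0L
  for (i in seq_len(n_permutations)) {
    if (f_stat(sample(groups)) >= f_obs) n_ge <- n_ge + 1L
  }
  ssw_obs <- ss_within(groups)
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + n_ge) / (1 + n_permutations),
                 R2 = (sst - ssw_obs) / sst,
                 n_permutations = n_permutations, seed = seed),
            class = "permanova_result")
}
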
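# Shared fixtures and independent oracles.

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

named_counts <- function(..., taxa) {
  x <- c(...)
  names(x) <- taxa
  x
}

# small deterministic table: 4 taxa x 3 samples
tiny_table <- function() {
  m <- matrix(c(2, 2, 2, 2,
                10, 30, 60, 0,
                1, 0, 0, 4), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2", "s3")))
  storage.mode(m) <- "integer"
  m
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# independent UniFrac oracle: walks every tip-to-root path explicitly
oracle_unifrac <- function(a, b, tree, weighted = FALSE, normalized = TRUE) {
  edges <- tree$edge
  ntip <- length(tree$tip.label)
  root <- setdiff(edges[, 1], edges[, 2])
  path_edges <- function(tip) {
    e <- integer(0)
    node <- tip
    while (node != root) {
      i <- which(edges[, 2] == node)
      e <- c(e, i)
      node <- edges[i, 1]
    }
    e
  }
  pe <- lapply(seq_len(ntip), path_edges)
  names(pe) <- tree$tip.label
  len <- tree$edge.length
  if (!weighted) {
    ea <- unique(unlist(pe[names(a)[a > 0]]))
    eb <- unique(unlist(pe[names(b)[b > 0]]))
    uni <- sum(len[setdiff(union(ea, eb), intersect(ea, eb))])
    tot <- sum(len[union(ea, eb)])
    return(uni / tot)
  }
  pa <- a / sum(a)
  pb <- b / sum(b)
  wa <- wb <- numeric(nrow(edges))
  for (tx in names(a)) wa[pe[[tx]]] <- wa[pe[[tx]]] + pa[[tx]]
  for (tx in names(b)) wb[pe[[tx]]] <- wb[pe[[tx]]] + pb[[tx]]
  num <- sum(len * abs(wa - wb))
  if (!normalized) return(num)
  num / sum(len * (wa + wb))
}

# independent pseudo-F oracle (Anderson partition, coded afresh)
oracle_pseudo_f <- function(dm, groups) {
  n <- nrow(dm)
  a <- length(unique(groups))
  sst <- sum(dm[lower.tri(dm)]^2) / n
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    ssw <- ssw + sum(dm[i, i][lower.tri(dm[i, i])]^2) / length(i)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

null_sim_config <- function(seed) {
  simulation_config(
    planted_effects = data.frame(taxon = character(), group = character(),
                                 log2fc = numeric()),
    richness_deficit_frac = 0,
    marker_links = data.frame(marker = character(), taxon = character(),
                              rho = numeric()),
    seed = seed)
}
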
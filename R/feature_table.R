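GROUP_LEVELS <- c("FRI", "FH", "HC")
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Validate a taxa-by-samples count matrix
#'
#' A feature table is a plain numeric matrix with taxa as rows and samples as
#' columns, unique dimnames, non-negative integer counts, and no all-zero
#' sample column.
#'
#' @param counts numeric matrix, taxa x samples, with rownames and colnames.
#' @return the matrix, invisibly, after validation.
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  dup_t <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_t))
    stop("duplicate taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  zero <- colnames(counts)[colSums(counts) == 0]
  if (length(zero))
    stop("all-zero sample column(s): ", paste(zero, collapse = ", "))
  invisible(counts)
}

#' Read / write a count table as TSV
#'
#' Tab-separated, UTF-8, header row; first column `taxon_id`, remaining
#' columns one per sample.
#'
#' @param path file path.
#' @return `read_table()`: a validated taxa x samples integer matrix.
#' @export
read_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon_id")
    stop("counts TSV must have first column 'taxon_id': ", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate taxon row(s) in ", path, ": ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_feature_table(m)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_table
#' @param counts validated count matrix.
#' @export
write_table <- function(counts, path) {
  validate_feature_table(counts)
  df <- data.frame(taxon_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Columns: `sample_id`, `group` (FRI/FH/HC), `age`, `sex` (M/F),
#' `sinus_pus` (yes/no/n/a); any further columns (serum markers) are
#' preserved untouched.
#'
#' @param path file path.
#' @return a data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
  df
}

#' @rdname read_metadata
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a taxonomy map
#'
#' TSV with columns `taxon_id` and `lineage`; lineages are GreenGenes-style
#' semicolon-separated strings with rank prefixes
#' `k__;p__;c__;o__;f__;g__;s__`, truncation allowed only as a suffix.
#'
#' @param path file path.
#' @return named character vector: lineage string per taxon id.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(df)))
    stop("taxonomy TSV needs columns taxon_id, lineage: ", path)
  dup <- unique(df$taxon_id[duplicated(df$taxon_id)])
  if (length(dup))
    stop("duplicate taxon id(s) in taxonomy: ", paste(dup, collapse = ", "))
  lin <- df$lineage
  names(lin) <- df$taxon_id
  validate_taxonomy(lin)
  lin
}

#' @rdname read_taxonomy
#' @param taxonomy named lineage vector.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(
    data.frame(taxon_id = names(taxonomy), lineage = unname(taxonomy),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_taxonomy <- function(taxonomy) {
  for (id in names(taxonomy)) {
    parts <- strsplit(taxonomy[[id]], ";", fixed = TRUE)[[1]]
    if (length(parts) > 7)
      stop("lineage for ", id, " has more than 7 ranks")
    for (i in seq_along(parts)) {
      if (!startsWith(trimws(parts[i]), TAX_PREFIXES[i]))
        stop("lineage for ", id, " malformed at rank ", TAX_RANKS[i],
             ": ", parts[i])
    }
  }
  invisible(taxonomy)
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' Thin wrapper over [ape::read.tree()] that additionally requires branch
#' lengths, non-negativity, and unique tip labels.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stop("malformed Newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in ", path)
  if (is.null(tree$edge.length))
    stop("tree in ", path, " has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree in ", path, " has negative branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  tree
}

#' Cross-validate identifiers between table, metadata, taxonomy and tree
#'
#' Fails with an explicit listing of every mismatch rather than silently
#' subsetting.
#'
#' @param counts feature table matrix.
#' @param metadata optional metadata data.frame.
#' @param taxonomy optional named lineage vector.
#' @param tree optional phylo; table taxa must be a subset of its tips.
#' @return TRUE, invisibly.
#' @export
check_ids <- function(counts, metadata = NULL, taxonomy = NULL, tree = NULL) {
  msgs <- character()
  if (!is.null(metadata)) {
    miss <- setdiff(colnames(counts), metadata$sample_id)
    if (length(miss))
      msgs <- c(msgs, paste0("samples absent from metadata: ",
                             paste(miss, collapse = ", ")))
  }
  if (!is.null(taxonomy)) {
    miss <- setdiff(rownames(counts), names(taxonomy))
    if (length(miss))
      msgs <- c(msgs, paste0("taxa absent from taxonomy: ",
                             paste(miss, collapse = ", ")))
  }
  if (!is.null(tree)) {
    miss <- setdiff(rownames(counts), tree$tip.label)
    if (length(miss))
      msgs <- c(msgs, paste0("taxa absent from tree: ",
                             paste(miss, collapse = ", ")))
  }
  if (length(msgs)) stop(paste(msgs, collapse = "; "))
  invisible(TRUE)
}

#' Collapse a feature table to a taxonomic rank
#'
#' Rows sharing the lineage prefix through `rank` are summed. Taxa whose
#' lineage is missing or truncated above `rank` are pooled into
#' `unclassified_<deepest known name>`. Column sums are preserved exactly.
#'
#' @param counts taxa x samples matrix.
#' @param taxonomy named lineage vector covering all table taxa.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return collapsed matrix whose rownames are rank labels.
#' @export
collapse_to_rank <- function(counts, taxonomy, rank = "genus") {
  if (!rank %in% TAX_RANKS)
    stop("unknown rank '", rank, "'; expected one of ",
         paste(TAX_RANKS, collapse = ", "))
  check_ids(counts, taxonomy = taxonomy)
  k <- match(rank, TAX_RANKS)
  key <- vapply(rownames(counts), function(id) {
    parts <- trimws(strsplit(taxonomy[[id]], ";", fixed = TRUE)[[1]])
    vals <- sub("^[kpcofgs]__", "", parts)
    if (length(vals) >= k && nzchar(vals[k])) {
      vals[k]
    } else {
      known <- vals[nzchar(vals)]
      parent <- if (length(known)) known[length(known)] else "root"
      paste0("unclassified_", parent)
    }
  }, character(1))
  out <- rowsum(counts, group = key)
  out <- out[order(rownames(out)), , drop = FALSE]
  stopifnot(all(colSums(out) == colSums(counts)))
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param counts taxa x samples matrix with positive column sums.
#' @return matrix of the same shape; each column sums to 1.
#' @export
relative_abundance <- function(counts) {
  tot <- colSums(counts)
  zero <- colnames(counts)[tot == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  sweep(counts, 2, tot, "/")
}

#' Abundance/prevalence filter for differential-genus selection
#'
#' Retains a taxon iff its relative abundance reaches at least `min_rel`
#' (default 0.01%) in at least a `min_prev` fraction of samples (default
#' 20%), both boundaries inclusive — i.e. the complement of removing taxa
#' below 0.01% in 20% or more of samples. Rows are subset without
#' renormalisation.
#'
#' @param rel relative-abundance matrix (taxa x samples).
#' @param min_rel minimum relative abundance, in (0, 1).
#' @param min_prev minimum prevalence fraction, in (0, 1].
#' @return row-subset of `rel`; warns (does not error) if empty.
#' @export
abundance_prevalence_filter <- function(rel, min_rel = 1e-4, min_prev = 0.2) {
  stopifnot(min_rel > 0, min_rel < 1, min_prev > 0, min_prev <= 1)
  prev <- rowMeans(rel >= min_rel)
  keep <- prev >= min_prev
  if (!any(keep))
    warning("abundance/prevalence filter removed every taxon")
  rel[keep, , drop = FALSE]
}

#' Even-depth subsampling (optional rarefaction)
#'
#' Subsamples every column without replacement to a common depth. Off by
#' default throughout the package: diversity is computed on full columns
#' unless a depth is requested explicitly.
#'
#' @param counts taxa x samples matrix.
#' @param depth target depth; default the minimum column sum.
#' @param seed integer seed.
#' @return subsampled integer matrix (samples shallower than `depth` are
#'   dropped with a warning).
#' @export
rarefy_even_depth <- function(counts, depth = min(colSums(counts)), seed = 1L) {
  set.seed(seed)
  keep <- colSums(counts) >= depth
  if (!all(keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth)
  counts <- counts[, keep, drop = FALSE]
  out <- apply(counts, 2, function(x) {
    pool <- rep.int(seq_along(x), x)
    tab <- tabulate(sample(pool, depth), nbins = length(x))
    tab
  })
  rownames(out) <- rownames(counts)
  out
}
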
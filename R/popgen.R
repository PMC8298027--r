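#' Pairwise allele-sharing divergence between individuals
#'
#' For individuals i and j, `d(i, j)` is the mean over markers non-missing in
#' both of `|x_i - x_j| / 2`: 0 for identical homozygotes, 0.5 for a
#' homozygote-heterozygote pair, 1 for opposite homozygotes. Requires hard
#' (un-imputed) calls. Invariant to marker and sample order.
#'
#' @param gm a [geno_matrix()] with hard calls.
#' @param scale `"per_site"` (mean over shared markers, the default) or
#'   `"count"` (sum of per-site differences over shared markers).
#' @return a symmetric `dist_matrix` (zero diagonal) with sample ids as
#'   dimnames.
#' @export
pairwise_divergence <- function(gm, scale = c("per_site", "count")) {
  stopifnot(inherits(gm, "geno_matrix"))
  scale <- match.arg(scale)
  if (gm$imputed)
    stop("pairwise divergence requires hard (un-imputed) calls")
  calls <- gm$calls
  n <- nrow(calls)
  ids <- rownames(calls)
  agg <- if (scale == "per_site") mean else sum
  if (!anyNA(calls)) {
    D <- as.matrix(stats::dist(calls, method = "manhattan")) / 2
    if (scale == "per_site") D <- D / ncol(calls)
    dimnames(D) <- list(ids, ids)
  } else {
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      xi <- calls[i, ]
      for (j in seq(i + 1, n)) {
        shared <- !is.na(xi) & !is.na(calls[j, ])
        if (!any(shared))
          stop("samples ", ids[i], " and ", ids[j],
               " share no non-missing markers")
        D[i, j] <- D[j, i] <- agg(abs(xi[shared] - calls[j, shared])) / 2
      }
    }
  }
  structure(D, class = c("dist_matrix", class(D)))
}

#' Nucleotide diversity (average pairwise divergence)
#'
#' The mean of [pairwise_divergence()] over all unordered pairs in the
#' subset: the average pairwise difference per assayed SNP site. With
#' `tag_length` set, diversity is instead expressed per tag base (SNP sites
#' diluted over the sequenced tag length).
#'
#' @param gm a [geno_matrix()] with hard calls.
#' @param subset optional character vector of sample ids (default: all).
#' @param tag_length optional tag length in bases for a per-tag-base scale.
#' @return scalar diversity.
#' @export
nucleotide_diversity <- function(gm, subset = NULL, tag_length = NULL) {
  ids <- if (is.null(subset)) sample_ids(gm) else as.character(subset)
  if (length(ids) < 2) stop("at least 2 individuals required")
  sub <- geno_matrix(gm$calls[ids, , drop = FALSE])
  D <- pairwise_divergence(sub)
  pi <- mean(D[lower.tri(D)])
  if (!is.null(tag_length)) pi <- pi / tag_length
  pi
}

#' Neighbor-joining tree from a divergence matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}), returning an
#' unrooted tree with the matrix row names as tips. Negative branch lengths
#' (which NJ can produce on non-additive input) are clamped to zero with the
#' deficit transferred to the sister branch so path lengths are preserved.
#'
#' @param dm symmetric distance matrix (>= 3 taxa) with finite entries.
#' @return an \pkg{ape} `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining requires at least 3 taxa")
  if (any(!is.finite(dm))) stop("non-finite distances")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    sisters <- which(tree$edge[, 1] == parent & seq_along(tree$edge[, 2]) != e)
    if (length(sisters) > 0)
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] +
        tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  tree
}

#' Fixation index from diversity partitioning
#'
#' `F_ST = (pi_total - pi_S) / pi_total` where `pi_S` is the size-weighted
#' mean within-cluster diversity; clamped to \[0, 1\].
#'
#' @param pi_total total-population nucleotide diversity.
#' @param pi_within numeric vector of within-cluster diversities.
#' @param sizes cluster sizes (weights); defaults to equal.
#' @return scalar F_ST, or `NA` with a warning when `pi_total` is zero.
#' @export
fst_from_diversity <- function(pi_total, pi_within,
                               sizes = rep(1, length(pi_within))) {
  if (pi_total <= 0) {
    warning("total diversity is zero: F_ST undefined")
    return(NA_real_)
  }
  pi_s <- stats::weighted.mean(pi_within, sizes)
  min(max((pi_total - pi_s) / pi_total, 0), 1)
}

#' Fixation index of a clustered sample
#'
#' Convenience wrapper computing total and within-cluster nucleotide
#' diversities from genotypes and applying [fst_from_diversity()].
#'
#' @param gm a [geno_matrix()] with hard calls.
#' @param clusters named vector (names = sample ids) or factor aligned with
#'   the samples, giving the cluster of each individual.
#' @return scalar F_ST.
#' @export
fst <- function(gm, clusters) {
  ids <- sample_ids(gm)
  cl <- if (!is.null(names(clusters))) clusters[ids] else clusters
  stopifnot(length(cl) == length(ids))
  pi_t <- nucleotide_diversity(gm)
  groups <- split(ids, cl)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  pi_w <- vapply(groups, function(g) nucleotide_diversity(gm, g), numeric(1))
  fst_from_diversity(pi_t, pi_w, vapply(groups, length, 1L))
}

#' Select unrelated individuals (one per full-sib family)
#'
#' Samples at most one individual per full-sib family (same sire and dam)
#' within a generation, the sibling-exclusion used for the population
#' structure analysis.
#'
#' @param ped pedigree `data.frame`.
#' @param n number of individuals to select.
#' @param generation generation to sample from.
#' @param seed integer seed.
#' @return character vector of `n` sample ids from `n` distinct families.
#' @export
select_unrelated <- function(ped, n = 50L, generation = 1L, seed = 1L) {
  sub <- ped[ped$generation == generation, ]
  fam <- paste(sub$sire, sub$dam, sep = "_")
  fams <- unique(fam)
  if (length(fams) < n)
    stop("only ", length(fams), " families available in generation ",
         generation, "; at most ", length(fams), " unrelated individuals")
  set.seed(seed)
  chosen <- sample(fams, n)
  vapply(chosen, function(f) {
    members <- sub$id[fam == f]
    as.character(if (length(members) == 1L) members else sample(members, 1L))
  }, character(1), USE.NAMES = FALSE)
}

#' Whole-weight category labels
#'
#' Bins whole weight (g) into the study's categories: I: 30-40, II: 40-50,
#' III: 50-60, IV: 60-70, V: >70, left-closed (a 40 g oyster is II). Weights
#' below 30 g are labelled `"unbinned"` rather than guessed into I.
#'
#' @param whole_weight numeric vector (g).
#' @return factor with levels `unbinned`, `I`..`V`.
#' @export
weight_categories <- function(whole_weight) {
  lab <- cut(whole_weight, breaks = c(-Inf, 30, 40, 50, 60, 70, Inf),
             labels = c("unbinned", "I", "II", "III", "IV", "V"),
             right = FALSE)
  factor(lab, levels = c("unbinned", "I", "II", "III", "IV", "V"))
}

#' Cut a neighbor-joining tree into clusters
#'
#' Removes the `k - 1` longest internal branches and returns the resulting
#' leaf partition (the automatic analog of coloring the tree's major
#' clusters).
#'
#' @param tree a `phylo` object.
#' @param k number of clusters.
#' @return named integer vector: cluster id per tip label.
#' @export
cut_tree_clusters <- function(tree, k = 4L) {
  n_tip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > n_tip)
  if (length(internal) < k - 1)
    stop("tree has too few internal branches for ", k, " clusters")
  drop_edges <- internal[order(tree$edge.length[internal],
                               decreasing = TRUE)][seq_len(k - 1)]
  keep <- setdiff(seq_len(nrow(tree$edge)), drop_edges)
  n_node <- max(tree$edge)
  comp <- seq_len(n_node)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  for (e in keep) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) comp[a] <- b
  }
  roots <- vapply(seq_len(n_tip), find, integer(1))
  stats::setNames(as.integer(factor(roots)), tree$tip.label)
}
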
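# Genotype distances, UPGMA / neighbor-joining trees with bootstrap
# support, K-medoids population clustering, PCA variance fractions and
# linkage-disequilibrium decay.

#' Pairwise genotype distance between varieties
#'
#' Default metric is the allele-sharing distance on 0/1/2 codes: per locus
#' where both calls are present, identical genotypes score 0, het vs hom
#' scores 0.5 and opposite homozygotes score 1 (i.e. `|g_i - g_j| / 2`);
#' the distance is the mean score over compared loci. `"mismatch"` scores
#' any differing genotype as 1 (strict character mismatch on the IUPAC
#' string). A pair with no co-called locus is an error.
#'
#' @param panel A [genotype_panel()] with at least two varieties.
#' @param metric `"allele_sharing"` (default) or `"mismatch"`.
#' @return A `dist` object with variety labels and attribute `n_loci`
#'   (matrix of per-pair compared-locus counts).
#' @export
genotype_distance <- function(panel, metric = c("allele_sharing", "mismatch")) {
  metric <- match.arg(metric)
  gm <- gt_matrix(panel)
  n <- nrow(gm)
  if (n < 2) stop("need at least two varieties", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(rownames(gm), rownames(gm)))
  nl <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      both <- !is.na(gm[i, ]) & !is.na(gm[j, ])
      if (!any(both)) {
        stop("varieties ", rownames(gm)[i], " and ", rownames(gm)[j],
             " share no called locus", call. = FALSE)
      }
      diffs <- abs(gm[i, both] - gm[j, both])
      val <- if (metric == "allele_sharing") mean(diffs / 2) else mean(diffs > 0)
      d[i, j] <- d[j, i] <- val
      nl[i, j] <- nl[j, i] <- sum(both)
    }
  }
  out <- stats::as.dist(d)
  attr(out, "n_loci") <- nl
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with node height = cluster distance / 2,
#' so the tree is ultrametric. Ties in the minimum distance are broken by
#' lexicographic label order (labels are sorted before clustering). The
#' attributes `sum_branch_length` and `min_pair_path` carry the total
#' branch length and the smallest leaf-pair path length (twice the lowest
#' join height) — the summary statistics usually quoted for such trees.
#'
#' @param dm A `dist` object (e.g. from [genotype_distance()]).
#' @return An [ape::phylo] tree (rooted, ultrametric) with the attributes
#'   described above.
#' @export
upgma_tree <- function(dm) {
  labs <- attr(dm, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(attr(dm, "Size")))
  if (attr(dm, "Size") < 2) stop("need at least two taxa", call. = FALSE)
  m <- as.matrix(dm)
  ord <- order(labs)
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  tree <- ape::as.phylo(hc)
  tree$edge.length <- tree$edge.length  # heights already halved by as.phylo
  attr(tree, "sum_branch_length") <- sum(tree$edge.length)
  attr(tree, "min_pair_path") <- min(m[upper.tri(m)])
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (unrooted). Negative branch lengths are
#' clamped to zero and the deficit shifted to the adjacent sister edge so
#' pairwise path lengths through the parent are preserved.
#'
#' @param dm A `dist` object with at least three taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  if (attr(dm, "Size") < 3) stop("need at least three taxa", call. = FALSE)
  tree <- ape::nj(dm)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sisters) > 0) {
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] +
        tree$edge.length[e]
      tree$edge.length[sisters[1]] <- max(tree$edge.length[sisters[1]], 0)
    }
    tree$edge.length[e] <- 0
  }
  tree
}

# Canonical bipartitions (splits) of a tree: for each internal edge, the
# tip set on the child side, complemented so it never contains tip 1.
tree_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  # descendant tips per node via postorder accumulation
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; c2 <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c2]])
  }
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    tips <- sort(unique(desc[[child]]))
    if (length(tips) < 2 || length(tips) > n_tip - 2) next  # trivial split
    if (tree$tip.label[1] %in% tips) {
      tips <- sort(setdiff(tree$tip.label, tips))
    }
    out[[length(out) + 1]] <- list(edge = e, node = child,
                                   key = paste(tips, collapse = "|"))
  }
  out
}

#' Bootstrap support for a genotype tree
#'
#' Resamples markers with replacement, rebuilds the tree per replicate and
#' reports, for each internal bipartition of the reference tree, the
#' fraction of replicate trees containing that bipartition. Resampling
#' indexes marker positions, so the supports are invariant to marker
#' order for a given seed.
#'
#' @param panel A [genotype_panel()].
#' @param tree_builder `"nj"` or `"upgma"`.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param metric Distance metric passed to [genotype_distance()].
#' @return The reference tree with `node.label` carrying support fractions
#'   for internal nodes (empty for the root/trivial splits).
#' @export
bootstrap_support <- function(panel, tree_builder = c("nj", "upgma"),
                              n_reps = 100, seed = 1,
                              metric = "allele_sharing") {
  tree_builder <- match.arg(tree_builder)
  stopifnot(n_reps >= 1)
  build <- function(p) {
    dm <- genotype_distance(p, metric = metric)
    if (tree_builder == "nj") nj_tree(dm) else upgma_tree(dm)
  }
  ref <- build(panel)
  ref_splits <- tree_splits(ref)
  counts <- stats::setNames(rep(0, length(ref_splits)),
                            vapply(ref_splits, `[[`, "", "key"))
  set.seed(seed)
  m <- nrow(panel)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    rep_panel <- panel[idx, , drop = FALSE]
    # resampling duplicates positions; rebuild distances directly
    rep_panel$pos <- seq_len(m)
    rep_panel$marker <- paste0("b", seq_len(m))
    rep_tree <- build(genotype_panel(rep_panel))
    rep_keys <- vapply(tree_splits(rep_tree), `[[`, "", "key")
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / n_reps
  n_tip <- length(ref$tip.label)
  n_node <- ref$Nnode
  labels <- rep("", n_node)
  for (i in seq_along(ref_splits)) {
    labels[ref_splits[[i]]$node - n_tip] <- format(support[i], digits = 3)
  }
  ref$node.label <- labels
  attr(ref, "support") <- tibble::tibble(
    node = vapply(ref_splits, `[[`, 0L, "node"),
    split = names(counts), support = unname(support)
  )
  ref
}

#' K-medoids clustering of varieties
#'
#' Partitions varieties around medoids (PAM) on the genotype distance
#' matrix — a deterministic surrogate for model-based ancestry estimation.
#' Soft membership proportions are normalised inverse distances to the
#' medoids (a Q-matrix analogue); the hard label is the argmax, i.e.
#' classification by highest membership proportion. Cluster ids are
#' relabelled by decreasing size. With `outgroup = TRUE` the cluster whose
#' allele-frequency centroid is farthest from the global frequencies is
#' given the sentinel label `"99"`.
#'
#' @param panel A [genotype_panel()].
#' @param k Number of clusters (1..n varieties).
#' @param seed RNG seed (kept for interface stability; PAM is
#'   deterministic).
#' @param outgroup Flag the most-divergent cluster as `"99"`.
#' @param metric Distance metric for [genotype_distance()].
#' @return List of class `cluster_model`: `assignments` (tibble: variety,
#'   cluster), `k`, `medoids`, `proportions` (varieties x clusters
#'   matrix), `centroids` (clusters x markers allele-frequency matrix) and
#'   `within_ss` (total within-cluster distance).
#' @export
cluster_varieties <- function(panel, k, seed = 1, outgroup = FALSE,
                              metric = "allele_sharing") {
  ids <- variety_ids(panel)
  n <- length(ids)
  if (k > n) stop("k exceeds the number of varieties", call. = FALSE)
  if (k == n) {
    hard <- seq_len(n)
    soft <- diag(1, n)
    medoids <- ids
    dmat <- if (n >= 2) as.matrix(genotype_distance(panel, metric)) else
      matrix(0, 1, 1, dimnames = list(ids, ids))
  } else if (k == 1) {
    hard <- rep(1L, n)
    soft <- matrix(1, n, 1)
    dmat <- as.matrix(genotype_distance(panel, metric))
    medoids <- ids[which.min(colSums(dmat))]
  } else {
    dm <- genotype_distance(panel, metric)
    dmat <- as.matrix(dm)
    set.seed(seed)
    fit <- cluster::pam(dm, k, diss = TRUE)
    hard <- as.integer(fit$clustering)
    medoids <- fit$medoids
    dmed <- dmat[, medoids, drop = FALSE]
    inv <- 1 / (dmed + 1e-9)
    soft <- inv / rowSums(inv)
  }
  # relabel clusters by decreasing size (ties by old label)
  sizes <- table(factor(hard, levels = seq_len(k)))
  new_of_old <- integer(k)
  new_of_old[order(-as.integer(sizes), seq_len(k))] <- seq_len(k)
  hard <- new_of_old[hard]
  ord <- order(new_of_old)
  soft <- soft[, ord, drop = FALSE]
  medoids <- medoids[ord]
  gm <- gt_matrix(panel)
  centroids <- t(vapply(seq_len(k), function(cl) {
    rows <- which(hard == cl)
    colMeans(gm[rows, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(gm))))
  labels <- as.character(seq_len(k))
  if (outgroup && k > 1) {
    global <- colMeans(gm, na.rm = TRUE) / 2
    dev <- apply(centroids, 1, function(f) mean((f - global)^2, na.rm = TRUE))
    labels[which.max(dev)] <- "99"
  }
  colnames(soft) <- labels
  assignments <- tibble::tibble(variety = ids, cluster = labels[hard])
  structure(list(assignments = assignments, k = k, medoids = medoids,
                 proportions = soft, centroids = centroids,
                 labels = labels,
                 within_ss = sum(dmat[cbind(seq_len(n),
                                            match(medoids, ids)[hard])])),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("K-medoids cluster model: k = %d\n", x$k))
  print(table(x$assignments$cluster))
  invisible(x)
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree (both together
#' or both apart).
#'
#' @param a,b Label vectors of equal length.
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  pr <- utils::combn(length(a), 2)
  same_a <- a[pr[1, ]] == a[pr[2, ]]
  same_b <- b[pr[1, ]] == b[pr[2, ]]
  mean(same_a == same_b)
}

#' PCA variance fractions of a genotype panel
#'
#' Centers the 0/1/2 genotype matrix (missing calls imputed to the marker
#' mean) and eigendecomposes its covariance. Fractions are eigenvalues
#' over total variance, so they are non-increasing and sum to at most 1.
#'
#' @param panel A [genotype_panel()].
#' @param n_components Number of leading components to report.
#' @return Tibble: component, variance_fraction, cumulative; attribute
#'   `scores` holds the variety scores for the reported components.
#' @export
pca_variance <- function(panel, n_components = 10) {
  gm <- gt_matrix(panel)
  if (length(gm) == 0) stop("empty panel", call. = FALSE)
  n_components <- min(n_components, nrow(gm), ncol(gm))
  for (j in seq_len(ncol(gm))) {
    mu <- mean(gm[, j], na.rm = TRUE)
    gm[is.na(gm[, j]), j] <- mu
  }
  storage.mode(gm) <- "double"
  fit <- stats::prcomp(gm, center = TRUE, scale. = FALSE)
  var_all <- fit$sdev^2
  frac <- var_all / sum(var_all)
  out <- tibble::tibble(component = seq_len(n_components),
                        variance_fraction = frac[seq_len(n_components)],
                        cumulative = cumsum(frac)[seq_len(n_components)])
  attr(out, "scores") <- fit$x[, seq_len(n_components), drop = FALSE]
  out
}

#' Linkage-disequilibrium decay
#'
#' Computes r-squared (squared Pearson correlation of 0/1/2 codes over
#' pairwise-complete varieties) for marker pairs on the same chromosome
#' within `max_dist_bp`, bins the values by physical distance and reports
#' the decay distance: the midpoint of the first bin whose mean r-squared
#' falls below `r2_threshold` (default: half the maximum bin mean). Pairs
#' involving a monomorphic marker are excluded.
#'
#' @param panel A [genotype_panel()].
#' @param max_dist_bp Maximum pair distance considered (default 100 kb).
#' @param bin_bp Bin width in bp (default 1 kb).
#' @param r2_threshold Decay threshold; `NULL` for the half-maximum rule.
#' @return Tibble of class `ld_decay`: bin_start, bin_mid, n_pairs,
#'   mean_r2; attributes `decay_distance` and `r2_threshold`.
#' @export
ld_decay <- function(panel, max_dist_bp = 1e5, bin_bp = 1e3,
                     r2_threshold = NULL) {
  gm <- gt_matrix(panel)
  storage.mode(gm) <- "double"
  info <- marker_info(panel)
  dist_v <- numeric(0)
  r2_v <- numeric(0)
  for (cc in unique(info$chrom)) {
    idx <- which(info$chrom == cc)
    if (length(idx) < 2) next
    pos <- info$pos[idx]
    pr <- utils::combn(length(idx), 2)
    dd <- abs(pos[pr[1, ]] - pos[pr[2, ]])
    keep <- dd <= max_dist_bp
    if (!any(keep)) next
    pr <- pr[, keep, drop = FALSE]
    dd <- dd[keep]
    for (k in seq_len(ncol(pr))) {
      g1 <- gm[, idx[pr[1, k]]]
      g2 <- gm[, idx[pr[2, k]]]
      both <- !is.na(g1) & !is.na(g2)
      if (sum(both) < 3) next
      if (stats::sd(g1[both]) == 0 || stats::sd(g2[both]) == 0) next
      r <- stats::cor(g1[both], g2[both])
      dist_v <- c(dist_v, dd[k])
      r2_v <- c(r2_v, r^2)
    }
  }
  if (length(r2_v) == 0) {
    stop("no polymorphic intra-chromosome marker pairs within range",
         call. = FALSE)
  }
  bin <- floor(dist_v / bin_bp)
  tab <- tibble::tibble(bin_start = bin * bin_bp,
                        bin_mid = bin * bin_bp + bin_bp / 2,
                        r2 = r2_v) |>
    dplyr::group_by(.data$bin_start, .data$bin_mid) |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2),
                     .groups = "drop") |>
    dplyr::arrange(.data$bin_start)
  if (is.null(r2_threshold)) r2_threshold <- max(tab$mean_r2) / 2
  below <- which(tab$mean_r2 < r2_threshold)
  decay <- if (length(below) > 0) tab$bin_mid[below[1]] else NA_real_
  attr(tab, "decay_distance") <- decay
  attr(tab, "r2_threshold") <- r2_threshold
  class(tab) <- c("ld_decay", class(tab))
  tab
}
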
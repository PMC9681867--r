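test_that("allele-sharing distance scores 0 / 0.5 / 1 as defined", {
  p <- genotype_panel(tibble::tibble(
    marker = c("m1", "m2"), chrom = "C1", pos = c(10L, 20L), ref = "A",
    alt = "T",
    v1 = c(0L, 0L), v2 = c(0L, 0L), v3 = c(2L, 2L), v4 = c(1L, NA)
  ))
  d <- as.matrix(genotype_distance(p))
  expect_equal(d["v1", "v2"], 0)
  expect_equal(d["v1", "v3"], 1)      # opposite homozygotes everywhere
  expect_equal(d["v1", "v4"], 0.5)    # het vs hom at the single compared locus
  expect_equal(attr(genotype_distance(p), "n_loci")["v1", "v4"], 1)
  # strict-mismatch metric counts any difference as 1
  dm <- as.matrix(genotype_distance(p, metric = "mismatch"))
  expect_equal(dm["v1", "v4"], 1)

  p2 <- genotype_panel(tibble::tibble(
    marker = c("m1", "m2"), chrom = "C1", pos = c(10L, 20L), ref = "A",
    alt = "T", v1 = c(0L, NA), v2 = c(NA, 0L)
  ))
  expect_error(genotype_distance(p2), "no called locus")
})

test_that("UPGMA reproduces the hand-executed 3-taxon example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(as.dist(d))
  expect_equal(attr(tr, "sum_branch_length"), 5)  # 1 + 1 + 1 + 2
  expect_equal(attr(tr, "min_pair_path"), 2)
  # ultrametric: equal root-to-leaf depths
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_lt(diff(range(depths)), 1e-9)
})

test_that("UPGMA stays ultrametric and consistent through Newick", {
  s <- sim_small(seed = 31)
  tr <- upgma_tree(genotype_distance(s$panel))
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(sum(back$edge.length), attr(tr, "sum_branch_length"),
               tolerance = 1e-8)
  # two-taxon degenerate case: two branches of d/2
  d2 <- as.dist(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                       dimnames = list(c("x", "y"), c("x", "y"))))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.2, 0.2))
})

test_that("NJ recovers additive metrics exactly and handles stars", {
  for (seed in 1:10) {
    gen <- random_additive_metric(sample(4:8, 1), seed)
    tr <- nj_tree(gen$dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), tr)), 0)
    rec <- ape::cophenetic.phylo(tr)
    labs <- rownames(as.matrix(gen$dm))
    expect_equal(rec[labs, labs], as.matrix(gen$dm)[labs, labs],
                 tolerance = 1e-8)
  }
  star <- as.dist(matrix(1, 4, 4) - diag(4))
  attr(star, "Labels") <- letters[1:4]
  st <- nj_tree(star)
  internal <- st$edge[, 2] > length(st$tip.label)
  expect_lt(max(st$edge.length[internal]), 1e-12)
  expect_true(all(st$edge.length >= 0))
})

test_that("NJ topology is invariant to taxon order", {
  gen <- random_additive_metric(6, 99)
  m <- as.matrix(gen$dm)
  perm <- sample(rownames(m))
  t1 <- nj_tree(as.dist(m))
  t2 <- nj_tree(as.dist(m[perm, perm]))
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("bootstrap supports are deterministic and force obvious cherries", {
  # v5/v6 identical and far from the rest -> their cherry has support 1
  set.seed(5)
  base <- matrix(sample(c(0L, 2L), 40 * 4, replace = TRUE), nrow = 40)
  twin <- sample(c(0L, 2L), 40, replace = TRUE)
  calls <- cbind(base, twin, twin)
  flip <- twin == 0L
  calls[flip, 1:4] <- 2L  # push the others away from the twins
  colnames(calls) <- paste0("v", 1:6)
  p <- genotype_panel(dplyr::bind_cols(
    tibble::tibble(marker = paste0("m", 1:40), chrom = "C1",
                   pos = as.integer(1:40 * 10), ref = "A", alt = "T"),
    tibble::as_tibble(as.data.frame(calls))))
  tr <- bootstrap_support(p, "nj", n_reps = 25, seed = 3)
  sup <- attr(tr, "support")
  cherry <- sup$support[sup$split %in% c("v5|v6")]
  expect_equal(cherry, 1)
  tr2 <- bootstrap_support(p, "nj", n_reps = 25, seed = 3)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))
  one <- bootstrap_support(p, "nj", n_reps = 1, seed = 4)
  expect_true(all(attr(one, "support")$support %in% c(0, 1)))
})

test_that("K-medoids recovers simulated structure and handles edge Ks", {
  s <- simulate_panel(panel_spec(n_varieties = 40, n_markers = 400,
                                 n_clusters = 2, fst = 0.3,
                                 missing_rate = 0.05, seed = 1))
  cm <- cluster_varieties(s$panel, k = 2)
  expect_gt(rand_index(cm$assignments$cluster, s$truth$clusters$cluster), 0.95)
  expect_equal(unname(rowSums(cm$proportions)), rep(1, 40), tolerance = 1e-9)
  # hard label is the argmax of the soft proportions
  am <- apply(cm$proportions, 1, function(r) colnames(cm$proportions)[which.max(r)])
  expect_equal(unname(am), cm$assignments$cluster)

  cm1 <- cluster_varieties(s$panel, k = 1)
  expect_equal(unique(cm1$assignments$cluster), "1")
  cmn <- cluster_varieties(select_varieties(s$panel, paste0("V00", 1:5)), k = 5)
  expect_equal(cmn$within_ss, 0)
  expect_equal(dplyr::n_distinct(cmn$assignments$cluster), 5)
  expect_error(cluster_varieties(s$panel, k = 41), "exceeds")
})

test_that("outgroup labelling tags the most divergent cluster as 99", {
  s <- simulate_panel(panel_spec(n_varieties = 45, n_markers = 300,
                                 n_clusters = 3, fst = 0.25, outgroup = TRUE,
                                 missing_rate = 0, seed = 17))
  cm <- cluster_varieties(s$panel, k = 3, outgroup = TRUE)
  expect_true("99" %in% cm$assignments$cluster)
  # the sentinel cluster should coincide with the simulator's outgroup
  truth_out <- s$truth$clusters$variety[s$truth$clusters$cluster == 3]
  got_out <- cm$assignments$variety[cm$assignments$cluster == "99"]
  expect_gt(length(intersect(truth_out, got_out)) /
              length(union(truth_out, got_out)), 0.8)
})

test_that("cluster labels are permutation-equivariant", {
  s <- sim_small(seed = 41, missing_rate = 0)
  cm <- cluster_varieties(s$panel, k = 3)
  perm <- rev(variety_ids(s$panel))
  cm2 <- cluster_varieties(select_varieties(s$panel, perm), k = 3)
  j <- dplyr::inner_join(cm$assignments, cm2$assignments, by = "variety")
  expect_equal(rand_index(j$cluster.x, j$cluster.y), 1)
})

test_that("PCA fractions behave like eigenvalue shares", {
  # rank-1 panel: one direction explains everything
  calls <- outer(c(0L, 1L, 2L, 0L, 2L), rep(1L, 6))
  colnames(calls) <- paste0("m", 1:6)
  p <- genotype_panel(dplyr::bind_cols(
    tibble::tibble(marker = paste0("m", 1:6), chrom = "C1",
                   pos = as.integer(1:6 * 10), ref = "A", alt = "T"),
    tibble::as_tibble(as.data.frame(t(calls)))))
  pv <- pca_variance(p, n_components = 3)
  expect_equal(pv$variance_fraction[1], 1, tolerance = 1e-12)
  s <- sim_small(seed = 51)
  pv2 <- pca_variance(s$panel, n_components = 8)
  expect_true(all(diff(pv2$variance_fraction) <= 1e-12))
  expect_lte(max(pv2$cumulative), 1 + 1e-9)

  # duplicating every marker column rescales but keeps the fractions
  dup <- s$panel
  dup2 <- dup
  dup2$pos <- dup2$pos + 1L
  dup2$marker <- paste0(dup2$marker, "_d")
  both <- genotype_panel(dplyr::bind_rows(dup, dup2))
  pv3 <- pca_variance(both, n_components = 8)
  expect_equal(pv3$variance_fraction, pv2$variance_fraction, tolerance = 1e-9)
})

test_that("LD decay: duplicate markers give r2 = 1; unlinked markers ~ 1/(n-1)", {
  set.seed(9)
  n <- 50
  g <- rbinom(n, 2, 0.4)
  calls <- cbind(g, g)
  colnames(calls) <- c("d1", "d2")
  p <- genotype_panel(dplyr::bind_cols(
    tibble::tibble(marker = c("d1", "d2"), chrom = "C1", pos = c(100L, 101L),
                   ref = "A", alt = "T"),
    tibble::as_tibble(as.data.frame(t(calls)))))
  ld <- ld_decay(p, max_dist_bp = 1000, bin_bp = 100)
  expect_equal(ld$mean_r2[1], 1)

  m <- 80
  calls2 <- t(matrix(rbinom(n * m, 2, 0.4), nrow = n))
  colnames(calls2) <- NULL
  p2 <- genotype_panel(dplyr::bind_cols(
    tibble::tibble(marker = paste0("u", 1:m), chrom = "C1",
                   pos = as.integer(1:m * 7), ref = "A", alt = "T"),
    tibble::as_tibble(as.data.frame(calls2))))
  ld2 <- ld_decay(p2, max_dist_bp = 1e4, bin_bp = 1e4)
  n_pairs <- sum(ld2$n_pairs)
  null_mean <- 1 / (n - 1)
  se <- sqrt(2) * null_mean / sqrt(n_pairs)  # r2 ~ chi2_1/(n-1): sd ~ sqrt(2)/(n-1)
  expect_lt(abs(weighted.mean(ld2$mean_r2, ld2$n_pairs) - null_mean), 3 * se)

  # monomorphic markers never enter the bins
  p3 <- genotype_panel(tibble::tibble(
    marker = c("a", "b"), chrom = "C1", pos = c(1L, 2L), ref = "A", alt = "T",
    v1 = c(0L, 0L), v2 = c(0L, 1L), v3 = c(0L, 2L)
  ))
  expect_error(ld_decay(p3, max_dist_bp = 100, bin_bp = 10), "no polymorphic")
})
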
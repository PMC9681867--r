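test_that("discrimination matrix records exactly the separating pairs", {
  p <- genotype_panel(tibble::tibble(
    marker = paste0("m", 1:5), chrom = "C1", pos = 1:5 * 10L, ref = "A",
    alt = "T",
    v1 = c(0L, 0L, 0L, 0L, 0L), v2 = c(2L, 0L, 0L, 0L, 0L)
  ))
  dm <- build_discrimination(p)
  expect_equal(nrow(dm$pairs), 1)
  expect_equal(unname(rowSums(dm$cov)), c(1, 0, 0, 0, 0))

  # a missing call never separates; het vs hom does
  p2 <- genotype_panel(tibble::tibble(
    marker = c("m1", "m2"), chrom = "C1", pos = c(10L, 20L), ref = "A",
    alt = "T", v1 = c(NA, 1L), v2 = c(2L, 0L)
  ))
  dm2 <- build_discrimination(p2)
  expect_equal(unname(rowSums(dm2$cov)), c(0, 1))

  # identical duplicate varieties are separated by nothing
  p3 <- genotype_panel(tibble::tibble(
    marker = c("m1", "m2"), chrom = "C1", pos = c(10L, 20L), ref = "A",
    alt = "T", v1 = c(0L, 1L), v2 = c(0L, 1L), v3 = c(2L, 2L)
  ))
  dm3 <- build_discrimination(p3)
  pair12 <- which(dm3$pairs$v1 == "v1" & dm3$pairs$v2 == "v2")
  expect_false(any(dm3$cov[, pair12]))
})

test_that("greedy matches brute force on the worked 3-variety instance", {
  # v1 differs from v2=v3 at m1; m2 splits v3 from the others
  p <- genotype_panel(tibble::tibble(
    marker = c("m1", "m2"), chrom = "C1", pos = c(10L, 20L), ref = "A",
    alt = "T",
    v1 = c(2L, 0L), v2 = c(0L, 0L), v3 = c(0L, 2L)
  ))
  dm <- build_discrimination(p)
  cs <- greedy_min_set(dm)
  expect_setequal(cs$marker, c("m1", "m2"))
  expect_equal(attr(cs, "n_covered"), 3)
  expect_equal(nrow(attr(cs, "unresolved")), 0)
  expect_equal(exact_min_cover(dm$cov), 2)
  cert <- attr(cs, "certificate")
  expect_false(any(is.na(cert$marker)))
})

test_that("duplicate varieties surface as an impossibility certificate", {
  p <- genotype_panel(tibble::tibble(
    marker = c("m1", "m2"), chrom = "C1", pos = c(10L, 20L), ref = "A",
    alt = "T", v1 = c(0L, 1L), v2 = c(0L, 1L), v3 = c(2L, 2L)
  ))
  cs <- greedy_min_set(build_discrimination(p))
  unres <- attr(cs, "unresolved")
  expect_equal(nrow(unres), 1)
  expect_equal(c(unres$v1, unres$v2), c("v1", "v2"))
})

test_that("greedy stays within the ln-bound of the exhaustive optimum", {
  # seeded random small instances; also record how often greedy is optimal
  n_opt <- 0
  n_inst <- 30
  for (seed in seq_len(n_inst)) {
    set.seed(seed)
    n_var <- sample(4:8, 1)
    n_mark <- sample(6:12, 1)
    calls <- matrix(sample(c(0L, 1L, 2L), n_var * n_mark, replace = TRUE,
                           prob = c(0.4, 0.2, 0.4)),
                    nrow = n_mark,
                    dimnames = list(NULL, paste0("v", seq_len(n_var))))
    p <- genotype_panel(dplyr::bind_cols(
      tibble::tibble(marker = paste0("m", seq_len(n_mark)), chrom = "C1",
                     pos = as.integer(seq_len(n_mark) * 10), ref = "A",
                     alt = "T"),
      tibble::as_tibble(as.data.frame(calls))))
    dm <- build_discrimination(p)
    cs <- greedy_min_set(dm)
    coverable <- colSums(dm$cov) > 0
    expect_equal(attr(cs, "n_covered"), sum(coverable))
    opt <- exact_min_cover(dm$cov)
    if (opt > 0) {
      expect_lte(nrow(cs), (log(ncol(dm$cov)) + 1) * opt)
      if (nrow(cs) == opt) n_opt <- n_opt + 1
    } else n_opt <- n_opt + 1
  }
  expect_gte(n_opt / n_inst, 0.8)
})

test_that("required markers are seeded first and size caps are honoured", {
  dm <- build_discrimination(toy$panel)
  cs <- greedy_min_set(dm, required = "m5")
  expect_equal(cs$marker[1], "m5")
  capped <- greedy_min_set(dm, size_cap = 1)
  expect_equal(nrow(capped), 1)
})

test_that("nested sets form a subset chain with monotone redundancy", {
  s <- simulate_panel(panel_spec(n_varieties = 30, n_markers = 150,
                                 n_clusters = 3, missing_rate = 0.02,
                                 seed = 12))
  sets <- nested_sets(s$panel, sizes = c(24, 10, 5), restarts = 5, seed = 2)
  expect_named(sets, c("F24", "F10", "F5"))
  expect_true(all(sets$F5$marker %in% sets$F10$marker))
  expect_true(all(sets$F10$marker %in% sets$F24$marker))
  expect_identical(sets$F10$marker[1:5], sets$F5$marker)
  # growing a fully covering set strictly increases total redundancy
  if (nrow(attr(sets$F10, "unresolved")) == 0) {
    expect_gt(attr(sets$F24, "redundancy"), attr(sets$F10, "redundancy"))
  }
})

test_that("full-coverage certificates verify on simulated panels", {
  for (seed in c(21, 22, 23)) {
    s <- simulate_panel(panel_spec(n_varieties = 25, n_markers = 200,
                                   n_clusters = 3, missing_rate = 0.01,
                                   maf_floor = 0.1, seed = seed))
    dm <- build_discrimination(s$panel)
    sets <- nested_sets(s$panel, sizes = c(10), restarts = 10, seed = seed)
    rep10 <- verify_identification(s$panel, sets$F10)
    cov_uncoverable <- sum(colSums(dm$cov) == 0)
    expect_equal(nrow(attr(sets$F10, "unresolved")), cov_uncoverable)
    if (cov_uncoverable == 0) {
      expect_equal(rep10$n_distinct, 25)
    }
  }
})

test_that("identification reports count collisions and shrink monotonically", {
  rep_all <- verify_identification(toy$panel, toy$panel$marker)
  expect_equal(rep_all$n_distinct, 6)
  expect_equal(length(rep_all$collisions), 0)

  rep_empty <- verify_identification(toy$panel, character(0))
  expect_equal(rep_empty$n_distinct, 1)
  expect_equal(lengths(rep_empty$collisions), 6)

  # removing markers never separates a previously colliding pair
  full <- verify_identification(toy$panel, toy$panel$marker[1:4])
  sub <- verify_identification(toy$panel, toy$panel$marker[1:2])
  expect_lte(sub$n_distinct, full$n_distinct)
  g <- glance(sub)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_markers, 2)
})

test_that("single-variety panels yield an empty set with zero pairs", {
  p <- genotype_panel(toy$panel[, c("marker", "chrom", "pos", "ref", "alt",
                                    "v1")])
  expect_error(build_discrimination(p), "two varieties")
  rep1 <- verify_identification(p, p$marker)
  expect_equal(rep1$n_varieties, 1)
  expect_equal(rep1$n_distinct, 1)
})
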
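test_that("one-way ANOVA matches hand-computed sums of squares", {
  d <- tibble::tibble(v = c(1, 2, 3, 7, 8, 9),
                      g = rep(c("a", "b"), each = 3))
  an <- anova_by_cluster(d, v, g)
  # SSB = 54, SSW = 4, df = (1, 4), F = 54 / 1 = 54
  expect_equal(an$statistic, 54)
  expect_equal(an$mse, 1)
  expect_equal(an$df_between, 1)
  expect_equal(an$df_within, 4)
  expect_equal(an$p_value, stats::pf(54, 1, 4, lower.tail = FALSE))
  expect_lt(an$p_value, 0.01)
})

test_that("degenerate ANOVA inputs are flagged, not crashed", {
  d <- tibble::tibble(v = rep(5, 6), g = rep(c("a", "b"), each = 3))
  an <- anova_by_cluster(d, v, g)
  expect_equal(an$p_value, 1)
  expect_true(an$zero_variance)
  # identical group means (but nonzero within-variance) -> F = 0
  d2 <- tibble::tibble(v = c(1, 3, 1, 3), g = c("a", "a", "b", "b"))
  expect_equal(anova_by_cluster(d2, v, g)$statistic, 0)
  d3 <- tibble::tibble(v = c(1, 2, NA), g = c("a", "a", "b"))
  expect_warning(expect_error(anova_by_cluster(d3, v, g), "two clusters"),
                 "dropped")
})

test_that("ANOVA p-values are calibrated under label permutation", {
  set.seed(8)
  n_rep <- 1000
  y <- rnorm(40)
  g <- rep(1:4, each = 10)
  hits <- 0
  for (i in seq_len(n_rep)) {
    gi <- sample(g)
    hits <- hits + (anova_by_cluster(tibble::tibble(v = y, g = gi), v, g)$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.03)
  expect_lte(hits / n_rep, 0.07)
})

test_that("Duncan letters match the studentized-range table oracle", {
  # 4 groups, n = 6 each, MSE = 1, df_error = 20
  means <- c(g1 = 10, g2 = 9.8, g3 = 5, g4 = 1)
  set.seed(1)
  vals <- unlist(lapply(means, function(m) m + scale(rnorm(6))[, 1]))
  d <- tibble::tibble(v = vals, g = rep(names(means), each = 6))
  dm <- duncan_mrt(d, v, g, alpha = 0.05)
  # oracle: critical ranges from the printed Duncan SSR table at df = 20
  mse <- dm$anova$mse
  r <- DUNCAN_SSR_DF20 * sqrt(mse / 6)
  expect_equal(dm$anova$df_within, 20)
  # hand decisions: |10 - 9.8| < R2 together; all other gaps exceed R
  expect_equal(dm$groups$letters[dm$groups$cluster == "g1"], "a")
  expect_equal(dm$groups$letters[dm$groups$cluster == "g2"], "a")
  expect_equal(dm$groups$letters[dm$groups$cluster == "g3"], "b")
  expect_equal(dm$groups$letters[dm$groups$cluster == "g4"], "c")
  expect_lt(abs(means[1] - means[2]), r["2"])
  expect_gt(abs(means[2] - means[3]), r["3"])
  expect_gt(abs(means[3] - means[4]), r["2"])
  # our internal quantiles agree with the printed table to ~3 decimals
  ours <- vapply(2:4, function(p)
    stats::qtukey((1 - 0.05)^(p - 1), p, 20), 0)
  expect_equal(unname(ours), unname(DUNCAN_SSR_DF20), tolerance = 2e-3)
})

test_that("span-2 Duncan decision coincides with the two-sample t-test", {
  set.seed(2)
  for (rep in 1:20) {
    a <- rnorm(8, 0, 1)
    b <- rnorm(8, rep / 10, 1)
    d <- tibble::tibble(v = c(a, b), g = rep(c("A", "B"), each = 8))
    dm <- duncan_mrt(d, v, g, alpha = 0.05)
    separated <- dm$groups$letters[1] != dm$groups$letters[2]
    tt <- stats::t.test(a, b, var.equal = TRUE)$p.value < 0.05
    expect_equal(separated, tt)
  }
})

test_that("equal means share one letter; separation is monotone in gap", {
  d <- tibble::tibble(v = rep(c(1.0, 1.1, 0.9), times = 4),
                      g = rep(c("a", "b", "c", "d"), each = 3))
  dm <- duncan_mrt(d, v, g)
  expect_equal(unique(dm$groups$letters), "a")

  # increasing one group's mean never merges letters
  n_sep_prev <- -1
  for (shift in c(0, 2, 5, 10)) {
    set.seed(3)
    base <- rnorm(18, 0, 1)
    d2 <- tibble::tibble(v = base + rep(c(0, 0, shift), each = 6),
                         g = rep(c("a", "b", "c"), each = 6))
    dm2 <- duncan_mrt(d2, v, g)
    n_sep <- length(unique(dm2$groups$letters))
    expect_gte(n_sep, n_sep_prev)
    n_sep_prev <- n_sep
  }
})

test_that("unbalanced clusters use harmonic-mean span sizes", {
  set.seed(4)
  d <- tibble::tibble(
    v = c(rnorm(3, 0), rnorm(12, 0.5), rnorm(5, 4)),
    g = rep(c("a", "b", "c"), times = c(3, 12, 5))
  )
  dm <- duncan_mrt(d, v, g)
  expect_equal(sort(dm$groups$n), c(3, 5, 12))
  expect_true(all(nchar(dm$groups$letters) >= 1))
})

test_that("explained-trait verdicts follow the letter partition", {
  fake_dmrt <- function(letters, p) {
    structure(list(
      groups = tibble::tibble(cluster = as.character(seq_along(letters)),
                              n = 5, mean = rev(seq_along(letters)),
                              letters = letters),
      anova = tibble::tibble(statistic = 10, p_value = p, mse = 1,
                             df_between = 1, df_within = 10, n = 20,
                             n_clusters = length(letters),
                             zero_variance = FALSE),
      alpha = 0.05, data = tibble::tibble()), class = "dmrt")
  }
  res <- explain_traits(list(
    F87 = list(T1 = fake_dmrt(c("a", "a", "b", "b"), 1e-5),
               T2 = fake_dmrt(c("a", "a", "a"), 0.001),
               T3 = fake_dmrt(c("a", "ab", "b"), 0.01),
               T4 = fake_dmrt(c("a", "ab", "ab", "ab"), 0.01),
               T5 = fake_dmrt(c("a", "b"), 0.6))))
  t1 <- res[res$trait_id == "T1", ]
  expect_true(t1$explained)
  expect_equal(t1$n_groups, 2L)
  expect_false(t1$overlap)
  expect_false(res$explained[res$trait_id == "T2"])  # single shared letter
  t3 <- res[res$trait_id == "T3", ]
  expect_true(t3$explained)
  expect_equal(t3$n_groups, 2L)   # pure 'a' and pure 'b'; middle unclear
  expect_true(t3$overlap)
  t4 <- res[res$trait_id == "T4", ]
  expect_equal(t4$n_groups, 1L)   # only one pure letter block
  expect_false(res$explained[res$trait_id == "T5"])  # p above the gate
})

test_that("verdicts are invariant to cluster relabelling", {
  set.seed(6)
  d <- tibble::tibble(v = c(rnorm(6, 0), rnorm(6, 3), rnorm(6, 6)),
                      g = rep(c("1", "2", "3"), each = 6))
  r1 <- explain_traits(list(S = list(T = duncan_mrt(d, v, g))))
  d2 <- d
  d2$g <- c("3" = "1", "1" = "2", "2" = "3")[d$g]
  r2 <- explain_traits(list(S = list(T = duncan_mrt(d2, v, g))))
  expect_equal(r1$n_groups, r2$n_groups)
  expect_equal(r1$explained, r2$explained)
})

test_that("trait correlations use pairwise-complete varieties", {
  tr <- tibble::tibble(
    variety = rep(paste0("v", 1:6), 3),
    trait_id = rep(c("A", "B", "C"), each = 6),
    value = c(1, 2, 3, 4, 5, 6,
              -1, -2, -3, -4, -5, -6,
              2, 4, 6, 8, 10, NA)
  )
  cc <- correlate_traits(tr)
  expect_equal(cc$r[cc$trait_x == "A" & cc$trait_y == "A"], 1)
  expect_equal(cc$r[cc$trait_x == "A" & cc$trait_y == "B"], -1)
  expect_equal(cc$n[cc$trait_x == "A" & cc$trait_y == "C"], 5L)
  const <- tibble::tibble(variety = rep(paste0("v", 1:4), 2),
                          trait_id = rep(c("A", "B"), each = 4),
                          value = c(1, 2, 3, 4, 7, 7, 7, 7))
  expect_warning(correlate_traits(const), "constant")
})

test_that("traits driven by the same causal SNP correlate near one at low noise", {
  s <- simulate_panel(panel_spec(n_varieties = 60, n_markers = 40,
                                 n_clusters = 2, missing_rate = 0, seed = 13))
  g <- gt_matrix(s$panel)[, 7]
  set.seed(14)
  tr <- tibble::tibble(
    variety = rep(names(g), 2),
    trait_id = rep(c("QN90", "QN91"), each = length(g)),
    type = "QN",
    value = c(g + rnorm(length(g), 0, 1e-4),
              2 * g + 1 + rnorm(length(g), 0, 1e-4))
  )
  cc <- correlate_traits(tr)
  off <- cc$r[cc$trait_x != cc$trait_y]
  expect_gt(abs(off), 0.99)
})
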
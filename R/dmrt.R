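# Cluster-versus-trait evaluation: one-way ANOVA across clusters, Duncan's
# new multiple range test with letter groups, and the "explained by g
# groups" summary used in DUS-trait determination.

#' One-way ANOVA of a trait across clusters
#'
#' Standard fixed-effects one-way ANOVA (unbalanced groups supported).
#' Clusters with no phenotyped member are dropped with a warning; if all
#' values are identical the test is flagged and `p_value = 1`.
#'
#' @param data A data frame.
#' @param value Column with the trait values (tidy-eval).
#' @param cluster Column with the cluster labels (tidy-eval).
#' @return One-row tibble: statistic (F), p_value, mse, df_between,
#'   df_within, n, n_clusters, zero_variance.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 7, 8, 9), g = rep(c("a", "b"), each = 3))
#' anova_by_cluster(d, v, g)
#' @export
anova_by_cluster <- function(data, value, cluster) {
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(cluster), data)
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- as.character(g[keep])
  dropped <- setdiff(unique(as.character(rlang::eval_tidy(rlang::enquo(cluster), data))),
                     unique(g))
  if (length(dropped) > 0) {
    warning("cluster(s) with no phenotyped member dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(unique(g)) < 2) stop("need at least two clusters", call. = FALSE)
  if (max(table(g)) < 2) stop("need a cluster with at least two values",
                              call. = FALSE)
  if (stats::var(y) == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, mse = 0,
                          df_between = length(unique(g)) - 1L,
                          df_within = length(y) - length(unique(g)),
                          n = length(y), n_clusters = length(unique(g)),
                          zero_variance = TRUE))
  }
  fit <- stats::aov(y ~ factor(g))
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(p)) { f <- 0; p <- 1 }
  tibble::tibble(statistic = f, p_value = p, mse = tab[["Mean Sq"]][2],
                 df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
                 n = length(y), n_clusters = length(unique(g)),
                 zero_variance = FALSE)
}

# Duncan critical range for a span of p ordered means:
# R_p = q((1-alpha)^(p-1); p, df) * sqrt(MSE / n_h), with q the studentized
# range quantile and n_h the harmonic mean of the span's group sizes.
duncan_range <- function(span, df, mse, n_h, alpha) {
  q <- stats::qtukey((1 - alpha)^(span - 1), span, df)
  q * sqrt(mse / n_h)
}

#' Duncan's new multiple range test with letter groups
#'
#' Means are ranked; for every span of `p` ordered means the critical
#' range uses the studentized-range quantile at the Duncan protection
#' level `1 - (1 - alpha)^(p - 1)` and the harmonic mean of the span's
#' group sizes (unbalanced clusters). Two means differ iff their gap
#' exceeds the critical range of their span, with the usual containment
#' rule (a span declared homogeneous is never split by a sub-span).
#' Letters are assigned by the insert-and-absorb algorithm, scanning from
#' the largest mean.
#'
#' @param data A data frame.
#' @param value,cluster Trait value and cluster label columns (tidy-eval).
#' @param alpha Significance level (default 0.05).
#' @return List of class `dmrt`: `groups` (tibble: cluster, n, mean,
#'   letters, ordered by decreasing mean), `anova` (the
#'   [anova_by_cluster()] row), `alpha` and the input `data` (for
#'   plotting).
#' @export
duncan_mrt <- function(data, value, cluster, alpha = 0.05) {
  value_q <- rlang::enquo(value)
  cluster_q <- rlang::enquo(cluster)
  y <- rlang::eval_tidy(value_q, data)
  g <- as.character(rlang::eval_tidy(cluster_q, data))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  if (length(unique(g)) < 2) stop("need at least two clusters", call. = FALSE)
  an <- anova_by_cluster(tibble::tibble(.y = y, .g = g), .y, .g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ord <- order(-means, names(means))
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  df <- an$df_within
  mse <- an$mse
  # pairwise homogeneity with containment: process spans largest to smallest
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  if (an$zero_variance || mse == 0) {
    nonsig[] <- TRUE
  } else {
    for (span in k:2) {
      for (i in seq_len(k - span + 1)) {
        j <- i + span - 1
        if (nonsig[i, j]) next
        n_h <- span / sum(1 / ns[i:j])
        gap <- means[i] - means[j]
        if (gap <= duncan_range(span, df, mse, n_h, alpha)) {
          nonsig[i:j, i:j] <- TRUE
        }
      }
    }
  }
  # letters: maximal homogeneous runs [i, maxj], absorbing contained runs
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    runs[[i]] <- c(i, j)
  }
  runs <- unique(runs)
  maximal <- Filter(function(r) {
    !any(vapply(runs, function(s)
      (s[1] < r[1] && s[2] >= r[2]) || (s[1] <= r[1] && s[2] > r[2]),
      logical(1)))
  }, runs)
  letters_of <- rep("", k)
  for (li in seq_along(maximal)) {
    r <- maximal[[li]]
    lab <- make_letter(li)
    for (i in r[1]:r[2]) letters_of[i] <- paste0(letters_of[i], lab)
  }
  groups <- tibble::tibble(cluster = names(means), n = as.integer(ns),
                           mean = as.numeric(means), letters = letters_of)
  structure(list(groups = groups, anova = an, alpha = alpha,
                 data = tibble::tibble(value = y, cluster = g)),
            class = "dmrt")
}

make_letter <- function(i) {
  # a, b, ..., z, aa, ab, ... for pathological numbers of groups
  if (i <= 26) return(letters[i])
  paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
}

#' @export
print.dmrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, F = %.3g, p = %.3g)\n",
              x$alpha, x$anova$statistic, x$anova$p_value))
  print(x$groups)
  invisible(x)
}

#' Summarise which traits are explained by cluster groups
#'
#' Reads each Duncan letter table into a verdict. The groups of a trait
#' are the letters with at least one "pure" cluster (a cluster carrying
#' only that letter); clusters with several letters are ambiguous and set
#' the `overlap` flag. A trait is explained when the global ANOVA p-value
#' is below `alpha` and at least one pure group exists with more than one
#' letter present overall; it is unexplained when p >= alpha or every
#' cluster shares a single letter. When several marker sets are supplied
#' the best per trait (smallest p) is flagged.
#'
#' @param dmrt_results Named list of lists: `dmrt_results[[marker_set]][[trait_id]]`
#'   is a [duncan_mrt()] result (a flat list of `dmrt` objects named by
#'   trait also works and is treated as one marker set).
#' @param alpha Significance gate (default 0.05).
#' @return Tibble: trait_id, marker_set, p_value, n_groups, groups
#'   (description string), overlap, explained, best.
#' @export
explain_traits <- function(dmrt_results, alpha = 0.05) {
  if (length(dmrt_results) > 0 && inherits(dmrt_results[[1]], "dmrt")) {
    dmrt_results <- list(set = dmrt_results)
  }
  rows <- list()
  for (ms in names(dmrt_results)) {
    for (tr in names(dmrt_results[[ms]])) {
      d <- dmrt_results[[ms]][[tr]]
      g <- d$groups
      letter_sets <- strsplit(g$letters, "")
      all_letters <- sort(unique(unlist(letter_sets)))
      pure <- vapply(all_letters, function(L) {
        members <- vapply(letter_sets, function(s) L %in% s, logical(1))
        any(members & lengths(letter_sets) == 1)
      }, logical(1))
      overlap <- any(lengths(letter_sets) > 1)
      n_groups <- sum(pure)
      desc <- vapply(all_letters[pure], function(L) {
        members <- g$cluster[vapply(letter_sets, function(s)
          identical(s, L), logical(1))]
        paste(members, collapse = ",")
      }, character(1))
      single_letter <- length(all_letters) <= 1
      explained <- d$anova$p_value < alpha && !single_letter && n_groups >= 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        trait_id = tr, marker_set = ms, p_value = d$anova$p_value,
        n_groups = if (explained) n_groups else NA_integer_,
        groups = if (explained) paste(desc, collapse = " / ") else "",
        overlap = overlap, explained = explained
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out |>
    dplyr::group_by(.data$trait_id) |>
    dplyr::mutate(best = .data$p_value == min(.data$p_value)) |>
    dplyr::ungroup()
}

#' Pairwise Pearson correlation between traits
#'
#' Pearson correlation over varieties with pairwise-complete values.
#' Constant traits yield `NA` entries and a warning.
#'
#' @param traits Long trait tibble (variety, trait_id, value).
#' @return Long tibble: trait_x, trait_y, r, n (distinct unordered pairs,
#'   plus the diagonal).
#' @export
correlate_traits <- function(traits) {
  wide <- tidyr::pivot_wider(traits[, c("variety", "trait_id", "value")],
                             names_from = "trait_id", values_from = "value")
  ids <- setdiff(names(wide), "variety")
  if (length(ids) < 2) stop("need at least two traits", call. = FALSE)
  m <- as.matrix(wide[, ids])
  const <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("constant trait(s): ", paste(ids[const], collapse = ", "),
            call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(m))
  idx <- which(upper.tri(cm, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(trait_x = ids[idx[, 1]], trait_y = ids[idx[, 2]],
                 r = cm[idx], n = as.integer(nmat[idx]))
}
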
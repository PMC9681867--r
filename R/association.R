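# The GWAS funnel: per-trait single-marker association scans, top-K pooling
# across traits, positional deduplication and annotation-aware candidate
# selection.

#' Single-trait association scan
#'
#' Ordinary least squares of the trait value on the additively coded
#' genotype (0/1/2), with an F-test p-value per marker — the plain
#' generalised-linear-model scan used for DUS-trait mapping, without
#' structure or kinship covariates and without multiple-testing correction
#' (markers are consumed as ranks, not as significance calls). Varieties
#' with a missing genotype or phenotype are dropped pairwise per marker.
#' Markers monomorphic among the phenotyped varieties are reported with
#' `p_value = 1` and flagged. Grade-coded QL/PQ traits are regressed on
#' their integer grades; set `method = "anova"` to use a one-way ANOVA on
#' genotype classes instead.
#'
#' @param panel A [genotype_panel()].
#' @param traits Long trait tibble (variety, trait_id, type, value).
#' @param trait_id Trait to scan.
#' @param method `"lm"` (default, additive regression) or `"anova"`
#'   (genotype-class one-way ANOVA, for unordered pseudo-qualitative
#'   traits).
#' @return Tibble: marker, chrom, pos, trait_id, n, maf, beta, p_value,
#'   neg_log10_p, monomorphic.
#' @export
scan_trait <- function(panel, traits, trait_id, method = c("lm", "anova")) {
  method <- match.arg(method)
  tr <- traits[traits$trait_id == trait_id, , drop = FALSE]
  if (nrow(tr) == 0) stop("trait not found: ", trait_id, call. = FALSE)
  y <- tr$value[match(variety_ids(panel), tr$variety)]
  ok <- !is.na(y)
  if (length(unique(y[ok])) < 2) {
    stop("trait ", trait_id, " is constant", call. = FALSE)
  }
  gm <- gt_matrix(panel)  # varieties x markers
  m <- ncol(gm)
  if (method == "lm") {
    # closed-form simple regression per marker, vectorised over markers
    # with pairwise-complete masking
    mask <- !is.na(gm) & ok
    g0 <- gm; g0[is.na(g0)] <- 0L
    storage.mode(g0) <- "double"
    y0 <- ifelse(is.na(y), 0, y)
    n_used <- colSums(mask)
    if (any(n_used < 3)) {
      stop("fewer than 3 varieties usable at marker ",
           colnames(gm)[which(n_used < 3)[1]], " for trait ", trait_id,
           call. = FALSE)
    }
    sg <- colSums(g0 * mask)
    sy <- colSums(y0 * mask)
    sgg <- colSums(g0^2 * mask)
    sgy <- colSums(g0 * y0 * mask)
    syy_t <- colSums(y0^2 * mask)
    sxx <- sgg - sg^2 / n_used
    sxy <- sgy - sg * sy / n_used
    syy <- syy_t - sy^2 / n_used
    p_alt <- sg / (2 * n_used)
    mafs <- pmin(p_alt, 1 - p_alt)
    mono <- sxx <= 1e-12
    beta <- ifelse(mono, NA_real_, sxy / sxx)
    ssr <- ifelse(mono, 0, sxy^2 / sxx)
    sse <- syy - ssr
    f <- ssr / (sse / (n_used - 2))
    pval <- stats::pf(f, 1, n_used - 2, lower.tail = FALSE)
    pval[mono | syy <= 0] <- 1
    pval[!mono & syy > 0 & sse <= 0] <- 0
  } else {
    n_used <- integer(m); beta <- rep(NA_real_, m); pval <- rep(1, m)
    mono <- logical(m); mafs <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      g <- gm[, j]
      use <- ok & !is.na(g)
      n <- sum(use)
      n_used[j] <- n
      if (n < 3) stop("fewer than 3 varieties usable at marker ",
                      colnames(gm)[j], " for trait ", trait_id, call. = FALSE)
      gj <- as.numeric(g[use]); yj <- y[use]
      p_alt <- mean(gj) / 2
      mafs[j] <- min(p_alt, 1 - p_alt)
      if (stats::var(gj) == 0) { mono[j] <- TRUE; next }
      fit <- stats::aov(yj ~ factor(gj))
      tab <- summary(fit)[[1]]
      pval[j] <- tab[["Pr(>F)"]][1]
      if (is.na(pval[j])) pval[j] <- 1
    }
  }
  tibble::tibble(
    marker = panel$marker, chrom = panel$chrom, pos = panel$pos,
    trait_id = trait_id, n = as.integer(unname(n_used)),
    maf = unname(mafs), beta = unname(beta), p_value = unname(pval),
    neg_log10_p = -log10(unname(pval)), monomorphic = unname(mono)
  )
}

#' Scan every trait in a trait table
#' @inheritParams scan_trait
#' @return Row-bound [scan_trait()] results over all traits.
#' @export
scan_traits <- function(panel, traits, method = c("lm", "anova")) {
  method <- match.arg(method)
  dplyr::bind_rows(lapply(unique(traits$trait_id), function(t)
    scan_trait(panel, traits, t, method = method)))
}

#' Pool the top-K markers per trait
#'
#' Per trait, the `k` smallest p-values are retained (ties broken by larger
#' MAF, then chromosome/position order). Duplicated markers across traits
#' are kept at this stage, so with `t` traits each having at least `k`
#' tested markers the pool has `t * k` rows.
#'
#' @param results Association results from [scan_traits()].
#' @param k Markers kept per trait (default 200).
#' @return The pooled tibble with a per-trait `rank` column.
#' @export
top_k_pool <- function(results, k = 200) {
  stopifnot(k >= 1)
  results |>
    dplyr::group_by(.data$trait_id) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$maf), .data$chrom,
                   .data$pos, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}

#' Deduplicate pooled markers by position
#'
#' One entry per (chrom, pos); the retained row is the one with the
#' smallest p-value across traits (its trait becomes `best_trait`), and
#' `n_traits` counts how many traits listed the position. Output is sorted
#' by chromosome and position; re-applying is the identity.
#'
#' @param pool Pooled tibble from [top_k_pool()].
#' @return Deduplicated tibble with columns of `pool` plus `best_trait`
#'   and `n_traits`.
#' @export
dedup_positions <- function(pool) {
  out <- pool |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::arrange(.data$p_value, dplyr::desc(.data$maf), .data$trait_id,
                   .by_group = TRUE)
  if (!"n_traits" %in% names(pool)) {
    # already-deduplicated inputs keep their recorded trait counts
    out <- dplyr::mutate(out, n_traits = dplyr::n_distinct(.data$trait_id))
  }
  out |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(best_trait = .data$trait_id) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Annotation- and spacing-aware candidate selection
#'
#' Greedy pick over the deduplicated list, ordered by genic class priority
#' (CDS classes first, then other genic, then the intergenic group) and
#' within a tier by association strength, subject to a minimum spacing from
#' already picked markers on the same chromosome. If `n_target` cannot be
#' reached, the spacing is halved (repeatedly) and the relaxation logged.
#'
#' @param unique_list Deduplicated tibble from [dedup_positions()].
#' @param classes Annotation tibble from [annotate_markers()].
#' @param n_target Number of candidates to select.
#' @param min_spacing_bp Minimum same-chromosome spacing in bp (default 0).
#' @return Candidate tibble (rows of `unique_list` plus `class`, `genic`
#'   and `selection_reason`), ordered by chromosome/position, with
#'   attribute `spacing_relaxations` (numeric vector of spacings tried).
#' @export
select_candidates <- function(unique_list, classes, n_target,
                              min_spacing_bp = 0) {
  if (n_target > nrow(unique_list)) {
    stop("n_target exceeds the candidate list size", call. = FALSE)
  }
  x <- dplyr::left_join(unique_list, classes[, c("marker", "class", "genic")],
                        by = "marker")
  x$class[is.na(x$class)] <- "intergenic"
  x$genic[is.na(x$genic)] <- FALSE
  tier <- ifelse(x$class %in% c("CDS-non-synonymous", "CDS-synonymous"), 1L,
                 ifelse(x$genic, 2L, 3L))
  ord <- order(tier, x$p_value, x$chrom, x$pos)
  picked <- logical(nrow(x))
  pos_by_chrom <- split(seq_len(nrow(x)), x$chrom)
  spacing <- min_spacing_bp
  relaxations <- spacing
  reason <- rep(NA_character_, nrow(x))
  repeat {
    for (i in ord) {
      if (sum(picked) >= n_target) break
      if (picked[i]) next
      sel_same <- picked[pos_by_chrom[[x$chrom[i]]]]
      if (spacing > 0 && any(sel_same)) {
        near <- abs(x$pos[pos_by_chrom[[x$chrom[i]]]][sel_same] - x$pos[i]) < spacing
        if (any(near)) next
      }
      picked[i] <- TRUE
      reason[i] <- if (tier[i] <= 2L) "annotation" else "spacing"
    }
    if (sum(picked) >= n_target || spacing == 0) break
    spacing <- floor(spacing / 2)
    relaxations <- c(relaxations, spacing)
  }
  out <- x[picked, , drop = FALSE]
  out$selection_reason <- reason[picked]
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "spacing_relaxations") <- relaxations
  attr(out, "final_spacing") <- spacing
  out
}
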
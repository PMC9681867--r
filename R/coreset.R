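# Minimal distinguishing (core) marker sets. A marker "separates" a pair of
# varieties iff both calls are non-missing and differ (het vs hom counts as
# different; a missing call never discriminates). Selecting a core set is a
# set-cover problem over the C(n, 2) variety pairs, solved by weighted
# greedy with an identification certificate.

#' Build the pair-discrimination structure of a panel
#'
#' @param panel A [genotype_panel()] with at least two varieties.
#' @return List of class `discrimination_matrix` with elements `markers`
#'   (marker ids), `pairs` (tibble: pair, v1, v2) and `cov` (logical
#'   markers x pairs matrix; `TRUE` where the marker separates the pair).
#' @export
build_discrimination <- function(panel) {
  ids <- variety_ids(panel)
  if (length(ids) < 2) stop("need at least two varieties", call. = FALSE)
  gm <- gt_matrix(panel)  # varieties x markers
  pr <- utils::combn(length(ids), 2)
  np <- ncol(pr)
  cov <- matrix(FALSE, nrow = ncol(gm), ncol = np,
                dimnames = list(colnames(gm), NULL))
  for (j in seq_len(ncol(gm))) {
    g <- gm[, j]
    d <- g[pr[1, ]] != g[pr[2, ]]
    d[is.na(d)] <- FALSE
    cov[j, ] <- d
  }
  structure(list(markers = colnames(gm),
                 pairs = tibble::tibble(pair = seq_len(np),
                                        v1 = ids[pr[1, ]], v2 = ids[pr[2, ]]),
                 cov = cov),
            class = "discrimination_matrix")
}

new_core_set <- function(dm, sel, panel_info = NULL, weights = NULL) {
  cov <- dm$cov
  covered <- rep(FALSE, ncol(cov))
  first_marker <- rep(NA_character_, ncol(cov))
  new_pairs <- integer(length(sel))
  for (k in seq_along(sel)) {
    hit <- cov[sel[k], ] & !covered
    new_pairs[k] <- sum(hit)
    first_marker[hit] <- dm$markers[sel[k]]
    covered <- covered | cov[sel[k], ]
  }
  out <- tibble::tibble(rank = seq_along(sel), marker = dm$markers[sel],
                        pairs_new = new_pairs)
  if (!is.null(panel_info)) {
    out <- dplyr::left_join(out, panel_info, by = "marker")
  }
  if (!is.null(weights)) out$weight <- weights[sel]
  cert <- dm$pairs
  cert$marker <- first_marker
  attr(out, "certificate") <- cert
  attr(out, "unresolved") <- dm$pairs[!covered, , drop = FALSE]
  attr(out, "n_pairs") <- ncol(cov)
  attr(out, "n_covered") <- sum(covered)
  # redundancy: total covered-pair multiplicity over the selected markers
  attr(out, "redundancy") <- if (length(sel) > 0)
    sum(cov[sel, , drop = FALSE]) else 0L
  class(out) <- c("core_set", class(out))
  out
}

greedy_order <- function(dm, weights, required = NULL, size_cap = Inf,
                         rand_pool = 1) {
  cov <- dm$cov
  nm <- nrow(cov)
  uncovered <- rep(TRUE, ncol(cov))
  sel <- integer(0)
  if (!is.null(required)) {
    sel <- match(required, dm$markers)
    if (anyNA(sel)) stop("required marker not in panel", call. = FALSE)
    for (j in sel) uncovered <- uncovered & !cov[j, ]
  }
  while (any(uncovered) && length(sel) < size_cap) {
    gains <- as.vector(cov %*% uncovered)
    gains[sel] <- -1
    if (max(gains) <= 0) break
    if (rand_pool > 1) {
      # randomized-restart mode: sample among the best few candidates
      pool <- order(-gains, -weights)[seq_len(min(rand_pool, nm))]
      pool <- pool[gains[pool] > 0]
      j <- pool[sample.int(length(pool), 1)]
    } else {
      best <- which(gains == max(gains))
      j <- best[order(-weights[best], best)][1]
    }
    sel <- c(sel, j)
    uncovered <- uncovered & !cov[j, ]
  }
  sel
}

#' Greedy minimal distinguishing marker set
#'
#' Classic greedy set cover over the unseparated variety pairs: repeatedly
#' add the marker separating the most still-unseparated pairs, breaking
#' ties by higher weight (PIC by default) and then by panel order. Pairs no
#' marker can separate (e.g. duplicated varieties) are reported in the
#' `unresolved` attribute, never dropped silently. A seeded
#' randomized-restart mode (best of `restarts` runs, each sampling among
#' the top `rand_pool` candidates per step) emulates a random-subset search
#' and can find smaller covers than the deterministic greedy.
#'
#' @param dm A [build_discrimination()] result.
#' @param weights Per-marker tie-break weights (default: PIC is a sensible
#'   choice; equal weights if `NULL`).
#' @param required Marker ids forced into the set first.
#' @param size_cap Maximum set size; the set is reported (with unresolved
#'   pairs) even when the cap stops it short of full coverage.
#' @param restarts Number of randomized restarts (1 = deterministic).
#' @param rand_pool Candidate pool size per randomized step (default 3).
#' @param seed Seed for the randomized mode.
#' @return A `core_set` tibble (rank, marker, pairs_new) with attributes
#'   `certificate` (pair -> first separating marker), `unresolved`,
#'   `n_pairs`, `n_covered` and `redundancy`.
#' @export
greedy_min_set <- function(dm, weights = NULL, required = NULL,
                           size_cap = Inf, restarts = 1, rand_pool = 3,
                           seed = 1) {
  stopifnot(inherits(dm, "discrimination_matrix"))
  if (is.null(weights)) weights <- rep(0, length(dm$markers))
  if (!is.null(names(weights))) weights <- weights[dm$markers]
  weights[is.na(weights)] <- 0
  best_sel <- greedy_order(dm, weights, required, size_cap, rand_pool = 1)
  if (restarts > 1) {
    set.seed(seed)
    score <- function(sel) {
      covered <- sum(colSums(dm$cov[sel, , drop = FALSE]) > 0)
      c(covered, -length(sel))
    }
    best_score <- score(best_sel)
    for (r in seq_len(restarts - 1)) {
      sel <- greedy_order(dm, weights, required, size_cap,
                          rand_pool = rand_pool)
      sc <- score(sel)
      if (sc[1] > best_score[1] ||
          (sc[1] == best_score[1] && sc[2] > best_score[2])) {
        best_sel <- sel
        best_score <- sc
      }
    }
  }
  new_core_set(dm, best_sel, weights = weights)
}

# Per-step score used when growing a nested set beyond full coverage:
# redundancy gain plus trait-evenness entropy gain plus cluster contrast.
grow_scores <- function(dm, in_set, trait_of, contrast, trait_counts) {
  cand <- which(!in_set)
  red <- rowSums(dm$cov[cand, , drop = FALSE])
  red <- red / max(red, 1)
  ent_gain <- numeric(length(cand))
  if (!is.null(trait_of)) {
    ent <- function(cnt) {
      p <- cnt[cnt > 0] / sum(cnt)
      if (length(p) == 0) 0 else -sum(p * log(p))
    }
    e0 <- ent(trait_counts)
    for (i in seq_along(cand)) {
      tr <- trait_of[dm$markers[cand[i]]]
      cnt <- trait_counts
      if (!is.na(tr)) cnt[tr] <- cnt[tr] + 1
      ent_gain[i] <- ent(cnt) - e0
    }
    rng <- max(abs(ent_gain), 1e-12)
    ent_gain <- ent_gain / rng
  }
  ctr <- numeric(length(cand))
  if (!is.null(contrast)) {
    ctr <- contrast[dm$markers[cand]]
    ctr[is.na(ctr)] <- 0
    ctr <- ctr / max(ctr, 1e-12)
  }
  list(cand = cand, score = red + ent_gain + ctr)
}

#' Nested core marker sets
#'
#' Builds the smallest requested set first by [greedy_min_set()], then
#' grows it to each larger size, guaranteeing the subset chain
#' `S_small` ⊂ `S_mid` ⊂ ... ⊂ `S_large`. Markers added beyond full pair
#' coverage are chosen to maximise a blend of (a) coverage redundancy,
#' (b) evenness of per-trait representation (entropy of trait counts,
#' using each marker's best associated trait) and (c) per-cluster
#' allele-frequency contrast when a cluster assignment is supplied.
#'
#' @param panel A [genotype_panel()].
#' @param sizes Strictly descending integer set sizes, e.g. `c(87, 24, 10)`.
#' @param dm Optional precomputed [build_discrimination()] result.
#' @param weights Optional per-marker weights (named; default PIC from
#'   [marker_metrics()]).
#' @param assoc Optional association results ([scan_traits()] output) used
#'   for the trait-evenness term.
#' @param clusters Optional cluster assignment tibble (variety, cluster)
#'   used for the allele-frequency contrast term.
#' @param restarts Randomized restarts for the innermost set (default 10).
#' @param seed Seed for the randomized search.
#' @return Named list of `core_set` objects (largest first, names like
#'   `"F87"`). If the smallest size cannot fully cover all pairs, its
#'   unresolved pairs are reported in the attribute, not raised as an
#'   error.
#' @export
nested_sets <- function(panel, sizes, dm = NULL, weights = NULL,
                        assoc = NULL, clusters = NULL, restarts = 10,
                        seed = 1) {
  if (is.unsorted(rev(sizes), strictly = TRUE)) {
    stop("sizes must be strictly descending", call. = FALSE)
  }
  if (is.null(dm)) dm <- build_discrimination(panel)
  if (is.null(weights)) {
    mm <- marker_metrics(panel)
    weights <- stats::setNames(mm$pic, mm$marker)
  }
  w <- weights[dm$markers]
  w[is.na(w)] <- 0
  trait_of <- NULL
  trait_counts <- NULL
  if (!is.null(assoc)) {
    best <- assoc |>
      dplyr::group_by(.data$marker) |>
      dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    trait_of <- stats::setNames(best$trait_id, best$marker)[dm$markers]
    names(trait_of) <- dm$markers
    trait_counts <- stats::setNames(rep(0L, length(unique(best$trait_id))),
                                    unique(best$trait_id))
  }
  contrast <- NULL
  if (!is.null(clusters)) {
    gm <- gt_matrix(panel)
    cl <- clusters$cluster[match(rownames(gm), clusters$variety)]
    freq_by <- function(g) tapply(g, cl, function(x) mean(x, na.rm = TRUE) / 2)
    fr <- apply(gm, 2, freq_by)
    contrast <- apply(fr, 2, stats::var, na.rm = TRUE)
    names(contrast) <- colnames(gm)
  }

  smallest <- min(sizes)
  base <- greedy_min_set(dm, weights = w, size_cap = smallest,
                         restarts = restarts, seed = seed)
  sel <- match(base$marker, dm$markers)
  sets <- list()
  covered <- colSums(dm$cov[sel, , drop = FALSE]) > 0
  for (s in sort(sizes)) {
    while (length(sel) < s) {
      in_set <- seq_along(dm$markers) %in% sel
      if (all(in_set)) break
      uncovered <- !covered
      if (any(uncovered)) {
        gains <- as.vector(dm$cov %*% uncovered)
        gains[sel] <- -1
        j <- which(gains == max(gains))
        j <- j[order(-w[j], j)][1]
      } else {
        gs <- grow_scores(dm, in_set, trait_of, contrast, trait_counts)
        j <- gs$cand[order(-gs$score, gs$cand)][1]
      }
      sel <- c(sel, j)
      covered <- covered | dm$cov[j, ]
      if (!is.null(trait_of)) {
        tr <- trait_of[dm$markers[j]]
        if (!is.na(tr)) trait_counts[tr] <- trait_counts[tr] + 1
      }
    }
    sets[[paste0("F", s)]] <- new_core_set(dm, sel[seq_len(min(s, length(sel)))],
                                           weights = w)
  }
  rev(sets)
}

#' Verify that a marker set identifies every variety
#'
#' Restricts the panel to `markers` and reports how many varieties carry a
#' unique restricted genotype vector. Two varieties collide when no marker
#' of the set separates them under the missing-call rule; collision groups
#' are the connected components of that relation.
#'
#' @param panel A [genotype_panel()].
#' @param markers Marker ids of the set (a `core_set` is also accepted).
#' @return List of class `ident_report`: `n_varieties`, `n_distinct`,
#'   `collisions` (list of variety-id groups), `min_dissimilarity`
#'   (minimum pairwise allele-sharing distance under the set) and
#'   `markers`.
#' @export
verify_identification <- function(panel, markers) {
  if (inherits(markers, "core_set")) markers <- markers$marker
  ids <- variety_ids(panel)
  n <- length(ids)
  if (length(markers) == 0) {
    return(structure(list(n_varieties = n, n_distinct = if (n > 0) 1L else 0L,
                          collisions = if (n > 1) list(ids) else list(),
                          min_dissimilarity = NA_real_, markers = character(0)),
                     class = "ident_report"))
  }
  sub <- select_markers(panel, markers)
  if (n < 2) {
    return(structure(list(n_varieties = n, n_distinct = n,
                          collisions = list(),
                          min_dissimilarity = NA_real_, markers = markers),
                     class = "ident_report"))
  }
  gm <- gt_matrix(sub)
  pr <- utils::combn(n, 2)
  sep <- logical(ncol(pr))
  for (k in seq_len(ncol(pr))) {
    d <- gm[pr[1, k], ] != gm[pr[2, k], ]
    sep[k] <- any(d, na.rm = TRUE)
  }
  # connected components of the "not separated" graph
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (k in which(!sep)) {
    a <- find(pr[1, k]); b <- find(pr[2, k])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, roots)
  collisions <- unname(groups[lengths(groups) > 1])
  n_distinct <- length(groups)
  dmat <- tryCatch(genotype_distance(sub), error = function(e) NULL)
  min_dis <- if (is.null(dmat)) NA_real_ else min(as.matrix(dmat)[upper.tri(as.matrix(dmat))])
  structure(list(n_varieties = n, n_distinct = n_distinct,
                 collisions = collisions, min_dissimilarity = min_dis,
                 markers = markers),
            class = "ident_report")
}

#' @export
print.ident_report <- function(x, ...) {
  cat(sprintf("Identification report: %d of %d varieties distinct under %d markers\n",
              x$n_distinct, x$n_varieties, length(x$markers)))
  if (length(x$collisions) > 0) {
    cat("Colliding groups:\n")
    for (g in x$collisions) cat("  ", paste(g, collapse = ", "), "\n")
  }
  if (!is.na(x$min_dissimilarity)) {
    cat(sprintf("Minimum pairwise dissimilarity: %.4f\n", x$min_dissimilarity))
  }
  invisible(x)
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Core marker set: %d markers, %d of %d pairs separated\n",
              nrow(x), attr(x, "n_covered"), attr(x, "n_pairs")))
  NextMethod()
}
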
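# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn duncan_mrt Tidy the letter table (one row per cluster).
#' @param x A `dmrt` object.
#' @param ... Unused.
#' @method tidy dmrt
#' @export
tidy.dmrt <- function(x, ...) x$groups

#' @describeIn duncan_mrt One-row model summary (F, p, df, MSE).
#' @method glance dmrt
#' @export
glance.dmrt <- function(x, ...) {
  dplyr::mutate(x$anova, alpha = x$alpha,
                n_letters = length(unique(unlist(strsplit(x$groups$letters, "")))))
}

#' @describeIn cluster_varieties Tidy the assignment table with soft
#'   membership proportions.
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) {
  props <- tibble::as_tibble(x$proportions, .name_repair = "minimal")
  names(props) <- paste0("q_", x$labels)
  dplyr::bind_cols(x$assignments, props)
}

#' @describeIn cluster_varieties One-row clustering summary.
#' @method glance cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, within_ss = x$within_ss,
                 n = nrow(x$assignments),
                 largest_cluster = max(table(x$assignments$cluster)))
}

#' @describeIn verify_identification Tidy collision summary (one row per
#'   colliding group; zero rows when identification is complete).
#' @param x An `ident_report`.
#' @param ... Unused.
#' @method tidy ident_report
#' @export
tidy.ident_report <- function(x, ...) {
  if (length(x$collisions) == 0) {
    return(tibble::tibble(group = integer(0), varieties = character(0),
                          size = integer(0)))
  }
  tibble::tibble(group = seq_along(x$collisions),
                 varieties = vapply(x$collisions, paste, "", collapse = ","),
                 size = lengths(x$collisions))
}

#' @describeIn verify_identification One-row identification summary.
#' @method glance ident_report
#' @export
glance.ident_report <- function(x, ...) {
  tibble::tibble(n_varieties = x$n_varieties, n_distinct = x$n_distinct,
                 n_markers = length(x$markers),
                 complete = x$n_distinct == x$n_varieties,
                 min_dissimilarity = x$min_dissimilarity)
}

#' @describeIn greedy_min_set One-row core-set summary.
#' @param x A `core_set`.
#' @param ... Unused.
#' @method glance core_set
#' @export
glance.core_set <- function(x, ...) {
  tibble::tibble(n_markers = nrow(x), n_pairs = attr(x, "n_pairs"),
                 n_covered = attr(x, "n_covered"),
                 n_unresolved = nrow(attr(x, "unresolved")),
                 redundancy = attr(x, "redundancy"))
}
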
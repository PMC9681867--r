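# Genotype panel: a marker-row tibble. The first five columns describe the
# marker (marker, chrom, pos, ref, alt); every remaining column is one
# variety, holding diploid genotype codes 0 (hom-ref), 1 (het), 2 (hom-alt)
# or NA (missing). Coordinates are 1-based throughout.

PANEL_META_COLS <- c("marker", "chrom", "pos", "ref", "alt")

#' Construct a genotype panel
#'
#' A genotype panel is a tibble with one row per biallelic SNP marker.
#' The columns `marker`, `chrom`, `pos` (1-based), `ref` and `alt` describe
#' the marker; each additional column is a variety whose values are diploid
#' genotype codes: `0` = homozygous reference, `1` = heterozygous,
#' `2` = homozygous alternate, `NA` = missing call.
#'
#' @param x A data frame with the columns described above.
#' @return A tibble of class `genotype_panel`.
#' @examples
#' toy <- worked_toy_panel()
#' genotype_panel(toy$panel)
#' @export
genotype_panel <- function(x) {
  x <- tibble::as_tibble(x)
  missing_meta <- setdiff(PANEL_META_COLS, names(x))
  if (length(missing_meta) > 0) {
    stop("genotype panel lacks column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::relocate(x, dplyr::all_of(PANEL_META_COLS))
  ids <- setdiff(names(x), PANEL_META_COLS)
  if (anyDuplicated(ids)) stop("variety ids must be unique", call. = FALSE)
  if (anyDuplicated(x[, c("chrom", "pos")])) {
    dup <- x[duplicated(x[, c("chrom", "pos")]), c("chrom", "pos")][1, ]
    stop("duplicate marker position at ", dup$chrom, ":", dup$pos, call. = FALSE)
  }
  # sorted within chromosome
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  calls <- as.matrix(x[, ids, drop = FALSE])
  if (length(calls) > 0 && !all(calls %in% c(0L, 1L, 2L) | is.na(calls))) {
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  x[ids] <- lapply(x[ids], as.integer)
  x$pos <- as.integer(x$pos)
  class(x) <- c("genotype_panel", class(tibble::tibble()))
  x
}

new_panel_from_matrix <- function(markers, calls) {
  # calls: markers x varieties integer matrix with variety colnames
  stopifnot(nrow(markers) == nrow(calls))
  genotype_panel(dplyr::bind_cols(tibble::as_tibble(markers),
                                  tibble::as_tibble(as.data.frame(calls))))
}

#' Variety identifiers of a panel
#' @param panel A [genotype_panel()].
#' @return Character vector of variety ids, in column order.
#' @export
variety_ids <- function(panel) setdiff(names(panel), PANEL_META_COLS)

#' Marker metadata of a panel
#' @param panel A [genotype_panel()].
#' @return Tibble with columns marker, chrom, pos, ref, alt.
#' @export
marker_info <- function(panel) {
  tibble::tibble(marker = panel$marker, chrom = panel$chrom, pos = panel$pos,
                 ref = panel$ref, alt = panel$alt)
}

#' Genotype calls as a varieties-by-markers matrix
#'
#' @param panel A [genotype_panel()].
#' @return Integer matrix with one row per variety and one column per
#'   marker (0/1/2/NA codes); dimnames are variety and marker ids.
#' @export
gt_matrix <- function(panel) {
  ids <- variety_ids(panel)
  m <- t(as.matrix(panel[, ids, drop = FALSE]))
  dimnames(m) <- list(ids, panel$marker)
  storage.mode(m) <- "integer"
  m
}

#' Restrict a panel to a subset of markers
#' @param panel A [genotype_panel()].
#' @param markers Character vector of marker ids (order ignored; panel
#'   order is preserved) or a logical/integer row index.
#' @return The restricted `genotype_panel`.
#' @export
select_markers <- function(panel, markers) {
  if (is.character(markers)) {
    missing <- setdiff(markers, panel$marker)
    if (length(missing) > 0) {
      stop("unknown marker(s): ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
    }
    keep <- panel$marker %in% markers
  } else {
    keep <- markers
  }
  genotype_panel(panel[keep, , drop = FALSE])
}

#' Restrict a panel to a subset of varieties
#' @param panel A [genotype_panel()].
#' @param varieties Character vector of variety ids to keep.
#' @return The restricted `genotype_panel`.
#' @export
select_varieties <- function(panel, varieties) {
  missing <- setdiff(varieties, variety_ids(panel))
  if (length(missing) > 0) {
    stop("unknown variety id(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  genotype_panel(panel[, c(PANEL_META_COLS, varieties)])
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("# Genotype panel: %d markers x %d varieties\n",
              nrow(x), length(variety_ids(x))))
  NextMethod()
}
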
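# Per-marker summary metrics and the threshold filter cascade.

#' Minor allele frequency of one marker
#'
#' Allele counts are taken over called diploid genotypes only; a
#' heterozygote contributes one copy of each allele. Returns
#' `min(p, 1 - p)`, so the value is invariant under swapping ref and alt.
#'
#' @param calls Integer vector of 0/1/2/NA genotype codes.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 1, 2, 0))   # 3 alt alleles of 8 -> 0.375
#' @export
compute_maf <- function(calls) {
  called <- calls[!is.na(calls)]
  if (length(called) == 0) stop("all genotypes missing", call. = FALSE)
  p_alt <- sum(called) / (2 * length(called))
  min(p_alt, 1 - p_alt)
}

#' Polymorphism information content of a biallelic marker
#'
#' Botstein's PIC for a biallelic locus with allele frequencies `p = 1 - maf`
#' and `q = maf`: `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`. This is the
#' probability that a random mating is informative for linkage: one parent
#' heterozygous, minus the ambiguous het x het offspring case. Maximal at
#' `maf = 0.5` (PIC = 0.375) and zero only for a monomorphic locus.
#'
#' @param maf Minor allele frequency (vectorised), each in `[0, 0.5]`.
#' @return PIC values in `[0, 0.375]`.
#' @examples
#' compute_pic(0.5)   # 0.375
#' @export
compute_pic <- function(maf) {
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]", call. = FALSE)
  p <- 1 - maf
  q <- maf
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Per-marker summary metrics
#'
#' @param panel A [genotype_panel()].
#' @return Tibble: marker, chrom, pos, n_called, call_rate, missing_rate,
#'   maf, pic. Rates use the number of varieties attempted as denominator;
#'   MAF and PIC are computed over called genotypes only.
#' @export
marker_metrics <- function(panel) {
  ids <- variety_ids(panel)
  gm <- as.matrix(panel[, ids, drop = FALSE])
  n <- length(ids)
  n_called <- rowSums(!is.na(gm))
  alt <- rowSums(gm, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  tibble::tibble(
    marker = panel$marker, chrom = panel$chrom, pos = panel$pos,
    n_called = as.integer(n_called),
    call_rate = n_called / n,
    missing_rate = 1 - n_called / n,
    maf = maf,
    pic = ifelse(is.na(maf), NA_real_, compute_pic(ifelse(is.na(maf), 0, maf)))
  )
}

#' Filter markers on MAF and missingness
#'
#' Keeps markers with `maf > maf_min` and `missing_rate < missing_max`
#' (both strict inequalities). Marker order is preserved and a per-marker
#' keep/drop log is attached as the `filter_log` attribute.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Strict lower MAF threshold (default 0.05).
#' @param missing_max Strict upper missing-rate threshold (default 0.30).
#' @return The filtered [genotype_panel()] (possibly empty) with attribute
#'   `filter_log` (tibble: marker, maf, missing_rate, kept).
#' @export
filter_markers <- function(panel, maf_min = 0.05, missing_max = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1)
  mm <- marker_metrics(panel)
  keep <- !is.na(mm$maf) & mm$maf > maf_min & mm$missing_rate < missing_max
  out <- genotype_panel(panel[keep, , drop = FALSE])
  attr(out, "filter_log") <- tibble::tibble(marker = mm$marker, maf = mm$maf,
                                            missing_rate = mm$missing_rate,
                                            kept = keep)
  out
}
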
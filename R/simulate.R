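# Synthetic variety-panel generator. Emulates the statistical structure of a
# commercial cabbage variety panel: K diverged subpopulations (Balding-
# Nichols allele frequencies), inbred and F1-hybrid varieties, UPOV-style
# QL/QN/PQ traits statistically linked to causal SNPs, and missing calls.

#' Default UPOV-style trait layout
#'
#' Nineteen test-guideline traits in the three UPOV types: QL (qualitative),
#' QN (quantitative) and PQ (pseudo-qualitative). Graded traits carry the
#' integer grade sets used on cabbage DUS score sheets (e.g. grades 3/5/7
#' for leaf attitude); QN traits measured in cm have no grade set and are
#' simulated as continuous values.
#'
#' @return Tibble with columns `trait_id`, `type`, `unit` and `grades`
#'   (list-column of integer grade sets, `NULL` for continuous traits).
#' @export
default_trait_spec <- function() {
  tibble::tibble(
    trait_id = c("QL16", "QL24",
                 "QN01", "QN02", "QN04", "QN05", "QN12", "QN15", "QN19",
                 "QN20", "QN22", "QN27", "QN32",
                 "PQ06", "PQ11", "PQ17", "PQ18", "PQ25", "PQ28"),
    type = c("QL", "QL",
             "QN", "QN", "QN", "QN", "QN", "QN", "QN", "QN", "QN", "QN", "QN",
             "PQ", "PQ", "PQ", "PQ", "PQ", "PQ"),
    unit = c("grade", "grade",
             "cm", "cm", "grade", "cm", "grade", "grade", "cm",
             "cm", "grade", "grade", "cm",
             "grade", "grade", "grade", "grade", "grade", "grade"),
    grades = list(c(1L, 9L), c(1L, 9L),
                  NULL, NULL, c(3L, 5L, 7L), NULL, c(1L, 3L, 5L),
                  c(3L, 5L, 7L), NULL, NULL, c(2L, 3L), c(1L, 3L, 5L, 7L), NULL,
                  c(3L, 4L, 5L), c(1L, 2L, 5L), c(2L, 3L, 4L, 6L, 7L),
                  c(1L, 2L), c(1L, 5L), c(2L, 4L))
  )
}

#' Specify a synthetic variety panel
#'
#' Parameters of the synthetic panel generator. Defaults describe the study
#' system the package targets: 96 commercial cabbage varieties, eight
#' chromosomes, seven subpopulations, a mostly-F1 panel and a genotyping-by-
#' sequencing-like missingness level.
#'
#' @param n_varieties Number of varieties (default 96).
#' @param n_markers Number of biallelic SNP markers (default 2000, a desk-
#'   scale stand-in for a genome-wide SNP set).
#' @param n_chromosomes Number of chromosomes (default 8).
#' @param chrom_length_bp Chromosome length in bp (default 45e6).
#' @param n_clusters Number of subpopulations K (default 7).
#' @param fst Balding-Nichols divergence in `[0, 1)` (default 0.2).
#' @param f1_fraction Fraction of varieties simulated as inbred x inbred F1
#'   hybrids (default 0.8; commercial cabbage is predominantly F1).
#' @param cross_between_clusters If `TRUE`, the two parents of an F1 are
#'   drawn from different clusters; default `FALSE` (within-cluster cross).
#' @param outcrossing If `TRUE`, non-F1 varieties are drawn as random-mating
#'   (Hardy-Weinberg) genotypes instead of fully inbred lines.
#' @param missing_rate Fraction of calls masked as missing (default 0.1).
#' @param marker_bias If `TRUE`, missingness is concentrated on a subset of
#'   low-call-rate markers instead of being uniform.
#' @param maf_floor Minimum ancestral minor allele frequency in `(0, 0.5]`
#'   (default 0.05).
#' @param traits Trait layout tibble as [default_trait_spec()].
#' @param causal_per_trait Causal SNPs per trait (default 5).
#' @param effect_size Standardised trait shift per alternate allele at a
#'   causal SNP (default 1).
#' @param noise_sd Residual standard deviation of the latent trait
#'   (default 1).
#' @param outgroup If `TRUE`, the last cluster is simulated at doubled
#'   divergence to mimic a genetically distant outgroup (e.g. purple types).
#' @param seed RNG seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_varieties = 96, n_markers = 2000, n_chromosomes = 8,
                       chrom_length_bp = 45e6, n_clusters = 7, fst = 0.2,
                       f1_fraction = 0.8, cross_between_clusters = FALSE,
                       outcrossing = FALSE,
                       missing_rate = 0.1, marker_bias = FALSE,
                       maf_floor = 0.05, traits = default_trait_spec(),
                       causal_per_trait = 5, effect_size = 1, noise_sd = 1,
                       outgroup = FALSE, seed = 1) {
  spec <- list(n_varieties = n_varieties, n_markers = n_markers,
               n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
               n_clusters = n_clusters, fst = fst, f1_fraction = f1_fraction,
               cross_between_clusters = cross_between_clusters,
               outcrossing = outcrossing,
               missing_rate = missing_rate, marker_bias = marker_bias,
               maf_floor = maf_floor, traits = tibble::as_tibble(traits),
               causal_per_trait = causal_per_trait, effect_size = effect_size,
               noise_sd = noise_sd, outgroup = outgroup, seed = seed)
  counts <- c("n_varieties", "n_markers", "n_chromosomes", "chrom_length_bp",
              "n_clusters", "causal_per_trait")
  for (nm in counts) {
    if (!is.numeric(spec[[nm]]) || spec[[nm]] < 1) {
      stop(nm, " must be a count >= 1", call. = FALSE)
    }
  }
  if (spec$fst < 0 || spec$fst >= 1) stop("fst must lie in [0, 1)", call. = FALSE)
  for (nm in c("f1_fraction", "missing_rate")) {
    if (spec[[nm]] < 0 || spec[[nm]] >= 1) {
      stop(nm, " must lie in [0, 1)", call. = FALSE)
    }
  }
  if (spec$maf_floor <= 0 || spec$maf_floor > 0.5) {
    stop("maf_floor must lie in (0, 0.5]", call. = FALSE)
  }
  if (spec$causal_per_trait > spec$n_markers) {
    stop("causal_per_trait exceeds n_markers", call. = FALSE)
  }
  if (spec$n_clusters > spec$n_varieties) {
    stop("n_clusters exceeds n_varieties", call. = FALSE)
  }
  class(spec) <- "panel_spec"
  spec
}

# Balding-Nichols cluster frequency: Beta(p(1-F)/F, (1-p)(1-F)/F)
bn_freq <- function(p, fst) {
  if (fst == 0) return(p)
  stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate a structured variety panel with linked traits
#'
#' Generates a genotype panel, a trait table and a ground-truth record under
#' a Balding-Nichols subpopulation model. Markers are placed at sorted
#' unique positions over the chromosomes; each cluster draws its allele
#' frequencies around an ancestral frequency with minor allele frequency at
#' least `maf_floor`. Inbred varieties are homozygous (one allele drawn per
#' locus); F1 varieties combine two inbred parents and are heterozygous
#' exactly where the parents differ. QN traits are sums of additive causal
#' effects on the 0/1/2 genotype plus Gaussian noise; graded QL/PQ traits
#' threshold the same latent score onto their integer grade set. Missing
#' calls are masked after trait construction. The same spec and seed always
#' reproduce the same output.
#'
#' @param spec A [panel_spec()].
#' @return List with elements `panel` (a [genotype_panel()]), `traits`
#'   (tibble: variety, trait_id, type, value) and `truth` (list with variety
#'   cluster labels, causal-marker effects and F1 parental genotypes).
#' @examples
#' sim <- simulate_panel(panel_spec(n_varieties = 12, n_markers = 50,
#'                                  n_clusters = 2, seed = 7))
#' sim$panel
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  m <- spec$n_markers
  n <- spec$n_varieties
  K <- spec$n_clusters

  # marker placement: spread over chromosomes, sorted unique positions
  chrom <- sprintf("C%d", sort(rep_len(seq_len(spec$n_chromosomes), m)))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(spec$chrom_length_bp, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- unname(vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1)))
  markers <- tibble::tibble(marker = paste0(chrom, "_", pos),
                            chrom = chrom, pos = pos, ref = ref, alt = alt)

  # ancestral and per-cluster allele frequencies (alt-allele frequency)
  p0 <- stats::runif(m, spec$maf_floor, 1 - spec$maf_floor)
  fst_k <- rep(spec$fst, K)
  if (spec$outgroup && K > 1) fst_k[K] <- min(0.6, 2 * spec$fst)
  pk <- vapply(seq_len(K), function(k) bn_freq(p0, fst_k[k]), numeric(m))
  pk <- matrix(pk, nrow = m)

  cluster_of <- sort(rep_len(seq_len(K), n))
  variety <- sprintf("V%03d", seq_len(n))
  n_f1 <- round(spec$f1_fraction * n)
  is_f1 <- seq_len(n) %in% sample.int(n, n_f1)

  draw_inbred <- function(p) 2L * stats::rbinom(m, 1L, p)
  draw_outbred <- function(p) stats::rbinom(m, 1L, p) + stats::rbinom(m, 1L, p)

  calls <- matrix(NA_integer_, nrow = m, ncol = n, dimnames = list(NULL, variety))
  parents <- list()
  for (i in seq_len(n)) {
    k <- cluster_of[i]
    if (is_f1[i]) {
      k2 <- k
      if (spec$cross_between_clusters && K > 1) {
        k2 <- sample(setdiff(seq_len(K), k), 1)
      }
      pa <- draw_inbred(pk[, k])
      pb <- draw_inbred(pk[, k2])
      calls[, i] <- as.integer((pa + pb) / 2L)  # 0/2 parents -> 0/1/2 offspring
      parents[[variety[i]]] <- list(a = pa, b = pb)
    } else if (spec$outcrossing) {
      calls[, i] <- draw_outbred(pk[, k])
    } else {
      calls[, i] <- draw_inbred(pk[, k])
    }
  }

  # traits before masking: additive causal score per trait
  tr <- spec$traits
  causal <- vector("list", nrow(tr))
  trait_rows <- vector("list", nrow(tr))
  for (t in seq_len(nrow(tr))) {
    cm <- sample.int(m, spec$causal_per_trait)
    eff <- rep(spec$effect_size, spec$causal_per_trait)
    score <- as.numeric(crossprod(calls[cm, , drop = FALSE], eff))
    latent <- score + stats::rnorm(n, 0, spec$noise_sd)
    grades <- tr$grades[[t]]
    if (is.null(grades)) {
      value <- latent
    } else {
      # threshold latent score at equally spaced quantiles onto the grade set
      qs <- stats::quantile(latent, probs = seq(0, 1, length.out = length(grades) + 1))
      qs[1] <- -Inf; qs[length(qs)] <- Inf
      value <- as.numeric(grades[cut(latent, breaks = unique(qs),
                                     labels = FALSE, include.lowest = TRUE)])
    }
    causal[[t]] <- tibble::tibble(trait_id = tr$trait_id[t],
                                  marker = markers$marker[cm], effect = eff)
    trait_rows[[t]] <- tibble::tibble(variety = variety,
                                      trait_id = tr$trait_id[t],
                                      type = tr$type[t], value = value)
  }
  traits <- dplyr::bind_rows(trait_rows)

  # missingness masking
  if (spec$missing_rate > 0) {
    if (spec$marker_bias) {
      # a third of markers carry three times the missingness of the rest
      rate <- rep(spec$missing_rate / (1 + 2 / 3), m)
      bad <- sample.int(m, ceiling(m / 3))
      rate[bad] <- 3 * rate[bad]
      mask <- matrix(stats::runif(m * n) < rate, nrow = m)
    } else {
      mask <- matrix(stats::runif(m * n) < spec$missing_rate, nrow = m)
    }
    calls[mask] <- NA_integer_
  }

  panel <- new_panel_from_matrix(markers, calls)
  # panel rows are sorted by (chrom, pos); chrom labels C1..C8 sort as text,
  # which matches the generation order here (single-digit chromosome count)
  truth <- list(
    clusters = tibble::tibble(variety = variety, cluster = cluster_of,
                              is_f1 = is_f1),
    causal = dplyr::bind_rows(causal),
    parents = parents
  )
  list(panel = panel, traits = traits, truth = truth)
}

#' Hand-written six-variety toy panel
#'
#' A fixed 6-variety, 8-marker panel with one quantitative (QN) and one
#' qualitative (QL) trait, used throughout examples and tests. All genotype
#' rows are pairwise distinct and marker `m1` has a minor allele frequency
#' of 0.25 (3 alternate alleles out of 12).
#'
#' @return List with `panel` (a [genotype_panel()]) and `traits` (tibble).
#' @export
worked_toy_panel <- function() {
  markers <- tibble::tibble(
    marker = paste0("m", 1:8),
    chrom = c("C1", "C1", "C1", "C2", "C2", "C3", "C3", "C4"),
    pos = c(100L, 2500L, 9000L, 400L, 7000L, 1200L, 5000L, 3000L),
    ref = c("A", "C", "G", "T", "A", "G", "C", "T"),
    alt = c("T", "G", "A", "C", "G", "T", "A", "A")
  )
  calls <- matrix(c(
    # v1 v2 v3 v4 v5 v6
    0L, 0L, 0L, 1L, 2L, 0L,   # m1: alt 3/12 -> MAF 0.25
    0L, 1L, 2L, 2L, 1L, 0L,   # m2
    2L, 2L, 0L, 0L, 1L, 1L,   # m3
    0L, 0L, 1L, 1L, 0L, 2L,   # m4
    1L, 0L, 0L, 2L, 2L, 2L,   # m5
    0L, 2L, 2L, 0L, 0L, 1L,   # m6
    2L, 0L, 1L, 0L, 2L, 0L,   # m7
    0L, 1L, 0L, 2L, 0L, 2L    # m8
  ), nrow = 8, byrow = TRUE,
  dimnames = list(NULL, paste0("v", 1:6)))
  panel <- new_panel_from_matrix(markers, calls)
  traits <- tibble::tibble(
    variety = rep(paste0("v", 1:6), 2),
    trait_id = rep(c("QN20", "QL16"), each = 6),
    type = rep(c("QN", "QL"), each = 6),
    value = c(14.2, 16.5, 21.0, 24.8, 18.3, 27.1,
              1, 1, 9, 9, 1, 9)
  )
  list(panel = panel, traits = traits)
}

#' Write the ground-truth record of a simulated panel to JSON
#' @param truth The `truth` element returned by [simulate_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(clusters = truth$clusters, causal = truth$causal,
              parents = lapply(truth$parents, function(p)
                list(a = p$a, b = p$b)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
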
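# End-to-end orchestration of the marker funnel, plus the cascade summary
# table used to report stage counts and annotation-class percentages.

#' Pipeline run configuration
#'
#' Thresholds follow the standard funnel: MAF > 0.05 with missingness
#' < 30% for the association panel, missingness < 10% for the structure
#' panel, top 200 markers per trait, nested core sizes 87/24/10 and a 0.05
#' significance gate for cluster-trait evaluation.
#'
#' @param maf_min Strict lower MAF threshold.
#' @param missing_assoc Strict missingness cap for the association panel.
#' @param missing_struct Strict missingness cap for the structure panel.
#' @param top_k Markers kept per trait in the pooling stage.
#' @param n_candidates Candidate markers to select (capped at the
#'   deduplicated list size at run time).
#' @param min_spacing_bp Candidate spacing in bp.
#' @param core_sizes Strictly descending nested core-set sizes.
#' @param k_clusters Number of population clusters.
#' @param alpha DMRT / ANOVA significance level.
#' @param bootstrap Bootstrap replicates for the NJ tree (0 disables).
#' @param restarts Randomized restarts for the core-set search.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(maf_min = 0.05, missing_assoc = 0.30,
                       missing_struct = 0.10, top_k = 200,
                       n_candidates = 348, min_spacing_bp = 0,
                       core_sizes = c(87, 24, 10), k_clusters = 7,
                       alpha = 0.05, bootstrap = 100, restarts = 10,
                       seed = 1) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            missing_assoc >= 0, missing_assoc <= 1,
            missing_struct >= 0, missing_struct <= 1,
            top_k >= 1, alpha > 0, alpha < 1)
  if (is.unsorted(rev(core_sizes), strictly = TRUE)) {
    stop("core_sizes must be strictly descending", call. = FALSE)
  }
  structure(list(maf_min = maf_min, missing_assoc = missing_assoc,
                 missing_struct = missing_struct, top_k = top_k,
                 n_candidates = n_candidates,
                 min_spacing_bp = min_spacing_bp, core_sizes = core_sizes,
                 k_clusters = k_clusters, alpha = alpha,
                 bootstrap = bootstrap, restarts = restarts, seed = seed),
            class = "run_config")
}

# Stable per-stage seed derived from the global seed and the stage name,
# so stages are reproducible independently of each other.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147483647L
}

#' Run the full core-marker pipeline
#'
#' Filter -> per-trait association -> top-K pooling -> positional dedup ->
#' candidate selection -> nested core sets -> trees -> clustering ->
#' cluster-trait evaluation -> reference database. Every intermediate
#' artifact is written under `out_dir` and listed in the JSON manifest,
#' together with the stage counts of the funnel. The same configuration
#' and seed always reproduce identical counts.
#'
#' @param panel A [genotype_panel()] (unfiltered genotype matrix).
#' @param traits Long trait tibble (variety, trait_id, type, value).
#' @param annotation Optional interval tibble ([read_annotation()]).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return List of class `run_report`: `manifest` (named list), plus the
#'   in-memory stage objects (`filtered`, `assoc`, `pool`, `deduped`,
#'   `candidates`, `core_sets`, `trees`, `clusters`, `dmrt`,
#'   `explanations`).
#' @export
run_pipeline <- function(panel, traits, annotation = NULL,
                         config = run_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name, writer = readr::write_tsv) {
    path <- file.path(out_dir, name)
    writer(x, path)
    files[[length(files) + 1]] <<- name
    path
  }

  n_input <- nrow(panel)
  assoc_panel <- filter_markers(panel, config$maf_min, config$missing_assoc)
  struct_panel <- filter_markers(panel, config$maf_min, config$missing_struct)
  emit(marker_metrics(assoc_panel), "filtered_metrics.tsv")

  assoc <- scan_traits(assoc_panel, traits)
  emit(assoc, "association.tsv")
  pool <- top_k_pool(assoc, k = config$top_k)
  deduped <- dedup_positions(pool)
  emit(deduped, "deduped.tsv")

  classes <- if (!is.null(annotation)) {
    annotate_markers(assoc_panel, annotation)
  } else {
    info <- marker_info(assoc_panel)
    tibble::tibble(marker = info$marker, chrom = info$chrom, pos = info$pos,
                   class = "intergenic", genic = FALSE)
  }
  n_cand <- min(config$n_candidates, nrow(deduped))
  candidates <- select_candidates(deduped, classes, n_target = n_cand,
                                  min_spacing_bp = config$min_spacing_bp)
  emit(candidates, "candidates.tsv")

  cand_panel <- select_markers(panel, candidates$marker)
  struct_seed <- stage_seed(config$seed, "cluster")
  clusters <- cluster_varieties(struct_panel, k = config$k_clusters,
                                seed = struct_seed)
  core_sizes <- config$core_sizes[config$core_sizes <= nrow(cand_panel)]
  core_sets <- nested_sets(cand_panel, sizes = core_sizes,
                           assoc = assoc[assoc$marker %in% candidates$marker, ],
                           clusters = clusters$assignments,
                           restarts = config$restarts,
                           seed = stage_seed(config$seed, "coreset"))
  unresolved <- lapply(core_sets, function(s) nrow(attr(s, "unresolved")))
  for (nm in names(core_sets)) {
    emit(tibble::as_tibble(core_sets[[nm]]), paste0("core_", nm, ".tsv"))
    cert <- attr(core_sets[[nm]], "certificate")
    jsonlite::write_json(cert, file.path(out_dir, paste0("certificate_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    files[[length(files) + 1]] <- paste0("certificate_", nm, ".json")
  }
  if (any(unlist(unresolved) > 0)) {
    warning("unresolved variety pairs remain in: ",
            paste(names(core_sets)[unlist(unresolved) > 0], collapse = ", "),
            call. = FALSE)
  }

  trees <- list()
  for (nm in names(core_sets)) {
    sub <- select_markers(panel, core_sets[[nm]]$marker)
    tr <- upgma_tree(genotype_distance(sub))
    trees[[nm]] <- tr
    path <- file.path(out_dir, paste0("upgma_", nm, ".nwk"))
    ape::write.tree(tr, path)
    files[[length(files) + 1]] <- basename(path)
  }
  largest <- names(core_sets)[1]
  big_panel <- select_markers(panel, core_sets[[largest]]$marker)
  if (config$bootstrap > 0 && length(variety_ids(big_panel)) >= 3) {
    nj <- bootstrap_support(big_panel, "nj", n_reps = config$bootstrap,
                            seed = stage_seed(config$seed, "bootstrap"))
  } else if (length(variety_ids(big_panel)) >= 3) {
    nj <- nj_tree(genotype_distance(big_panel))
  } else nj <- NULL
  if (!is.null(nj)) {
    ape::write.tree(nj, file.path(out_dir, "nj_core.nwk"))
    files[[length(files) + 1]] <- "nj_core.nwk"
    trees$nj <- nj
  }

  # per-core-set clustering and cluster-trait evaluation
  trait_ids <- unique(traits$trait_id)
  dmrt <- list()
  cluster_models <- list(GBS = clusters)
  for (nm in names(core_sets)) {
    sub <- select_markers(panel, core_sets[[nm]]$marker)
    cm <- cluster_varieties(sub, k = min(config$k_clusters,
                                         length(variety_ids(sub))),
                            seed = struct_seed)
    cluster_models[[nm]] <- cm
    dmrt[[nm]] <- list()
    for (tr_id in trait_ids) {
      tt <- traits[traits$trait_id == tr_id, ]
      dat <- dplyr::inner_join(tt, cm$assignments, by = "variety")
      res <- tryCatch(duncan_mrt(dat, value, cluster, alpha = config$alpha),
                      error = function(e) NULL)
      if (!is.null(res)) dmrt[[nm]][[tr_id]] <- res
    }
  }
  explanations <- explain_traits(dmrt, alpha = config$alpha)
  emit(explanations, "trait_explanations.tsv")
  emit(clusters$assignments, "clusters.tsv")
  write_reference_db(select_markers(panel, core_sets[[largest]]$marker),
                     file.path(out_dir, "reference_db.tsv"))
  files[[length(files) + 1]] <- "reference_db.tsv"

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    counts = list(
      input_markers = n_input,
      assoc_markers = nrow(assoc_panel),
      struct_markers = nrow(struct_panel),
      pooled = nrow(pool),
      deduped = nrow(deduped),
      candidates = nrow(candidates),
      core_sizes = vapply(core_sets, nrow, integer(1)),
      unresolved_pairs = unlist(unresolved),
      n_varieties = length(variety_ids(panel)),
      n_traits = length(trait_ids),
      explained_traits = sum(explanations$explained[explanations$best])
    ),
    files = unlist(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(manifest = manifest, filtered = assoc_panel,
                 struct_panel = struct_panel, assoc = assoc, pool = pool,
                 deduped = deduped, candidates = candidates,
                 core_sets = core_sets, trees = trees,
                 clusters = cluster_models, dmrt = dmrt,
                 explanations = explanations, out_dir = out_dir),
            class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cascade summary with class percentages
#'
#' Renders stage counts with one-decimal percentages. The input is a
#' tibble with columns `stage`, `class` and `count`; percentages are
#' computed within stage over the top-level classes, so the genic and
#' intergenic group rows always sum to 100% (up to rounding). A stage's
#' total is the sum of its subclass counts unless a `total` row is
#' present.
#'
#' @param counts Tibble: stage, class, count.
#' @return Tibble: stage, class, count, pct (percent, 1 decimal).
#' @export
summarize_cascade <- function(counts) {
  top <- c("Genic region", "Intergenic region")
  counts |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(
      total = dplyr::if_else(rep(any(.data$class %in% top), dplyr::n()),
                             sum(.data$count[.data$class %in% top]),
                             sum(.data$count)),
      pct = round(100 * .data$count / .data$total, 1)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"total")
}

#' Sequencing run summary statistics
#'
#' Derives per-variety averages from a sequencing run summary table
#' (metric/value rows), e.g. the mean number of demultiplexed reads per
#' variety = total demultiplexed reads / number of samples (rounded to a
#' whole read).
#'
#' @param summary_tbl Tibble with columns `metric` and `value`.
#' @return Tibble with `reads_per_variety` and the inputs used.
#' @export
sequencing_summary <- function(summary_tbl) {
  get <- function(m) {
    v <- summary_tbl$value[summary_tbl$metric == m]
    if (length(v) != 1) stop("metric not found: ", m, call. = FALSE)
    as.numeric(v)
  }
  total <- get("total_demultiplexed_reads")
  n <- get("n_samples")
  tibble::tibble(n_samples = n, total_demultiplexed_reads = total,
                 reads_per_variety = round(total / n))
}
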
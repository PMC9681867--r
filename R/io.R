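# Readers and writers for the formats the pipeline touches: VCF, trait
# tables, annotation intervals, IUPAC genotype FASTA and the reference-
# variety database TSV. All coordinates are 1-based inclusive.

ANNOTATION_CLASSES <- c("CDS-non-synonymous", "CDS-synonymous", "splice",
                        "intron", "up/downstream", "upstream", "downstream",
                        "intergenic")
GENIC_CLASSES <- c("CDS-non-synonymous", "CDS-synonymous", "splice", "intron")

#' Read a VCF file into a genotype panel
#'
#' Loads biallelic SNP records from a VCFv4.2 file with a diploid GT field.
#' Multiallelic records and indels are skipped (their count is reported as
#' a message and stored in the `n_skipped` attribute). Phased (`0|1`) and
#' unphased (`0/1`) genotypes are treated identically.
#'
#' @param path Path to a VCF file.
#' @return A [genotype_panel()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  if (nrow(fix) == 0) stop("no records in VCF: ", path, call. = FALSE)
  if (!"GT" %in% rownames(v@gt) && !grepl("GT", v@gt[1, "FORMAT"])) {
    stop("VCF has no GT format field", call. = FALSE)
  }
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  fix <- fix[snp, , drop = FALSE]
  key <- paste(fix$CHROM, fix$POS)
  if (anyDuplicated(key)) {
    stop("duplicate site in VCF: ", key[duplicated(key)][1], call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- apply(gt, 2, code)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list(NULL, colnames(gt)))
  markers <- tibble::tibble(
    marker = paste0(fix$CHROM, "_", fix$POS),
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT
  )
  panel <- new_panel_from_matrix(markers, calls)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a genotype panel as VCFv4.2
#'
#' Emits a minimal VCFv4.2 with unphased diploid GT calls and `./.` for
#' missing genotypes, so that `read_vcf(write_vcf(p)) == p`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  ids <- variety_ids(panel)
  gm <- as.matrix(panel[, ids, drop = FALSE])
  gt <- matrix("./.", nrow = nrow(gm), ncol = ncol(gm))
  gt[gm == 0L] <- "0/0"
  gt[gm == 1L] <- "0/1"
  gt[gm == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos, panel$marker, panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

IUPAC_PAIR <- c("AA" = "A", "CC" = "C", "GG" = "G", "TT" = "T",
                "AC" = "M", "CA" = "M", "AG" = "R", "GA" = "R",
                "AT" = "W", "TA" = "W", "CG" = "S", "GC" = "S",
                "CT" = "Y", "TC" = "Y", "GT" = "K", "TG" = "K")

#' Encode one variety's genotypes as an IUPAC string
#'
#' One character per marker: homozygous calls give the allele letter,
#' heterozygous calls the IUPAC ambiguity code (A/T = W, C/G = S, A/C = M,
#' G/T = K, A/G = R, C/T = Y) and missing calls `N`.
#'
#' @param panel A [genotype_panel()].
#' @param variety A variety id present in the panel.
#' @return A single string of length `nrow(panel)`.
#' @export
encode_iupac <- function(panel, variety) {
  if (!variety %in% variety_ids(panel)) {
    stop("unknown variety: ", variety, call. = FALSE)
  }
  g <- panel[[variety]]
  a1 <- ifelse(g == 2L, panel$alt, panel$ref)
  a2 <- ifelse(g == 0L, panel$ref, panel$alt)
  key <- paste0(a1, a2)
  ch <- unname(IUPAC_PAIR[key])
  if (any(is.na(ch) & !is.na(g))) {
    bad <- which(is.na(ch) & !is.na(g))[1]
    stop("unknown allele pair at marker ", panel$marker[bad], call. = FALSE)
  }
  ch[is.na(g)] <- "N"
  paste(ch, collapse = "")
}

#' Write all varieties as an IUPAC genotype FASTA
#' @param panel A [genotype_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotype_fasta <- function(panel, path) {
  ids <- variety_ids(panel)
  lines <- unlist(lapply(ids, function(v) c(paste0(">", v),
                                            encode_iupac(panel, v))))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read the reference-variety genotype database
#'
#' The database is a TSV with the marker metadata columns followed by one
#' two-letter genotype column per variety (`AA`, `AT`, ...; missing written
#' as `NN`). `read_reference_db(write_reference_db(p)) == p`.
#'
#' @param panel A [genotype_panel()].
#' @param path TSV file path.
#' @return `write_reference_db()` returns `path` invisibly;
#'   `read_reference_db()` returns a [genotype_panel()].
#' @export
write_reference_db <- function(panel, path) {
  ids <- variety_ids(panel)
  out <- marker_info(panel)
  for (v in ids) {
    g <- panel[[v]]
    a1 <- ifelse(g == 2L, panel$alt, panel$ref)
    a2 <- ifelse(g == 0L, panel$ref, panel$alt)
    cell <- paste0(a1, a2)
    cell[is.na(g)] <- "NN"
    out[[v]] <- cell
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                               marker = "c", pos = "i",
                                               .default = "c"))
  if (!all(PANEL_META_COLS %in% names(x))) {
    stop("malformed reference DB header in ", path, call. = FALSE)
  }
  ids <- setdiff(names(x), PANEL_META_COLS)
  for (v in ids) {
    cell <- x[[v]]
    g <- rep(NA_integer_, length(cell))
    g[cell == paste0(x$ref, x$ref)] <- 0L
    g[cell == paste0(x$alt, x$alt)] <- 2L
    het <- cell == paste0(x$ref, x$alt) | cell == paste0(x$alt, x$ref)
    g[het] <- 1L
    x[[v]] <- g
  }
  genotype_panel(x)
}

#' Read / write a long-format trait table
#'
#' Trait tables are TSVs with columns `variety`, `trait_id`, `type`
#' (QL/QN/PQ) and numeric `value` (grades as printed integers).
#'
#' @param path TSV file path.
#' @param traits Trait tibble to write.
#' @return `read_trait_table()` returns a tibble; `write_trait_table()`
#'   returns `path` invisibly.
#' @export
read_trait_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(variety = "c", trait_id = "c",
                                               type = "c", value = "d"))
  bad <- setdiff(unique(x$type), c("QL", "QN", "PQ"))
  if (length(bad) > 0) {
    stop("unknown trait type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(traits, path) {
  readr::write_tsv(traits[, c("variety", "trait_id", "type", "value")], path)
  invisible(path)
}

#' Read an annotation interval table
#'
#' A BED-like TSV with columns `chrom`, `start`, `end` (1-based inclusive)
#' and `class`, where class is one of the annotation vocabulary:
#' CDS-synonymous, CDS-non-synonymous, splice, intron, intergenic,
#' upstream, downstream, up/downstream.
#'
#' @param path TSV file path.
#' @return Tibble of intervals.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(chrom = "c", start = "i",
                                               end = "i", class = "c"))
  bad <- setdiff(unique(x$class), ANNOTATION_CLASSES)
  if (length(bad) > 0) {
    stop("unknown annotation class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Assign one annotation class per marker
#'
#' Each marker gets exactly one class by interval lookup. Markers outside
#' every interval are `intergenic`. When overlapping intervals disagree the
#' precedence is CDS-non-synonymous > CDS-synonymous > splice > intron >
#' up/downstream > upstream > downstream > intergenic. The `genic` column
#' rolls the classes up into the two-level grouping (genic = CDS/splice/
#' intron; everything else counts as the intergenic group).
#'
#' @param panel A [genotype_panel()].
#' @param annotation Interval tibble as from [read_annotation()].
#' @return Tibble: marker, chrom, pos, class, genic.
#' @export
annotate_markers <- function(panel, annotation) {
  info <- marker_info(panel)
  cls <- rep("intergenic", nrow(info))
  for (cc in unique(info$chrom)) {
    ann <- annotation[annotation$chrom == cc, , drop = FALSE]
    if (nrow(ann) == 0) next
    idx <- which(info$chrom == cc)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = info$pos[idx], width = 1L),
      IRanges::IRanges(start = ann$start, end = ann$end)
    )
    if (length(hits) == 0) next
    h <- tibble::tibble(q = S4Vectors::queryHits(hits),
                        class = ann$class[S4Vectors::subjectHits(hits)])
    h$prec <- match(h$class, ANNOTATION_CLASSES)
    best <- dplyr::summarise(dplyr::group_by(h, .data$q),
                             class = .data$class[which.min(.data$prec)],
                             .groups = "drop")
    cls[idx[best$q]] <- best$class
  }
  tibble::tibble(marker = info$marker, chrom = info$chrom, pos = info$pos,
                 class = cls, genic = cls %in% GENIC_CLASSES)
}
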
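# Shared fixtures, built in code at test time.

toy <- worked_toy_panel()

# tiny VCF text written to a temp file on demand
write_toy_vcf <- function(lines = NULL) {
  path <- tempfile(fileext = ".vcf")
  if (is.null(lines)) {
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tva\tvb\tvc",
      "C1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0|1\t1/1",
      "C1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t./.\t0/1"
    )
  }
  writeLines(lines, path)
  path
}

# brute-force oracle for PIC: enumerate parental genotypes and offspring;
# a mating is informative iff one chosen parent is heterozygous and the
# offspring genotype identifies the transmitted parental allele (the only
# ambiguous case is het x het producing a het offspring).
pic_oracle <- function(maf) {
  q <- maf; p <- 1 - maf
  gprob <- c(hom1 = p^2, het = 2 * p * q, hom2 = q^2)
  total <- 0
  for (m in names(gprob)) for (f in names(gprob)) {
    if (m != "het") next
    pm <- gprob[[m]] * gprob[[f]]
    if (f == "het") {
      # offspring het with prob 1/2 -> uninformative
      total <- total + pm * 0.5
    } else {
      total <- total + pm
    }
  }
  total
}

# from-scratch simple-regression F-test (explicit sums of squares)
ols_f_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  ssr <- sxy^2 / sxx
  sse <- syy - ssr
  f <- ssr / (sse / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

# exhaustive minimum set cover size over a logical coverage matrix
# (markers x pairs), considering only coverable pairs
exact_min_cover <- function(cov) {
  coverable <- colSums(cov) > 0
  cov <- cov[, coverable, drop = FALSE]
  if (ncol(cov) == 0) return(0L)
  m <- nrow(cov)
  for (k in 1:m) {
    for (sub in utils::combn(m, k, simplify = FALSE)) {
      if (all(colSums(cov[sub, , drop = FALSE]) > 0)) return(k)
    }
  }
  m
}

# random additive (tree) metric from a random topology
random_additive_metric <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.1, 1))
  tr <- ape::unroot(tr)
  dm <- stats::as.dist(ape::cophenetic.phylo(tr))
  list(tree = tr, dm = dm)
}

# Duncan significant-ranges oracle from printed studentized-range tables
# (alpha = 0.05 protection levels, error df = 20, spans 2..4)
DUNCAN_SSR_DF20 <- c(`2` = 2.95, `3` = 3.10, `4` = 3.18)

sim_small <- function(seed = 1, ...) {
  simulate_panel(panel_spec(n_varieties = 24, n_markers = 120,
                            n_clusters = 3, seed = seed, ...))
}
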
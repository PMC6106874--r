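# geno_matrix: samples x SNPs container for A1-allele counts ----------------

#' Construct a genotype matrix object
#'
#' A `geno_matrix` holds a samples x SNPs matrix of A1-allele counts
#' (0, 1, 2 or `NA` for missing) together with marker and sample metadata.
#' A1 is the counted allele throughout the package (the `.bim` first-allele
#' convention); minor-allele frequency is always reported as
#' `min(freq(A1), 1 - freq(A1))`.
#'
#' @param values Integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}` (or `{0, 1, NA}` when `haploid = TRUE`).
#' @param marker Data frame with one row per SNP: columns `snp`, `chr`, `pos`
#'   (1-based), `a1`, `a2`.
#' @param samples Data frame with one row per sample: columns `sample_id`,
#'   `sex` (1 male, 2 female, 0 unknown), `pheno`.
#' @param haploid Logical; `TRUE` for hemizygous pseudo-X matrices whose
#'   entries are single-allele counts in `{0, 1}`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(values, marker, samples, haploid = FALSE) {
  values <- as.matrix(values)
  marker <- as_tibble(marker)
  samples <- as_tibble(samples)
  if (ncol(values) != nrow(marker)) {
    stop_dyad("marker table rows must equal genotype columns", "dim")
  }
  if (nrow(values) != nrow(samples)) {
    stop_dyad("sample table rows must equal genotype rows", "dim")
  }
  if (any(marker$a1 == marker$a2)) {
    stop_dyad("alleles A1 and A2 must differ per SNP", "alleles")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > (if (haploid) 1 else 2)) {
    stop_dyad("genotype values out of range", "range")
  }
  rownames(values) <- samples$sample_id
  colnames(values) <- marker$snp
  structure(
    list(values = values, marker = marker, samples = samples,
         haploid = haploid),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (%s)\n",
    nrow(x$values), ncol(x$values),
    if (x$haploid) "haploid" else "diploid"
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by sample and/or marker index
#'
#' @param x A `geno_matrix`.
#' @param i,j Sample / marker indices (any standard index vector).
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the selected rows and columns.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  geno_matrix(
    x$values[i, j, drop = FALSE],
    x$marker[j, , drop = FALSE],
    x$samples[i, , drop = FALSE],
    haploid = x$haploid
  )
}

# pseudo_haploid: 0/1 allele matrix from duo partitioning --------------------

#' Construct a pseudo-haploid allele matrix
#'
#' Holds one allele per sample per SNP (A1 count in `{0, 1}`, `NA` when the
#' allele could not be resolved), as produced by [partition_cohort()]. The
#' provenance tag records whether the alleles are maternal non-transmitted or
#' fetal non-maternal (paternally inherited).
#'
#' @param values Matrix of 0/1/NA allele counts, samples x SNPs.
#' @param marker Marker metadata (as in [geno_matrix()]).
#' @param samples Sample metadata.
#' @param provenance `"maternal_non_transmitted"` or `"fetal_non_maternal"`.
#' @return An object of class `pseudo_haploid`.
#' @export
pseudo_haploid <- function(values, marker, samples,
                           provenance = c("maternal_non_transmitted",
                                          "fetal_non_maternal")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (any(values == 2, na.rm = TRUE)) {
    stop_dyad("pseudo-haploid values must be 0/1/NA", "range")
  }
  marker <- as_tibble(marker)
  samples <- as_tibble(samples)
  rownames(values) <- samples$sample_id
  colnames(values) <- marker$snp
  structure(
    list(values = values, marker = marker, samples = samples,
         provenance = provenance,
         resolved_fraction = colMeans(!is.na(values))),
    class = "pseudo_haploid"
  )
}

#' @export
print.pseudo_haploid <- function(x, ...) {
  cat(sprintf(
    "<pseudo_haploid> %d samples x %d SNPs [%s], mean resolved %.3f\n",
    nrow(x$values), ncol(x$values), x$provenance,
    mean(x$resolved_fraction)
  ))
  invisible(x)
}
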
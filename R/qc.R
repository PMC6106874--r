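# Marker and duo quality control --------------------------------------------

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele count
#' (Wigginton-style enumeration): the p-value is the total probability of
#' heterozygote counts no more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (A1 homozygote, heterozygote,
#'   A2 homozygote).
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2L * n_aa + n_ab                # copies of allele A1
  rare <- min(n_a, 2L * n - n_a)         # rare-allele copies
  het_obs <- n_ab                        # heterozygote count, allele-symmetric
  # possible heterozygote counts share parity with the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # unnormalized log-probabilities by the recurrence
  # P(h+2)/P(h) = 4 * hom_rare(h) * hom_common(h) / ((h+2)(h+1)),
  # with hom_rare = (rare-h)/2 and hom_common = (2n - rare - h)/2
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    logp[i] <- logp[i - 1] +
      log(4) + log((rare - h) / 2) + log((2 * n - rare - h) / 2) -
      log(h + 2) - log(h + 1)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(het_obs, hets)
  if (is.na(obs)) stop_dyad("genotype counts inconsistent with alleles", "hwe")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Per-marker quality control
#'
#' Computes per-SNP minor-allele frequency (on non-missing calls), call rate
#' and exact HWE p-value, and returns the indices of markers passing
#' `maf >= maf_min`, `call_rate >= call_min` and `hwe_p >= hwe_alpha`.
#' The MAF threshold is inclusive.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param hwe_alpha HWE exact-test significance floor (default 1e-6).
#' @param call_min Minimum call rate (default 0.95).
#' @param mendel_errors Optional per-SNP Mendelian-error counts (from
#'   [mendel_check()]) to attach to the stats.
#' @return List with `keep` (integer indices) and `stats` (tibble `snp`,
#'   `maf`, `call_rate`, `hwe_p`, `mendel_error_count`, `pass`).
#' @export
marker_qc <- function(geno, maf_min = 0.01, hwe_alpha = 1e-6,
                      call_min = 0.95, mendel_errors = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  stopifnot(maf_min >= 0, maf_min <= 1, hwe_alpha >= 0, hwe_alpha <= 1,
            call_min >= 0, call_min <= 1)
  x <- geno$values
  n <- nrow(x)
  miss <- is.na(x)
  n_obs <- n - colSums(miss)
  freq_a1 <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(freq_a1, 1 - freq_a1)
  call_rate <- n_obs / n
  n_aa <- colSums(x == 2, na.rm = TRUE)
  n_ab <- colSums(x == 1, na.rm = TRUE)
  n_bb <- colSums(x == 0, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(x)), function(j) {
    hwe_exact_test(n_aa[j], n_ab[j], n_bb[j])
  }, numeric(1))
  mend <- if (is.null(mendel_errors)) rep(0L, ncol(x)) else mendel_errors
  pass <- maf >= maf_min & call_rate >= call_min & hwe_p >= hwe_alpha
  pass[n_obs == 0] <- FALSE
  stats <- tibble(
    snp = geno$marker$snp, maf = unname(maf), call_rate = unname(call_rate),
    hwe_p = hwe_p, mendel_error_count = unname(mend), pass = unname(pass)
  )
  list(keep = unname(which(pass)), stats = stats)
}

#' Flag duo Mendelian inconsistencies
#'
#' For each dyad and SNP, flags the two impossible duo combinations
#' (mother homozygous A2 with child homozygous A1 and vice versa:
#' counts (0, 2) and (2, 0)). Missing genotypes are never flagged.
#'
#' @param maternal,offspring [geno_matrix()] objects on a shared marker set.
#' @param pairing Tibble with columns `maternal_id`, `offspring_id` mapping
#'   each offspring to exactly one mother.
#' @return List with `mask` (dyads x SNPs logical matrix of flags),
#'   `per_snp` (integer error counts) and `rate` (overall error fraction).
#' @export
mendel_check <- function(maternal, offspring, pairing) {
  stopifnot(inherits(maternal, "geno_matrix"),
            inherits(offspring, "geno_matrix"))
  if (!identical(maternal$marker$snp, offspring$marker$snp)) {
    stop_dyad("maternal and offspring marker sets differ", "pairing")
  }
  im <- match(pairing$maternal_id, maternal$samples$sample_id)
  ic <- match(pairing$offspring_id, offspring$samples$sample_id)
  if (anyNA(im) || anyNA(ic)) {
    stop_dyad("pairing refers to samples absent from the genotype data",
              "pairing")
  }
  gm <- maternal$values[im, , drop = FALSE]
  gc <- offspring$values[ic, , drop = FALSE]
  mask <- (gm == 0L & gc == 2L) | (gm == 2L & gc == 0L)
  mask[is.na(mask)] <- FALSE
  list(mask = mask, per_snp = colSums(mask), rate = mean(mask))
}

#' Recode a pseudo-haploid matrix as a male pseudo-X genotype set
#'
#' Converts resolved single alleles into a diploid-coded [geno_matrix()]
#' ready for PLINK1 output: every sample's sex is set to male (1), every
#' marker's chromosome to `"X"`, and each hemizygous allele is stored as the
#' corresponding homozygous genotype (allele count doubled), the `.bed`
#' convention for male X calls.
#'
#' @param ph A [pseudo_haploid()] matrix.
#' @return A [geno_matrix()] with `haploid = TRUE`.
#' @export
recode_pseudo_x <- function(ph) {
  stopifnot(inherits(ph, "pseudo_haploid"))
  if (any(ph$values == 2, na.rm = TRUE)) {
    stop_dyad("diploid value 2 found in pseudo-haploid input", "range")
  }
  marker <- ph$marker
  marker$chr <- "X"
  samples <- ph$samples
  samples$sex <- 1L
  geno_matrix(ph$values, marker, samples, haploid = TRUE)
}

#' Convert a male pseudo-X genotype set back to a pseudo-haploid matrix
#'
#' Inverse of [recode_pseudo_x()] after a file round-trip: homozygous codes
#' 0/2 become allele counts 0/1; a heterozygous call is impossible for a
#' hemizygous male and raises an error.
#'
#' @param geno A [geno_matrix()] read back from disk (diploid codes).
#' @param provenance Provenance tag for the result.
#' @return A [pseudo_haploid()] matrix.
#' @export
as_pseudo_haploid <- function(geno, provenance = "maternal_non_transmitted") {
  x <- geno$values
  if (any(x == 1L, na.rm = TRUE)) {
    stop_dyad("heterozygous call in male pseudo-X data", "range")
  }
  x <- x %/% 2L
  pseudo_haploid(x, geno$marker, geno$samples, provenance = provenance)
}
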
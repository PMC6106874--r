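# Duo allele partitioning: maternal non-transmitted / fetal non-maternal ----
#
# For each dyad and SNP the maternal genotype is compared with the offspring
# genotype; when the transmitted maternal allele can be deduced, the maternal
# record is replaced by the single non-transmitted allele and the offspring
# record by the single allele not inherited from the mother (the paternal
# allele). Double heterozygotes are unresolvable and set missing.

#' Resolve one duo genotype pair into partitioned alleles
#'
#' Truth table over A1-allele counts (`gm` mother, `gc` child):
#' \itemize{
#'   \item (0,0) -> non-transmitted a2 (0), non-maternal a2 (0)
#'   \item (0,1) -> a2 (0), a1 (1)
#'   \item (1,0) -> a1 (1), a2 (0)
#'   \item (1,2) -> a2 (0), a1 (1)
#'   \item (2,1) -> a1 (1), a2 (0)
#'   \item (2,2) -> a1 (1), a1 (1)
#'   \item (1,1) -> both missing (transmission ambiguous)
#'   \item any missing input -> both missing
#'   \item (0,2) and (2,0) -> Mendelian inconsistency
#' }
#'
#' @param gm,gc Integer vectors/matrices of maternal and offspring A1 counts
#'   (`{0, 1, 2, NA}`), equal shape.
#' @param on_mendel_error `"missing"` (default: inconsistent entries become
#'   missing and are counted) or `"error"` (abort).
#' @return List: `maternal_nt` and `fetal_nm` (A1 counts in `{0, 1, NA}`,
#'   same shape as input), `n_mendel_errors`.
#' @export
resolve_duo <- function(gm, gc, on_mendel_error = c("missing", "error")) {
  on_mendel_error <- match.arg(on_mendel_error)
  if (!identical(dim(gm), dim(gc)) || length(gm) != length(gc)) {
    stop_dyad("gm and gc must have identical shape", "dim")
  }
  # encode the pair as 4*gm + gc (missing -> lookup NA)
  key <- 4L * gm + gc + 1L
  # lookup over keys 1..12 for gm in 0..2, gc in 0..2 (gc 3 unused)
  nt_tab <- rep(NA_integer_, 12L)
  nm_tab <- rep(NA_integer_, 12L)
  set <- function(m, c, nt, nm) {
    nt_tab[4L * m + c + 1L] <<- nt
    nm_tab[4L * m + c + 1L] <<- nm
  }
  set(0L, 0L, 0L, 0L)
  set(0L, 1L, 0L, 1L)
  set(1L, 0L, 1L, 0L)
  set(1L, 2L, 0L, 1L)
  set(2L, 1L, 1L, 0L)
  set(2L, 2L, 1L, 1L)
  # (1,1) stays NA/NA; (0,2) and (2,0) are Mendelian errors
  mendel <- !is.na(gm) & !is.na(gc) &
    ((gm == 0L & gc == 2L) | (gm == 2L & gc == 0L))
  if (any(mendel) && on_mendel_error == "error") {
    stop_dyad(sprintf("%d Mendelian-inconsistent duo genotype(s)",
                      sum(mendel)), "mendel")
  }
  valid <- !is.na(key)
  nt <- gm
  nm <- gm
  nt[] <- NA_integer_
  nm[] <- NA_integer_
  nt[valid] <- nt_tab[key[valid]]
  nm[valid] <- nm_tab[key[valid]]
  nt[mendel] <- NA_integer_
  nm[mendel] <- NA_integer_
  list(maternal_nt = nt, fetal_nm = nm, n_mendel_errors = sum(mendel))
}

#' Partition a dyad cohort into pseudo-haploid genomes
#'
#' Applies [resolve_duo()] per dyad per SNP, producing the maternal-specific
#' (non-transmitted) and fetal-specific (non-inherited, i.e. paternal)
#' allele matrices with per-SNP resolved fractions. Optionally re-filters
#' markers at a minimum MAF on the resolved alleles before the matrices are
#' used for GRM construction.
#'
#' @param cohort A [simulate_dyads()] cohort, or a list with elements
#'   `maternal`, `offspring` ([geno_matrix()]) and `pairing`.
#' @param maf_min Minimum resolved-allele MAF retained (default 0.01; `NULL`
#'   disables).
#' @param mendel_ceiling Abort when the aggregate Mendelian-error rate
#'   exceeds this fraction (default 0.01).
#' @return List of class `duo_partition`: `maternal_nt` and `fetal_nm`
#'   ([pseudo_haploid()] matrices), `n_mendel_errors`, `kept_snps`.
#' @export
partition_cohort <- function(cohort, maf_min = 0.01, mendel_ceiling = 0.01) {
  im <- match(cohort$pairing$maternal_id, cohort$maternal$samples$sample_id)
  ic <- match(cohort$pairing$offspring_id, cohort$offspring$samples$sample_id)
  if (anyNA(im) || anyNA(ic)) stop_dyad("pairing does not match samples", "pairing")
  gm <- cohort$maternal$values[im, , drop = FALSE]
  gc <- cohort$offspring$values[ic, , drop = FALSE]
  res <- resolve_duo(gm, gc, on_mendel_error = "missing")
  if (res$n_mendel_errors / length(gm) > mendel_ceiling) {
    stop_dyad(sprintf("Mendelian-error rate %.3f exceeds ceiling %.3f",
                      res$n_mendel_errors / length(gm), mendel_ceiling),
              "mendel")
  }
  keep <- seq_len(ncol(gm))
  if (!is.null(maf_min)) {
    keep_ok <- function(x) {
      p <- colMeans(x, na.rm = TRUE)
      ok <- !is.na(p) & pmin(p, 1 - p) >= maf_min
      ok
    }
    ok <- keep_ok(res$maternal_nt) & keep_ok(res$fetal_nm)
    keep <- which(ok)
  }
  marker <- cohort$maternal$marker[keep, , drop = FALSE]
  sm <- cohort$maternal$samples[im, , drop = FALSE]
  sc <- cohort$offspring$samples[ic, , drop = FALSE]
  structure(
    list(
      maternal_nt = pseudo_haploid(res$maternal_nt[, keep, drop = FALSE],
                                   marker, sm, "maternal_non_transmitted"),
      fetal_nm = pseudo_haploid(res$fetal_nm[, keep, drop = FALSE],
                                marker, sc, "fetal_non_maternal"),
      n_mendel_errors = res$n_mendel_errors,
      kept_snps = keep
    ),
    class = "duo_partition"
  )
}
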
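# Genetic relationship matrices: diploid and haploid no-dosage-compensation -

new_grm <- function(values, n_snps, model, sample_ids) {
  dimnames(values) <- list(sample_ids, sample_ids)
  dimnames(n_snps) <- dimnames(values)
  structure(list(values = values, n_snps = n_snps, model = model,
                 sample_ids = sample_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d samples [%s], mean diagonal %.3f\n",
              nrow(x$values), x$model, mean(diag(x$values))))
  invisible(x)
}

# shared machinery: standardized crossproduct with per-pair SNP counts
grm_core <- function(x, center, scale2) {
  n <- nrow(x)
  obs <- !is.na(x)
  z <- sweep(x, 2, center)
  z <- sweep(z, 2, sqrt(scale2), "/")
  z[!obs] <- 0
  obs_n <- matrix(as.numeric(obs), n)
  m_pair <- tcrossprod(obs_n)
  a <- tcrossprod(z)
  list(a = a, m_pair = m_pair, z = z, obs = obs)
}

#' Diploid genetic relationship matrix
#'
#' Standard SNP-based relatedness estimator: for samples `j != k`,
#' `A_jk = (1/m_jk) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over SNPs non-missing in both, and a variance-corrected diagonal
#' `A_jj = 1 + (1/m_j) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) /
#' (2 p_i (1 - p_i))`, with `p_i` the sample A1 frequency.
#'
#' @param geno A [geno_matrix()] (diploid).
#' @return A `grm` object (model `"diploid"`).
#' @export
diploid_grm <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"), !geno$haploid)
  x <- geno$values
  p <- colMeans(x, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    stop_dyad("monomorphic SNP in GRM input; filter markers first", "mono")
  }
  core <- grm_core(x, center = 2 * p, scale2 = 2 * p * (1 - p))
  a <- core$a / pmax(core$m_pair, 1)
  # diagonal: 1 + mean over observed SNPs of the correction term
  corr <- sweep(x^2, 2, 2 * p^2, "+") - sweep(x, 2, 1 + 2 * p, "*")
  corr <- sweep(corr, 2, 2 * p * (1 - p), "/")
  corr[!core$obs] <- 0
  m_j <- rowSums(core$obs)
  diag(a) <- 1 + rowSums(corr) / pmax(m_j, 1)
  new_grm(a, core$m_pair, "diploid", geno$samples$sample_id)
}

#' Haploid GRM under full and no dosage compensation
#'
#' For pseudo-haploid (male pseudo-X) 0/1 allele matrices: the
#' full-dosage-compensation male-male entry is
#' `A_jk = (1/m_jk) sum_i (x_ij - p_i)(x_ik - p_i) / (p_i (1 - p_i))`;
#' under the no-dosage-compensation (ND) model, which assumes each allele
#' has a similar effect on the trait, every male-male entry is halved:
#' `A^ND = A / 2`. The self-pair is treated as male-male, so the diagonal is
#' halved too by default; `nd_diagonal = FALSE` restricts the rescaling to
#' off-diagonal entries.
#'
#' @param ph A [pseudo_haploid()] matrix (values 0/1/NA).
#' @param dosage_compensation `"none"` (ND model, default) or `"full"`.
#' @param nd_diagonal Halve the diagonal under ND as well (default `TRUE`).
#' @return A `grm` object (model `"haploid_nd"` or `"haploid_full"`).
#' @export
haploid_nd_grm <- function(ph, dosage_compensation = c("none", "full"),
                           nd_diagonal = TRUE) {
  dosage_compensation <- match.arg(dosage_compensation)
  x <- if (inherits(ph, "pseudo_haploid")) ph$values else as.matrix(ph)
  if (any(x == 2, na.rm = TRUE)) stop_dyad("values must be 0/1/NA", "range")
  p <- colMeans(x, na.rm = TRUE)
  if (any(is.na(p) | p <= 0 | p >= 1)) {
    stop_dyad("monomorphic or all-missing SNP on resolved alleles", "mono")
  }
  core <- grm_core(x, center = p, scale2 = p * (1 - p))
  if (any(core$m_pair == 0)) {
    warning("sample pair(s) with no jointly resolved SNPs; entries set to 0")
  }
  a <- core$a / pmax(core$m_pair, 1)
  ids <- if (inherits(ph, "pseudo_haploid")) ph$samples$sample_id else
    rownames(x) %||% as.character(seq_len(nrow(x)))
  if (dosage_compensation == "none") {
    a_nd <- a / 2
    if (!nd_diagonal) diag(a_nd) <- diag(a)
    new_grm(a_nd, core$m_pair, "haploid_nd", ids)
  } else {
    new_grm(a, core$m_pair, "haploid_full", ids)
  }
}

#' Write a GRM to gzipped-text format
#'
#' Lower triangle (including diagonal) as tab-separated
#' `index_1 index_2 n_snps value` in `<prefix>.grm.gz`, plus an id file
#' `<prefix>.grm.id` with family/within-family ids.
#'
#' @param grm A `grm` object.
#' @param prefix Output path prefix.
#' @return Invisibly, `prefix`.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  if (n == 0) stop_dyad("empty GRM", "empty")
  idx <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(
    i = idx[, 1], j = idx[, 2],
    m = grm$n_snps[idx],
    a = grm$values[idx]
  )
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  write.table(data.frame(grm$sample_ids, grm$sample_ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from gzipped-text format
#'
#' @param prefix Path prefix as used by [write_grm()].
#' @param model Model tag to attach (default `"diploid"`).
#' @return A `grm` object.
#' @export
read_grm <- function(prefix, model = "diploid") {
  idf <- paste0(prefix, ".grm.id")
  gzf <- paste0(prefix, ".grm.gz")
  if (!file.exists(idf) || !file.exists(gzf)) {
    stop_dyad("GRM fileset not found", "io")
  }
  ids <- read.table(idf, colClasses = "character")
  n <- nrow(ids)
  df <- read.table(gzfile(gzf),
                   col.names = c("i", "j", "m", "a"),
                   colClasses = c("integer", "integer", "numeric", "numeric"))
  if (max(df$i, df$j) > n) stop_dyad("GRM ids do not match entries", "io")
  vals <- matrix(0, n, n)
  cnts <- matrix(0, n, n)
  vals[cbind(df$i, df$j)] <- df$a
  vals[cbind(df$j, df$i)] <- df$a
  cnts[cbind(df$i, df$j)] <- df$m
  cnts[cbind(df$j, df$i)] <- df$m
  new_grm(vals, cnts, model, ids[[2]])
}
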
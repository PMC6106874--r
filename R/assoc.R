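# Per-SNP association scans and follow-up models ----------------------------

#' Per-SNP linear association scan
#'
#' Additive-dosage ordinary least squares per SNP with Wald t-tests,
#' covariates included (typically ten ancestry coordinates). Missing
#' genotypes are handled per SNP by complete-case analysis; monomorphic
#' SNPs are skipped with a reason. Pseudo-haploid input uses the 0/1 allele
#' as the dosage.
#'
#' @param y Phenotype vector.
#' @param geno A [geno_matrix()], [pseudo_haploid()] or bare dosage matrix.
#' @param covariates Covariate matrix / data frame (`NULL` for intercept
#'   only).
#' @param gw_threshold Genome-wide significance threshold (default 5e-8).
#' @param suggestive_threshold Suggestive threshold (default 1e-7).
#' @return A tibble of class `gwas_scan`: `snp`, `a1`, `maf`, `beta`, `se`,
#'   `statistic`, `p`, `n`, `genome_wide`, `suggestive`, `skipped`, `model`.
#' @export
gwas_linear <- function(y, geno, covariates = NULL,
                        gw_threshold = 5e-8, suggestive_threshold = 1e-7) {
  x <- geno_values(geno)
  mk <- geno_marker(geno)
  n <- length(y)
  stopifnot(nrow(x) == n)
  C <- build_design(covariates, n)
  cn <- ncol(C)
  model <- sprintf("linear+%dcov", cn - 1)
  maf_all <- {
    f <- colMeans(x, na.rm = TRUE) / geno_ploidy(geno)
    pmin(f, 1 - f)
  }
  ok_y <- !is.na(y)
  has_miss <- anyNA(x) || any(!ok_y)
  m <- ncol(x)
  beta <- se <- tstat <- pval <- rep(NA_real_, m)
  nn <- rep(0L, m)
  skipped <- rep(NA_character_, m)
  mono <- maf_all == 0 | is.na(maf_all)
  if (!has_miss) {
    qC <- qr(C)
    ry <- qr.resid(qC, y)
    rx <- qr.resid(qC, x)
    sxx <- colSums(rx^2)
    mono <- mono | sxx < .Machine$double.eps * n
    syy <- sum(ry^2)
    bet <- colSums(rx * ry) / sxx
    rss <- syy - bet^2 * sxx
    df <- n - cn - 1
    s2 <- pmax(rss, 0) / df
    sei <- sqrt(s2 / sxx)
    ti <- bet / sei
    keep <- !mono
    beta[keep] <- bet[keep]
    se[keep] <- sei[keep]
    tstat[keep] <- ti[keep]
    pval[keep] <- 2 * pt(-abs(ti[keep]), df)
    nn[keep] <- n
    skipped[mono] <- "monomorphic"
  } else {
    for (j in seq_len(m)) {
      ok <- ok_y & !is.na(x[, j])
      xv <- x[ok, j]
      if (length(unique(xv)) < 2) {
        skipped[j] <- "monomorphic"
        next
      }
      X <- cbind(C[ok, , drop = FALSE], xv)
      fit <- lm.fit(X, y[ok])
      dfj <- sum(ok) - fit$rank
      if (dfj <= 0 || is.na(fit$coefficients[ncol(X)])) {
        skipped[j] <- "rank-deficient"
        next
      }
      rssj <- sum(fit$residuals^2)
      XtXinv <- chol2inv(chol(crossprod(X[, seq_len(fit$rank), drop = FALSE])))
      bj <- fit$coefficients[ncol(X)]
      sej <- sqrt(rssj / dfj * XtXinv[fit$rank, fit$rank])
      beta[j] <- bj
      se[j] <- sej
      tstat[j] <- bj / sej
      pval[j] <- 2 * pt(-abs(bj / sej), dfj)
      nn[j] <- sum(ok)
    }
  }
  out <- tibble(
    snp = mk$snp, chr = mk$chr, pos = mk$pos, a1 = mk$a1,
    maf = maf_all, beta = beta, se = se, statistic = tstat, p = pval,
    n = nn,
    genome_wide = !is.na(pval) & pval < gw_threshold,
    suggestive = !is.na(pval) & pval < suggestive_threshold,
    skipped = skipped, model = model
  )
  class(out) <- c("gwas_scan", class(out))
  out
}

geno_values <- function(g) {
  if (inherits(g, "geno_matrix") || inherits(g, "pseudo_haploid")) g$values
  else as.matrix(g)
}
geno_marker <- function(g) {
  if (inherits(g, "geno_matrix") || inherits(g, "pseudo_haploid")) g$marker
  else {
    m <- ncol(as.matrix(g))
    tibble(snp = colnames(as.matrix(g)) %||% paste0("snp", seq_len(m)),
           chr = "1", pos = seq_len(m), a1 = "A", a2 = "G")
  }
}
geno_ploidy <- function(g) {
  if (inherits(g, "pseudo_haploid")) 1
  else if (inherits(g, "geno_matrix") && g$haploid) 1
  else 2
}

#' Genomic inflation factor of a scan
#'
#' `lambda = median(t^2) / qchisq(0.5, 1)` over tested SNPs; a population
#' stratification diagnostic (1 under a calibrated null).
#'
#' @param scan A `gwas_scan` tibble.
#' @return Numeric scalar.
#' @export
genomic_lambda <- function(scan) {
  t2 <- scan$statistic[!is.na(scan$statistic)]^2
  median(t2) / qchisq(0.5, df = 1)
}

#' Inverse-variance fixed-effect meta-analysis of per-SNP results
#'
#' Combines per-sub-population scans with weights `w_s = 1/se_s^2`:
#' `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum(w))`, z-test p-value.
#' Alleles are aligned to the first study's A1; a study whose A1/A2 are
#' swapped contributes with negated beta. SNPs with unresolvable allele
#' mismatches are dropped.
#'
#' @param scans List of `gwas_scan` tibbles (one per sub-population), each
#'   with columns `snp`, `a1`, `beta`, `se` (an `a2` column enables
#'   swap-and-negate alignment).
#' @return Tibble `snp`, `a1`, `beta`, `se`, `statistic`, `p`, `n_studies`.
#' @export
meta_fixed <- function(scans) {
  stopifnot(length(scans) >= 1)
  ref <- scans[[1]]
  rows <- lapply(ref$snp, function(s) {
    a1_ref <- ref$a1[ref$snp == s][1]
    bs <- c(); ws <- c()
    for (sc in scans) {
      i <- which(sc$snp == s)
      if (length(i) != 1 || is.na(sc$beta[i]) || is.na(sc$se[i])) next
      b <- sc$beta[i]
      if (!identical(sc$a1[i], a1_ref)) {
        a2 <- if ("a2" %in% names(sc)) sc$a2[i] else NA_character_
        if (identical(a2, a1_ref)) b <- -b else return(NULL)  # unresolvable
      }
      bs <- c(bs, b)
      ws <- c(ws, 1 / sc$se[i]^2)
    }
    if (length(bs) == 0) return(NULL)
    bm <- sum(ws * bs) / sum(ws)
    sem <- 1 / sqrt(sum(ws))
    tibble(snp = s, a1 = a1_ref, beta = bm, se = sem,
           statistic = bm / sem, p = 2 * pnorm(-abs(bm / sem)),
           n_studies = length(bs))
  })
  dplyr::bind_rows(rows)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype dosage vectors (composite LD)
#' over jointly non-missing samples.
#'
#' @param snp_a,snp_b SNP identifiers (or column indices).
#' @param geno A [geno_matrix()] or dosage matrix.
#' @return Tibble `snp_a`, `snp_b`, `r2`, `n`.
#' @export
ld_r2 <- function(snp_a, snp_b, geno) {
  x <- geno_values(geno)
  ga <- x[, snp_a]
  gb <- x[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  if (sd(ga[ok]) == 0 || sd(gb[ok]) == 0) {
    stop_dyad("zero-variance genotype vector: r2 undefined", "mono")
  }
  r <- cor(ga[ok], gb[ok])
  tibble(snp_a = as.character(snp_a), snp_b = as.character(snp_b),
         r2 = r^2, n = sum(ok))
}

#' Conditional association scan
#'
#' Re-tests every SNP with the dosages of one or more index SNPs appended
#' to the covariates; the index SNPs themselves are skipped.
#'
#' @param y Phenotype vector.
#' @param geno Genotype object or matrix.
#' @param covariates Covariate matrix (`NULL` ok).
#' @param index_snps SNP ids or column indices to condition on.
#' @return A `gwas_scan` tibble (index SNPs carry `skipped = "index"`).
#' @export
conditional_scan <- function(y, geno, covariates = NULL, index_snps) {
  x <- geno_values(geno)
  mk <- geno_marker(geno)
  idx <- if (is.character(index_snps)) match(index_snps, mk$snp) else
    as.integer(index_snps)
  if (anyNA(idx)) stop_dyad("index SNP not found", "index")
  dos <- x[, idx, drop = FALSE]
  C <- build_design(covariates, length(y))
  aug <- cbind(C, dos)
  if (qr(aug)$rank < ncol(aug)) {
    stop_dyad("index SNP collinear with covariates", "collinear")
  }
  res <- gwas_linear(y, geno, covariates = cbind(
    if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates)),
    index_dosage = dos))
  res$beta[idx] <- NA_real_
  res$se[idx] <- NA_real_
  res$statistic[idx] <- NA_real_
  res$p[idx] <- NA_real_
  res$genome_wide[idx] <- FALSE
  res$suggestive[idx] <- FALSE
  res$skipped[idx] <- "index"
  res$model <- sprintf("%s|cond:%s", res$model,
                       paste(mk$snp[idx], collapse = ","))
  res
}

#' Joint maternal + fetal (dual-genome) regression at a locus
#'
#' Fits `mediator ~ maternal dosage + fetal dosage + covariates` by OLS on
#' dyad-aligned records and reports the residual (conditional) Wald test of
#' each genome's term. Transmission induces a correlation of about 0.5
#' between the two dosages; near-perfect collinearity is flagged.
#'
#' @param mediator Phenotype vector (one value per dyad).
#' @param maternal_snp,fetal_snp Dosage vectors aligned to the dyads.
#' @param covariates Covariate matrix (`NULL` ok).
#' @return Tibble with rows `maternal` and `fetal`: `term`, `beta`, `se`,
#'   `statistic`, `p`, `n`, `collinear`.
#' @export
dual_genome_model <- function(mediator, maternal_snp, fetal_snp,
                              covariates = NULL) {
  ok <- complete.cases(mediator, maternal_snp, fetal_snp)
  y <- mediator[ok]
  gm <- maternal_snp[ok]
  gf <- fetal_snp[ok]
  collinear <- isTRUE(cor(gm, gf)^2 > 0.99)
  if (collinear) warning("maternal and fetal dosages are collinear")
  C <- build_design(covariates, length(mediator))[ok, , drop = FALSE]
  d <- data.frame(y = y, C[, -1, drop = FALSE], maternal = gm, fetal = gf)
  fit <- lm(y ~ ., data = d)
  sm <- summary(fit)$coefficients
  pick <- function(term) {
    if (!term %in% rownames(sm)) {
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    }
    unname(sm[term, ])
  }
  rows <- rbind(pick("maternal"), pick("fetal"))
  tibble(term = c("maternal", "fetal"), beta = rows[, 1], se = rows[, 2],
         statistic = rows[, 3], p = rows[, 4],
         n = length(y), collinear = collinear)
}

#' Plot an association scan
#'
#' @param object A `gwas_scan` tibble.
#' @param type `"manhattan"` or `"qq"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_scan <- function(object, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  df <- object[!is.na(object$p), ]
  if (type == "manhattan") {
    df$index <- seq_len(nrow(df))
    ggplot2::ggplot(df, ggplot2::aes(.data$index, -log10(.data$p),
                                     colour = factor(as.integer(factor(.data$chr)) %% 2))) +
      ggplot2::geom_point(show.legend = FALSE, size = 0.8) +
      ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = 2) +
      ggplot2::labs(x = "SNP index", y = expression(-log[10](p))) +
      ggplot2::theme_minimal()
  } else {
    p_sorted <- sort(df$p)
    qdf <- tibble(expected = -log10(stats::ppoints(length(p_sorted))),
                  observed = -log10(p_sorted))
    ggplot2::ggplot(qdf, ggplot2::aes(.data$expected, .data$observed)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)") +
      ggplot2::theme_minimal()
  }
}
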
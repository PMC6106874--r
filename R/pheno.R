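# Analyte phenotype preparation ---------------------------------------------
#
# Fixed pipeline order: detection filter -> LOD imputation -> natural log ->
# outlier masking (on residuals by default) -> covariate residualization.

#' Filter analytes by detection fraction
#'
#' Keeps analytes with strictly more than `min_fraction` of values above
#' their limit of detection.
#'
#' @param values Tibble of raw concentrations, one column per analyte (plus
#'   optional id columns, ignored for the computation).
#' @param analyte_meta Tibble with columns `name` and `lod`.
#' @param min_fraction Detection-fraction threshold (strict `>`; default 0.6).
#' @return Tibble `name`, `lod`, `detect_fraction`, `kept`.
#' @export
detection_filter <- function(values, analyte_meta, min_fraction = 0.6) {
  if (anyNA(analyte_meta$lod)) {
    stop_dyad("missing LOD for at least one analyte", "lod")
  }
  res <- lapply(seq_len(nrow(analyte_meta)), function(i) {
    nm <- analyte_meta$name[i]
    if (!nm %in% names(values)) stop_dyad(paste("analyte not found:", nm), "lod")
    v <- values[[nm]]
    frac <- mean(v > analyte_meta$lod[i], na.rm = TRUE)
    tibble(name = nm, lod = analyte_meta$lod[i], detect_fraction = frac,
           kept = frac > min_fraction)
  })
  dplyr::bind_rows(res)
}

#' Impute sub-LOD values and log-transform
#'
#' Values strictly below the limit of detection are replaced by
#' `lod / sqrt(2)`; the vector is then natural-log transformed. A value equal
#' to the LOD is left unchanged before the log.
#'
#' @param values Numeric vector of raw concentrations.
#' @param lod Positive limit of detection.
#' @return Log-transformed vector.
#' @export
lod_impute_and_log <- function(values, lod) {
  if (!is.numeric(lod) || lod <= 0) stop_dyad("lod must be positive", "lod")
  out <- ifelse(!is.na(values) & values < lod, lod / sqrt(2), values)
  if (any(out <= 0, na.rm = TRUE)) {
    stop_dyad("non-positive value after LOD imputation", "lod")
  }
  log(out)
}

#' Mask outliers beyond a standard-deviation threshold
#'
#' Flags values with `|v - mean| > sd_threshold * SD`; mean and SD are
#' computed once on the full vector (no re-iteration after masking).
#'
#' @param values Numeric vector.
#' @param sd_threshold 3 or 4 (other positive values accepted but
#'   non-standard).
#' @return List with `mask` (logical, `TRUE` = outlier) and `count`.
#' @export
outlier_mask <- function(values, sd_threshold = 4) {
  stopifnot(sd_threshold > 0)
  mu <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warning("constant vector: no outliers can be defined")
    mask <- rep(FALSE, length(values))
    return(list(mask = mask, count = 0L))
  }
  mask <- !is.na(values) & abs(values - mu) > sd_threshold * s
  list(mask = mask, count = sum(mask))
}

#' Screen candidate covariates against a panel of mediators
#'
#' Fits one univariable linear model per (covariate, mediator) pair and
#' keeps covariates nominally associated (`p < alpha`) with at least
#' `min_hits` mediators.
#'
#' @param mediators Data frame / matrix of mediator values (columns =
#'   mediators).
#' @param covariates Data frame of candidate covariates (columns =
#'   candidates; factors allowed).
#' @param alpha Nominal significance level (default 0.05).
#' @param min_hits Minimum number of nominal hits (default 3).
#' @return Tibble `covariate`, `n_hits`, `selected`.
#' @export
covariate_screen <- function(mediators, covariates, alpha = 0.05,
                             min_hits = 3) {
  mediators <- as.data.frame(mediators)
  covariates <- as.data.frame(covariates)
  res <- lapply(names(covariates), function(cv) {
    hits <- vapply(names(mediators), function(md) {
      d <- data.frame(y = mediators[[md]], x = covariates[[cv]])
      d <- d[complete.cases(d), , drop = FALSE]
      fit <- lm(y ~ x, data = d)
      a <- anova(fit)              # overall covariate test (factors included)
      a$`Pr(>F)`[1] < alpha
    }, logical(1))
    tibble(covariate = cv, n_hits = sum(hits),
           selected = sum(hits) >= min_hits)
  })
  dplyr::bind_rows(res)
}

#' Residualize mediator values on selected covariates
#'
#' Ordinary least-squares residuals after regressing each analyte on the
#' covariate design (intercept always included; collinear columns dropped
#' with a warning). A Shapiro-Wilk normality p-value is attached per analyte,
#' and outliers are masked on the residual scale when `sd_threshold` is
#' given.
#'
#' @param values Data frame of log-scale analyte values (columns = analytes).
#' @param covariates Data frame of selected covariates (may be empty).
#' @param sd_threshold Optional outlier threshold applied to residuals
#'   (`NULL` disables masking).
#' @return List of class `residual_table`: `residuals` (tibble),
#'   `summary` (tibble `name`, `shapiro_p`, `n_outliers`, `n_used`).
#' @export
residualize <- function(values, covariates = NULL, sd_threshold = NULL) {
  values <- as.data.frame(values)
  n <- nrow(values)
  X <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    matrix(1, n, 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf("dropping %d collinear covariate column(s)",
                    ncol(X) - qrX$rank))
  }
  resid_one <- function(v) {
    ok <- complete.cases(cbind(v, X))
    r <- rep(NA_real_, n)
    fit <- lm.fit(X[ok, , drop = FALSE], v[ok])
    r[ok] <- fit$residuals
    r
  }
  res <- vapply(values, resid_one, numeric(n))
  res <- as.data.frame(res)
  summ <- lapply(names(res), function(nm) {
    r <- res[[nm]]
    n_out <- 0L
    if (!is.null(sd_threshold)) {
      om <- outlier_mask(r, sd_threshold)
      r[om$mask] <- NA_real_
      res[[nm]] <<- r
      n_out <- om$count
    }
    ok <- !is.na(r)
    sw <- if (sum(ok) >= 3 && sd(r[ok]) > 0) shapiro.test(r[ok])$p.value else NA_real_
    tibble(name = nm, shapiro_p = sw, n_outliers = n_out, n_used = sum(ok))
  })
  structure(
    list(residuals = as_tibble(res), summary = dplyr::bind_rows(summ)),
    class = "residual_table"
  )
}

#' Spearman correlation matrix with variance and correlation comparisons
#'
#' Pairwise Spearman rank correlations with tie-corrected p-values; for
#' matched analyte pairs across two tables, a two-sample F-test of variances
#' and a Fisher z comparison of the correlation coefficients.
#'
#' @param x Data frame of analyte values (columns = analytes).
#' @param y Optional second data frame; when supplied, correlations are
#'   computed between columns of `x` and `y`.
#' @return List of class `correlation_suite`: `rho` (matrix), `p` (matrix),
#'   `n` (matrix of pairwise sample sizes).
#' @export
correlation_suite <- function(x, y = NULL) {
  x <- as.data.frame(x)
  y2 <- if (is.null(y)) x else as.data.frame(y)
  rho <- matrix(NA_real_, ncol(x), ncol(y2),
                dimnames = list(names(x), names(y2)))
  p <- rho
  nmat <- rho
  for (i in seq_len(ncol(x))) {
    for (j in seq_len(ncol(y2))) {
      ok <- complete.cases(x[[i]], y2[[j]])
      nmat[i, j] <- sum(ok)
      ct <- suppressWarnings(
        cor.test(x[[i]][ok], y2[[j]][ok], method = "spearman")
      )
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = p, n = nmat), class = "correlation_suite")
}

#' Compare two correlation coefficients by Fisher's z transformation
#'
#' `z = atanh(rho)`; the comparison statistic is
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to a standard normal.
#'
#' @param rho1,rho2 Correlation coefficients.
#' @param n1,n2 Sample sizes (both must exceed 3).
#' @return Tibble `z1`, `z2`, `statistic`, `p`.
#' @export
fisher_z_compare <- function(rho1, rho2, n1, n2) {
  if (n1 < 4 || n2 < 4) {
    stop_dyad("Fisher z comparison needs n > 3 in both samples", "fisherz")
  }
  z1 <- atanh(rho1)
  z2 <- atanh(rho2)
  stat <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(z1 = z1, z2 = z2, statistic = stat,
         p = 2 * pnorm(-abs(stat)))
}

#' Two-sample variance F-test
#'
#' Thin wrapper over [stats::var.test()] returning a tidy row.
#'
#' @param x,y Numeric vectors.
#' @return Tibble `f`, `df1`, `df2`, `p`.
#' @export
variance_f_test <- function(x, y) {
  vt <- var.test(x, y)
  tibble(f = unname(vt$statistic), df1 = unname(vt$parameter[1]),
         df2 = unname(vt$parameter[2]), p = vt$p.value)
}

#' Run the full phenotype-preparation pipeline
#'
#' Applies, in order: detection filter, LOD/sqrt(2) imputation, natural log,
#' covariate screening, residualization with outlier masking on residuals.
#'
#' @param values Tibble of raw concentrations (id columns allowed).
#' @param analyte_meta Tibble `name`, `lod`, optional `outlier_sd_threshold`.
#' @param covariates Data frame of candidate covariates.
#' @param min_fraction Detection threshold (default 0.6).
#' @param alpha,min_hits Covariate-screen parameters.
#' @return List of class `pheno_prep`: `detection`, `screen`,
#'   `residuals` (a `residual_table`), `kept_analytes`,
#'   `selected_covariates`.
#' @export
prepare_phenotypes <- function(values, analyte_meta, covariates,
                               min_fraction = 0.6, alpha = 0.05,
                               min_hits = 3) {
  det <- detection_filter(values, analyte_meta, min_fraction)
  kept <- det$name[det$kept]
  logged <- as.data.frame(lapply(setNames(kept, kept), function(nm) {
    lod_impute_and_log(values[[nm]], det$lod[det$name == nm])
  }))
  screen <- covariate_screen(logged, covariates, alpha, min_hits)
  sel <- screen$covariate[screen$selected]
  thr <- if ("outlier_sd_threshold" %in% names(analyte_meta)) {
    max(analyte_meta$outlier_sd_threshold)
  } else 4
  res <- residualize(logged,
                     covariates = as.data.frame(covariates)[, sel, drop = FALSE],
                     sd_threshold = thr)
  structure(
    list(detection = det, screen = screen, residuals = res,
         kept_analytes = kept, selected_covariates = sel),
    class = "pheno_prep"
  )
}
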
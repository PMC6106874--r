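# Case-control outcome models -----------------------------------------------

#' Two-sample Mann-Whitney Wilcoxon comparison of mediator residuals
#'
#' Rank-sum test of case versus control residuals: exact enumeration when
#' the smaller group has fewer than 10 observations and the data are
#' untied, otherwise the tie-corrected normal approximation.
#'
#' @param residuals Numeric vector.
#' @param status 0/1 (or two-level) case status.
#' @return Tibble `statistic` (rank-sum W), `p`, `n_case`, `n_control`,
#'   `exact`.
#' @export
case_control_wilcoxon <- function(residuals, status) {
  ok <- complete.cases(residuals, status)
  r <- residuals[ok]
  s <- status[ok]
  lv <- sort(unique(s))
  if (length(lv) != 2) stop_dyad("status must have exactly two classes", "status")
  g1 <- r[s == lv[2]]   # cases
  g0 <- r[s == lv[1]]
  use_exact <- min(length(g1), length(g0)) < 10 &&
    !anyDuplicated(c(g1, g0))
  wt <- suppressWarnings(
    wilcox.test(g1, g0, exact = use_exact, correct = !use_exact)
  )
  tibble(statistic = unname(wt$statistic), p = wt$p.value,
         n_case = length(g1), n_control = length(g0), exact = use_exact)
}

# tidy one glm into OutcomeResult rows
tidy_logistic <- function(fit, n) {
  sm <- unname(summary(fit)$coefficients)
  tibble(
    term = rownames(summary(fit)$coefficients),
    beta = sm[, 1], se = sm[, 2],
    or = exp(sm[, 1]),
    ci_lo = exp(sm[, 1] - 1.96 * sm[, 2]),
    ci_hi = exp(sm[, 1] + 1.96 * sm[, 2]),
    statistic = sm[, 3], p = sm[, 4], n = n
  )
}

check_separation <- function(fit) {
  mu <- fit$fitted.values
  if (any(mu < 1e-8) || any(mu > 1 - 1e-8) ||
      any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop_dyad("(quasi-)complete separation detected in logistic fit",
              "separation")
  }
}

#' Logistic model of a binary outcome on a mediator
#'
#' Maximum-likelihood logistic regression of case status on mediator
#' residuals plus covariates; Wald statistics with odds ratios and normal
#' 95\% confidence intervals. Complete separation is a flagged error, never
#' a silently divergent fit.
#'
#' @param mediator_residuals Numeric vector.
#' @param covariates Covariate data frame (`NULL` ok).
#' @param status 0/1 outcome.
#' @return Tibble of per-term rows (see [interaction_model()] for columns).
#' @export
logistic_outcome <- function(mediator_residuals, covariates = NULL, status) {
  d <- data.frame(status = status, mediator = mediator_residuals)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[complete.cases(d), , drop = FALSE]
  # separation is detected explicitly below; glm's own divergence warnings
  # would only duplicate that signal
  fit <- suppressWarnings(glm(status ~ ., data = d, family = binomial()))
  check_separation(fit)
  tidy_logistic(fit, nrow(d))
}

#' SNP-by-mediator interaction model for a binary outcome
#'
#' Fits `status ~ snp + mediator + snp:mediator + covariates` by logistic
#' regression (genotype treated additively) and reports every term's Wald
#' test; the `snp:mediator` row is the interaction of interest. Optionally
#' adds genotype-stratified Mann-Whitney case/control comparisons of the
#' mediator, with rare homozygotes either kept as their own stratum,
#' dropped, or collapsed into the heterozygote class.
#'
#' @param status 0/1 outcome.
#' @param snp_dosage Genotype dosage vector (0/1/2).
#' @param mediator Mediator residual vector.
#' @param covariates Covariate data frame (`NULL` ok).
#' @param stratified Also compute per-genotype Mann-Whitney contrasts.
#' @param collapse_rare_hom Collapse the rarer homozygote class into the
#'   heterozygote stratum (explicit flag; default `FALSE`).
#' @return List of class `interaction_fit`: `terms` (tibble, one row per
#'   model term), `strata` (tibble or `NULL`).
#' @export
interaction_model <- function(status, snp_dosage, mediator,
                              covariates = NULL, stratified = FALSE,
                              collapse_rare_hom = FALSE) {
  d <- data.frame(status = status, snp = snp_dosage, mediator = mediator)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  d <- d[complete.cases(d), , drop = FALSE]
  others <- setdiff(names(d), c("status", "snp", "mediator"))
  form <- as.formula(paste(
    "status ~ snp * mediator",
    if (length(others)) paste("+", paste(others, collapse = " + ")) else ""
  ))
  fit <- suppressWarnings(glm(form, data = d, family = binomial()))
  check_separation(fit)
  terms <- tidy_logistic(fit, nrow(d))
  strata <- NULL
  if (stratified) {
    g <- d$snp
    if (collapse_rare_hom) {
      hom_counts <- c(`0` = sum(g == 0), `2` = sum(g == 2))
      rare <- as.integer(names(which.min(hom_counts)))
      g[g == rare] <- 1L
    }
    strata <- dplyr::bind_rows(lapply(sort(unique(g)), function(gg) {
      sel <- g == gg
      if (length(unique(d$status[sel])) < 2) {
        message(sprintf("genotype stratum %s has a single outcome class; skipped", gg))
        return(NULL)
      }
      cw <- case_control_wilcoxon(d$mediator[sel], d$status[sel])
      dplyr::mutate(cw, genotype = gg, .before = 1)
    }))
  }
  structure(list(terms = terms, strata = strata), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  int <- x$terms[grepl(":", x$terms$term), ]
  cat(sprintf("<interaction_fit> snp:mediator beta = %.3f (SE %.3f), p = %.3g\n",
              int$beta[1], int$se[1], int$p[1]))
  invisible(x)
}

#' Tidy an interaction fit
#'
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @return The per-term tibble.
#' @export
tidy.interaction_fit <- function(x, ...) x$terms
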
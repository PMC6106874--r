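# Restricted maximum likelihood variance components --------------------------
#
# Model: y = C b + g + e, g ~ N(0, s2g A), e ~ N(0, s2e I).
# V = s2g A + s2e I. The GRM eigendecomposition A = U D U' reduces every
# iteration to diagonal algebra: with y* = U'y and C* = U'C,
# V* = s2g D + s2e I. Updates are average-information steps with a
# Fisher-scoring (expected information) fallback when an AI step fails to
# increase the restricted likelihood.

# Rotated-space restricted log-likelihood and derivatives.
# d: eigenvalues; ys: U'y; Cs: U'C; th = c(s2g, s2e).
reml_eval <- function(th, d, ys, Cs, want_info = c("none", "ai", "fisher")) {
  want_info <- match.arg(want_info)
  v <- th[1] * d + th[2]
  if (any(v <= 0)) return(list(ll = -Inf))
  n <- length(ys)
  c_ <- ncol(Cs)
  W <- Cs / v
  B <- crossprod(Cs, W)                      # C'V^-1 C
  Bch <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(Bch)) return(list(ll = -Inf))
  Binv <- chol2inv(Bch)
  cvy <- crossprod(W, ys)                    # C'V^-1 y
  alpha <- Binv %*% cvy
  py <- ys / v - W %*% alpha                 # P y
  ypy <- sum(ys * py)
  ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(Bch))) + ypy)
  out <- list(ll = ll, py = as.numeric(py), v = v, W = W, Binv = Binv,
              ypy = ypy)
  if (want_info == "none") return(out)

  # gradient: dll/dthi = -0.5 (tr(P Vi) - py' Vi py), Vi = diag(di) resp. I
  tr_p_diag <- function(dd) {
    sum(dd / v) - sum((crossprod(Cs * (dd / v^2), Cs)) * Binv)
  }
  py_n <- as.numeric(py)
  grad <- c(
    -0.5 * (tr_p_diag(d) - sum(py_n^2 * d)),
    -0.5 * (tr_p_diag(rep(1, n)) - sum(py_n^2))
  )
  # P x = V^-1 x - W Binv C' V^-1 x  (with W = V^-1 C)
  apply_p <- function(x) as.numeric(x / v - W %*% (Binv %*% crossprod(Cs, x / v)))
  if (want_info == "ai") {
    wg <- d * py_n                           # V.g P y
    we <- py_n                               # V.e P y
    pwg <- apply_p(wg)
    pwe <- apply_p(we)
    info <- 0.5 * matrix(c(sum(wg * pwg), sum(wg * pwe),
                           sum(wg * pwe), sum(we * pwe)), 2, 2)
  } else {
    # expected information: 0.5 tr(P Vi P Vj) with P = R - S,
    # R = diag(1/v), S = W Binv W'
    tr_pp <- function(di, dj) {
      t1 <- sum(di * dj / v^2)
      M1 <- crossprod(Cs * (di * dj / v^3), Cs)      # W' Dj R Di W variants
      t2 <- sum(M1 * Binv)
      Mi <- crossprod(Cs * (di / v^2), Cs)
      Mj <- crossprod(Cs * (dj / v^2), Cs)
      t3 <- sum((Binv %*% Mi) * t(Binv %*% Mj))
      t1 - 2 * t2 + t3
    }
    one <- rep(1, n)
    info <- 0.5 * matrix(c(tr_pp(d, d), tr_pp(d, one),
                           tr_pp(d, one), tr_pp(one, one)), 2, 2)
  }
  out$grad <- grad
  out$info <- info
  out
}

#' Univariate REML estimation of SNP-based heritability
#'
#' Fits `y = C b + g + e` with `g ~ N(0, s2g A)` by restricted maximum
#' likelihood using average-information updates with step-halving; when an
#' AI step cannot increase the restricted likelihood the update falls back
#' to Fisher scoring. Variance components are constrained non-negative
#' (projected to a small floor each iteration). The reported
#' `h2g = s2g / (s2g + s2e)` and its standard error come from the inverse
#' information at the optimum by the delta method; `lrt_p` compares the full
#' model against `s2g = 0` using the boundary mixture
#' `p = 0.5 P(chi2_1 > LRT)`.
#'
#' @param y Numeric phenotype vector.
#' @param covariates Covariate matrix / data frame (intercept added
#'   automatically; `NULL` for intercept only).
#' @param A A `grm` object or symmetric relatedness matrix.
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence tolerance on the restricted log-likelihood change
#'   and the maximum relative component change (default 1e-4).
#' @param algorithm `"ai"` (default, with Fisher fallback) or `"fisher"`.
#' @param constrain Keep components non-negative (default `TRUE`).
#' @param eigen_A Optional precomputed `eigen(A, symmetric = TRUE)` to reuse
#'   across fits on the same GRM.
#' @return Object of class `reml_fit` with elements `sigma2_g`, `sigma2_e`,
#'   `h2g`, `se_h2g`, `se_sigma2`, `loglik_full`, `loglik_null`, `lrt`,
#'   `lrt_p`, `n_iter`, `algorithm`, `converged`, `n`.
#' @export
reml_univariate <- function(y, covariates = NULL, A,
                            max_iter = 100, tol = 1e-4,
                            algorithm = c("ai", "fisher"),
                            constrain = TRUE, eigen_A = NULL) {
  algorithm <- match.arg(algorithm)
  if (inherits(A, "grm")) A <- A$values
  n <- length(y)
  stopifnot(nrow(A) == n)
  if (n < 30) warning("fewer than 30 samples: REML estimates are unstable")
  C <- build_design(covariates, n)
  eg <- eigen_A %||% eigen(A, symmetric = TRUE)
  d <- eg$values
  if (sd(d) < 1e-10 * max(abs(d), 1)) {
    stop_dyad(paste("GRM eigenvalues are constant (A proportional to I):",
                    "s2g and s2e are unidentifiable"), "identifiability")
  }
  ys <- crossprod(eg$vectors, y)
  Cs <- crossprod(eg$vectors, C)
  vp <- var(y)
  floor_v <- 1e-6 * vp
  th <- c(vp / 2, vp / 2)
  used_fisher <- FALSE
  cur <- reml_eval(th, d, ys, Cs, want_info = "none")
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    mode <- if (algorithm == "fisher") "fisher" else "ai"
    ev <- reml_eval(th, d, ys, Cs, want_info = mode)
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step)) {
      sc <- 1
      for (half in 1:20) {
        th_new <- th + sc * step
        if (constrain) th_new <- pmax(th_new, floor_v)
        ev_new <- reml_eval(th_new, d, ys, Cs, want_info = "none")
        if (is.finite(ev_new$ll) && ev_new$ll >= ev$ll - 1e-10) {
          accepted <- TRUE
          break
        }
        sc <- sc / 2
      }
    }
    if (!accepted && algorithm == "ai") {
      # Fisher-scoring fallback for steps that cannot increase the likelihood
      used_fisher <- TRUE
      evf <- reml_eval(th, d, ys, Cs, want_info = "fisher")
      step <- tryCatch(solve(evf$info, evf$grad), error = function(e) NULL)
      if (!is.null(step)) {
        sc <- 1
        for (half in 1:20) {
          th_new <- th + sc * step
          if (constrain) th_new <- pmax(th_new, floor_v)
          ev_new <- reml_eval(th_new, d, ys, Cs, want_info = "none")
          if (is.finite(ev_new$ll) && ev_new$ll >= evf$ll - 1e-10) {
            accepted <- TRUE
            break
          }
          sc <- sc / 2
        }
      }
    }
    if (!accepted) break
    rel <- max(abs(th_new - th) / pmax(abs(th), floor_v))
    dll <- ev_new$ll - cur$ll
    th <- th_new
    cur <- ev_new
    if (abs(dll) < tol && rel < tol) {
      converged <- TRUE
      break
    }
  }
  # information at the optimum for standard errors
  ev_fin <- reml_eval(th, d, ys, Cs,
                      want_info = if (algorithm == "fisher" || used_fisher)
                        "fisher" else "ai")
  cov_th <- tryCatch(solve(ev_fin$info), error = function(e)
    matrix(NA_real_, 2, 2))
  s2g <- th[1]
  s2e <- th[2]
  s2p <- s2g + s2e
  h2 <- s2g / s2p
  grad_h2 <- c(s2e, -s2g) / s2p^2
  se_h2 <- sqrt(max(drop(t(grad_h2) %*% cov_th %*% grad_h2), 0))

  # null model s2g = 0: profile OLS
  ll0 <- reml_null_loglik(ys, Cs)
  lrt <- max(0, 2 * (cur$ll - ll0))
  lrt_p <- 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(
    list(sigma2_g = s2g, sigma2_e = s2e, h2g = h2, se_h2g = se_h2,
         se_sigma2 = sqrt(pmax(diag(cov_th), 0)),
         loglik_full = cur$ll, loglik_null = ll0,
         lrt = lrt, lrt_p = max(min(lrt_p, 1), .Machine$double.xmin),
         n_iter = iter,
         algorithm = if (algorithm == "fisher") "Fisher" else
           if (used_fisher) "AI+Fisher" else "AI",
         converged = converged, n = n),
    class = "reml_fit"
  )
}

# restricted log-likelihood of the s2g = 0 model (same constant convention)
reml_null_loglik <- function(ys, Cs) {
  n <- length(ys)
  c_ <- ncol(Cs)
  fit <- lm.fit(Cs, ys)
  rss <- sum(fit$residuals^2)
  s2e <- rss / (n - c_)
  v <- rep(s2e, n)
  B <- crossprod(Cs) / s2e
  -0.5 * (sum(log(v)) + determinant(B, logarithm = TRUE)$modulus[1] +
            rss / s2e)
}

build_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  C <- cbind(`(Intercept)` = 1, C)
  q <- qr(C)
  if (q$rank < ncol(C)) C <- C[, q$pivot[seq_len(q$rank)], drop = FALSE]
  C
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> h2g = %.3f (SE %.3f), s2g = %.4f, s2e = %.4f\n  LRT p = %.3g, %s, %d iter, converged: %s\n",
    x$h2g, x$se_h2g, x$sigma2_g, x$sigma2_e, x$lrt_p, x$algorithm,
    x$n_iter, x$converged))
  invisible(x)
}

#' Tidy a REML fit into one row per component
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(
    term = c("sigma2_g", "sigma2_e", "h2g"),
    estimate = c(x$sigma2_g, x$sigma2_e, x$h2g),
    std.error = c(x$se_sigma2, x$se_h2g)
  )
}

#' One-row summary of a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return One-row tibble with heritability, likelihoods and convergence.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(
    h2g = x$h2g, se_h2g = x$se_h2g, sigma2_g = x$sigma2_g,
    sigma2_e = x$sigma2_e, loglik_full = x$loglik_full,
    loglik_null = x$loglik_null, lrt_p = x$lrt_p, n_iter = x$n_iter,
    algorithm = x$algorithm, converged = x$converged, n = x$n
  )
}

#' Permutation null distribution of the heritability estimate
#'
#' Re-estimates `h2g` after permuting phenotype records (by default the
#' phenotype and its covariate row are swapped together, a full label swap
#' against the genotypes; `mode = "phenotype"` permutes the phenotype
#' alone). Reports the permuted estimates, their median, and the empirical
#' quantile of the observed estimate.
#'
#' @param y,covariates,A As in [reml_univariate()].
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for the permutation stream.
#' @param mode `"record"` (default) or `"phenotype"`.
#' @param ... Passed to [reml_univariate()].
#' @return Object of class `perm_null`: `observed` (`reml_fit`), `h2_perm`,
#'   `median_perm`, `quantile_observed`, `top5` (is the observed estimate in
#'   the top 5\% of the permuted distribution).
#' @export
permutation_null <- function(y, covariates = NULL, A, n_perm = 100,
                             seed = 1L, mode = c("record", "phenotype"),
                             ...) {
  mode <- match.arg(mode)
  if (inherits(A, "grm")) A <- A$values
  eg <- eigen(A, symmetric = TRUE)
  obs <- reml_univariate(y, covariates, A, eigen_A = eg, ...)
  Cdf <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  h2p <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(y))
      Cb <- if (mode == "record" && !is.null(Cdf)) Cdf[idx, , drop = FALSE] else Cdf
      fit <- suppressWarnings(
        reml_univariate(y[idx], Cb, A, eigen_A = eg, ...)
      )
      fit$h2g
    }, numeric(1))
  })
  structure(
    list(observed = obs, h2_perm = h2p, median_perm = median(h2p),
         quantile_observed = mean(h2p < obs$h2g),
         top5 = mean(h2p >= obs$h2g) <= 0.05),
    class = "perm_null"
  )
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf(
    "<perm_null> observed h2g = %.3f at quantile %.2f of %d permutations (median %.3f)\n",
    x$observed$h2g, x$quantile_observed, length(x$h2_perm), x$median_perm))
  invisible(x)
}

#' Plot a permutation null distribution
#'
#' @param object A `perm_null` object.
#' @param ... Unused.
#' @return A ggplot object: permuted h2g histogram with the observed value.
#' @export
autoplot.perm_null <- function(object, ...) {
  df <- tibble(h2 = object$h2_perm)
  ggplot2::ggplot(df, ggplot2::aes(.data$h2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed$h2g,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "permuted h2g", y = "count") +
    ggplot2::theme_minimal()
}

#' GREML power approximation
#'
#' The standard error of a SNP-based heritability estimate is approximated
#' by `SE(h2) ~ sqrt(2 / (n^2 var_offdiag))`, with `var_offdiag` the
#' variance of the GRM off-diagonal entries; power is a one-sided normal
#' test of `h2 / SE` at level `alpha`.
#'
#' @param n Sample size.
#' @param true_h2 Assumed heritability.
#' @param var_offdiag Variance of GRM off-diagonal entries (about `1/m` for
#'   `m` independent SNPs in an unstructured cohort).
#' @param alpha Test level (default 0.05).
#' @return Tibble `n`, `true_h2`, `se_approx`, `power`.
#' @export
greml_power <- function(n, true_h2, var_offdiag, alpha = 0.05) {
  stopifnot(var_offdiag > 0)
  se <- sqrt(2 / (n^2 * var_offdiag))
  power <- pnorm(true_h2 / se - qnorm(1 - alpha))
  tibble(n = n, true_h2 = true_h2, se_approx = se, power = power)
}
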
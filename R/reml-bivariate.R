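# Bivariate REML: genetic covariance and correlation between two traits -----
#
# Stacked model for traits (y1, y2) on the same samples and GRM A:
# genetic covariance matrix G = [[g1, g12], [g12, g2]] scaled by A, residual
# covariance E = [[e1, e12], [e12, e2]] scaled by I. After rotation by the
# GRM eigenvectors the covariance is block-diagonal in per-sample 2x2 blocks
# V_i = d_i G + E, so every quantity reduces to vectorized 2x2 algebra.

# blockwise inverse of V_i = d_i G + E; returns entry vectors and logdet
biv_blocks <- function(th, d) {
  v11 <- th[1] * d + th[4]
  v12 <- th[2] * d + th[5]
  v22 <- th[3] * d + th[6]
  det <- v11 * v22 - v12^2
  if (any(det <= 0) || any(v11 <= 0) || any(v22 <= 0)) return(NULL)
  list(a = v22 / det, b = -v12 / det, dd = v11 / det,
       logdet = sum(log(det)))
}

# apply blockdiag 2x2 operator (a,b,dd) to trait-pair vectors
biv_apply <- function(bl, x1, x2) {
  list(bl$a * x1 + bl$b * x2, bl$b * x1 + bl$dd * x2)
}

# V-dot structure per parameter k = 1..6: (m11, m12, m22, weight)
biv_vdot <- function(k, d, n) {
  w <- if (k <= 3) d else rep(1, n)
  m <- switch(k, c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  list(m11 = m[1] * w, m12 = m[2] * w, m22 = m[3] * w)
}

biv_eval <- function(th, d, ys1, ys2, Cs, want_info = c("none", "ai", "fisher")) {
  want_info <- match.arg(want_info)
  bl <- biv_blocks(th, d)
  if (is.null(bl)) return(list(ll = -Inf))
  n <- length(d)
  c_ <- ncol(Cs)
  # B = X' V^-1 X in trait blocks
  B <- rbind(
    cbind(crossprod(Cs, bl$a * Cs), crossprod(Cs, bl$b * Cs)),
    cbind(crossprod(Cs, bl$b * Cs), crossprod(Cs, bl$dd * Cs))
  )
  Bch <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(Bch)) return(list(ll = -Inf))
  Binv <- chol2inv(Bch)
  viy <- biv_apply(bl, ys1, ys2)
  u <- c(crossprod(Cs, viy[[1]]), crossprod(Cs, viy[[2]]))
  alpha <- Binv %*% u
  a1 <- alpha[seq_len(c_)]
  a2 <- alpha[c_ + seq_len(c_)]
  xa1 <- drop(Cs %*% a1)
  xa2 <- drop(Cs %*% a2)
  vxa <- biv_apply(bl, xa1, xa2)
  py1 <- viy[[1]] - vxa[[1]]
  py2 <- viy[[2]] - vxa[[2]]
  ypy <- sum(ys1 * py1) + sum(ys2 * py2)
  ll <- -0.5 * (bl$logdet + 2 * sum(log(diag(Bch))) + ypy)
  out <- list(ll = ll, py1 = py1, py2 = py2, bl = bl, Binv = Binv)
  if (want_info == "none") return(out)

  # P x = V^-1 x - V^-1 X Binv X' V^-1 x
  apply_p <- function(x1, x2) {
    vx <- biv_apply(bl, x1, x2)
    uu <- c(crossprod(Cs, vx[[1]]), crossprod(Cs, vx[[2]]))
    aa <- Binv %*% uu
    xb1 <- drop(Cs %*% aa[seq_len(c_)])
    xb2 <- drop(Cs %*% aa[c_ + seq_len(c_)])
    vb <- biv_apply(bl, xb1, xb2)
    list(vx[[1]] - vb[[1]], vx[[2]] - vb[[2]])
  }
  vd <- lapply(1:6, biv_vdot, d = d, n = n)
  # gradient
  grad <- numeric(6)
  for (k in 1:6) {
    m <- vd[[k]]
    # tr(V^-1 Vdot_k)
    tr1 <- sum(bl$a * m$m11 + 2 * bl$b * m$m12 + bl$dd * m$m22)
    # T_i = V^-1 M V^-1 per block (symmetric)
    t11 <- bl$a * m$m11 * bl$a + 2 * bl$a * m$m12 * bl$b + bl$b * m$m22 * bl$b
    t12 <- bl$a * m$m11 * bl$b + bl$a * m$m12 * bl$dd + bl$b * m$m12 * bl$b +
      bl$b * m$m22 * bl$dd
    t22 <- bl$b * m$m11 * bl$b + 2 * bl$b * m$m12 * bl$dd +
      bl$dd * m$m22 * bl$dd
    XtX <- rbind(
      cbind(crossprod(Cs, t11 * Cs), crossprod(Cs, t12 * Cs)),
      cbind(crossprod(Cs, t12 * Cs), crossprod(Cs, t22 * Cs))
    )
    tr_p <- tr1 - sum(Binv * XtX)
    vpy <- c(sum(py1 * (m$m11 * py1 + m$m12 * py2)) +
               sum(py2 * (m$m12 * py1 + m$m22 * py2)))
    grad[k] <- -0.5 * (tr_p - vpy)
  }
  # average information
  wv <- lapply(vd, function(m) {
    list(m$m11 * py1 + m$m12 * py2, m$m12 * py1 + m$m22 * py2)
  })
  pw <- lapply(wv, function(w) apply_p(w[[1]], w[[2]]))
  info <- matrix(0, 6, 6)
  for (k in 1:6) {
    for (j in k:6) {
      info[k, j] <- info[j, k] <-
        0.5 * (sum(wv[[k]][[1]] * pw[[j]][[1]]) +
                 sum(wv[[k]][[2]] * pw[[j]][[2]]))
    }
  }
  out$grad <- grad
  out$info <- info
  out
}

# project parameters to the feasible region
biv_project <- function(th, floor_v) {
  th[c(1, 3, 4, 6)] <- pmax(th[c(1, 3, 4, 6)], floor_v)
  cap_g <- sqrt(th[1] * th[3]) * (1 - 1e-6)
  cap_e <- sqrt(th[4] * th[6]) * (1 - 1e-6)
  th[2] <- max(min(th[2], cap_g), -cap_g)
  th[5] <- max(min(th[5], cap_e), -cap_e)
  th
}

#' Bivariate REML estimation of the genetic correlation
#'
#' Jointly fits genetic and residual (co)variance components for two traits
#' measured on the same samples and reports
#' `rg = sigma_g12 / sqrt(sigma2_g1 * sigma2_g2)` with a delta-method
#' standard error from the inverse average information. Average-information
#' updates with step-halving; `|rg|` is clamped to 1 at the boundary with a
#' warning. Identical traits are a degenerate input (singular residual
#' covariance) and return `rg = 1` directly.
#'
#' @param y1,y2 Phenotype vectors on the same samples.
#' @param covariates Shared covariate matrix (intercept added; `NULL` ok).
#' @param A A `grm` object or relatedness matrix.
#' @param max_iter,tol As in [reml_univariate()].
#' @param eigen_A Optional precomputed eigendecomposition of `A`.
#' @return Object of class `reml_biv_fit`: `rg`, `se_rg`, `sigma_g12`,
#'   `components` (named 6-vector), `loglik`, `n_iter`, `converged`,
#'   `boundary`, `n`.
#' @export
reml_bivariate <- function(y1, y2, covariates = NULL, A,
                           max_iter = 200, tol = 1e-4, eigen_A = NULL) {
  if (inherits(A, "grm")) A <- A$values
  n <- length(y1)
  stopifnot(length(y2) == n, nrow(A) == n)
  if (stats::cor(y1, y2) > 1 - 1e-10) {
    warning("traits are (numerically) identical: returning rg = 1")
    return(structure(
      list(rg = 1, se_rg = 0, sigma_g12 = NA_real_,
           components = setNames(rep(NA_real_, 6),
                                 c("g1", "g12", "g2", "e1", "e12", "e2")),
           loglik = NA_real_, n_iter = 0L, converged = TRUE,
           boundary = TRUE, n = n),
      class = "reml_biv_fit"
    ))
  }
  C <- build_design(covariates, n)
  eg <- eigen_A %||% eigen(A, symmetric = TRUE)
  d <- eg$values
  ys1 <- drop(crossprod(eg$vectors, y1))
  ys2 <- drop(crossprod(eg$vectors, y2))
  Cs <- crossprod(eg$vectors, C)

  f1 <- suppressWarnings(reml_univariate(y1, covariates, A, eigen_A = eg))
  f2 <- suppressWarnings(reml_univariate(y2, covariates, A, eigen_A = eg))
  r0 <- stats::cor(y1, y2)
  th <- c(f1$sigma2_g, 0.5 * r0 * sqrt(f1$sigma2_g * f2$sigma2_g),
          f2$sigma2_g,
          f1$sigma2_e, 0.5 * r0 * sqrt(f1$sigma2_e * f2$sigma2_e),
          f2$sigma2_e)
  floor_v <- 1e-6 * max(var(y1), var(y2))
  th <- biv_project(th, floor_v)
  cur <- biv_eval(th, d, ys1, ys2, Cs)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    ev <- biv_eval(th, d, ys1, ys2, Cs, want_info = "ai")
    if (!is.finite(ev$ll)) break
    step <- tryCatch(solve(ev$info + diag(1e-8, 6), ev$grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    accepted <- FALSE
    sc <- 1
    for (half in 1:25) {
      th_new <- biv_project(th + sc * step, floor_v)
      ev_new <- biv_eval(th_new, d, ys1, ys2, Cs)
      if (is.finite(ev_new$ll) && ev_new$ll >= ev$ll - 1e-10) {
        accepted <- TRUE
        break
      }
      sc <- sc / 2
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
  ev_fin <- biv_eval(th, d, ys1, ys2, Cs, want_info = "ai")
  cov_th <- tryCatch(solve(ev_fin$info + diag(1e-10, 6)),
                     error = function(e) matrix(NA_real_, 6, 6))
  g1 <- th[1]; g12 <- th[2]; g2 <- th[3]
  rg <- g12 / sqrt(g1 * g2)
  boundary <- abs(rg) >= 1 - 1e-5
  if (abs(rg) > 1) {
    warning("rg at the boundary; clamped to +/-1")
    rg <- sign(rg)
  }
  grad_rg <- c(-rg / (2 * g1), 1 / sqrt(g1 * g2), -rg / (2 * g2))
  se_rg <- sqrt(max(drop(t(grad_rg) %*% cov_th[1:3, 1:3] %*% grad_rg), 0))
  structure(
    list(rg = rg, se_rg = se_rg, sigma_g12 = g12,
         components = setNames(th, c("g1", "g12", "g2", "e1", "e12", "e2")),
         loglik = cur$ll, n_iter = iter, converged = converged,
         boundary = boundary, n = n),
    class = "reml_biv_fit"
  )
}

#' @export
print.reml_biv_fit <- function(x, ...) {
  cat(sprintf("<reml_biv_fit> rg = %.3f (SE %.3f), %d iter, converged: %s\n",
              x$rg, x$se_rg, x$n_iter, x$converged))
  invisible(x)
}

#' Tidy a bivariate REML fit
#'
#' @param x A `reml_biv_fit`.
#' @param ... Unused.
#' @return Tibble with the six (co)variance components and `rg`.
#' @export
tidy.reml_biv_fit <- function(x, ...) {
  tibble(
    term = c(names(x$components), "rg"),
    estimate = c(unname(x$components), x$rg),
    std.error = c(rep(NA_real_, 6), x$se_rg)
  )
}

#' One-row summary of a bivariate REML fit
#'
#' @param x A `reml_biv_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.reml_biv_fit <- function(x, ...) {
  tibble(rg = x$rg, se_rg = x$se_rg, sigma_g12 = x$sigma_g12,
         loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         boundary = x$boundary, n = x$n)
}
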
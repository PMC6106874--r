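# Independent oracles used across the suite. These deliberately use naive,
# dense, closed-form computations so they share no code path with the
# package implementations they check.

# dense restricted log-likelihood for V = s2g A + s2e I (direct solves)
dense_reml_ll <- function(s2g, s2e, y, C, A) {
  n <- length(y)
  V <- s2g * A + s2e * diag(n)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(-Inf)
  B <- t(C) %*% Vi %*% C
  ldV <- determinant(V, logarithm = TRUE)$modulus[1]
  ldB <- determinant(B, logarithm = TRUE)$modulus[1]
  P <- Vi - Vi %*% C %*% solve(B) %*% t(C) %*% Vi
  -0.5 * (ldV + ldB + drop(t(y) %*% P %*% y))
}

# 200 x 200 grid search of the restricted likelihood over (h2, s2p), then a
# fine profile refinement in h2 (nested 1-d optimizations, still dense)
grid_reml_h2 <- function(y, C, A, n_grid = 200) {
  vp <- var(y)
  h2s <- seq(0, 0.999, length.out = n_grid)
  s2ps <- seq(vp / 4, vp * 3, length.out = n_grid)
  best <- c(ll = -Inf, h2 = NA, s2p = NA)
  for (h2 in h2s) {
    lls <- vapply(s2ps, function(sp)
      dense_reml_ll(h2 * sp, (1 - h2) * sp, y, C, A), numeric(1))
    i <- which.max(lls)
    if (lls[i] > best["ll"]) best <- c(ll = lls[i], h2 = h2, s2p = s2ps[i])
  }
  prof <- function(h2) {
    optimize(function(sp) dense_reml_ll(h2 * sp, (1 - h2) * sp, y, C, A),
             interval = range(s2ps), maximum = TRUE)$objective
  }
  lo <- max(0, best["h2"] - 0.02)
  hi <- min(0.999, best["h2"] + 0.02)
  fine <- optimize(prof, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  list(h2 = fine$maximum, ll = fine$objective, grid_h2 = unname(best["h2"]))
}

# exact HWE probabilities by full enumeration with log-factorials
hwe_enum_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n - n_a
  lp_het <- function(h) {
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    if (h < 0 || haa < 0 || hbb < 0 || (n_a - h) %% 2 != 0) return(-Inf)
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }
  hets <- 0:min(n_a, n_b)
  lp <- vapply(hets, lp_het, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-12)])
}

# logistic regression by hand-written IRLS
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  beta
}

# Procrustes error after optimal rotation/reflection + translation
procrustes_error <- function(target, recovered) {
  ct <- scale(target, scale = FALSE)
  cr <- scale(recovered, scale = FALSE)
  sv <- svd(t(cr) %*% ct)
  rot <- sv$u %*% t(sv$v)
  # allow scale (cmdscale preserves distances, so scale should be ~1)
  aligned <- cr %*% rot
  s <- sum(aligned * ct) / sum(aligned^2)
  sqrt(mean((s * aligned - ct)^2)) / sqrt(mean(ct^2))
}

# Hudson Fst estimator (ratio of averages) from two population frequency rows
hudson_fst <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# all permutations of 1..n (for exhaustive small-n rank tests)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# small random diploid geno_matrix fixture
random_geno <- function(n, m, miss_rate = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  x <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss_rate > 0) x[runif(n * m) < miss_rate] <- NA
  geno_matrix(
    x,
    tibble::tibble(snp = paste0("s", 1:m), chr = "1", pos = 1:m,
                   a1 = "A", a2 = "G"),
    tibble::tibble(sample_id = paste0("i", 1:n), sex = 0L, pheno = -9)
  )
}

# toy univariate heritability problem (shared across REML tests)
make_toy <- function(n, m, h2, seed) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  x <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  w <- scale(x)
  A <- tcrossprod(w) / m
  g <- drop(w %*% rnorm(m))
  g <- g / sd(g) * sqrt(h2)
  y <- g + rnorm(n, sd = sqrt(1 - h2))
  list(y = y, A = A)
}

# toy bivariate problem with built-in genetic correlation
make_biv <- function(n, m, h2, rg, seed) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  x <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  w <- scale(x)
  A <- tcrossprod(w) / m
  u1 <- rnorm(m)
  u2 <- rg * u1 + sqrt(1 - rg^2) * rnorm(m)
  mk <- function(u) {
    g <- drop(w %*% u)
    g / sd(g) * sqrt(h2)
  }
  y1 <- mk(u1) + rnorm(n, sd = sqrt(1 - h2))
  y2 <- mk(u2) + rnorm(n, sd = sqrt(1 - h2))
  list(y1 = y1, y2 = y2, A = A)
}
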
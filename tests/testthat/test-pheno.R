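# Analyte preparation pipeline

test_that("detection filter applies a strict > threshold", {
  vals <- tibble::tibble(
    a = c(rep(10, 61), rep(1, 39)),   # 61% above LOD = 2
    b = c(rep(10, 60), rep(1, 40)),   # exactly 60%
    c = rep(10, 100)                  # all above
  )
  meta <- tibble::tibble(name = c("a", "b", "c"), lod = 2)
  det <- detection_filter(vals, meta, min_fraction = 0.6)
  expect_equal(det$kept, c(TRUE, FALSE, TRUE))
  expect_error(
    detection_filter(vals, tibble::tibble(name = "a", lod = NA_real_)),
    class = "dyadherit_lod"
  )
})

test_that("LOD imputation replaces sub-LOD values with LOD/sqrt(2) then logs", {
  expect_equal(lod_impute_and_log(1, lod = 2), log(sqrt(2)))
  expect_equal(lod_impute_and_log(2, lod = 2), log(2))     # at LOD: unchanged
  expect_equal(lod_impute_and_log(10, lod = 2), log(10))
  expect_error(lod_impute_and_log(1, lod = 0), class = "dyadherit_lod")
})

test_that("outlier mask matches the normal tail and never re-iterates", {
  set.seed(1)
  v <- rnorm(1e5)
  om <- outlier_mask(v, 4)
  expect_lt(abs(mean(om$mask) - 2 * pnorm(-4)), 1e-4)
  expect_warning(om0 <- outlier_mask(rep(3, 10), 4), "constant")
  expect_equal(om0$count, 0L)
  # a single gross outlier in tight data is masked
  v2 <- c(rnorm(500, sd = 1), 50)
  expect_true(outlier_mask(v2, 4)$mask[501])
})

test_that("covariate screening counts nominal hits", {
  set.seed(2)
  n <- 300
  covs <- data.frame(signal = rnorm(n), noise = rnorm(n))
  meds <- as.data.frame(replicate(6, rnorm(n)))
  meds[, 1:5] <- meds[, 1:5] + 0.8 * covs$signal   # built into 5 mediators
  sc <- covariate_screen(meds, covs, alpha = 0.05, min_hits = 3)
  expect_true(sc$selected[sc$covariate == "signal"])
  expect_gte(sc$n_hits[sc$covariate == "signal"], 5)
  # min_hits = 0 selects everything
  sc0 <- covariate_screen(meds, covs, min_hits = 0)
  expect_true(all(sc0$selected))
})

test_that("residualize equals the normal-equations OLS oracle", {
  set.seed(3)
  n <- 50
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n)
  rt <- residualize(data.frame(y = y), data.frame(X))
  Xd <- cbind(1, X)
  bhat <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(rt$residuals$y, drop(y - Xd %*% bhat), tolerance = 1e-10)

  # exact linear function -> residuals ~ 0
  y2 <- drop(X %*% c(2, 1, 1)) + 3
  rt2 <- residualize(data.frame(y = y2), data.frame(X))
  expect_lt(max(abs(rt2$residuals$y)), 1e-8)

  # residuals invariant to affine rescaling of a covariate
  X2 <- X
  X2[, 1] <- 100 * X2[, 1] - 7
  rt3 <- residualize(data.frame(y = y), data.frame(X2))
  expect_equal(rt$residuals$y, rt3$residuals$y, tolerance = 1e-8)

  # covariates orthogonal to values: residuals equal centered values
  yc <- rnorm(n)
  Xo <- qr.Q(qr(cbind(1, X)))[, -1]   # orthogonal to intercept
  yo <- yc - mean(yc)
  yo <- yo - Xo %*% solve(crossprod(Xo), crossprod(Xo, yo))  # orthogonalize
  rt4 <- residualize(data.frame(y = drop(yo)), data.frame(Xo))
  expect_equal(rt4$residuals$y, drop(yo) - mean(yo), tolerance = 1e-8)
})

test_that("small-sample Spearman p matches exhaustive permutation", {
  set.seed(4)
  x <- rnorm(7)
  y <- rnorm(7)
  cs <- correlation_suite(data.frame(x = x), data.frame(y = y))
  rho_obs <- abs(cs$rho[1, 1])
  perms <- all_perms(7)
  rx <- rank(x)
  rhos <- apply(perms, 1, function(pp) cor(rx, rank(y)[pp]))
  p_enum <- mean(abs(rhos) >= rho_obs - 1e-12)
  expect_equal(cs$p[1, 1], p_enum, tolerance = 1e-8)
})

test_that("Spearman matrix is invariant to monotone transforms", {
  set.seed(5)
  d <- data.frame(a = rexp(40), b = rnorm(40))
  c1 <- correlation_suite(d)
  c2 <- correlation_suite(data.frame(a = log(d$a), b = exp(d$b)))
  expect_equal(c1$rho, c2$rho, tolerance = 1e-12)
  expect_equal(diag(c1$rho), c(a = 1, b = 1))
})

test_that("Fisher z comparison and F test behave at their fixed points", {
  fz <- fisher_z_compare(0.5, 0.5, 50, 50)
  expect_equal(fz$statistic, 0)
  expect_equal(fz$p, 1)
  expect_error(fisher_z_compare(0.5, 0.4, 3, 50), class = "dyadherit_fisherz")
  set.seed(6)
  x <- rnorm(100)
  ft <- variance_f_test(x, 2 * x)
  expect_equal(ft$f, 0.25, tolerance = 1e-10)
})

test_that("the full preparation pipeline runs in the documented order", {
  cfg <- sim_config(n_dyads = 400, n_snps = 100, n_traits = 3,
                    lod_quantile = 0.15, seed = 11)
  co <- simulate_dyads(cfg)
  ph <- simulate_phenotypes(co, cfg)
  prep <- prepare_phenotypes(ph$values, ph$analyte_meta,
                             co$covariates[, -1], min_hits = 1)
  expect_equal(prep$kept_analytes, ph$analyte_meta$name)
  res <- prep$residuals$residuals
  for (nm in names(res)) {
    expect_lt(abs(mean(res[[nm]], na.rm = TRUE)), 1e-8)
  }
  expect_true(all(prep$residuals$summary$n_used <= nrow(ph$values)))
})
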
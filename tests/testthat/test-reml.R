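# Univariate REML, permutation null, power approximation

test_that("AI-REML matches a dense grid-search oracle on toy problems", {
  for (seed in 1:5) {
    toy <- make_toy(20, 40, h2 = 0.5, seed = seed)
    fit <- suppressWarnings(reml_univariate(toy$y, NULL, toy$A))
    C <- matrix(1, 20, 1)
    oracle <- grid_reml_h2(toy$y, C, toy$A)
    expect_lt(abs(fit$h2g - oracle$h2), 1e-3, label = paste("seed", seed))
    # the returned optimum is at least as good as any grid point
    ll_at_fit <- dense_reml_ll(fit$sigma2_g, fit$sigma2_e, toy$y, C, toy$A)
    expect_gte(ll_at_fit + 1e-6, oracle$ll - 1e-4)
  }
})

test_that("null phenotypes give near-zero heritability", {
  cfg <- sim_config(n_dyads = 400, n_snps = 1000, h2_fetal = 0,
                    lod_quantile = 0, seed = 22)
  co <- simulate_dyads(cfg)
  y <- log(simulate_phenotypes(co, cfg)$values[[2]])
  A <- diploid_grm(co$offspring)
  fit <- reml_univariate(y, NULL, A)
  expect_lt(fit$h2g, 2 * fit$se_h2g + 0.05)
  expect_gt(fit$lrt_p, 0.01)
})

test_that("an identity GRM is reported as unidentifiable", {
  set.seed(23)
  expect_error(reml_univariate(rnorm(50), NULL, diag(50)),
               class = "dyadherit_identifiability")
})

test_that("scaling invariances hold for phenotype and GRM", {
  toy <- make_toy(200, 300, h2 = 0.4, seed = 24)
  f1 <- suppressWarnings(reml_univariate(toy$y, NULL, toy$A))
  f2 <- suppressWarnings(reml_univariate(3 * toy$y, NULL, toy$A))
  expect_equal(f2$sigma2_g, 9 * f1$sigma2_g, tolerance = 1e-3)
  expect_equal(f2$h2g, f1$h2g, tolerance = 1e-5)
  expect_equal(f2$lrt, f1$lrt, tolerance = 1e-4)

  # GRM scaled by k: s2g scales by 1/k, h2 and LRT unchanged -- the reason
  # the ND half-factor leaves inference invariant
  f3 <- suppressWarnings(reml_univariate(toy$y, NULL, 0.5 * toy$A))
  expect_equal(f3$sigma2_g, 2 * f1$sigma2_g, tolerance = 1e-3)
  expect_equal(f3$h2g / (f3$sigma2_g / (f3$sigma2_g + f3$sigma2_e)), 1,
               tolerance = 1e-6)
  expect_equal(f3$lrt, f1$lrt, tolerance = 1e-3)
  expect_equal(f3$lrt_p, f1$lrt_p, tolerance = 1e-3)
})

test_that("AI and Fisher-scoring paths agree at the optimum", {
  toy <- make_toy(150, 200, h2 = 0.5, seed = 25)
  fa <- suppressWarnings(reml_univariate(toy$y, NULL, toy$A, algorithm = "ai"))
  ff <- suppressWarnings(reml_univariate(toy$y, NULL, toy$A,
                                         algorithm = "fisher"))
  expect_true(fa$converged && ff$converged)
  expect_equal(fa$h2g, ff$h2g, tolerance = 1e-3)
  expect_equal(fa$loglik_full, ff$loglik_full, tolerance = 1e-4)
  expect_equal(ff$algorithm, "Fisher")
})

test_that("covariates are absorbed: fixed effects do not inflate h2", {
  toy <- make_toy(300, 400, h2 = 0.3, seed = 26)
  covar <- cbind(rnorm(300))
  y2 <- toy$y + drop(covar %*% 2)
  f_adj <- suppressWarnings(reml_univariate(y2, covar, toy$A))
  f_ref <- suppressWarnings(reml_univariate(toy$y, NULL, toy$A))
  expect_lt(abs(f_adj$h2g - f_ref$h2g), 0.05)
})

test_that("permutation null centers at zero and is seed-stable", {
  toy <- make_toy(250, 500, h2 = 0.6, seed = 27)
  pn <- suppressWarnings(
    permutation_null(toy$y, NULL, toy$A, n_perm = 30, seed = 5)
  )
  pn2 <- suppressWarnings(
    permutation_null(toy$y, NULL, toy$A, n_perm = 30, seed = 5)
  )
  expect_identical(pn$h2_perm, pn2$h2_perm)
  expect_lt(pn$median_perm, 0.15)
  expect_true(pn$top5)           # a strongly heritable trait beats its null
  expect_gte(pn$quantile_observed, 0.95)
})

test_that("the GREML power approximation behaves sanely", {
  p0 <- greml_power(1000, 0, var_offdiag = 1 / 5000)
  expect_equal(p0$power, 0.05, tolerance = 1e-10)
  p1 <- greml_power(500, 0.5, var_offdiag = 1 / 5000)
  p2 <- greml_power(1000, 0.5, var_offdiag = 1 / 5000)
  p3 <- greml_power(1000, 0.8, var_offdiag = 1 / 5000)
  expect_gt(p2$power, p1$power)
  expect_gt(p3$power, p2$power)

  # SE approximation within a factor of 2 of the empirical SD
  h2s <- vapply(1:12, function(s) {
    toy <- make_toy(500, 800, h2 = 0.3, seed = 100 + s)
    suppressWarnings(reml_univariate(toy$y, NULL, toy$A))$h2g
  }, numeric(1))
  toy <- make_toy(500, 800, h2 = 0.3, seed = 100)
  v_off <- var(toy$A[upper.tri(toy$A)])
  se_app <- greml_power(500, 0.3, v_off)$se_approx
  expect_lt(se_app / sd(h2s), 2)
  expect_gt(se_app / sd(h2s), 0.5)
})

test_that("tidiers expose the fit as tibbles", {
  toy <- make_toy(100, 150, h2 = 0.5, seed = 28)
  fit <- suppressWarnings(reml_univariate(toy$y, NULL, toy$A))
  td <- tidy(fit)
  expect_equal(td$term, c("sigma2_g", "sigma2_e", "h2g"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$h2g, fit$h2g)
})
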
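# Association scans, meta-analysis, LD, conditional and dual-genome models

test_that("a noiseless phenotype recovers its exact slope", {
  g <- random_geno(50, 5, seed = 40)
  y <- 2 * g$values[, 3]
  scan <- gwas_linear(y, g)
  expect_equal(scan$beta[3], 2, tolerance = 1e-10)
  expect_lt(scan$p[3], 1e-30)
})

test_that("gwas_linear equals the closed-form simple regression", {
  g <- random_geno(80, 10, seed = 41)
  set.seed(41)
  y <- rnorm(80)
  scan <- gwas_linear(y, g)
  for (j in c(1, 5, 10)) {
    x <- g$values[, j]
    b <- cov(x, y) / var(x)
    fit <- summary(lm(y ~ x))$coefficients
    expect_equal(scan$beta[j], unname(fit["x", 1]), tolerance = 1e-10)
    expect_equal(scan$se[j], unname(fit["x", 2]), tolerance = 1e-10)
    expect_equal(scan$p[j], unname(fit["x", 4]), tolerance = 1e-10)
    expect_equal(scan$beta[j], b, tolerance = 1e-10)
  }
})

test_that("missing genotypes fall back to per-SNP complete cases", {
  g <- random_geno(100, 6, miss_rate = 0.2, seed = 42)
  set.seed(42)
  y <- rnorm(100)
  covar <- cbind(rnorm(100))
  scan <- gwas_linear(y, g, covar)
  j <- 2
  ok <- !is.na(g$values[, j])
  fit <- summary(lm(y[ok] ~ covar[ok, ] + g$values[ok, j]))$coefficients
  expect_equal(scan$beta[j], unname(fit[3, 1]), tolerance = 1e-8)
  expect_equal(scan$se[j], unname(fit[3, 2]), tolerance = 1e-8)
  expect_equal(scan$n[j], sum(ok))
})

test_that("null scans are calibrated and a planted QTL is recovered", {
  cfg <- sim_config(n_dyads = 2000, n_snps = 800, h2_fetal = 0,
                    lod_quantile = 0,
                    qtl_effects = data.frame(snp = 5, beta = 0.5,
                                             genome = "offspring",
                                             trait = 1),
                    seed = 43)
  co <- simulate_dyads(cfg)
  ph <- simulate_phenotypes(co, cfg)
  y <- log(ph$values[[2]])
  scan <- gwas_linear(y, co$offspring)
  expect_lt(abs(scan$beta[5] - 0.5), 2 * scan$se[5])
  null_p <- scan$p[-5]
  expect_lt(abs(mean(null_p < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / length(null_p)) + 0.005)
})

test_that("A1/A2 swap negates beta and preserves p", {
  g <- random_geno(60, 4, seed = 44)
  set.seed(44)
  y <- rnorm(60)
  s1 <- gwas_linear(y, g)
  g2 <- g
  g2$values <- 2L - g$values
  tmp <- g$marker$a1
  g2$marker$a1 <- g$marker$a2
  g2$marker$a2 <- tmp
  s2 <- gwas_linear(y, g2)
  expect_equal(s2$beta, -s1$beta, tolerance = 1e-10)
  expect_equal(s2$p, s1$p, tolerance = 1e-10)
  expect_equal(s2$maf, s1$maf, tolerance = 1e-12)
})

test_that("fixed-effect meta matches the closed form and metafor", {
  s <- tibble::tibble(snp = "s1", a1 = "A", a2 = "G", beta = 1, se = 1)
  m <- meta_fixed(list(s, s))
  expect_equal(m$beta, 1)
  expect_equal(m$se, 1 / sqrt(2))
  expect_equal(meta_fixed(list(s))$beta, 1)
  expect_equal(meta_fixed(list(s))$se, 1)

  # allele flip: second study coded on the other allele
  s2 <- tibble::tibble(snp = "s1", a1 = "G", a2 = "A", beta = -1, se = 1)
  m2 <- meta_fixed(list(s, s2))
  expect_equal(m2$beta, 1)

  skip_if_not_installed("metafor")
  set.seed(45)
  betas <- rnorm(4)
  ses <- runif(4, 0.5, 1.5)
  scans <- lapply(1:4, function(i)
    tibble::tibble(snp = "s1", a1 = "A", a2 = "G",
                   beta = betas[i], se = ses[i]))
  m3 <- meta_fixed(scans)
  rma <- metafor::rma(yi = betas, sei = ses, method = "FE")
  expect_equal(m3$beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(m3$se, rma$se, tolerance = 1e-10)
})

test_that("LD r2 matches the generating haplotype table", {
  lp <- simulate_ld_pair(50000, 0.4, 0.25, r2 = 0.5, seed = 46)
  g <- cbind(a = lp$ga, b = lp$gb)
  r2 <- ld_r2("a", "b", g)
  expect_equal(r2$r2, lp$r2, tolerance = 0.04)
  expect_equal(ld_r2("a", "a", g)$r2, 1)
  # independent SNPs: E[r2] ~ 1/n
  set.seed(46)
  r2s <- replicate(50, {
    ga <- rbinom(300, 2, 0.3)
    gb <- rbinom(300, 2, 0.3)
    cor(ga, gb)^2
  })
  expect_lt(abs(mean(r2s) - 1 / 300), 2.5 / 300)
  expect_error(ld_r2(1, 2, cbind(rep(1, 10), rbinom(10, 2, 0.5))),
               class = "dyadherit_mono")
})

test_that("conditioning on the causal SNP silences its LD proxy", {
  hits <- vapply(1:20, function(s) {
    lp <- simulate_ld_pair(1000, 0.3, 0.3, r2 = 0.7, seed = 400 + s)
    set.seed(500 + s)
    y <- 0.4 * lp$ga + rnorm(1000)
    g <- cbind(causal = lp$ga, proxy = lp$gb)
    marginal <- gwas_linear(y, g)
    cond <- conditional_scan(y, g, index_snps = "causal")
    c(marginal$p[2] < 0.05, cond$p[2] > 0.05)
  }, logical(2))
  expect_gte(mean(hits[1, ]), 0.8)   # proxy is marginally associated
  expect_gte(mean(hits[2, ]), 0.8)   # and silenced by conditioning
})

test_that("conditioning on an independent SNP leaves beta unchanged", {
  g <- random_geno(500, 10, seed = 47)
  set.seed(47)
  y <- 0.3 * g$values[, 1] + rnorm(500)
  s0 <- gwas_linear(y, g)
  s1 <- conditional_scan(y, g, index_snps = 9)
  expect_lt(abs(s1$beta[1] - s0$beta[1]), 0.05)
  expect_true(is.na(s1$p[9]))
  expect_equal(s1$skipped[9], "index")
})

test_that("dual-genome model separates maternal from fetal effects", {
  cfg <- sim_config(n_dyads = 2000, n_snps = 50, h2_fetal = 0,
                    lod_quantile = 0,
                    qtl_effects = data.frame(snp = 3, beta = 0.4,
                                             genome = "maternal", trait = 1),
                    seed = 48)
  co <- simulate_dyads(cfg)
  y <- log(simulate_phenotypes(co, cfg)$values[[2]])
  gm <- co$maternal$values[, 3]
  gf <- co$offspring$values[, 3]
  expect_gt(cor(gm, gf), 0.3)   # transmission-induced correlation
  res <- dual_genome_model(y, gm, gf)
  expect_lt(res$p[res$term == "maternal"], 1e-6)
  expect_gt(res$p[res$term == "fetal"], 0.01)
  expect_lt(abs(res$beta[res$term == "maternal"] - 0.4),
            2 * res$se[res$term == "maternal"])

  # duplicated dosage flags collinearity
  expect_warning(res2 <- dual_genome_model(y, gm, gm + 0L), "collinear")
  expect_true(all(res2$collinear))
})

test_that("both-causal dual models recover both terms", {
  set.seed(49)
  n <- 1500
  gm <- rbinom(n, 2, 0.4)
  gf <- rbinom(n, 2, 0.4)
  y <- 0.3 * gm + 0.2 * gf + rnorm(n)
  res <- dual_genome_model(y, gm, gf)
  expect_lt(abs(res$beta[1] - 0.3), 2 * res$se[1])
  expect_lt(abs(res$beta[2] - 0.2), 2 * res$se[2])
})
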
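# Genetic relationship matrices

test_that("diploid GRM matches direct substitution and the loop oracle", {
  # single SNP, p = 0.5, x_j = 2, x_k = 0 -> A_jk = (2-1)(0-1)/0.5 = -2
  mk <- tibble::tibble(snp = "s", chr = "1", pos = 1L, a1 = "A", a2 = "G")
  sm <- tibble::tibble(sample_id = c("j", "k"), sex = 0L, pheno = -9)
  g <- geno_matrix(matrix(c(2L, 0L), 2, 1), mk, sm)
  A <- diploid_grm(g)
  expect_equal(A$values["j", "k"], -2)

  # random matrix with missingness vs brute-force double loop
  g2 <- random_geno(10, 50, miss_rate = 0.1, seed = 16)
  poly <- which(apply(g2$values, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && min(v) < max(v)
  }))
  g2 <- g2[, poly]
  A2 <- diploid_grm(g2)
  x <- g2$values
  p <- colMeans(x, na.rm = TRUE) / 2
  for (j in 1:10) {
    for (k in 1:10) {
      ok <- !is.na(x[j, ]) & !is.na(x[k, ])
      if (j == k) {
        e <- 1 + mean((x[j, ok]^2 - (1 + 2 * p[ok]) * x[j, ok] +
                         2 * p[ok]^2) / (2 * p[ok] * (1 - p[ok])))
      } else {
        e <- mean((x[j, ok] - 2 * p[ok]) * (x[k, ok] - 2 * p[ok]) /
                    (2 * p[ok] * (1 - p[ok])))
      }
      expect_equal(A2$values[j, k], e, tolerance = 1e-10)
    }
  }
  expect_equal(A2$n_snps[1, 2],
               sum(!is.na(x[1, ]) & !is.na(x[2, ])))
})

test_that("diploid GRM is invariant to swapping A1/A2 labels", {
  g <- random_geno(30, 60, seed = 17)
  A1 <- diploid_grm(g)
  g2 <- g
  g2$values <- 2L - g$values
  A2 <- diploid_grm(g2)
  expect_equal(A1$values, A2$values, tolerance = 1e-10)
})

test_that("haploid GRM obeys the ND halving and the loop oracle", {
  set.seed(18)
  x <- matrix(rbinom(8 * 40, 1, 0.4), 8, 40)
  a_full <- haploid_nd_grm(x, dosage_compensation = "full")
  a_nd <- haploid_nd_grm(x, dosage_compensation = "none")
  nz <- a_full$values != 0
  expect_true(all(abs(a_nd$values[nz] / a_full$values[nz] - 0.5) < 1e-12))
  # off-diagonal-only variant keeps the diagonal
  a_nd2 <- haploid_nd_grm(x, dosage_compensation = "none",
                          nd_diagonal = FALSE)
  expect_equal(diag(a_nd2$values), diag(a_full$values))

  p <- colMeans(x)
  for (j in 1:8) {
    for (k in 1:8) {
      e <- mean((x[j, ] - p) * (x[k, ] - p) / (p * (1 - p)))
      expect_equal(a_full$values[j, k], e, tolerance = 1e-10)
    }
  }
})

test_that("mother-offspring relatedness is about one half", {
  cfg <- sim_config(n_dyads = 150, n_snps = 3000, seed = 19)
  co <- simulate_dyads(cfg)
  both <- geno_matrix(
    rbind(co$maternal$values, co$offspring$values),
    co$maternal$marker,
    dplyr::bind_rows(co$maternal$samples, co$offspring$samples)
  )
  A <- diploid_grm(both)
  n <- cfg$n_dyads
  duo_rel <- A$values[cbind(seq_len(n), n + seq_len(n))]
  # in-sample allele frequencies shrink pairwise relatedness by O(1/n),
  # so the duo mean sits just under one half
  expect_lt(abs(mean(duo_rel) - 0.5), 0.02)
  expect_lt(sd(duo_rel), 0.1)
  # unrelated pairs center at zero with spread ~ 1/sqrt(m)
  off <- A$values[1, 3:40]
  expect_lt(mean(abs(off)), 5 / sqrt(3000))
  expect_gt(mean(diag(A$values)), 0.8)
  expect_lt(mean(diag(A$values)), 1.2)
})

test_that("NT and NM haplomes share no inherited material", {
  cfg <- sim_config(n_dyads = 400, n_snps = 2000, seed = 20)
  co <- simulate_dyads(cfg)
  # on the true underlying alleles (no resolution censoring), the maternal
  # non-transmitted and paternal haplomes of a dyad are independent draws:
  # their cross-set relatedness centers at zero
  nt_true <- co$maternal$values - co$maternal_transmitted
  nm_true <- co$offspring$values - co$maternal_transmitted
  joint <- rbind(nt_true, nm_true)
  A <- haploid_nd_grm(joint, dosage_compensation = "full")
  n <- nrow(nt_true)
  cross <- A$values[cbind(seq_len(n), n + seq_len(n))]
  expect_lt(abs(mean(cross)), 4 * sd(cross) / sqrt(n))

  # on resolved entries, excluding double heterozygotes anti-correlates the
  # two resolved alleles at each dyad (at p = 0.5 the within-dyad covariance
  # is exactly -1/12), so the observable cross-relatedness is negative --
  # a known cost of the partition, not residual shared inheritance
  part <- partition_cohort(co)
  jr <- rbind(part$maternal_nt$values, part$fetal_nm$values)
  Ar <- haploid_nd_grm(jr, dosage_compensation = "full")
  cross_r <- Ar$values[cbind(seq_len(n), n + seq_len(n))]
  expect_lt(mean(cross_r), 0)
})

test_that("GRM text round-trip is lossless and matches a hand-built fixture", {
  g <- random_geno(6, 30, seed = 21)
  A <- diploid_grm(g)
  tmp <- tempfile()
  write_grm(A, tmp)
  B <- read_grm(tmp)
  expect_equal(B$values, A$values, tolerance = 1e-12)
  expect_equal(B$n_snps, A$n_snps)
  expect_equal(B$sample_ids, A$sample_ids)

  # hand-written 2x2 fixture
  tmp2 <- tempfile()
  con <- gzfile(paste0(tmp2, ".grm.gz"), "w")
  writeLines(c("1\t1\t30\t1.01", "2\t1\t30\t-0.02", "2\t2\t30\t0.97"), con)
  close(con)
  writeLines(c("a\ta", "b\tb"), paste0(tmp2, ".grm.id"))
  C <- read_grm(tmp2)
  expect_equal(C$values, matrix(c(1.01, -0.02, -0.02, 0.97), 2, 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  # empty GRM rejected
  A0 <- A
  A0$values <- matrix(numeric(0), 0, 0)
  expect_error(write_grm(A0, tempfile()), class = "dyadherit_empty")
})
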
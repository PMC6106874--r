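# PLINK1 binary codec and marker QC

test_that("a hand-constructed fileset decodes to the hand-decoded matrix", {
  # 3 samples x 2 SNPs. Per the .bed spec, genotypes pack 4 per byte, LSB
  # pair first; codes 00 = hom A1 (2), 01 = missing, 10 = het (1),
  # 11 = hom A2 (0). SNP1: sample1 = 2 (00), sample2 = 1 (10),
  # sample3 = NA (01) -> bits (pad 11): 11 01 10 00 = 0xD8.
  # SNP2: 0 (11), 2 (00), 1 (10) -> 11 10 00 11 = 0xE3.
  tmp <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xD8, 0xE3)), paste0(tmp, ".bed"))
  writeLines(c("1\tsnpA\t0\t100\tA\tG", "1\tsnpB\t0\t200\tC\tT"),
             paste0(tmp, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t2\t-9", "f2\ti2\t0\t0\t1\t-9",
               "f3\ti3\t0\t0\t2\t-9"), paste0(tmp, ".fam"))
  g <- read_plink1(tmp)
  expect_equal(unname(g$values),
               matrix(c(2L, 1L, NA, 0L, 2L, 1L), 3, 2))
  expect_equal(g$marker$snp, c("snpA", "snpB"))
  expect_equal(g$samples$sex, c(2L, 1L, 2L))
})

test_that("write/read round-trips arbitrary matrices bit-exactly", {
  for (seed in 1:3) {
    g <- random_geno(13, 7, miss_rate = 0.15, seed = seed)
    tmp <- tempfile()
    write_plink1(g, tmp)
    g2 <- read_plink1(tmp)
    expect_identical(unname(g2$values), unname(g$values))
    expect_equal(g2$marker, g$marker)
    expect_equal(g2$samples$sample_id, g$samples$sample_id)
    # writing again yields byte-identical files
    tmp2 <- tempfile()
    write_plink1(g2, tmp2)
    expect_identical(readBin(paste0(tmp, ".bed"), "raw", 1e6),
                     readBin(paste0(tmp2, ".bed"), "raw", 1e6))
  }
})

test_that("malformed filesets are rejected", {
  g <- random_geno(13, 3)
  tmp <- tempfile()
  write_plink1(g, tmp)
  # corrupt magic
  raw <- readBin(paste0(tmp, ".bed"), "raw", 1e6)
  writeBin(c(as.raw(0), raw[-1]), paste0(tmp, ".bed"))
  expect_error(read_plink1(tmp), class = "dyadherit_format")
  # size mismatch: truncated .fam against a payload sized for 13 samples
  writeBin(raw, paste0(tmp, ".bed"))
  fam <- readLines(paste0(tmp, ".fam"))
  writeLines(fam[1:3], paste0(tmp, ".fam"))
  expect_error(read_plink1(tmp), class = "dyadherit_length")
})

test_that("marker_qc applies inclusive MAF, HWE and call-rate thresholds", {
  # three SNPs with MAFs 0.005, 0.01, 0.30 in 200 samples (HWE-exact)
  n <- 200
  mk_geno <- function(n_aa, n_ab, n_bb) {
    rep(c(2L, 1L, 0L), c(n_aa, n_ab, n_bb))
  }
  x <- cbind(
    mk_geno(0, 2, 198),    # maf 0.005
    mk_geno(0, 4, 196),    # maf 0.01
    mk_geno(18, 84, 98)    # maf 0.30
  )
  g <- geno_matrix(
    x,
    tibble::tibble(snp = c("a", "b", "c"), chr = "1", pos = 1:3,
                   a1 = "A", a2 = "G"),
    tibble::tibble(sample_id = paste0("i", 1:n), sex = 0L, pheno = -9)
  )
  qc <- marker_qc(g, maf_min = 0.01, hwe_alpha = 1e-6, call_min = 0.95)
  expect_equal(qc$keep, c(2L, 3L))
  expect_equal(qc$stats$maf, c(0.005, 0.01, 0.30), tolerance = 1e-12)

  # idempotence: filtering a filtered set changes nothing
  g2 <- g[, qc$keep]
  qc2 <- marker_qc(g2, maf_min = 0.01, hwe_alpha = 1e-6, call_min = 0.95)
  expect_equal(qc2$keep, seq_along(qc$keep))
})

test_that("exact HWE test matches full enumeration", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(3, 14, 83), c(0, 2, 198),
                c(10, 10, 10), c(1, 0, 99))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_enum_p(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10,
                 label = paste(cs, collapse = "/"))
  }
  expect_gt(hwe_exact_test(25, 50, 25), 0.99)  # perfect HWE
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)  # extreme het deficit
})

test_that("mendel_check flags exactly the impossible duo combinations", {
  mk <- tibble::tibble(snp = "s1", chr = "1", pos = 1L, a1 = "A", a2 = "G")
  sm <- tibble::tibble(sample_id = paste0("m", 1:12), sex = 2L, pheno = -9)
  sc <- tibble::tibble(sample_id = paste0("c", 1:12), sex = 1L, pheno = -9)
  grid <- expand.grid(gm = c(0L, 1L, 2L, NA), gc = c(0L, 1L, 2L))
  gm <- geno_matrix(matrix(grid$gm, ncol = 1), mk, sm)
  gc <- geno_matrix(matrix(grid$gc, ncol = 1), mk, sc)
  pair <- tibble::tibble(maternal_id = sm$sample_id,
                         offspring_id = sc$sample_id)
  mc <- mendel_check(gm, gc, pair)
  expected <- !is.na(grid$gm) &
    ((grid$gm == 0 & grid$gc == 2) | (grid$gm == 2 & grid$gc == 0))
  expect_equal(as.vector(mc$mask), expected)
  expect_error(
    mendel_check(gm, gc, tibble::tibble(maternal_id = "nope",
                                        offspring_id = "c1")),
    class = "dyadherit_pairing"
  )
})

test_that("pseudo-X recoding round-trips through a fileset", {
  set.seed(42)
  vals <- matrix(sample(c(0L, 1L, NA), 30, replace = TRUE), 6, 5)
  ph <- pseudo_haploid(
    vals,
    tibble::tibble(snp = paste0("s", 1:5), chr = "1", pos = 1:5,
                   a1 = "A", a2 = "G"),
    tibble::tibble(sample_id = paste0("i", 1:6), sex = 2L, pheno = -9),
    provenance = "maternal_non_transmitted"
  )
  gx <- recode_pseudo_x(ph)
  expect_true(all(gx$marker$chr == "X"))
  expect_true(all(gx$samples$sex == 1L))
  tmp <- tempfile()
  write_plink1(gx, tmp)
  back <- read_plink1(tmp)
  expect_true(all(back$marker$chr == "X"))
  ph2 <- as_pseudo_haploid(back)
  expect_identical(unname(ph2$values), unname(vals))
  # diploid het value in input is rejected
  bad <- ph
  bad$values[1, 1] <- 2L
  expect_error(recode_pseudo_x(bad), class = "dyadherit_range")
})
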
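# Synthetic mother-offspring dyad cohorts with known architecture -----------

#' Simulation configuration for dyad cohorts
#'
#' Collects every knob of the synthetic-cohort generator. One global integer
#' seed fully determines all output; each stage (frequencies, dyads,
#' phenotypes, outcome) draws from its own stream derived from `seed` by a
#' fixed stride-and-offset rule, so outputs are reproducible independently
#' of call order and stage streams never overlap across nearby seeds.
#'
#' @param n_dyads Number of mother-offspring pairs.
#' @param n_snps Number of independent SNPs (no linkage disequilibrium beyond
#'   population structure).
#' @param n_pops Number of sub-populations.
#' @param fst Balding-Nichols differentiation parameter in `[0, 1)`.
#' @param causal_fraction_maternal,causal_fraction_fetal Fractions of SNPs
#'   carrying maternal-genome / offspring-genome effects; the two causal sets
#'   are drawn disjoint by default (see `overlap_causal`).
#' @param h2_maternal,h2_fetal Target variance shares of the maternal and
#'   fetal polygenic components; must sum to at most 1. Components are
#'   rescaled so the realized sample shares match the targets exactly.
#' @param n_traits Number of analytes to simulate.
#' @param rg_pairs List of `list(pair = c(i, j), rg = r)` entries: trait `j`
#'   reuses trait `i`'s causal sets with effect vectors correlated at `r`
#'   (identical vectors at `r = 1`).
#' @param qtl_effects Data frame with columns `snp` (index), `beta` (per-A1
#'   allele, trait units), `genome` (`"maternal"` or `"offspring"`), `trait`
#'   (index); planted single-SNP effects for association testing.
#' @param covariate_effects Numeric vector of length 2: effects of the two
#'   simulated covariates (a continuous maternal-age-like covariate and a
#'   continuous batch-like covariate) on every trait.
#' @param lod_quantile Left-censoring point as a sample quantile of each
#'   analyte's concentration in `[0, 1)`; 0 disables censoring. Censored
#'   concentrations are stored as `LOD/2` (an arbitrary sub-LOD sentinel:
#'   values below the limit of detection are unquantifiable) and the LOD is
#'   recorded per analyte so the preparation step can apply the
#'   `LOD/sqrt(2)` substitution.
#' @param interaction_beta Log-odds per (genotype x standardized mediator)
#'   unit used by [simulate_outcome()].
#' @param case_fraction Target case fraction of the binary outcome.
#' @param overlap_causal Allow maternal and fetal causal sets to overlap.
#' @param freq_range Range of the uniform ancestral allele frequency.
#' @param freq_clip Population frequencies are clipped into this interval,
#'   keeping SNPs past a MAF >= 1\% filter by construction.
#' @param seed Global integer seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 500,
                       n_snps = 2000,
                       n_pops = 1,
                       fst = 0,
                       causal_fraction_maternal = 0.1,
                       causal_fraction_fetal = 0.1,
                       h2_maternal = 0,
                       h2_fetal = 0,
                       n_traits = 1,
                       rg_pairs = list(),
                       qtl_effects = NULL,
                       covariate_effects = c(0, 0),
                       lod_quantile = 0.1,
                       interaction_beta = 0,
                       case_fraction = 0.5,
                       overlap_causal = FALSE,
                       freq_range = c(0.05, 0.95),
                       freq_clip = c(0.01, 0.99),
                       seed = 1L) {
  cfg <- list(
    n_dyads = as.integer(n_dyads), n_snps = as.integer(n_snps),
    n_pops = as.integer(n_pops), fst = fst,
    causal_fraction_maternal = causal_fraction_maternal,
    causal_fraction_fetal = causal_fraction_fetal,
    h2_maternal = h2_maternal, h2_fetal = h2_fetal,
    n_traits = as.integer(n_traits), rg_pairs = rg_pairs,
    qtl_effects = qtl_effects,
    covariate_effects = covariate_effects,
    lod_quantile = lod_quantile,
    interaction_beta = interaction_beta,
    case_fraction = case_fraction,
    overlap_causal = isTRUE(overlap_causal),
    freq_range = freq_range, freq_clip = freq_clip,
    seed = as.integer(seed)
  )
  if (cfg$fst < 0 || cfg$fst >= 1) {
    stop_dyad("fst must lie in [0, 1)", "config")
  }
  if (cfg$n_pops < 1) stop_dyad("n_pops must be >= 1", "config")
  props <- c(cfg$causal_fraction_maternal, cfg$causal_fraction_fetal,
             cfg$h2_maternal, cfg$h2_fetal, cfg$lod_quantile)
  if (any(props < 0) || any(props > 1) || cfg$lod_quantile >= 1) {
    stop_dyad("proportions must lie in their stated ranges", "config")
  }
  if (cfg$h2_maternal + cfg$h2_fetal > 1) {
    stop_dyad("h2_maternal + h2_fetal must be <= 1", "config")
  }
  structure(cfg, class = "sim_config")
}

# stage-specific streams derived from the single global seed; the stride
# keeps the four stage streams disjoint even across adjacent global seeds
seed_for <- function(config, stage) {
  offs <- c(frequencies = 0, dyads = 1, phenotypes = 2, outcome = 3)
  as.integer((as.double(config$seed) * 4 + offs[[stage]]) %% 2147483647)
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are uniform on `config$freq_range`; each
#' population's frequency is Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst) around the
#' ancestral value when `fst > 0`, and identical to it when `fst = 0`. All
#' frequencies are clipped into `config$freq_clip`.
#'
#' @param config A [sim_config()].
#' @return A `n_pops` x `n_snps` matrix of A1 allele frequencies.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed_for(config, "frequencies"), {
    p_anc <- runif(config$n_snps, config$freq_range[1], config$freq_range[2])
    freq <- if (config$fst == 0) {
      matrix(rep(p_anc, each = config$n_pops), nrow = config$n_pops)
    } else {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      matrix(
        stats::rbeta(config$n_pops * config$n_snps,
                     rep(a, each = config$n_pops),
                     rep(b, each = config$n_pops)),
        nrow = config$n_pops
      )
    }
    pmin(pmax(freq, config$freq_clip[1]), config$freq_clip[2])
  })
}

#' Simulate a mother-offspring dyad cohort
#'
#' Maternal genotypes are Hardy-Weinberg draws within each dyad's population;
#' the offspring receives one uniformly chosen maternal allele (recorded as
#' ground truth) plus a paternal allele drawn from the same population's
#' frequency. Paternal genotypes are never observed.
#'
#' @param config A [sim_config()].
#' @param frequencies Matrix from [simulate_frequencies()].
#' @return A list of class `dyad_cohort` with elements `maternal`
#'   and `offspring` ([geno_matrix()] objects), `maternal_transmitted`
#'   (simulator-only ground-truth matrix of transmitted A1 counts),
#'   `pairing` (tibble `dyad_id`, `maternal_id`, `offspring_id`),
#'   `covariates` (tibble of simulated covariates), `population`
#'   (integer labels) and `frequencies`.
#' @export
simulate_dyads <- function(config, frequencies = simulate_frequencies(config)) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_dyads
  m <- config$n_snps
  if (nrow(frequencies) != config$n_pops || ncol(frequencies) != m) {
    stop_dyad("frequency matrix does not match config", "config")
  }
  with_seed(seed_for(config, "dyads"), {
    pop <- rep_len(seq_len(config$n_pops), n)
    pmat <- frequencies[pop, , drop = FALSE]         # n x m per-dyad freqs
    draw <- function() {
      matrix(rbinom(n * m, 1L, pmat), n, m)
    }
    mat_a <- draw()                                   # maternal allele 1
    mat_b <- draw()                                   # maternal allele 2
    pat <- draw()                                     # paternal allele
    pick_a <- matrix(rbinom(n * m, 1L, 0.5), n, m)    # 1 = transmit allele a
    transmitted <- pick_a * mat_a + (1L - pick_a) * mat_b
    gm <- mat_a + mat_b
    gc <- transmitted + pat

    dyad_id <- sprintf("dyad%04d", seq_len(n))
    marker <- tibble(
      snp = sprintf("snp%06d", seq_len(m)),
      chr = as.character(rep_len(1:22, m)),
      pos = 1000L * seq_len(m),
      a1 = "A", a2 = "G"
    )
    mothers <- tibble(sample_id = paste0("M_", dyad_id), sex = 2L, pheno = -9)
    children <- tibble(sample_id = paste0("C_", dyad_id), sex = 1L, pheno = -9)
    covariates <- tibble(
      dyad_id = dyad_id,
      cov_age = rnorm(n, 30, 5),
      cov_batch = rnorm(n)
    )
    structure(
      list(
        maternal = geno_matrix(gm, marker, mothers),
        offspring = geno_matrix(gc, marker, children),
        maternal_transmitted = transmitted,
        pairing = tibble(dyad_id = dyad_id,
                         maternal_id = mothers$sample_id,
                         offspring_id = children$sample_id),
        covariates = covariates,
        population = pop,
        frequencies = frequencies,
        config = config
      ),
      class = "dyad_cohort"
    )
  })
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %d dyads x %d SNPs, %d population(s)\n",
              nrow(x$maternal$values), ncol(x$maternal$values),
              x$config$n_pops))
  invisible(x)
}

# standardize genotype columns by sample mean/sd; zero-variance columns -> 0
standardize_cols <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2)
  s[s == 0] <- Inf
  sweep(sweep(x, 2, mu), 2, s, "/")
}

# scale a vector to an exact target standard deviation (0 -> zero vector)
scale_to_sd <- function(x, target_sd) {
  if (target_sd == 0) return(numeric(length(x)))
  s <- sd(x)
  if (s == 0) stop_dyad("degenerate component with zero variance", "simulate")
  x / s * target_sd
}

#' Simulate analyte phenotypes with maternal and fetal polygenic components
#'
#' Builds, per trait, `y = C b_cov + W_m u + W_f v + sum_q x_q b_q + e` on a
#' latent log-concentration scale, where `W_m`, `W_f` are standardized
#' maternal and offspring genotypes at the maternal-causal and fetal-causal
#' SNP sets and the genetic components and noise are rescaled so realized
#' sample variance shares equal `h2_maternal`, `h2_fetal` and
#' `1 - h2_maternal - h2_fetal` exactly. Observed concentrations are
#' `exp(y)`; when `lod_quantile > 0` values below the per-analyte LOD
#' (the `lod_quantile` sample quantile) are replaced by the sub-LOD sentinel
#' `LOD/2`.
#'
#' @param cohort A [simulate_dyads()] cohort.
#' @param config The same [sim_config()].
#' @return A list of class `dyad_phenotypes`: `values` (tibble, `dyad_id`
#'   plus one concentration column per analyte), `analyte_meta` (tibble
#'   `name`, `lod`, `detect_fraction`, `outlier_sd_threshold`), and `truth`
#'   (per-trait latent values, causal indices, effect vectors and realized
#'   shares; simulator-only ground truth).
#' @export
simulate_phenotypes <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  n <- nrow(cohort$maternal$values)
  m <- ncol(cohort$maternal$values)
  k <- config$n_traits
  if (config$h2_maternal + config$h2_fetal > 1) {
    stop_dyad("h2 shares sum above 1", "config")
  }
  n_cm <- round(config$causal_fraction_maternal * m)
  n_cf <- round(config$causal_fraction_fetal * m)

  with_seed(seed_for(config, "phenotypes"), {
    Wm_all <- standardize_cols(cohort$maternal$values)
    Wf_all <- standardize_cols(cohort$offspring$values)
    C <- as.matrix(cohort$covariates[, c("cov_age", "cov_batch")])
    C <- scale(C)

    # resolve rg sharing: source trait index per trait (self if unshared)
    src <- seq_len(k)
    rg_of <- rep(NA_real_, k)
    for (pr in config$rg_pairs) {
      i <- pr$pair[1]; j <- pr$pair[2]
      src[j] <- i
      rg_of[j] <- pr$rg
    }

    traits <- vector("list", k)
    for (t in seq_len(k)) {
      if (src[t] == t) {
        idx_m <- if (n_cm > 0) sort(sample.int(m, n_cm)) else integer()
        pool <- if (config$overlap_causal) seq_len(m) else setdiff(seq_len(m), idx_m)
        idx_f <- if (n_cf > 0) sort(sample(pool, n_cf)) else integer()
        u <- rnorm(n_cm)
        v <- rnorm(n_cf)
      } else {
        s <- traits[[src[t]]]
        idx_m <- s$idx_m; idx_f <- s$idx_f
        r <- rg_of[t]
        mix <- function(e0) {
          if (r == 1) e0 else r * e0 + sqrt(1 - r^2) * rnorm(length(e0))
        }
        u <- mix(s$u)
        v <- mix(s$v)
      }
      g_m <- if (n_cm > 0) drop(Wm_all[, idx_m, drop = FALSE] %*% u) else numeric(n)
      g_f <- if (n_cf > 0) drop(Wf_all[, idx_f, drop = FALSE] %*% v) else numeric(n)
      g_m <- scale_to_sd(g_m, sqrt(config$h2_maternal))
      g_f <- scale_to_sd(g_f, sqrt(config$h2_fetal))
      eps <- scale_to_sd(rnorm(n), sqrt(1 - config$h2_maternal - config$h2_fetal))
      y <- g_m + g_f + eps + drop(C %*% config$covariate_effects)
      if (!is.null(config$qtl_effects)) {
        qe <- config$qtl_effects
        qe_t <- qe[(qe$trait %||% 1) == t, , drop = FALSE]
        for (q in seq_len(nrow(qe_t))) {
          dose <- if (identical(qe_t$genome[q], "maternal")) {
            cohort$maternal$values[, qe_t$snp[q]]
          } else {
            cohort$offspring$values[, qe_t$snp[q]]
          }
          y <- y + qe_t$beta[q] * dose
        }
      }
      traits[[t]] <- list(y = y, idx_m = idx_m, idx_f = idx_f, u = u, v = v,
                          g_m = g_m, g_f = g_f,
                          share_m = var(g_m) / var(y),
                          share_f = var(g_f) / var(y))
    }

    conc <- vapply(traits, function(tr) exp(tr$y), numeric(n))
    names_tr <- sprintf("analyte_%02d", seq_len(k))
    lod <- rep(NA_real_, k)
    for (t in seq_len(k)) {
      if (config$lod_quantile > 0) {
        lod[t] <- quantile(conc[, t], config$lod_quantile, names = FALSE)
        conc[conc[, t] < lod[t], t] <- lod[t] / 2
      } else {
        lod[t] <- min(conc[, t]) / 2
      }
    }
    values <- tibble(dyad_id = cohort$pairing$dyad_id)
    for (t in seq_len(k)) values[[names_tr[t]]] <- conc[, t]
    meta <- tibble(
      name = names_tr, lod = lod,
      detect_fraction = vapply(seq_len(k),
                               function(t) mean(conc[, t] > lod[t]), 0),
      outlier_sd_threshold = 4
    )
    names(traits) <- names_tr
    structure(list(values = values, analyte_meta = meta, truth = traits),
              class = "dyad_phenotypes")
  })
}

#' @export
print.dyad_phenotypes <- function(x, ...) {
  cat(sprintf("<dyad_phenotypes> %d dyads x %d analyte(s)\n",
              nrow(x$values), nrow(x$analyte_meta)))
  invisible(x)
}

#' Simulate a binary outcome with an optional SNP x mediator interaction
#'
#' Case status follows
#' `logit P(case) = alpha + gamma g + delta med + beta_int (g x med)` with the
#' mediator standardized; `alpha` is solved numerically so the expected case
#' fraction equals `config$case_fraction`.
#'
#' @param cohort A [simulate_dyads()] cohort.
#' @param mediator Numeric vector (one value per dyad), e.g. a latent trait
#'   from [simulate_phenotypes()].
#' @param config The [sim_config()]; `interaction_beta` and `case_fraction`
#'   are used.
#' @param snp Column index of the interacting SNP.
#' @param genome `"maternal"` or `"offspring"`: whose genotype interacts.
#' @param gamma,delta Main effects of the genotype and the mediator
#'   (log-odds).
#' @return Integer vector of 0/1 case status.
#' @export
simulate_outcome <- function(cohort, mediator, config = cohort$config,
                             snp = 1L, genome = c("maternal", "offspring"),
                             gamma = 0, delta = 0) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  genome <- match.arg(genome)
  g <- if (genome == "maternal") cohort$maternal$values[, snp] else
    cohort$offspring$values[, snp]
  med <- drop(scale(mediator))
  eta0 <- gamma * g + delta * med + config$interaction_beta * g * med
  alpha <- uniroot(
    function(a) mean(plogis(a + eta0)) - config$case_fraction,
    interval = c(-20, 20)
  )$root
  with_seed(seed_for(config, "outcome"), {
    rbinom(length(med), 1L, plogis(alpha + eta0))
  })
}

#' Simulate one pair of SNPs in linkage disequilibrium
#'
#' Draws genotypes for two biallelic SNPs from a two-locus haplotype
#' distribution with disequilibrium `D = sqrt(r2 pA(1-pA) pB(1-pB))`
#' (positive phase), the closed-form construction used to test LD and
#' conditional-analysis behaviour; `D` is truncated at the Frechet bounds.
#'
#' @param n Number of individuals (2n haplotypes).
#' @param p_a,p_b A1 allele frequencies at the two SNPs.
#' @param r2 Target squared correlation of allele indicators.
#' @param seed Integer seed.
#' @return List with genotype vectors `ga`, `gb`, the haplotype frequency
#'   table `hap_freq` and the theoretical `r2` after truncation.
#' @export
simulate_ld_pair <- function(n, p_a = 0.3, p_b = 0.3, r2 = 0.7, seed = 1L) {
  d_max <- min(p_a * (1 - p_b), p_b * (1 - p_a))
  d <- min(sqrt(r2 * p_a * (1 - p_a) * p_b * (1 - p_b)), d_max)
  # haplotypes: AB, Ab, aB, ab
  hf <- c(AB = p_a * p_b + d, Ab = p_a * (1 - p_b) - d,
          aB = (1 - p_a) * p_b - d, ab = (1 - p_a) * (1 - p_b) + d)
  if (any(hf < 0)) stop_dyad("infeasible haplotype frequencies", "config")
  with_seed(seed, {
    hap <- sample.int(4L, 2L * n, replace = TRUE, prob = hf)
    carries_a <- hap <= 2L
    carries_b <- hap %in% c(1L, 3L)
    ga <- colSums(matrix(carries_a, nrow = 2L))
    gb <- colSums(matrix(carries_b, nrow = 2L))
    list(ga = ga, gb = gb, hap_freq = hf,
         r2 = d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
  })
}

#' Write a simulated cohort to disk
#'
#' Emits one PLINK1 binary fileset per individual set (`<prefix>_mothers`,
#' `<prefix>_offspring`), a tab-separated dyad-pairing file, a tab-separated
#' phenotype table with analyte metadata, and a JSON ground-truth sidecar
#' with causal indices, effect vectors and target shares.
#'
#' @param cohort A [simulate_dyads()] cohort.
#' @param phenotypes Optional [simulate_phenotypes()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, phenotypes = NULL, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mothers = file.path(dir, paste0(prefix, "_mothers")),
    offspring = file.path(dir, paste0(prefix, "_offspring")),
    pairing = file.path(dir, paste0(prefix, "_pairing.tsv"))
  )
  write_plink1(cohort$maternal, paths$mothers)
  write_plink1(cohort$offspring, paths$offspring)
  write.table(cohort$pairing, paths$pairing, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(phenotypes)) {
    paths$phenotypes <- file.path(dir, paste0(prefix, "_phenotypes.tsv"))
    paths$analytes <- file.path(dir, paste0(prefix, "_analytes.tsv"))
    paths$truth <- file.path(dir, paste0(prefix, "_truth.json"))
    write.table(phenotypes$values, paths$phenotypes, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(phenotypes$analyte_meta, paths$analytes, sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- lapply(phenotypes$truth, function(tr) {
      tr[c("idx_m", "idx_f", "u", "v", "share_m", "share_f")]
    })
    jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}
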
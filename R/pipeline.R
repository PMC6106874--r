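# Stage orchestration: one config, deterministic seeds, manifests -----------

#' Build a run configuration
#'
#' Assembles the pipeline configuration, either from arguments or from a
#' YAML file via [read_run_config()]. Thresholds default to the analysis
#' constants: genome-wide significance 5e-8, suggestive 1e-7, MAF floor
#' 0.01, 100 permutations, 10 ancestry coordinates.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param sim Named list of [sim_config()] overrides.
#' @param seed Global seed.
#' @param maf_min,hwe_alpha,call_min Marker QC thresholds.
#' @param gw_threshold,suggestive_threshold GWAS thresholds.
#' @param n_pcs Ancestry coordinates used as covariates.
#' @param n_groups Sub-populations for the meta-analysis stage.
#' @param n_perm Permutations for the heritability null.
#' @param detect_min Detection-fraction threshold for analytes.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, sim = list(), seed = 1L,
                       maf_min = 0.01, hwe_alpha = 1e-6, call_min = 0.95,
                       gw_threshold = 5e-8, suggestive_threshold = 1e-7,
                       n_pcs = 10, n_groups = 4, n_perm = 100,
                       detect_min = 0.6) {
  stopifnot(gw_threshold > 0, suggestive_threshold > 0, maf_min > 0,
            n_pcs > 0, n_perm > 0)
  structure(
    list(out_dir = out_dir, sim = sim, seed = as.integer(seed),
         maf_min = maf_min, hwe_alpha = hwe_alpha, call_min = call_min,
         gw_threshold = gw_threshold,
         suggestive_threshold = suggestive_threshold,
         n_pcs = n_pcs, n_groups = n_groups, n_perm = n_perm,
         detect_min = detect_min),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match [run_config()]
#'   arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_order <- c("simulate", "qc", "ancestry", "prep", "partition", "grm",
                 "reml", "rg", "gwas", "meta", "condition", "dual",
                 "outcome", "interact")

stage_deps <- list(
  simulate = character(), qc = "simulate", prep = c("simulate", "ancestry"),
  ancestry = "qc", partition = "qc", grm = c("qc", "partition"),
  reml = c("grm", "prep"), rg = c("grm", "prep"),
  gwas = c("qc", "prep", "ancestry"), meta = c("qc", "prep", "ancestry"),
  condition = c("gwas"), dual = c("gwas"),
  outcome = c("simulate", "prep"), interact = c("simulate", "prep", "gwas")
)

stage_done_file <- function(cfg, stage) {
  file.path(cfg$out_dir, sprintf("%s.manifest.json", stage))
}

write_manifest <- function(cfg, stage, inputs, outputs, params = list()) {
  man <- list(
    stage = stage,
    package_version = as.character(packageVersion("dyadherit")),
    seed = cfg$seed,
    params = params,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(man, stage_done_file(cfg, stage), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(man)
}

p_ <- function(cfg, ...) file.path(cfg$out_dir, paste0(...))

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
read_tsv <- function(path, ...) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, ...))
}

#' Run one pipeline stage
#'
#' Stages: `simulate | qc | prep | ancestry | partition | grm | reml | rg |
#' gwas | meta | condition | dual | outcome | interact`. Each stage reads
#' only files produced by its upstream stages, writes tab-separated
#' artifacts under `cfg$out_dir`, and records a JSON manifest (parameters
#' and input/output checksums) enabling exact re-runs; missing upstream
#' artifacts raise an error naming the producing stage.
#'
#' @param name Stage name.
#' @param cfg A [run_config()].
#' @return Invisibly, the stage manifest.
#' @export
run_stage <- function(name, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  name <- match.arg(name, stage_order)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (dep in stage_deps[[name]]) {
    if (!file.exists(stage_done_file(cfg, dep))) {
      stop_dyad(sprintf(
        "stage '%s' requires artifacts from stage '%s'; run that stage first",
        name, dep), "missing_upstream")
    }
  }
  switch(name,
    simulate = stage_simulate(cfg),
    qc = stage_qc(cfg),
    prep = stage_prep(cfg),
    ancestry = stage_ancestry(cfg),
    partition = stage_partition(cfg),
    grm = stage_grm(cfg),
    reml = stage_reml(cfg),
    rg = stage_rg(cfg),
    gwas = stage_gwas(cfg),
    meta = stage_meta(cfg),
    condition = stage_condition(cfg),
    dual = stage_dual(cfg),
    outcome = stage_outcome(cfg),
    interact = stage_interact(cfg)
  )
}

#' Run every pipeline stage in order
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the list of stage manifests.
#' @export
run_pipeline <- function(cfg) {
  invisible(lapply(stage_order, run_stage, cfg = cfg))
}

stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, utils::modifyList(cfg$sim,
                                              list(seed = cfg$seed)))
  cohort <- simulate_dyads(sc)
  ph <- simulate_phenotypes(cohort, sc)
  paths <- write_cohort(cohort, ph, cfg$out_dir, "cohort")
  cov_path <- p_(cfg, "cohort_covariates.tsv")
  write_tsv(cohort$covariates, cov_path)
  med <- log(ph$values[[2]])
  status <- simulate_outcome(cohort, med, sc)
  out_path <- p_(cfg, "cohort_outcome.tsv")
  write_tsv(tibble(dyad_id = cohort$pairing$dyad_id, status = status),
            out_path)
  outs <- c(unlist(lapply(paths[c("mothers", "offspring")], function(p)
    paste0(p, c(".bed", ".bim", ".fam")))),
    paths$pairing, paths$phenotypes, paths$analytes, paths$truth,
    cov_path, out_path)
  write_manifest(cfg, "simulate", character(), outs,
                 params = unclass(sc)[!vapply(unclass(sc), is.null, TRUE)])
}

read_cohort_files <- function(cfg, suffix = "") {
  list(
    maternal = read_plink1(p_(cfg, "cohort_mothers", suffix)),
    offspring = read_plink1(p_(cfg, "cohort_offspring", suffix)),
    pairing = read_tsv(p_(cfg, "cohort_pairing.tsv"))
  )
}

stage_qc <- function(cfg) {
  co <- read_cohort_files(cfg)
  mc <- mendel_check(co$maternal, co$offspring, co$pairing)
  qm <- marker_qc(co$maternal, cfg$maf_min, cfg$hwe_alpha, cfg$call_min,
                  mendel_errors = mc$per_snp)
  qo <- marker_qc(co$offspring, cfg$maf_min, cfg$hwe_alpha, cfg$call_min,
                  mendel_errors = mc$per_snp)
  keep <- intersect(qm$keep, qo$keep)
  write_plink1(co$maternal[, keep], p_(cfg, "cohort_mothers_qc"))
  write_plink1(co$offspring[, keep], p_(cfg, "cohort_offspring_qc"))
  write_tsv(qm$stats, p_(cfg, "qc_maternal_stats.tsv"))
  write_tsv(qo$stats, p_(cfg, "qc_offspring_stats.tsv"))
  outs <- c(paste0(p_(cfg, "cohort_mothers_qc"), c(".bed", ".bim", ".fam")),
            paste0(p_(cfg, "cohort_offspring_qc"), c(".bed", ".bim", ".fam")),
            p_(cfg, "qc_maternal_stats.tsv"), p_(cfg, "qc_offspring_stats.tsv"))
  write_manifest(cfg, "qc",
                 paste0(p_(cfg, c("cohort_mothers", "cohort_offspring")),
                        rep(c(".bed", ".bim", ".fam"), each = 2)),
                 outs,
                 params = list(maf_min = cfg$maf_min,
                               hwe_alpha = cfg$hwe_alpha,
                               call_min = cfg$call_min,
                               n_kept = length(keep)))
}

stage_ancestry <- function(cfg) {
  outs <- character()
  for (who in c("mothers", "offspring")) {
    g <- read_plink1(p_(cfg, "cohort_", who, "_qc"))
    k <- min(cfg$n_pcs, nrow(g$values) - 1)
    pcs <- classical_mds(ibs_distance(g), k = k)
    groups <- assign_subpopulations(pcs, cfg$n_groups, seed = cfg$seed)
    tab <- tidy(pcs)
    tab$group <- groups
    f <- p_(cfg, "ancestry_", who, ".tsv")
    write_tsv(tab, f)
    outs <- c(outs, f)
  }
  write_manifest(cfg, "ancestry",
                 paste0(p_(cfg, "cohort_mothers_qc"), ".bed"), outs,
                 params = list(n_pcs = cfg$n_pcs, n_groups = cfg$n_groups))
}

stage_prep <- function(cfg) {
  values <- read_tsv(p_(cfg, "cohort_phenotypes.tsv"))
  meta <- read_tsv(p_(cfg, "cohort_analytes.tsv"))
  covs <- read_tsv(p_(cfg, "cohort_covariates.tsv"))
  anc <- read_tsv(p_(cfg, "ancestry_mothers.tsv"))
  cand <- cbind(covs[, -1, drop = FALSE],
                anc[, grep("^C", names(anc)), drop = FALSE])
  prep <- prepare_phenotypes(values, meta, cand,
                             min_fraction = cfg$detect_min)
  res <- prep$residuals$residuals
  res <- dplyr::mutate(res, dyad_id = values$dyad_id, .before = 1)
  write_tsv(res, p_(cfg, "prep_residuals.tsv"))
  write_tsv(prep$residuals$summary, p_(cfg, "prep_summary.tsv"))
  write_tsv(prep$screen, p_(cfg, "prep_covariate_screen.tsv"))
  write_manifest(cfg, "prep",
                 p_(cfg, c("cohort_phenotypes.tsv", "cohort_analytes.tsv")),
                 p_(cfg, c("prep_residuals.tsv", "prep_summary.tsv",
                           "prep_covariate_screen.tsv")),
                 params = list(detect_min = cfg$detect_min))
}

stage_partition <- function(cfg) {
  co <- read_cohort_files(cfg, "_qc")
  part <- partition_cohort(co, maf_min = cfg$maf_min)
  write_plink1(recode_pseudo_x(part$maternal_nt), p_(cfg, "haploid_maternal_nt"))
  write_plink1(recode_pseudo_x(part$fetal_nm), p_(cfg, "haploid_fetal_nm"))
  outs <- c(paste0(p_(cfg, "haploid_maternal_nt"), c(".bed", ".bim", ".fam")),
            paste0(p_(cfg, "haploid_fetal_nm"), c(".bed", ".bim", ".fam")))
  write_manifest(cfg, "partition",
                 paste0(p_(cfg, "cohort_mothers_qc"), ".bed"), outs,
                 params = list(n_mendel_errors = part$n_mendel_errors,
                               n_kept = length(part$kept_snps)))
}

stage_grm <- function(cfg) {
  outs <- character()
  for (who in c("mothers", "offspring")) {
    g <- read_plink1(p_(cfg, "cohort_", who, "_qc"))
    write_grm(diploid_grm(g), p_(cfg, "grm_", who))
    outs <- c(outs, paste0(p_(cfg, "grm_", who), c(".grm.gz", ".grm.id")))
  }
  for (who in c("maternal_nt", "fetal_nm")) {
    g <- read_plink1(p_(cfg, "haploid_", who))
    ph <- as_pseudo_haploid(g)
    write_grm(haploid_nd_grm(ph), p_(cfg, "grm_", who))
    outs <- c(outs, paste0(p_(cfg, "grm_", who), c(".grm.gz", ".grm.id")))
  }
  write_manifest(cfg, "grm", paste0(p_(cfg, "cohort_mothers_qc"), ".bed"),
                 outs)
}

reml_inputs <- function(cfg) {
  res <- read_tsv(p_(cfg, "prep_residuals.tsv"))
  anc <- read_tsv(p_(cfg, "ancestry_mothers.tsv"))
  covs <- anc[, grep("^C", names(anc)), drop = FALSE]
  list(res = res, covs = covs)
}

stage_reml <- function(cfg) {
  inp <- reml_inputs(cfg)
  traits <- setdiff(names(inp$res), "dyad_id")
  rows <- list()
  for (who in c("mothers", "offspring", "maternal_nt", "fetal_nm")) {
    model <- if (who %in% c("mothers", "offspring")) "diploid" else "haploid_nd"
    A <- read_grm(p_(cfg, "grm_", who), model = model)
    eg <- eigen(A$values, symmetric = TRUE)
    for (tr in traits) {
      y <- inp$res[[tr]]
      ok <- !is.na(y)
      fit <- suppressWarnings(reml_univariate(
        y[ok], inp$covs[ok, , drop = FALSE],
        A$values[ok, ok],
        eigen_A = if (all(ok)) eg else NULL
      ))
      pn <- suppressWarnings(permutation_null(
        y[ok], inp$covs[ok, , drop = FALSE], A$values[ok, ok],
        n_perm = cfg$n_perm, seed = cfg$seed
      ))
      row <- glance(fit)
      row$genome <- who
      row$trait <- tr
      row$perm_median <- pn$median_perm
      row$perm_top5 <- pn$top5
      rows[[paste(who, tr)]] <- row
    }
  }
  write_tsv(dplyr::bind_rows(rows), p_(cfg, "reml_results.tsv"))
  write_manifest(cfg, "reml", p_(cfg, "prep_residuals.tsv"),
                 p_(cfg, "reml_results.tsv"),
                 params = list(n_perm = cfg$n_perm))
}

stage_rg <- function(cfg) {
  inp <- reml_inputs(cfg)
  traits <- setdiff(names(inp$res), "dyad_id")
  out <- p_(cfg, "rg_results.tsv")
  if (length(traits) < 2) {
    write_tsv(tibble(note = "fewer than two analytes; rg not estimable"), out)
  } else {
    A <- read_grm(p_(cfg, "grm_mothers"), model = "diploid")
    pairs <- utils::combn(traits[seq_len(min(3, length(traits)))], 2)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      y1 <- inp$res[[pairs[1, i]]]
      y2 <- inp$res[[pairs[2, i]]]
      ok <- !is.na(y1) & !is.na(y2)
      fit <- suppressWarnings(reml_bivariate(
        y1[ok], y2[ok], inp$covs[ok, , drop = FALSE], A$values[ok, ok]))
      g <- glance(fit)
      g$trait1 <- pairs[1, i]
      g$trait2 <- pairs[2, i]
      g
    })
    write_tsv(dplyr::bind_rows(rows), out)
  }
  write_manifest(cfg, "rg", p_(cfg, "prep_residuals.tsv"), out)
}

gwas_inputs <- function(cfg) {
  inp <- reml_inputs(cfg)
  g <- read_plink1(p_(cfg, "cohort_offspring_qc"))
  anc <- read_tsv(p_(cfg, "ancestry_offspring.tsv"))
  list(res = inp$res, geno = g,
       covs = anc[, grep("^C", names(anc)), drop = FALSE],
       groups = anc$group)
}

stage_gwas <- function(cfg) {
  inp <- gwas_inputs(cfg)
  traits <- setdiff(names(inp$res), "dyad_id")
  outs <- character()
  for (tr in traits) {
    y <- inp$res[[tr]]
    ok <- !is.na(y)
    scan <- gwas_linear(y[ok], inp$geno[ok, ], inp$covs[ok, , drop = FALSE],
                        cfg$gw_threshold, cfg$suggestive_threshold)
    f <- p_(cfg, "gwas_", tr, ".tsv")
    write_tsv(scan, f)
    outs <- c(outs, f)
  }
  write_manifest(cfg, "gwas", p_(cfg, "prep_residuals.tsv"), outs,
                 params = list(gw = cfg$gw_threshold,
                               suggestive = cfg$suggestive_threshold))
}

first_trait <- function(res) setdiff(names(res), "dyad_id")[1]

stage_meta <- function(cfg) {
  inp <- gwas_inputs(cfg)
  tr <- first_trait(inp$res)
  y <- inp$res[[tr]]
  scans <- lapply(sort(unique(inp$groups)), function(g) {
    sel <- inp$groups == g & !is.na(y)
    gwas_linear(y[sel], inp$geno[sel, ], inp$covs[sel, , drop = FALSE])
  })
  meta <- meta_fixed(scans)
  write_tsv(meta, p_(cfg, "meta_results.tsv"))
  write_manifest(cfg, "meta", p_(cfg, "prep_residuals.tsv"),
                 p_(cfg, "meta_results.tsv"),
                 params = list(n_groups = length(scans)))
}

top_snp <- function(cfg, tr) {
  scan <- read_tsv(p_(cfg, "gwas_", tr, ".tsv"))
  scan$snp[which.min(scan$p)]
}

stage_condition <- function(cfg) {
  inp <- gwas_inputs(cfg)
  tr <- first_trait(inp$res)
  y <- inp$res[[tr]]
  ok <- !is.na(y)
  idx <- top_snp(cfg, tr)
  scan <- conditional_scan(y[ok], inp$geno[ok, ],
                           inp$covs[ok, , drop = FALSE], idx)
  write_tsv(scan, p_(cfg, "conditional_results.tsv"))
  write_manifest(cfg, "condition", p_(cfg, "gwas_", tr, ".tsv"),
                 p_(cfg, "conditional_results.tsv"),
                 params = list(index = idx))
}

stage_dual <- function(cfg) {
  inp <- gwas_inputs(cfg)
  co <- read_cohort_files(cfg, "_qc")
  tr <- first_trait(inp$res)
  y <- inp$res[[tr]]
  idx <- top_snp(cfg, tr)
  gm <- co$maternal$values[, idx]
  gf <- co$offspring$values[, idx]
  res <- dual_genome_model(y, gm, gf, inp$covs)
  res$snp <- idx
  write_tsv(res, p_(cfg, "dual_genome_results.tsv"))
  write_manifest(cfg, "dual", p_(cfg, "gwas_", tr, ".tsv"),
                 p_(cfg, "dual_genome_results.tsv"),
                 params = list(index = idx))
}

stage_outcome <- function(cfg) {
  res <- read_tsv(p_(cfg, "prep_residuals.tsv"))
  status <- read_tsv(p_(cfg, "cohort_outcome.tsv"))$status
  rows <- lapply(setdiff(names(res), "dyad_id"), function(tr) {
    y <- res[[tr]]
    ok <- !is.na(y)
    cw <- case_control_wilcoxon(y[ok], status[ok])
    lg <- logistic_outcome(y[ok], NULL, status[ok])
    med_row <- lg[lg$term == "mediator", ]
    dplyr::mutate(med_row, trait = tr, wilcoxon_p = cw$p, .before = 1)
  })
  write_tsv(dplyr::bind_rows(rows), p_(cfg, "outcome_results.tsv"))
  write_manifest(cfg, "outcome", p_(cfg, "prep_residuals.tsv"),
                 p_(cfg, "outcome_results.tsv"))
}

stage_interact <- function(cfg) {
  res <- read_tsv(p_(cfg, "prep_residuals.tsv"))
  status <- read_tsv(p_(cfg, "cohort_outcome.tsv"))$status
  co <- read_cohort_files(cfg, "_qc")
  tr <- first_trait(res)
  y <- res[[tr]]
  idx <- top_snp(cfg, tr)
  ok <- !is.na(y)
  fit <- interaction_model(status[ok], co$maternal$values[ok, idx], y[ok],
                           stratified = TRUE)
  out <- fit$terms
  out$snp <- idx
  write_tsv(out, p_(cfg, "interaction_results.tsv"))
  if (!is.null(fit$strata)) {
    write_tsv(fit$strata, p_(cfg, "interaction_strata.tsv"))
  }
  write_manifest(cfg, "interact", p_(cfg, "prep_residuals.tsv"),
                 p_(cfg, "interaction_results.tsv"),
                 params = list(index = idx))
}
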
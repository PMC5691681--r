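## End-to-end orchestration: simulate or read inputs, score the diet, build
## frequency/HWE tables, assemble matched pairs, fit the per-SNP and GRS
## interaction models, and emit the analysis tables plus a run manifest.

write_csv_quiet <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- lapply(unclass(config), function(x) {
    if (is.numeric(x) || is.character(x) || is.logical(x)) x else
      as.character(x)
  })
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

## Eight-group OR grid + per-stratum trend + 1-df interaction LRT for one
## binary genotype factor, conditional (matched pairs) version.
conditional_snp_table <- function(pairs, subjects, carrier, quartile, mds,
                                  label) {
  data <- subjects
  data$carrier <- carrier
  data$mds_q <- quartile
  data$carrier_mds_q <- carrier * quartile
  data$trend_score <- quartile_median_score(mds, quartile)
  grp <- build_groups(quartile, carrier)
  dummies <- stats::model.matrix(~grp)[, -1, drop = FALSE]
  colnames(dummies) <- make.names(levels(grp)[-1])
  data <- cbind(data, as.data.frame(dummies))
  educ <- "education_years_ge14"
  ## 8-group OR grid (7 dummies vs Q1 non-carrier), education-adjusted
  ors <- tryCatch({
    grid_fit <- clogit_fit(
      pair_differences(pairs, data, c(colnames(dummies), educ)),
      model_label = paste(label, "8-group"))
    or_report(grid_fit, colnames(dummies))
  }, error = function(e) {
    data.frame(term = colnames(dummies), beta = NA_real_, se = NA_real_,
               or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               p_value = NA_real_)
  })
  ## interaction: carrier x ordinal quartile, 1-df LRT
  full <- clogit_fit(
    pair_differences(pairs, data, c("carrier", "mds_q", "carrier_mds_q",
                                    educ)),
    model_label = paste(label, "full"))
  reduced <- clogit_fit(
    pair_differences(pairs, data, c("carrier", "mds_q", educ)),
    model_label = paste(label, "reduced"))
  lrt <- lrt_interaction(full, reduced)
  ## per-stratum trend: unconditional on the quartile-median score within
  ## each genotype stratum
  trend_p <- vapply(c(0, 1), function(gv) {
    idx <- data$carrier == gv
    y <- as.numeric(data$id[idx] %in% pairs$case_id)
    x <- cbind(trend_score = data$trend_score[idx],
               education = data[[educ]][idx])
    tryCatch(trend_test(logit_fit(x, y), "trend_score")$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
  list(or_grid = cbind(snp = label, ors),
       interaction = data.frame(snp = label, lr_chi2 = lrt$lr_chi2,
                                df = lrt$df, p_interaction = lrt$p_value),
       trend = data.frame(snp = label, stratum = c("noncarrier", "carrier"),
                          p_trend = trend_p))
}

## Unconditional analogue for abdominal-obesity / high-WHR outcomes, with
## the fuller adjustment set.
unconditional_snp_table <- function(data, outcome, carrier, quartile, mds,
                                    label) {
  adj <- cbind(education = data$education_years_ge14,
               age = data$age,
               male = as.numeric(data$sex == "male"),
               smoking_current = as.numeric(data$smoking == "current"),
               smoking_ex = as.numeric(data$smoking == "ex"),
               activity_low = as.numeric(data$activity == "low"),
               activity_moderate = as.numeric(data$activity == "moderate"),
               energy = as.numeric(scale(data$energy_kcal)))
  y <- as.numeric(outcome)
  grp <- build_groups(quartile, carrier)
  dummies <- stats::model.matrix(~grp)[, -1, drop = FALSE]
  colnames(dummies) <- make.names(levels(grp)[-1])
  ors <- tryCatch({
    grid_fit <- logit_fit(cbind(dummies, adj), y,
                          model_label = paste(label, "8-group"))
    or_report(grid_fit, colnames(dummies))
  }, error = function(e) {
    data.frame(term = colnames(dummies), beta = NA_real_, se = NA_real_,
               or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               p_value = NA_real_)
  })
  x_full <- cbind(carrier = carrier, mds_q = quartile,
                  carrier_mds_q = carrier * quartile, adj)
  full <- logit_fit(x_full, y, model_label = paste(label, "full"))
  reduced <- logit_fit(x_full[, colnames(x_full) != "carrier_mds_q"], y,
                       model_label = paste(label, "reduced"))
  lrt <- lrt_interaction(full, reduced)
  trend_score <- quartile_median_score(mds, quartile)
  trend_p <- vapply(c(0, 1), function(gv) {
    idx <- carrier == gv
    tryCatch(trend_test(
      logit_fit(cbind(trend_score = trend_score[idx],
                      adj[idx, , drop = FALSE]), y[idx]),
      "trend_score")$p_value, error = function(e) NA_real_)
  }, numeric(1))
  list(or_grid = cbind(snp = label, ors),
       interaction = data.frame(snp = label, lr_chi2 = lrt$lr_chi2,
                                df = lrt$df, p_interaction = lrt$p_value),
       trend = data.frame(snp = label, stratum = c("noncarrier", "carrier"),
                          p_trend = trend_p))
}

#' Run the full gene-diet interaction pipeline
#'
#' Simulates (or accepts) a cohort, applies the exclusion cascade, scores
#' the Mediterranean diet, matches incident cases to normal-weight controls
#' on age and sex, and fits: the case-control descriptive comparison;
#' allele/genotype frequencies with Hardy-Weinberg tests by group; per-SNP
#' conditional 8-group OR grids with per-stratum trend and 1-df interaction
#' LRT for obesity; unconditional analogues for abdominal obesity and high
#' WHR; and the GRS (median-split) versions of all three. Writes one CSV
#' per table plus a JSON run manifest to `out_dir`.
#'
#' @param config a [sim_config()]; its seed drives the simulation and the
#'   matching randomisation.
#' @param out_dir output directory (created if needed).
#' @param cohort optional pre-built [simulate_cohort()]-shaped list; when
#'   supplied the simulation stage is skipped.
#' @param panel [snp_panel()] describing the genotype columns. Default
#'   [fto_panel()].
#' @return invisibly, a list with every table and the manifest.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL,
                         panel = fto_panel()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  subjects <- cohort$subjects
  subjects$energy_kcal <- cohort$diet$energy_kcal[
    match(subjects$id, cohort$diet$subject_id)]

  ## exclusion cascade (energy-ratio screen against a Schofield prediction)
  ratio <- subjects$energy_kcal /
    schofield_energy(subjects$age, subjects$sex, subjects$weight_kg)
  excl <- apply_exclusions(subjects, energy_ratio = ratio)
  analysis <- excl$retained

  ## diet scoring on the retained sample
  diet <- cohort$diet[cohort$diet$subject_id %in% analysis$id, , drop = FALSE]
  mds <- mediterranean_diet_score(diet, analysis$sex[
    match(diet$subject_id, analysis$id)])
  analysis$mds <- mds$scores$mds[match(analysis$id, mds$scores$subject_id)]

  ## phenotypes and matching
  analysis <- classify_phenotypes(analysis)
  cases <- analysis[analysis$is_case %in% TRUE, , drop = FALSE]
  controls <- analysis[!(analysis$is_case %in% TRUE) &
                         analysis$normal_weight %in% TRUE, , drop = FALSE]
  pairs <- match_pairs(cases, controls,
                       seed = stage_seed(config$seed, "pairs"))
  matched_ids <- c(pairs$case_id, pairs$control_id)
  m <- analysis[match(matched_ids, analysis$id), , drop = FALSE]
  m$is_case <- m$id %in% pairs$case_id

  ## genetics on the matched sample
  geno <- cohort$genotypes[matched_ids, , drop = FALSE]
  rownames(geno) <- matched_ids
  freq <- genotype_frequencies(geno, ifelse(m$is_case, "case", "control"),
                               panel)
  grs <- weighted_grs(geno, panel)
  high_grs <- dichotomize_grs(grs)

  ## MDS quartiles on the matched sample
  quartile <- assign_quartiles(m$mds)

  descr <- cohort_descriptives(
    m, ifelse(m$is_case, "case", "control"),
    continuous = c("age", "bmi", "wc", "whr", "energy_kcal", "mds"),
    categorical = c("smoking", "activity", "education_years_ge14"))

  strata <- c(stats::setNames(lapply(seq_len(nrow(panel)), function(j) {
    dominant_code(geno[, j])
  }), panel$snp_id), list(GRS = high_grs))

  obesity <- list(); abdominal <- list(); whr_tab <- list()
  for (nm in names(strata)) {
    carrier <- strata[[nm]]
    if (anyNA(carrier)) next
    obesity[[nm]] <- conditional_snp_table(pairs, m, carrier, quartile,
                                           m$mds, nm)
    abdominal[[nm]] <- unconditional_snp_table(m, m$abdominal_obese, carrier,
                                               quartile, m$mds, nm)
    whr_tab[[nm]] <- unconditional_snp_table(m, m$high_whr, carrier,
                                             quartile, m$mds, nm)
  }
  collect <- function(lst, part) do.call(rbind, lapply(lst, `[[`, part))

  tables <- list(
    descriptives = descr,
    frequencies = freq,
    exclusion_audit = excl$audit,
    obesity_or = collect(obesity, "or_grid"),
    obesity_interaction = collect(obesity, "interaction"),
    obesity_trend = collect(obesity, "trend"),
    abdominal_or = collect(abdominal, "or_grid"),
    abdominal_interaction = collect(abdominal, "interaction"),
    abdominal_trend = collect(abdominal, "trend"),
    whr_or = collect(whr_tab, "or_grid"),
    whr_interaction = collect(whr_tab, "interaction"),
    whr_trend = collect(whr_tab, "trend"))
  for (nm in names(tables)) {
    write_csv_quiet(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dietGxE")),
    n_input = config$n_subjects,
    n_retained = nrow(analysis),
    n_pairs = nrow(pairs),
    grs_threshold = attr(high_grs, "threshold"),
    mds_quartile_means = as.numeric(attr(quartile, "means")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tables, list(manifest = manifest, pairs = pairs)))
}

#' Monte-Carlo calibration of the interaction likelihood-ratio test
#'
#' Repeatedly simulates matched-pair data at each requested interaction
#' effect size, fits the full and reduced conditional models, and reports
#' the LRT rejection rate at level `alpha` with an exact binomial
#' confidence interval — type-I error when `beta_gxe = 0`, power otherwise.
#'
#' @param beta_gxe numeric vector of interaction log-odds to calibrate at.
#' @param n_reps Monte-Carlo replicates per effect size.
#' @param n_pairs matched pairs per replicate.
#' @param alpha test level. Default 0.05.
#' @param beta_g,beta_e main-effect log-odds used in every replicate.
#' @param seed integer seed.
#' @param conf_level confidence level of the binomial interval.
#' @return data.frame: `beta_gxe`, `n_reps`, `n_pairs`, `rejections`,
#'   `rate`, `ci_lo`, `ci_hi`, `mean_beta_gxe_hat`.
#' @export
calibrate <- function(beta_gxe = 0, n_reps = 200, n_pairs = 500,
                      alpha = 0.05, beta_g = 0.15, beta_e = 0, seed = NULL,
                      conf_level = 0.95) {
  stopifnot(n_reps >= 1, n_pairs >= 10)
  with_seed(seed, {
    rows <- lapply(beta_gxe, function(bg) {
      rej <- 0L
      est <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        sim <- simulate_matched_pairs(n_pairs, beta_g = beta_g,
                                      beta_e = beta_e, beta_gxe = bg)
        d <- sim$diffs[, c("carrier", "mds_q", "carrier_mds_q")]
        full <- clogit_fit(d)
        reduced <- clogit_fit(d[, c("carrier", "mds_q")])
        p <- lrt_interaction(full, reduced)$p_value
        rej <- rej + (p < alpha)
        est[r] <- full$beta[["carrier_mds_q"]]
      }
      ci <- stats::binom.test(rej, n_reps, conf.level = conf_level)$conf.int
      data.frame(beta_gxe = bg, n_reps = n_reps, n_pairs = n_pairs,
                 rejections = rej, rate = rej / n_reps,
                 ci_lo = ci[1], ci_hi = ci[2],
                 mean_beta_gxe_hat = mean(est))
    })
    do.call(rbind, rows)
  })
}
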
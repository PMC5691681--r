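## Phenotype classification, exclusion cascade, age/sex pair matching, and
## the MDS-quartile x genotype group design.

#' Classify obesity phenotypes from anthropometrics
#'
#' Adds the four phenotype flags used in the analysis: general obesity
#' (BMI at or above `bmi_obese`), normal weight (BMI within `bmi_normal`,
#' inclusive), abdominal obesity (waist circumference at or above `wc_cut`
#' for both sexes), and high waist-to-hip ratio with sex-specific cutoffs.
#' Missing anthropometrics give missing flags.
#'
#' @param subjects data.frame with `bmi`, `wc`, `whr`, `sex`
#'   ("male"/"female").
#' @param bmi_obese obesity BMI cutoff (kg/m^2), inclusive. Default 30.
#' @param bmi_normal normal-weight BMI range, inclusive. Default
#'   `c(18.5, 24.9)`.
#' @param wc_cut abdominal-obesity waist cutoff (cm), inclusive, both sexes.
#'   Default 95.
#' @param whr_cut_male,whr_cut_female high-WHR cutoffs, inclusive. Defaults
#'   0.8 (men) and 0.9 (women) as used in the source population's cutoffs;
#'   override if your convention differs.
#' @return `subjects` with logical columns `obese`, `normal_weight`,
#'   `abdominal_obese`, `high_whr` appended.
#' @export
classify_phenotypes <- function(subjects, bmi_obese = 30,
                                bmi_normal = c(18.5, 24.9), wc_cut = 95,
                                whr_cut_male = 0.8, whr_cut_female = 0.9) {
  stop_if_not_df(subjects, c("bmi", "wc", "whr", "sex"), "subjects")
  subjects$obese <- subjects$bmi >= bmi_obese
  subjects$normal_weight <- subjects$bmi >= bmi_normal[1] &
    subjects$bmi <= bmi_normal[2]
  subjects$abdominal_obese <- subjects$wc >= wc_cut
  whr_cut <- ifelse(subjects$sex == "male", whr_cut_male, whr_cut_female)
  subjects$high_whr <- subjects$whr >= whr_cut
  subjects
}

#' Predicted daily energy from a Schofield-type equation
#'
#' Basal metabolic rate from the Schofield age/sex/weight equations
#' (kcal/day), multiplied by a physical-activity factor. Used to form the
#' reported/predicted energy ratio for the implausible-intake screen; a
#' pass-through alternative is to supply predicted energy directly to
#' [apply_exclusions()].
#'
#' @param age years; `sex` "male"/"female"; `weight_kg` body weight.
#' @param sex,weight_kg see above.
#' @param activity_factor multiplier on BMR (default 1.55, moderate).
#' @return predicted energy intake, kcal/day.
#' @export
schofield_energy <- function(age, sex, weight_kg, activity_factor = 1.55) {
  stopifnot(length(age) == length(sex), length(age) == length(weight_kg))
  bmr <- numeric(length(age))
  male <- sex == "male"
  ## Schofield (1985) coefficients, kcal/day
  co <- function(a, m) {
    if (m) {
      if (a < 30) c(15.057, 692.2) else if (a < 60) c(11.472, 873.1)
      else c(11.711, 587.7)
    } else {
      if (a < 30) c(14.818, 486.6) else if (a < 60) c(8.126, 845.6)
      else c(9.082, 658.5)
    }
  }
  for (i in seq_along(age)) {
    k <- co(age[i], male[i])
    bmr[i] <- k[1] * weight_kg[i] + k[2]
  }
  bmr * activity_factor
}

#' Apply the study exclusion cascade
#'
#' Drops subjects, in a fixed and auditable order, for: recent weight change
#' over 5 kg, pregnancy/lactation, use of weight-affecting drugs, failed DNA
#' quality, and implausible energy reporting (reported/predicted energy
#' ratio outside mean +/- `sd_limit` SD, computed among subjects surviving
#' the earlier rules). The audit log records the count removed by each rule
#' in application order, so the per-rule counts sum to input minus retained.
#'
#' @param subjects data.frame with logical flag columns
#'   `weight_change_gt5kg`, `pregnant_lactating`, `weight_drug`,
#'   `dna_quality_ok`.
#' @param energy_ratio optional numeric vector (reported/predicted energy),
#'   one per row; `NULL` skips the ratio screen.
#' @param sd_limit half-width of the ratio screen in SDs. Default 3.
#' @return list with `retained` (data.frame) and `audit` (data.frame of
#'   `rule`, `n_removed`, `n_remaining`).
#' @export
apply_exclusions <- function(subjects, energy_ratio = NULL, sd_limit = 3) {
  flags <- c("weight_change_gt5kg", "pregnant_lactating", "weight_drug",
             "dna_quality_ok")
  stop_if_not_df(subjects, flags, "subjects")
  if (!is.null(energy_ratio) && length(energy_ratio) != nrow(subjects)) {
    stop("`energy_ratio` must have one entry per subject", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(subjects))
  audit <- data.frame(rule = character(), n_removed = integer(),
                      n_remaining = integer(), stringsAsFactors = FALSE)
  drop_rule <- function(rule, hit) {
    hit <- hit & keep
    keep <<- keep & !hit
    audit <<- rbind(audit, data.frame(rule = rule, n_removed = sum(hit),
                                      n_remaining = sum(keep)))
  }
  drop_rule("weight_change_gt5kg", subjects$weight_change_gt5kg %in% TRUE)
  drop_rule("pregnant_lactating", subjects$pregnant_lactating %in% TRUE)
  drop_rule("weight_drug", subjects$weight_drug %in% TRUE)
  drop_rule("dna_quality_fail", !(subjects$dna_quality_ok %in% TRUE))
  if (!is.null(energy_ratio)) {
    r <- energy_ratio[keep]
    mu <- mean(r, na.rm = TRUE)
    sd_r <- stats::sd(r, na.rm = TRUE)
    out_of_range <- !is.na(energy_ratio) &
      abs(energy_ratio - mu) > sd_limit * sd_r
    drop_rule("energy_ratio_3sd", out_of_range)
  }
  list(retained = subjects[keep, , drop = FALSE], audit = audit)
}

#' Match incident cases to controls by age and sex
#'
#' Randomised greedy 1:1 matching: cases are visited in random order and
#' each is paired with one control sampled uniformly from the unused
#' controls of the same sex within `age_window` years. Controls must
#' already be restricted to those eligible (normal weight) at the case's
#' phase; pass `eligible` to enforce per-phase eligibility. Cases with no
#' eligible control are reported unmatched with a warning. Deterministic
#' under a fixed `seed`.
#'
#' @param cases data.frame with `id`, `age`, `sex` and optionally `phase`.
#' @param controls data.frame with `id`, `age`, `sex`.
#' @param age_window maximum |age difference| in years. Default 5.
#' @param eligible optional logical matrix (rows = controls, columns =
#'   phases) of phase-specific eligibility; requires `cases$phase`.
#' @param seed integer seed for the matching randomisation.
#' @return data.frame of class `matched_pairs`: `case_id`, `control_id`,
#'   `phase`, `age_case`, `age_control`, `sex`. Attribute `unmatched` lists
#'   case ids that found no control.
#' @export
match_pairs <- function(cases, controls, age_window = 5, eligible = NULL,
                        seed = NULL) {
  stop_if_not_df(cases, c("id", "age", "sex"), "cases")
  stop_if_not_df(controls, c("id", "age", "sex"), "controls")
  if (!is.null(eligible)) {
    stopifnot(nrow(eligible) == nrow(controls), "phase" %in% names(cases))
  }
  phase <- if ("phase" %in% names(cases)) cases$phase else rep(NA_integer_,
                                                               nrow(cases))
  with_seed(seed, {
    order_cases <- sample.int(nrow(cases))
    used <- rep(FALSE, nrow(controls))
    rows <- vector("list", nrow(cases))
    unmatched <- character()
    for (i in order_cases) {
      ok <- !used & controls$sex == cases$sex[i] &
        abs(controls$age - cases$age[i]) <= age_window
      if (!is.null(eligible)) ok <- ok & eligible[, phase[i]]
      cand <- which(ok)
      if (length(cand) == 0L) {
        unmatched <- c(unmatched, as.character(cases$id[i]))
        next
      }
      j <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      used[j] <- TRUE
      rows[[i]] <- data.frame(case_id = cases$id[i],
                              control_id = controls$id[j],
                              phase = phase[i],
                              age_case = cases$age[i],
                              age_control = controls$age[j],
                              sex = cases$sex[i],
                              stringsAsFactors = FALSE)
    }
    if (length(unmatched) > 0L) {
      warning(length(unmatched), " case(s) had no eligible control",
              call. = FALSE)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) {
      out <- data.frame(case_id = character(), control_id = character(),
                        phase = integer(), age_case = numeric(),
                        age_control = numeric(), sex = character())
    }
    attr(out, "unmatched") <- unmatched
    class(out) <- c("matched_pairs", "data.frame")
    out
  })
}

#' Rank-based quartiles with whole tie blocks
#'
#' Cuts a score into quartiles at the ordered 25/50/75% positions; all
#' subjects sharing a cutpoint value are kept together in the lower
#' quartile (relevant for a discrete 0-8 score, where ties are pervasive).
#' Permutation-invariant: the quartile multiset depends only on the value
#' multiset. If fewer distinct values than cutpoints exist, quartiles
#' collapse with a warning.
#'
#' @param x numeric scores (length at least 4).
#' @return integer vector of quartile labels in 1..4, with attributes
#'   `cutpoints` (the three upper-boundary values) and `means` (mean score
#'   per occupied quartile).
#' @export
assign_quartiles <- function(x) {
  if (length(x) < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (anyNA(x)) stop("missing scores", call. = FALSE)
  s <- sort(x)
  n <- length(x)
  cuts <- s[ceiling((1:3) * n / 4)]
  if (anyDuplicated(cuts)) {
    warning("fewer distinct values than cutpoints: quartiles collapsed",
            call. = FALSE)
  }
  q <- 1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
  means <- tapply(x, q, mean)
  attr(q, "cutpoints") <- cuts
  attr(q, "means") <- means
  q
}

#' Cross MDS quartile with a binary genotype factor
#'
#' Builds the 8-level design factor: 4 MDS quartiles crossed with a binary
#' genotype group (minor-allele carrier / high GRS). The reference (first)
#' level is the lowest quartile in the non-carrier (low) group by default;
#' `reference = "highest"` puts Q4 non-carriers first instead.
#'
#' @param quartile integer 1..4 vector.
#' @param carrier 0/1 vector (carrier or high-GRS flag).
#' @param labels length-2 labels for the genotype groups, low/high order.
#' @param reference `"lowest"` (default) or `"highest"` quartile as the
#'   reference.
#' @return factor with 8 levels `"Q<k>:<label>"`, reference level first.
#' @export
build_groups <- function(quartile, carrier, labels = c("noncarrier",
                                                       "carrier"),
                         reference = c("lowest", "highest")) {
  reference <- match.arg(reference)
  stopifnot(length(quartile) == length(carrier),
            all(quartile %in% 1:4), all(carrier %in% 0:1))
  qlev <- if (reference == "lowest") 1:4 else 4:1
  levels <- c(paste0("Q", qlev, ":", labels[1]),
              paste0("Q", qlev, ":", labels[2]))
  factor(paste0("Q", quartile, ":", labels[carrier + 1L]), levels = levels)
}
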
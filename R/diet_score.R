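## Mediterranean diet score (MDS) construction from component-level daily
## intakes: energy-density adjustment (g per 1000 kcal), sex-specific median
## cutoffs, and the 8-component 0-8 adherence score.

#' Raw intake columns expected in a diet profile table
#'
#' @format Character vector of the eight food-component column names
#'   (grams/day) used by [energy_adjust()].
#' @export
DIET_COMPONENTS <- c("vegetables_g", "legumes_g", "fruits_g", "nuts_g",
                     "cereals_g", "fish_g", "meat_poultry_g", "dairy_g")

#' Energy-density adjustment of food-component intakes
#'
#' Converts raw daily intakes (grams/day) into grams per 1000 kcal of total
#' energy, and computes the MUFA:SFA ratio (which is invariant to energy
#' adjustment). Records with non-positive energy or negative intakes cannot
#' be adjusted and are dropped; they are returned in the `"rejected"`
#' attribute with a diagnostic reason. A zero SFA intake makes the ratio
#' undefined in the arithmetic sense; it is carried as `Inf` (the limiting
#' value as SFA tends to zero) and flagged in `ratio_undefined`.
#'
#' @param diet data.frame with columns `subject_id`, the eight components in
#'   [DIET_COMPONENTS] (grams/day), `mufa_g`, `sfa_g` (grams/day) and
#'   `energy_kcal` (kcal/day).
#' @return data.frame with `subject_id`, one column per component in grams
#'   per 1000 kcal (same names without the `_g` suffix), `mufa_sfa_ratio`
#'   and logical `ratio_undefined`. Attribute `"rejected"` holds a
#'   data.frame of dropped records (`subject_id`, `reason`).
#' @export
#' @examples
#' d <- data.frame(subject_id = 1, vegetables_g = 300, legumes_g = 40,
#'                 fruits_g = 200, nuts_g = 10, cereals_g = 350, fish_g = 25,
#'                 meat_poultry_g = 80, dairy_g = 200, mufa_g = 21,
#'                 sfa_g = 20, energy_kcal = 2000)
#' energy_adjust(d)$vegetables  # 150 g / 1000 kcal
energy_adjust <- function(diet) {
  stop_if_not_df(diet, c("subject_id", DIET_COMPONENTS, "mufa_g", "sfa_g",
                         "energy_kcal"), "diet")
  bad_energy <- !is.finite(diet$energy_kcal) | diet$energy_kcal <= 0
  intake_cols <- c(DIET_COMPONENTS, "mufa_g", "sfa_g")
  bad_intake <- Reduce(`|`, lapply(intake_cols, function(cl) {
    v <- diet[[cl]]
    !is.finite(v) | v < 0
  }))
  bad <- bad_energy | bad_intake
  rejected <- data.frame(
    subject_id = diet$subject_id[bad],
    reason = ifelse(bad_energy[bad], "non-positive or missing energy",
                    "negative or missing intake"),
    stringsAsFactors = FALSE)
  if (nrow(rejected) > 0L) {
    warning(nrow(rejected), " record(s) rejected during energy adjustment",
            call. = FALSE)
  }
  keep <- diet[!bad, , drop = FALSE]
  out <- data.frame(subject_id = keep$subject_id)
  for (cl in DIET_COMPONENTS) {
    out[[sub("_g$", "", cl)]] <- keep[[cl]] * 1000 / keep$energy_kcal
  }
  undefined <- keep$sfa_g == 0
  ratio <- ifelse(undefined, Inf, keep$mufa_g / keep$sfa_g)
  out$mufa_sfa_ratio <- ratio
  out$ratio_undefined <- undefined
  attr(out, "rejected") <- rejected
  out
}

## Scored component names in the fixed order used throughout the package.
mds_component_names <- function(combine_fruits_nuts = TRUE) {
  if (combine_fruits_nuts) {
    c("vegetables", "legumes", "fruits_nuts", "cereals", "fish",
      "meat_poultry", "dairy", "mufa_sfa")
  } else {
    c("vegetables", "legumes", "fruits", "nuts", "cereals", "fish",
      "meat_poultry", "dairy", "mufa_sfa")
  }
}

mds_desirable <- function(combine_fruits_nuts = TRUE) {
  if (combine_fruits_nuts) {
    c("vegetables", "legumes", "fruits_nuts", "cereals", "fish")
  } else {
    c("vegetables", "legumes", "fruits", "nuts", "cereals", "fish")
  }
}

MDS_UNDESIRABLE <- c("meat_poultry", "dairy")

## Matrix of scored-component values (adjusted g/1000 kcal; ratio units for
## mufa_sfa) in the canonical column order.
mds_component_matrix <- function(adjusted, combine_fruits_nuts = TRUE) {
  comps <- mds_component_names(combine_fruits_nuts)
  m <- matrix(NA_real_, nrow(adjusted), length(comps),
              dimnames = list(NULL, comps))
  for (cl in setdiff(comps, c("fruits_nuts", "mufa_sfa"))) {
    m[, cl] <- adjusted[[cl]]
  }
  if (combine_fruits_nuts) m[, "fruits_nuts"] <- adjusted$fruits + adjusted$nuts
  m[, "mufa_sfa"] <- adjusted$mufa_sfa_ratio
  m
}

#' Sex-specific component medians for MDS cutoffs
#'
#' Computes, for each scored component and each sex stratum, the sample
#' median of the energy-adjusted intake (ratio units for MUFA:SFA). These
#' medians are the cutoffs of [score_mds()]. Even-sized strata use the
#' standard sample median (midpoint of the two central order statistics).
#' Medians are intended to be computed on the pooled analysis sample.
#'
#' @param adjusted output of [energy_adjust()].
#' @param sex character/factor vector, one label per row of `adjusted`.
#' @param combine_fruits_nuts combine fruits and nuts into a single
#'   desirable component (the default, giving 8 scored components), or keep
#'   them separate (9 components).
#' @return data.frame with columns `component`, `sex`, `cutoff`.
#' @export
compute_medians <- function(adjusted, sex, combine_fruits_nuts = TRUE) {
  if (length(sex) != nrow(adjusted)) {
    stop("`sex` must have one entry per row of `adjusted`", call. = FALSE)
  }
  sex <- as.character(sex)
  strata <- sort(unique(sex))
  sizes <- table(sex)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    stop("sex stratum with fewer than 2 subjects: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  m <- mds_component_matrix(adjusted, combine_fruits_nuts)
  rows <- lapply(strata, function(s) {
    data.frame(component = colnames(m), sex = s,
               cutoff = apply(m[sex == s, , drop = FALSE], 2, stats::median),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Score the Mediterranean diet score against median cutoffs
#'
#' Assigns one point per component relative to the sex-specific median:
#' desirable components (vegetables, legumes, fruits+nuts, cereals, fish)
#' score 1 when intake is at or above the median; undesirable components
#' (meat & poultry, dairy) score 1 when intake is below the median (at or
#' above scores 0); the MUFA:SFA ratio scores 1 only when strictly greater
#' than the median. The total ranges from 0 (no adherence) to the number of
#' components (8 by default; maximal adherence). Alcohol is not a component.
#' An undefined (infinite) ratio exceeds any finite cutoff and scores 1; a
#' message reports how many subjects this concerned.
#'
#' @inheritParams compute_medians
#' @param medians median table from [compute_medians()] (must cover every
#'   component for each subject's sex).
#' @return data.frame with `subject_id`, one `pt_<component>` 0/1 column per
#'   component, and the integer total `mds`.
#' @export
score_mds <- function(adjusted, medians, sex, combine_fruits_nuts = TRUE) {
  stop_if_not_df(medians, c("component", "sex", "cutoff"), "medians")
  sex <- as.character(sex)
  comps <- mds_component_names(combine_fruits_nuts)
  m <- mds_component_matrix(adjusted, combine_fruits_nuts)
  cut <- matrix(NA_real_, nrow(adjusted), length(comps),
                dimnames = list(NULL, comps))
  for (s in unique(sex)) {
    sub <- medians[medians$sex == s, , drop = FALSE]
    missing <- setdiff(comps, sub$component)
    if (length(missing) > 0L) {
      stop("median table lacks component(s) for sex '", s, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    cut[sex == s, ] <- matrix(sub$cutoff[match(comps, sub$component)],
                              nrow = sum(sex == s), ncol = length(comps),
                              byrow = TRUE)
  }
  pts <- matrix(0L, nrow(adjusted), length(comps),
                dimnames = list(NULL, comps))
  for (cl in mds_desirable(combine_fruits_nuts)) {
    pts[, cl] <- as.integer(m[, cl] >= cut[, cl])
  }
  for (cl in MDS_UNDESIRABLE) {
    pts[, cl] <- as.integer(m[, cl] < cut[, cl])
  }
  pts[, "mufa_sfa"] <- as.integer(m[, "mufa_sfa"] > cut[, "mufa_sfa"])
  n_undef <- sum(is.infinite(m[, "mufa_sfa"]))
  if (n_undef > 0L) {
    message(n_undef, " subject(s) with undefined MUFA:SFA ratio scored 1 ",
            "(limiting value)")
  }
  out <- data.frame(subject_id = adjusted$subject_id)
  for (cl in comps) out[[paste0("pt_", cl)]] <- pts[, cl]
  out$mds <- as.integer(rowSums(pts))
  out
}

#' One-call Mediterranean diet scoring
#'
#' Convenience wrapper: energy-adjusts a diet profile table, computes pooled
#' sex-specific medians, and scores every subject.
#'
#' @inheritParams energy_adjust
#' @inheritParams compute_medians
#' @return list with `scores` (see [score_mds()]), `medians`, `adjusted`.
#' @export
mediterranean_diet_score <- function(diet, sex, combine_fruits_nuts = TRUE) {
  if (length(sex) != nrow(diet)) {
    stop("`sex` must have one entry per row of `diet`", call. = FALSE)
  }
  adjusted <- energy_adjust(diet)
  keep <- match(adjusted$subject_id, diet$subject_id)
  sex_kept <- sex[keep]
  medians <- compute_medians(adjusted, sex_kept, combine_fruits_nuts)
  scores <- score_mds(adjusted, medians, sex_kept, combine_fruits_nuts)
  list(scores = scores, medians = medians, adjusted = adjusted)
}
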
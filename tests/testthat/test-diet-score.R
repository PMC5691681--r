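test_that("energy adjustment is exact arithmetic and rejects bad records", {
  d <- random_diet_profiles(3, seed = 11)
  d$vegetables_g <- c(300, 0, 150)
  d$energy_kcal <- c(2000, 1500, 3000)
  adj <- energy_adjust(d)
  expect_equal(adj$vegetables, c(150, 0, 50))
  ## MUFA:SFA ratio does not depend on energy
  d2 <- d; d2$energy_kcal <- d$energy_kcal * 7
  expect_equal(energy_adjust(d2)$mufa_sfa_ratio, adj$mufa_sfa_ratio)
  d$mufa_g <- 21; d$sfa_g <- 20
  expect_equal(energy_adjust(d)$mufa_sfa_ratio, rep(1.05, 3))

  bad <- random_diet_profiles(4, seed = 12)
  bad$energy_kcal[2] <- 0
  bad$fish_g[4] <- -1
  expect_warning(adj <- energy_adjust(bad), "rejected")
  expect_equal(adj$subject_id, c(1, 3))
  rej <- attr(adj, "rejected")
  expect_setequal(rej$subject_id, c(2, 4))
  expect_match(rej$reason[rej$subject_id == 2], "energy")

  zs <- random_diet_profiles(2, seed = 13)
  zs$sfa_g[1] <- 0
  adj <- energy_adjust(zs)
  expect_true(adj$ratio_undefined[1] && is.infinite(adj$mufa_sfa_ratio[1]))
})

test_that("sex-specific medians match a sort-based order-statistic oracle", {
  d <- random_diet_profiles(1000, seed = 21)
  sex <- rep(c("male", "female"), 500)
  adj <- energy_adjust(d)
  med <- compute_medians(adj, sex)
  sort_median <- function(v) {
    s <- sort(v); m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  for (s in c("male", "female")) {
    expect_equal(
      med$cutoff[med$sex == s & med$component == "vegetables"],
      sort_median(adj$vegetables[sex == s]))
    expect_equal(
      med$cutoff[med$sex == s & med$component == "fruits_nuts"],
      sort_median(adj$fruits[sex == s] + adj$nuts[sex == s]))
    expect_equal(
      med$cutoff[med$sex == s & med$component == "mufa_sfa"],
      sort_median(adj$mufa_sfa_ratio[sex == s]))
  }
  expect_error(compute_medians(adj[1, , drop = FALSE], "male"),
               "fewer than 2")
})

## Hand-built median table: every cutoff 1, subject values controlled.
flat_median_table <- function(sex = "female", combine = TRUE) {
  data.frame(component = dietGxE:::mds_component_names(combine), sex = sex,
             cutoff = 1)
}

adjusted_row <- function(desirable, undesirable, ratio) {
  data.frame(subject_id = 1, vegetables = desirable, legumes = desirable,
             fruits = desirable / 2, nuts = desirable / 2,
             cereals = desirable, fish = desirable,
             meat_poultry = undesirable, dairy = undesirable,
             mufa_sfa_ratio = ratio, ratio_undefined = FALSE)
}

test_that("score boundaries: maximal adherence 8, no adherence 0", {
  med <- flat_median_table()
  hi <- score_mds(adjusted_row(2, 0.5, 2), med, "female")
  expect_identical(hi$mds, 8L)
  lo <- score_mds(adjusted_row(0.5, 2, 0.5), med, "female")
  expect_identical(lo$mds, 0L)
})

test_that("tie rules at the median: desirable score, undesirable and ratio do not", {
  at_median <- adjusted_row(1, 1, 1)
  sc <- score_mds(at_median, flat_median_table(), "female")
  ## 5 desirable components at the median each score; meat/dairy at the
  ## median score 0; ratio needs strictly greater
  expect_identical(sc$mds, 5L)
  expect_equal(sc$pt_meat_poultry + sc$pt_dairy + sc$pt_mufa_sfa, 0L)
  ## with fruits and nuts as separate at-median components, the six
  ## desirable components all score: total 6
  at_median9 <- at_median
  at_median9$fruits <- 1; at_median9$nuts <- 1
  sc9 <- score_mds(at_median9, flat_median_table(combine = FALSE), "female",
                   combine_fruits_nuts = FALSE)
  expect_identical(sc9$mds, 6L)
})

test_that("undefined MUFA:SFA ratio takes its limiting value and scores 1", {
  row <- adjusted_row(0.5, 2, Inf)
  row$ratio_undefined <- TRUE
  expect_message(sc <- score_mds(row, flat_median_table(), "female"),
                 "undefined")
  expect_identical(sc$pt_mufa_sfa, 1L)
})

test_that("scoring is invariant to a common scaling of intakes and energy", {
  d <- random_diet_profiles(200, seed = 31)
  sex <- sample(c("male", "female"), 200, replace = TRUE)
  base <- mediterranean_diet_score(d, sex)
  for (k in c(0.25, 3.7)) {
    ds <- d
    cols <- setdiff(names(d), "subject_id")
    ds[cols] <- d[cols] * k
    scaled <- mediterranean_diet_score(ds, sex)
    expect_equal(scaled$scores$mds, base$scores$mds)
    expect_equal(scaled$adjusted$vegetables, base$adjusted$vegetables)
  }
})

test_that("raising a desirable intake never lowers a subject's score, and conversely for meat", {
  d <- random_diet_profiles(60, seed = 32)
  sex <- rep(c("male", "female"), 30)
  base <- mediterranean_diet_score(d, sex)$scores$mds
  for (i in c(3, 17, 44)) {
    up <- d; up$vegetables_g[i] <- up$vegetables_g[i] * 2
    expect_gte(mediterranean_diet_score(up, sex)$scores$mds[i], base[i])
    meat <- d; meat$meat_poultry_g[i] <- meat$meat_poultry_g[i] * 2
    expect_lte(mediterranean_diet_score(meat, sex)$scores$mds[i], base[i])
  }
})

test_that("with continuous tie-free intakes each point splits a stratum near half", {
  d <- random_diet_profiles(401, seed = 33)
  sex <- rep("female", 401)   # single stratum, odd n
  res <- mediterranean_diet_score(d, sex)
  pts <- res$scores[, grep("^pt_", names(res$scores))]
  for (cl in names(pts)) {
    expect_true(sum(pts[[cl]]) %in% c(200L, 201L), label = cl)
  }
})

test_that("package scorer agrees exactly with the straight-line oracle on 200 profiles", {
  d <- random_diet_profiles(200, seed = 34)
  sex <- sample(c("male", "female"), 200, replace = TRUE)
  got <- mediterranean_diet_score(d, sex)$scores$mds
  expect_identical(got, oracle_mds(d, sex))
})
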
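## Fixtures and independent oracles shared across test files. Oracles are
## deliberately straight-line implementations, kept separate from the
## package code paths they check.

random_diet_profiles <- function(n, seed) {
  withr::local_seed(seed)
  data.frame(
    subject_id = seq_len(n),
    vegetables_g = rlnorm(n, log(280), 0.5),
    legumes_g = rlnorm(n, log(35), 0.6),
    fruits_g = rlnorm(n, log(250), 0.5),
    nuts_g = rlnorm(n, log(12), 0.8),
    cereals_g = rlnorm(n, log(420), 0.4),
    fish_g = rlnorm(n, log(18), 0.9),
    meat_poultry_g = rlnorm(n, log(70), 0.5),
    dairy_g = rlnorm(n, log(280), 0.5),
    mufa_g = rlnorm(n, log(25), 0.3),
    sfa_g = rlnorm(n, log(24), 0.3),
    energy_kcal = rlnorm(n, log(2400), 0.35))
}

## Independent straight-line re-scorer of the 8-component diet score:
## energy adjustment, pooled sex-specific medians by explicit sorting, and
## the at/above vs strictly-above tie rules applied literally.
oracle_mds <- function(diet, sex) {
  n <- nrow(diet)
  adj <- function(col) diet[[col]] * 1000 / diet$energy_kcal
  vals <- list(
    vegetables = adj("vegetables_g"),
    legumes = adj("legumes_g"),
    fruits_nuts = adj("fruits_g") + adj("nuts_g"),
    cereals = adj("cereals_g"),
    fish = adj("fish_g"),
    meat_poultry = adj("meat_poultry_g"),
    dairy = adj("dairy_g"),
    mufa_sfa = diet$mufa_g / diet$sfa_g)
  sort_median <- function(v) {
    s <- sort(v); m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  total <- integer(n)
  for (i in seq_len(n)) {
    pts <- 0L
    for (comp in names(vals)) {
      med <- sort_median(vals[[comp]][sex == sex[i]])
      v <- vals[[comp]][i]
      pts <- pts + switch(comp,
        meat_poultry = , dairy = as.integer(v < med),
        mufa_sfa = as.integer(v > med),
        as.integer(v >= med))
    }
    total[i] <- pts
  }
  total
}

## Minimal VCF v4.2 text for the six-SNP FTO panel, 4 subjects, including
## one missing genotype and one half-call.
write_fixture_vcf <- function(path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3\tS4")
  ## REF = major, ALT = risk (minor) allele for each panel SNP
  body <- c(
    "16\t53809247\trs1121980\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t0/1",
    "16\t53800954\trs1421085\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "16\t53800568\trs9939973\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/1\t1/1",
    "16\t53816275\trs8050136\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0\t0/1",
    "16\t53813367\trs17817449\tT\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t0/1\t./1",
    "16\t53818460\trs3751812\tG\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t1/1\t0/0")
  writeLines(c(header, body), path)
  path
}

expected_vcf_dosages <- function() {
  m <- rbind(S1 = c(1, 0, 1, 2, 0, 1),
             S2 = c(2, 1, 0, 1, 1, 1),
             S3 = c(0, 2, 1, 0, 1, 2),
             S4 = c(1, NA, 2, 1, NA, 0))
  colnames(m) <- c("rs1121980", "rs1421085", "rs9939973", "rs8050136",
                   "rs17817449", "rs3751812")
  m
}
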
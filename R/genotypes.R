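## Genotype coding, allele/genotype frequency tables, Hardy-Weinberg
## testing, and the weighted genetic risk score (GRS).

#' SNP panel metadata
#'
#' Builds the per-SNP metadata table used by the dosage readers and
#' [weighted_grs()]: the risk (trait-increasing) allele, the other allele,
#' and a positive literature odds-ratio weight per SNP.
#'
#' @param snp_id character rsIDs.
#' @param risk_allele,other_allele single-base alleles; must differ per SNP.
#' @param weight_or positive odds-ratio weights.
#' @return data.frame of class `snp_panel` with attribute `sum_weights`.
#' @export
snp_panel <- function(snp_id, risk_allele, other_allele, weight_or) {
  n <- length(snp_id)
  stopifnot(length(risk_allele) == n, length(other_allele) == n,
            length(weight_or) == n)
  if (anyDuplicated(snp_id)) stop("duplicated snp_id", call. = FALSE)
  if (any(risk_allele == other_allele)) {
    stop("risk_allele must differ from other_allele", call. = FALSE)
  }
  if (any(!is.finite(weight_or) | weight_or <= 0)) {
    stop("weight_or must be positive", call. = FALSE)
  }
  out <- data.frame(snp_id = as.character(snp_id),
                    risk_allele = as.character(risk_allele),
                    other_allele = as.character(other_allele),
                    weight_or = as.numeric(weight_or),
                    stringsAsFactors = FALSE)
  attr(out, "sum_weights") <- sum(out$weight_or)
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Default six-SNP FTO panel
#'
#' The six FTO intron-1 polymorphisms commonly genotyped in obesity studies,
#' with the minor (BMI-increasing) allele as the risk allele. Published
#' per-SNP effect odds ratios are rarely reported alongside their sum; the
#' default assigns equal weights that preserve a weight sum of 8.18 over the
#' six SNPs (so the normalised GRS keeps its 0-12 range and each GRS point
#' corresponds to one risk allele). Supply `weights` to use study-specific
#' per-SNP odds ratios.
#'
#' @param weights optional numeric vector of six per-SNP odds ratios.
#' @return A [snp_panel()].
#' @export
fto_panel <- function(weights = NULL) {
  ids <- c("rs1121980", "rs1421085", "rs9939973",
           "rs8050136", "rs17817449", "rs3751812")
  risk <- c("A", "C", "A", "A", "G", "T")
  other <- c("G", "T", "G", "G", "T", "G")
  if (is.null(weights)) weights <- rep(8.18 / 6, 6)
  snp_panel(ids, risk, other, weights)
}

#' Allele counts and frequencies from genotype counts
#'
#' Tallies allele counts from the three genotype counts of a biallelic SNP:
#' the minor-allele count is twice the minor-homozygote count plus the
#' heterozygote count (and symmetrically for the major allele). Percentages
#' are reported both raw and rounded to integers for frequency-table output.
#' Vectorised over SNPs.
#'
#' @param hom_major,het,hom_minor non-negative integer genotype counts.
#' @return data.frame with `n` (genotyped subjects), `minor_count`,
#'   `major_count`, `minor_pct`, `major_pct` (raw percentages) and rounded
#'   `minor_pct_int`, `major_pct_int`.
#' @export
#' @examples
#' allele_counts(238, 279, 92)  # minor allele count 463
allele_counts <- function(hom_major, het, hom_minor) {
  counts <- cbind(hom_major, het, hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- hom_major + het + hom_minor
  if (any(n == 0)) stop("all-zero genotype counts", call. = FALSE)
  minor <- 2 * hom_minor + het
  major <- 2 * hom_major + het
  data.frame(n = n,
             minor_count = minor, major_count = major,
             minor_pct = 100 * minor / (2 * n),
             major_pct = 100 * major / (2 * n),
             minor_pct_int = round(100 * minor / (2 * n)),
             major_pct_int = round(100 * major / (2 * n)))
}

#' Hardy-Weinberg equilibrium test (Pearson chi-square)
#'
#' Pearson's chi-square goodness-of-fit of observed genotype counts against
#' the Hardy-Weinberg expectation n*(p^2, 2pq, q^2) at the estimated allele
#' frequencies, on 1 degree of freedom, without continuity correction. A
#' monomorphic SNP fits its (degenerate) expectation exactly: chi-square 0
#' with a warning.
#'
#' @inheritParams allele_counts
#' @return list of class `hwe_test`: `chi2`, `df` (1), `p_value`, observed
#'   and expected counts.
#' @export
#' @examples
#' hwe_test(25, 50, 25)$chi2   # 0: exact HWE proportions
#' hwe_test(10, 10, 10)$chi2   # 10/3
hwe_test <- function(hom_major, het, hom_minor) {
  stopifnot(length(hom_major) == 1, length(het) == 1, length(hom_minor) == 1)
  obs <- c(hom_major = hom_major, het = het, hom_minor = hom_minor)
  n <- sum(obs)
  if (n < 1) stop("no genotyped subjects", call. = FALSE)
  p <- (2 * hom_major + het) / (2 * n)  # major-allele frequency
  q <- 1 - p
  if (p == 0 || q == 0) {
    warning("monomorphic SNP: chi-square is 0 by construction", call. = FALSE)
    out <- list(chi2 = 0, df = 1L, p_value = 1,
                observed = obs, expected = obs)
    class(out) <- "hwe_test"
    return(out)
  }
  expd <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((obs - expd)^2 / expd)
  out <- list(chi2 = chi2, df = 1L,
              p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
              observed = obs, expected = expd)
  class(out) <- "hwe_test"
  out
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Hardy-Weinberg equilibrium (Pearson chi-square, 1 df)\n")
  cat(sprintf("  chi2 = %.4f, p = %.4g\n", x$chi2, x$p_value))
  invisible(x)
}

check_dosages <- function(dosages) {
  v <- as.vector(dosages)
  ok <- is.na(v) | v %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("dosages must be 0, 1, 2 or missing; found: ",
         paste(unique(v[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(dosages)
}

#' Weighted genetic risk score
#'
#' For risk-allele dosages g_1..g_n and per-SNP odds-ratio weights w_1..w_n,
#' the score is
#' \deqn{GRS = (w_1 g_1 + \dots + w_n g_n) \times n / (w_1 + \dots + w_n),}
#' so it ranges from 0 to 2n (0 to 12 for a six-SNP panel) and each point
#' corresponds to one risk allele. Subjects with any missing dosage get
#' `NA` (complete-case policy; no imputation).
#'
#' @param dosages numeric matrix or data.frame, subjects x SNPs, entries in
#'   \{0, 1, 2, NA\}; columns must match `panel$snp_id` (reordered by name
#'   when column names are present).
#' @param panel a [snp_panel()].
#' @return numeric vector of scores, named by rownames of `dosages` if set.
#' @export
weighted_grs <- function(dosages, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(panel)) {
    stop("dosage matrix has ", ncol(dosages), " columns; panel has ",
         nrow(panel), " SNPs", call. = FALSE)
  }
  if (!is.null(colnames(dosages))) {
    if (!setequal(colnames(dosages), panel$snp_id)) {
      stop("dosage columns do not match panel snp_id", call. = FALSE)
    }
    dosages <- dosages[, panel$snp_id, drop = FALSE]
  }
  check_dosages(dosages)
  w <- panel$weight_or
  raw <- dosages %*% w
  grs <- as.vector(raw) * nrow(panel) / sum(w)
  names(grs) <- rownames(dosages)
  grs
}

#' Split genetic risk scores at the sample median
#'
#' Flags subjects at or above the sample median GRS as high-GRS. The
#' threshold (median, midpoint convention for even n) is attached as an
#' attribute and reported.
#'
#' @param grs numeric vector (NAs allowed; flagged NA).
#' @return integer vector of 0/1 flags with attribute `threshold`.
#' @export
dichotomize_grs <- function(grs) {
  if (all(is.na(grs))) stop("no non-missing GRS values", call. = FALSE)
  thr <- stats::median(grs, na.rm = TRUE)
  flags <- as.integer(grs >= thr)
  attr(flags, "threshold") <- thr
  flags
}

#' Dominant (carrier) coding of a risk-allele dosage
#'
#' Collapses dosages to carrier (at least one risk allele) versus
#' non-carrier. Missing stays missing.
#'
#' @param dosage numeric vector with entries in \{0, 1, 2, NA\}.
#' @return integer 0/1 vector.
#' @export
dominant_code <- function(dosage) {
  check_dosages(dosage)
  as.integer(dosage >= 1)
}

#' Genotype and allele frequency table by group
#'
#' Builds a frequency table in the style of case-control genetics reports:
#' per SNP and group, the three genotype counts (in risk-allele dosage
#' order), allele counts and percentages, and the Hardy-Weinberg chi-square
#' p-value. With risk allele = minor allele, dosage 2 is the minor
#' homozygote.
#'
#' @param dosages subjects x SNPs matrix of risk-allele dosages.
#' @param group optional grouping vector (e.g. case/control); `NULL` pools.
#' @param panel a [snp_panel()] naming the SNPs/alleles.
#' @return data.frame, one row per SNP x group.
#' @export
genotype_frequencies <- function(dosages, group = NULL, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  dosages <- as.matrix(dosages)
  check_dosages(dosages)
  if (is.null(group)) group <- rep("all", nrow(dosages))
  rows <- list()
  for (g in unique(group)) {
    sub <- dosages[group == g, , drop = FALSE]
    for (j in seq_len(nrow(panel))) {
      d <- sub[, j]
      d <- d[!is.na(d)]
      cnt <- c(sum(d == 0), sum(d == 1), sum(d == 2))
      ac <- allele_counts(cnt[1], cnt[2], cnt[3])
      hw <- suppressWarnings(hwe_test(cnt[1], cnt[2], cnt[3]))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = panel$snp_id[j], group = g,
        risk_allele = panel$risk_allele[j],
        other_allele = panel$other_allele[j],
        n = ac$n, hom_other = cnt[1], het = cnt[2], hom_risk = cnt[3],
        risk_allele_count = ac$minor_count,
        other_allele_count = ac$major_count,
        risk_allele_pct = ac$minor_pct,
        hwe_chi2 = hw$chi2, hwe_p = hw$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a TSV dosage matrix
#'
#' Reads a tab-separated file with one row per subject, a `subject_id`
#' column, and one column of risk-allele dosages (0/1/2, `NA` allowed) per
#' rsID.
#'
#' @param path file path.
#' @param panel optional [snp_panel()]; when given, columns are checked and
#'   reordered to match.
#' @return numeric matrix with subject ids as rownames.
#' @export
read_dosage_tsv <- function(path, panel = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(tab)) {
    stop("dosage TSV needs a subject_id column", call. = FALSE)
  }
  m <- as.matrix(tab[, setdiff(names(tab), "subject_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(tab$subject_id)
  check_dosages(m)
  if (!is.null(panel)) {
    if (!setequal(colnames(m), panel$snp_id)) {
      stop("dosage TSV columns do not match panel snp_id", call. = FALSE)
    }
    m <- m[, panel$snp_id, drop = FALSE]
  }
  m
}

#' Read risk-allele dosages from a VCF
#'
#' Extracts GT fields from a VCF (via the vcfR reader) and counts the
#' configured risk allele among the two called alleles at each panel SNP.
#' Only biallelic diploid records are accepted; half-calls and missing
#' genotypes give `NA`. Sites are matched to the panel by ID, and the risk
#' allele must be the REF or ALT base of the record.
#'
#' @param path VCF file path.
#' @param panel a [snp_panel()].
#' @return numeric matrix, subjects x panel SNPs.
#' @export
read_vcf_dosages <- function(path, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  idx <- match(panel$snp_id, fix[, "ID"])
  if (anyNA(idx)) {
    stop("VCF lacks panel SNP(s): ",
         paste(panel$snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  n_sub <- ncol(gt)
  out <- matrix(NA_real_, n_sub, nrow(panel),
                dimnames = list(colnames(gt), panel$snp_id))
  for (j in seq_len(nrow(panel))) {
    i <- idx[j]
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    if (grepl(",", alt)) {
      stop("multi-allelic record at ", panel$snp_id[j], call. = FALSE)
    }
    alleles <- c(ref, alt)
    risk_code <- match(panel$risk_allele[j], alleles) - 1L
    if (is.na(risk_code)) {
      stop("risk allele ", panel$risk_allele[j], " is neither REF nor ALT at ",
           panel$snp_id[j], call. = FALSE)
    }
    calls <- strsplit(gt[i, ], "[/|]")
    out[, j] <- vapply(calls, function(a) {
      if (length(a) != 2L || any(a == ".") || anyNA(a)) return(NA_real_)
      sum(as.integer(a) == risk_code)
    }, numeric(1))
  }
  out
}
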
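## Likelihood machinery: conditional logistic regression for 1:1 matched
## pairs (Newton-Raphson on within-pair covariate differences),
## unconditional logistic regression (IRLS), likelihood-ratio interaction
## tests, quartile-median trend tests, and OR reporting.
##
## For a 1:1 matched pair with case covariates x1 and control covariates
## x0, the conditional likelihood contribution is
##     exp(d'b) / (1 + exp(d'b)),  d = x1 - x0,
## i.e. a logistic likelihood on the pair differences with outcome fixed at
## 1 and no intercept. Concordant pairs (d = 0) carry no information.

new_fit <- function(beta, cov, loglik, n_obs, converged, iterations,
                    model_label, subclass) {
  out <- list(beta = beta, cov = cov, loglik = loglik, n_obs = n_obs,
              converged = converged, iterations = iterations,
              model_label = model_label)
  class(out) <- c(subclass, "gxe_fit")
  out
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(x$model_label, if (!x$converged) "(NOT converged)", "\n")
  cat(sprintf("  n = %d, loglik = %.4f, iterations = %d\n",
              x$n_obs, x$loglik, x$iterations))
  se <- sqrt(diag(x$cov))
  print(round(cbind(beta = x$beta, se = se, or = exp(x$beta)), 4))
  invisible(x)
}

#' Case-minus-control covariate differences for matched pairs
#'
#' Aligns a subject-level data.frame to a matched-pair table and returns
#' the case-minus-control difference matrix for the named covariates — the
#' design matrix of [clogit_fit()].
#'
#' @param pairs a [match_pairs()] result (or any data.frame with `case_id`,
#'   `control_id`).
#' @param data subject-level data.frame with an `id` column and the
#'   covariates in `terms`.
#' @param terms character vector of covariate column names.
#' @return numeric matrix, one row per pair, columns `terms`.
#' @export
pair_differences <- function(pairs, data, terms) {
  stop_if_not_df(pairs, c("case_id", "control_id"), "pairs")
  stop_if_not_df(data, c("id", terms), "data")
  i_case <- match(pairs$case_id, data$id)
  i_ctrl <- match(pairs$control_id, data$id)
  if (anyNA(i_case) || anyNA(i_ctrl)) {
    stop("pair member(s) missing from `data`", call. = FALSE)
  }
  m <- sapply(terms, function(cl) {
    as.numeric(data[[cl]][i_case]) - as.numeric(data[[cl]][i_ctrl])
  })
  m <- matrix(m, nrow = nrow(pairs), dimnames = list(NULL, terms))
  if (anyNA(m)) stop("missing covariate values in fitted columns",
                     call. = FALSE)
  m
}

## Shared Newton-Raphson driver. loglik_fn(beta) must return
## list(loglik, score, info). Converges on max|score| < score_tol or
## Newton step norm < step_tol; halves the step while the log-likelihood
## decreases.
newton_fit <- function(loglik_fn, p, max_iter, score_tol, step_tol) {
  beta <- rep(0, p)
  cur <- loglik_fn(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (max(abs(cur$score)) < score_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$score), error = function(e) {
      stop("singular information matrix (rank-deficient or separated design)",
           call. = FALSE)
    })
    if (sqrt(sum(step^2)) < step_tol) { converged <- TRUE; break }
    new_beta <- beta + step
    new <- loglik_fn(new_beta)
    halvings <- 0L
    while (new$loglik < cur$loglik - 1e-12 && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new <- loglik_fn(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    cur <- new
  }
  if (!converged && max(abs(cur$score)) < score_tol) converged <- TRUE
  list(beta = beta, fit = cur, converged = converged, iterations = iter)
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximises the exact 1:1 conditional likelihood over case-minus-control
#' difference vectors by Newton-Raphson, with standard errors from the
#' inverse observed information. Convergence is declared when the maximum
#' absolute score falls below `score_tol` (default 1e-8) or the Newton step
#' is below `step_tol`; at most `max_iter` iterations. A covariate whose
#' nonzero differences all share one sign separates the conditional
#' likelihood: the maximum lies at infinity, and the fit is returned with
#' `converged = FALSE` and a warning.
#'
#' @param diffs numeric matrix of pair differences (rows = pairs, named
#'   columns = covariates), e.g. from [pair_differences()].
#' @param max_iter,score_tol,step_tol convergence control.
#' @param model_label label stored on the fit.
#' @return object of class `c("clogit_fit", "gxe_fit")`: `beta`, `cov`,
#'   `loglik`, `n_obs`, `converged`, `iterations`, `model_label`.
#' @export
clogit_fit <- function(diffs, max_iter = 50L, score_tol = 1e-8,
                       step_tol = 1e-10, model_label = "conditional logistic") {
  diffs <- as.matrix(diffs)
  if (is.null(colnames(diffs))) {
    colnames(diffs) <- paste0("x", seq_len(ncol(diffs)))
  }
  if (anyNA(diffs)) stop("missing entries in difference matrix",
                         call. = FALSE)
  separated <- apply(diffs, 2, function(d) {
    nz <- d[d != 0]
    length(nz) > 0L && (all(nz > 0) || all(nz < 0))
  })
  no_discord <- apply(diffs, 2, function(d) all(d == 0))
  if (any(no_discord)) {
    stop("column(s) with no discordant pairs: ",
         paste(colnames(diffs)[no_discord], collapse = ", "), call. = FALSE)
  }
  ll_fn <- function(beta) {
    eta <- drop(diffs %*% beta)
    p <- stats::plogis(eta)
    list(loglik = sum(eta - log1pexp(eta)),
         score = drop(crossprod(diffs, 1 - p)),
         info = crossprod(diffs * (p * (1 - p)), diffs))
  }
  res <- newton_fit(ll_fn, ncol(diffs), max_iter, score_tol, step_tol)
  if (any(separated)) {
    warning("separation in column(s): ",
            paste(colnames(diffs)[separated], collapse = ", "),
            "; estimate diverges", call. = FALSE)
    res$converged <- FALSE
  }
  beta <- stats::setNames(res$beta, colnames(diffs))
  cov <- solve(res$fit$info)
  dimnames(cov) <- list(colnames(diffs), colnames(diffs))
  new_fit(beta, cov, res$fit$loglik, nrow(diffs), res$converged,
          res$iterations, model_label, "clogit_fit")
}

#' Unconditional logistic regression by iteratively reweighted least squares
#'
#' Standard maximum-likelihood logistic fit with an intercept, under the
#' same convergence contract as [clogit_fit()]. The design must be full
#' rank; complete separation is flagged with `converged = FALSE`.
#'
#' @param x numeric covariate matrix (no intercept column; one is added
#'   unless `intercept = FALSE`).
#' @param y binary 0/1 outcome vector.
#' @param intercept include an intercept. Default TRUE.
#' @inheritParams clogit_fit
#' @return object of class `c("logit_fit", "gxe_fit")`.
#' @export
logit_fit <- function(x, y, intercept = TRUE, max_iter = 50L,
                      score_tol = 1e-8, step_tol = 1e-10,
                      model_label = "logistic") {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0L) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (intercept) x <- cbind(`(Intercept)` = 1, x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (anyNA(x)) stop("missing entries in design matrix", call. = FALSE)
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient",
                                 call. = FALSE)
  ll_fn <- function(beta) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    list(loglik = sum(y * eta - log1pexp(eta)),
         score = drop(crossprod(x, y - p)),
         info = crossprod(x * (p * (1 - p)), x))
  }
  res <- newton_fit(ll_fn, ncol(x), max_iter, score_tol, step_tol)
  if (!res$converged || max(abs(res$beta)) > 15) {
    if (max(abs(res$beta)) > 15) {
      warning("possible separation: coefficient diverging", call. = FALSE)
      res$converged <- FALSE
    }
  }
  beta <- stats::setNames(res$beta, colnames(x))
  cov <- solve(res$fit$info)
  dimnames(cov) <- list(colnames(x), colnames(x))
  new_fit(beta, cov, res$fit$loglik, nrow(x), res$converged,
          res$iterations, model_label, "logit_fit")
}

#' Likelihood-ratio test between nested fits
#'
#' Twice the log-likelihood difference between a full and a reduced model
#' fitted to the same observations, referred to a chi-square distribution.
#' The standard test for a gene-diet interaction: full model with the
#' product term(s), reduced model without.
#'
#' @param full,reduced fits from [clogit_fit()] or [logit_fit()]; `reduced`
#'   must be nested in `full`.
#' @param df degrees of freedom; defaults to the difference in parameter
#'   count.
#' @return list of class `lrt`: `lr_chi2`, `df`, `p_value`.
#' @export
lrt_interaction <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "gxe_fit"), inherits(reduced, "gxe_fit"))
  if (full$n_obs != reduced$n_obs) {
    stop("full and reduced models use different observations", call. = FALSE)
  }
  if (is.null(df)) df <- length(full$beta) - length(reduced$beta)
  if (df < 1L && length(full$beta) != length(reduced$beta)) {
    stop("reduced model has more parameters than full", call. = FALSE)
  }
  delta <- full$loglik - reduced$loglik
  if (delta < -1e-6) {
    stop("full model log-likelihood below reduced: convergence failure",
         call. = FALSE)
  }
  chi2 <- max(0, 2 * delta)
  df <- max(df, 1L)
  out <- list(lr_chi2 = chi2, df = df,
              p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE))
  class(out) <- "lrt"
  out
}

#' @export
print.lrt <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.4f on %d df, p = %.4g\n",
              x$lr_chi2, x$df, x$p_value))
  invisible(x)
}

#' Median score of each quartile, as a continuous trend variable
#'
#' Replaces the quartile label by the median score within that quartile —
#' the standard continuous coding for a test of trend across quartiles.
#'
#' @param score numeric score vector (e.g. MDS totals).
#' @param quartile integer quartile labels aligned with `score`.
#' @return numeric vector: the within-quartile median score per subject.
#' @export
quartile_median_score <- function(score, quartile) {
  stopifnot(length(score) == length(quartile))
  med <- tapply(score, quartile, stats::median)
  as.numeric(med[as.character(quartile)])
}

#' Wald trend test on a fitted slope
#'
#' Wald z-test of a single coefficient — used for the p-for-trend on the
#' quartile-median continuous covariate.
#'
#' @param fit a [clogit_fit()] or [logit_fit()] result.
#' @param term coefficient name.
#' @return list: `slope`, `se`, `z`, `p_value`.
#' @export
trend_test <- function(fit, term) {
  stopifnot(inherits(fit, "gxe_fit"))
  if (!term %in% names(fit$beta)) {
    stop("term '", term, "' not in fit", call. = FALSE)
  }
  slope <- fit$beta[[term]]
  se <- sqrt(fit$cov[term, term])
  z <- slope / se
  list(slope = slope, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Odds ratios with Wald confidence intervals
#'
#' OR = exp(beta) with 95% limits exp(beta +/- 1.96 se) and Wald p-values.
#'
#' @param fit a converged [clogit_fit()] or [logit_fit()].
#' @param terms coefficient names to report (default: all).
#' @param z critical value for the interval. Default 1.96 (95%).
#' @return data.frame: `term`, `beta`, `se`, `or`, `ci_lo`, `ci_hi`,
#'   `p_value`.
#' @export
or_report <- function(fit, terms = NULL, z = 1.96) {
  stopifnot(inherits(fit, "gxe_fit"))
  if (is.null(terms)) terms <- names(fit$beta)
  stopifnot(all(terms %in% names(fit$beta)))
  beta <- fit$beta[terms]
  se <- sqrt(diag(fit$cov)[terms])
  data.frame(term = terms, beta = as.numeric(beta), se = as.numeric(se),
             or = exp(as.numeric(beta)),
             ci_lo = exp(as.numeric(beta) - z * as.numeric(se)),
             ci_hi = exp(as.numeric(beta) + z * as.numeric(se)),
             p_value = 2 * stats::pnorm(-abs(as.numeric(beta) /
                                               as.numeric(se))),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Case-control descriptive comparison
#'
#' Means (SD) with Student's t-test for continuous variables and
#' percentages with a Pearson chi-square test (no continuity correction)
#' for categorical variables, compared between two groups.
#'
#' @param data subject-level data.frame.
#' @param group binary grouping vector (e.g. case/control), two levels.
#' @param continuous,categorical character vectors of column names.
#' @return data.frame: one row per continuous variable or per level of each
#'   categorical variable, with per-group summaries and the test p-value.
#' @export
cohort_descriptives <- function(data, group, continuous = character(),
                                categorical = character()) {
  stop_if_not_df(data, c(continuous, categorical), "data")
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("`group` must have two levels",
                                 call. = FALSE)
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  rows <- list()
  for (v in continuous) {
    a <- data[[v]][group == g1]; b <- data[[v]][group == g2]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) 1
         else stats::t.test(a, b, var.equal = TRUE)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA_character_, type = "continuous",
      stat_1 = mean(a), sd_1 = stats::sd(a),
      stat_2 = mean(b), sd_2 = stats::sd(b),
      p_value = p, test = "t", stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- as.factor(data[[v]])
    tab <- table(x, group)
    p <- if (all(prop.table(tab, 2)[, 1] == prop.table(tab, 2)[, 2])) 1
         else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    for (lev in levels(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, type = "categorical",
        stat_1 = 100 * mean(x[group == g1] == lev), sd_1 = NA_real_,
        stat_2 = 100 * mean(x[group == g2] == lev), sd_2 = NA_real_,
        p_value = p, test = "chi-square", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
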
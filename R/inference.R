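#' Two-way ANCOVA on regional fALFF z-scores
#'
#' Ordinary least squares of the regional mean z-score on blood-pressure
#' group, brain region, their interaction, and the age, BMI and sex
#' covariates, with Type-II sums of squares by default (each term tested
#' against the model that drops it while respecting marginality, so main
#' effects are adjusted for each other but not for the interaction).
#' Participant-by-region rows are treated as independent observations --
#' the design the statistic is defined on, kept deliberately even though
#' regional values within a participant are correlated.
#'
#' Partial eta-squared for a term is `SS_term / (SS_term + SS_residual)`.
#'
#' @param data Data.frame with columns `mean_z`, `group`, `region`, `age`,
#'   `bmi`, `sex` -- typically a [regional_means()] table joined with the
#'   participant table (see [join_regional()]).
#' @param ss_type `"II"` (default) or `"I"` (sequential `stats::anova`).
#' @return An object of class `falff_ancova`: list with the underlying
#'   `lm` fit (`model`) and a per-term `table` (term, df1, df2, ss, F, p,
#'   partial_eta2).
#' @export
fit_ancova <- function(data, ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  need <- c("mean_z", "group", "region", "age", "bmi", "sex")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- data.frame(
    mean_z = data$mean_z,
    group = factor(data$group),
    region = factor(data$region),
    age = data$age, bmi = data$bmi,
    sex = as.integer(data$sex == "male")
  )
  if (anyNA(data$mean_z)) data <- data[!is.na(data$mean_z), , drop = FALSE]
  model <- stats::lm(mean_z ~ group + region + age + bmi + sex + group:region,
                     data = data)
  if (model$rank < ncol(stats::model.matrix(model))) {
    al <- stats::alias(model)$Complete
    stop("rank-deficient ANCOVA design; aliased column(s): ",
         paste(rownames(al), collapse = ", "))
  }
  at <- if (ss_type == "II") {
    tryCatch(
      car::Anova(model, type = 2),
      error = function(e) type2_table_degenerate(model, data)
    )
  } else {
    stats::anova(model)
  }
  terms <- rownames(at)
  resid_row <- which(terms == "Residuals")
  ss_res <- at[resid_row, "Sum Sq"]
  df_res <- at[resid_row, "Df"]
  keep <- setdiff(seq_len(nrow(at)), resid_row)
  tab <- data.frame(
    term = terms[keep],
    df1 = at[keep, "Df"],
    df2 = df_res,
    ss = at[keep, "Sum Sq"],
    F = at[keep, "F value"],
    p = at[keep, "Pr(>F)"],
    stringsAsFactors = FALSE
  )
  tab$partial_eta2 <- mapply(partial_eta_squared, tab$ss, ss_res)
  structure(
    list(model = model, table = tab, ss_residual = ss_res, df_residual = df_res,
         ss_type = ss_type, n_obs = nrow(data)),
    class = "falff_ancova"
  )
}

#' @export
print.falff_ancova <- function(x, ...) {
  cat(sprintf("Two-way ANCOVA (%d observations, Type-%s SS)\n", x$n_obs, x$ss_type))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-14s F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.4g\n",
                r$term, r$df1, r$df2, r$F, r$p, r$partial_eta2))
  }
  invisible(x)
}

#' @export
summary.falff_ancova <- function(object, ...) {
  print(object)
  invisible(object$table)
}

#' @export
coef.falff_ancova <- function(object, ...) stats::coef(object$model)

#' @export
residuals.falff_ancova <- function(object, ...) stats::residuals(object$model)

# Type-II table by explicit nested-model comparison, used when the
# standard route refuses a (near-)perfect fit: each term's SS is the RSS
# drop from adding it to the model of all terms that do not contain it.
type2_table_degenerate <- function(model, data) {
  tl <- attr(stats::terms(model), "term.labels")
  rss_of <- function(terms_in) {
    f <- stats::reformulate(if (length(terms_in)) terms_in else "1",
                            response = "mean_z")
    fit <- stats::lm(f, data = data)
    c(sum(stats::residuals(fit)^2), fit$df.residual)
  }
  contains <- function(a, b) all(strsplit(a, ":")[[1]] %in% strsplit(b, ":")[[1]])
  ss_res <- sum(stats::residuals(model)^2)
  df_res <- model$df.residual
  rows <- lapply(tl, function(term) {
    others <- tl[!vapply(tl, function(o) contains(term, o), logical(1))]
    with_t <- rss_of(c(others, term))
    without_t <- rss_of(others)
    ss <- max(without_t[1] - with_t[1], 0)
    df <- without_t[2] - with_t[2]
    ms_res <- ss_res / df_res
    f <- if (ms_res > 0) (ss / df) / ms_res else if (ss > 0) Inf else NaN
    p <- if (is.nan(f)) NA_real_ else stats::pf(f, df, df_res, lower.tail = FALSE)
    data.frame(`Sum Sq` = ss, Df = df, `F value` = f, `Pr(>F)` = p,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(`Sum Sq` = ss_res, Df = df_res,
                               `F value` = NA_real_, `Pr(>F)` = NA_real_,
                               check.names = FALSE))
  rownames(out) <- c(tl, "Residuals")
  out
}

#' Partial eta-squared effect size
#'
#' `ss_term / (ss_term + ss_residual)`: the proportion of the variance not
#' explained by the other terms that is attributable to this term.
#'
#' @param ss_term Sum of squares of the term, `>= 0`.
#' @param ss_residual Residual sum of squares, `>= 0`; not both zero.
#' @return Value in `[0, 1]`.
#' @examples
#' partial_eta_squared(1, 3) # 0.25
#' @export
partial_eta_squared <- function(ss_term, ss_residual) {
  if (ss_term < 0 || ss_residual < 0) stop("sums of squares must be nonnegative")
  if (ss_term == 0 && ss_residual == 0) stop("both sums of squares are zero")
  ss_term / (ss_term + ss_residual)
}

#' Bonferroni-corrected significance level
#'
#' Dividing the family-wise level by the number of tests controls the
#' family-wise error rate; three parallel ANCOVAs at family level 0.05
#' give a per-test threshold of 0.0167.
#'
#' @param family_alpha Family-wise significance level in `(0, 1)`.
#' @param m_tests Number of tests, `>= 1`.
#' @return Per-test significance level `family_alpha / m_tests`.
#' @examples
#' bonferroni_alpha(0.05, 3) # 0.0167
#' @export
bonferroni_alpha <- function(family_alpha, m_tests) {
  if (family_alpha <= 0 || family_alpha >= 1) stop("'family_alpha' must be in (0, 1)")
  if (m_tests < 1) stop("'m_tests' must be at least 1")
  family_alpha / m_tests
}

#' Power query for an F test
#'
#' Bundles the inputs of a fixed-effects F-test power calculation in the
#' G*Power convention: Cohen's f, numerator degrees of freedom, the
#' significance level, the target power and the degrees of freedom spent
#' on other model terms.
#'
#' @param effect_size_f Cohen's f, `> 0`.
#' @param df1 Numerator degrees of freedom of the tested term.
#' @param alpha Significance level in `(0, 1)`.
#' @param target_power Desired power in `(0, 1)` (used by [required_n()]).
#' @param n_covariates Continuous covariates in the model (each costs one
#'   denominator df).
#' @param df_other Degrees of freedom of other factor terms in the model
#'   (e.g. the two main effects when the tested term is the interaction).
#' @return An object of class `power_query`.
#' @export
power_query <- function(effect_size_f, df1, alpha = 0.05, target_power = 0.8,
                        n_covariates = 0, df_other = 0) {
  if (effect_size_f <= 0) stop("'effect_size_f' must be positive")
  if (df1 < 1) stop("'df1' must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (target_power <= 0 || target_power >= 1) stop("'target_power' must be in (0, 1)")
  structure(
    list(effect_size_f = effect_size_f, df1 = df1, alpha = alpha,
         target_power = target_power, n_covariates = n_covariates,
         df_other = df_other),
    class = "power_query"
  )
}

#' Power of a fixed-effects F test
#'
#' Noncentral-F power: with total sample size `n`, noncentrality
#' `lambda = f^2 * n` and denominator degrees of freedom
#' `df2 = n - df1 - df_other - n_covariates - 1` (one df for the
#' intercept, one per covariate, plus the other factor terms), the power
#' is `P(F' > F_crit(alpha, df1, df2))` under the noncentral F with
#' `lambda`.
#'
#' @param query A [power_query()].
#' @param n_total Total number of observations.
#' @return Power in `(0, 1)`.
#' @export
power_f_test <- function(query, n_total) {
  stopifnot(inherits(query, "power_query"))
  df2 <- n_total - query$df1 - query$df_other - query$n_covariates - 1
  if (df2 <= 0) {
    stop("infeasible sample size: denominator df = ", df2, " at n = ", n_total)
  }
  lambda <- query$effect_size_f^2 * n_total
  fc <- stats::qf(1 - query$alpha, query$df1, df2)
  stats::pf(fc, query$df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Required sample size for target power
#'
#' Smallest integer `n` whose [power_f_test()] power reaches the query's
#' target, found by doubling the bracket then bisecting (power is
#' monotone increasing in `n`).
#'
#' @param query A [power_query()].
#' @param n_max Search cap; exceeding it raises an error.
#' @return Integer sample size.
#' @export
required_n <- function(query, n_max = 1e7) {
  stopifnot(inherits(query, "power_query"))
  lo <- query$df1 + query$df_other + query$n_covariates + 2
  if (power_f_test(query, lo) >= query$target_power) return(as.integer(lo))
  hi <- lo
  repeat {
    hi <- hi * 2
    if (hi > n_max) {
      stop("required sample size exceeds the search cap ", n_max)
    }
    if (power_f_test(query, hi) >= query$target_power) break
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_f_test(query, mid) >= query$target_power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
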
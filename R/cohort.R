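# Participant tables are plain data.frames with columns:
#   id, group ("hypertensive"/"normotensive"), age (years), sex
#   ("male"/"female"), bmi (kg/m^2), systolic, diastolic (mmHg);
# fit_propensity() adds `propensity`, match_cohort() adds `matched` and
# `pair`. Sex enters the propensity model coded male = 1, female = 0.

check_participants <- function(table) {
  need <- c("id", "group", "age", "sex", "bmi")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) {
    stop("participant table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(table$id)) stop("participant ids must be unique")
  if (!all(table$group %in% c("hypertensive", "normotensive"))) {
    stop("group must be 'hypertensive' or 'normotensive'")
  }
  if (!all(table$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (any(!is.finite(table$age)) || any(!is.finite(table$bmi))) {
    stop("age and bmi must be complete")
  }
  if (any(table$age <= 0) || any(table$bmi <= 0)) {
    stop("age and bmi must be positive")
  }
  invisible(table)
}

#' Fit the propensity-score model
#'
#' Logistic regression of hypertension status on age, sex and BMI
#' (intercept included), fitted by maximum likelihood. The fitted
#' probability of being hypertensive given the confounders is the
#' propensity score; matching on it balances the confounder distributions
#' between groups.
#'
#' @param table Participant data.frame (see [simulate_cohort()] for the
#'   column contract).
#' @return The table with a `propensity` column in `(0, 1)`.
#' @export
fit_propensity <- function(table) {
  check_participants(table)
  if (length(unique(table$group)) < 2L) stop("both groups must be nonempty")
  dat <- data.frame(
    y = as.integer(table$group == "hypertensive"),
    age = table$age,
    sex_male = as.integer(table$sex == "male"),
    bmi = table$bmi
  )
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ age + sex_male + bmi, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  p <- stats::fitted(fit)
  if (sep || any(p < 1e-10) || any(p > 1 - 1e-10)) {
    stop("propensity model is (quasi-)separated: fitted probabilities of 0/1; ",
         "coefficients: ",
         paste(sprintf("%s=%.3g", names(stats::coef(fit)), stats::coef(fit)),
               collapse = ", "))
  }
  table$propensity <- unname(p)
  attr(table, "propensity_model") <- fit
  table
}

#' Greedy 1:1 propensity-score matching
#'
#' Nearest-neighbour matching without replacement on the logit of the
#' propensity score. Treated (hypertensive) units are processed in
#' descending propensity order, ties broken by id; each is paired with the
#' closest remaining normotensive donor. If a caliper is given (as a
#' multiple of the standard deviation of the logit propensity over all
#' units), treated units whose nearest donor lies beyond it stay unmatched.
#' Exhausting the donor pool leaves remaining treated unmatched with a
#' warning, not an error -- a design can legitimately end up with fewer
#' matched controls than treated.
#'
#' @param table Output of [fit_propensity()].
#' @param caliper Optional positive number: maximal |logit distance| in
#'   units of sd(logit propensity). Default `NULL`, no caliper.
#' @return The table with logical `matched` and integer `pair` columns
#'   (`pair` is `NA` for unmatched rows).
#' @export
match_cohort <- function(table, caliper = NULL) {
  if (is.null(table$propensity)) stop("run fit_propensity() first")
  lp <- stats::qlogis(table$propensity)
  max_d <- Inf
  if (!is.null(caliper)) {
    if (caliper <= 0) stop("'caliper' must be positive")
    max_d <- caliper * stats::sd(lp)
  }
  trt <- which(table$group == "hypertensive")
  ctl <- which(table$group == "normotensive")
  # descending propensity, id as deterministic tie-break
  trt <- trt[order(-table$propensity[trt], table$id[trt])]
  ctl <- ctl[order(table$id[ctl])]
  avail <- rep(TRUE, length(ctl))
  pair <- rep(NA_integer_, nrow(table))
  k <- 0L
  for (i in trt) {
    if (!any(avail)) break
    cand <- ctl[avail]
    d <- abs(lp[cand] - lp[i])
    j <- cand[which.min(d)]   # which.min takes the first minimum: id tie-break
    if (min(d) > max_d) next
    k <- k + 1L
    pair[i] <- k
    pair[j] <- k
    avail[match(j, ctl)] <- FALSE
  }
  n_un <- sum(is.na(pair[table$group == "hypertensive"]))
  if (n_un > 0L) {
    warning(n_un, " treated unit(s) left unmatched (donor pool exhausted or caliper)")
  }
  table$matched <- !is.na(pair)
  table$pair <- pair
  table
}

# standardized mean difference with the usual matching denominator
# sqrt((s1^2 + s2^2)/2); for a binary covariate the group variances are
# p(1-p).
smd <- function(x1, x2, binary = FALSE) {
  m1 <- mean(x1); m2 <- mean(x2)
  if (binary) {
    s2 <- (m1 * (1 - m1) + m2 * (1 - m2)) / 2
  } else {
    s2 <- (stats::var(x1) + stats::var(x2)) / 2
  }
  if (s2 <= 0) return(0)
  (m1 - m2) / sqrt(s2)
}

#' Covariate balance diagnostics
#'
#' Baseline-characteristics table comparing the two groups: Welch
#' two-sample t-tests for age, BMI and blood pressure, Pearson chi-square
#' (without continuity correction, so the statistic equals the textbook
#' contingency formula) for the sex proportion, and standardised mean
#' differences with the `sqrt((s1^2+s2^2)/2)` pooling used in the matching
#' literature. After successful matching on age, sex and BMI these
#' covariates should be balanced while the group-defining blood pressure
#' stays different.
#'
#' @param table Participant data.frame; if a `matched` column is present
#'   only matched rows are used.
#' @return A data.frame of class `balance_table` with one row per
#'   covariate: group means (or proportions) and sds, test statistic,
#'   p-value, SMD.
#' @export
balance_table <- function(table) {
  if (!is.null(table$matched)) table <- table[table$matched, , drop = FALSE]
  g1 <- table[table$group == "hypertensive", , drop = FALSE]
  g2 <- table[table$group == "normotensive", , drop = FALSE]
  if (nrow(g1) == 0L || nrow(g2) == 0L) {
    stop("balance table needs matched participants in both groups")
  }
  cont <- intersect(c("age", "bmi", "systolic", "diastolic"), names(table))
  rows <- lapply(cont, function(v) {
    x1 <- g1[[v]]; x2 <- g2[[v]]
    tt <- stats::t.test(x1, x2)   # Welch by default
    data.frame(
      covariate = v,
      hypertensive_mean = mean(x1), hypertensive_sd = stats::sd(x1),
      normotensive_mean = mean(x2), normotensive_sd = stats::sd(x2),
      statistic = unname(tt$statistic), test = "welch_t",
      p_value = tt$p.value,
      smd = smd(x1, x2),
      stringsAsFactors = FALSE
    )
  })
  x1 <- as.integer(g1$sex == "male")
  x2 <- as.integer(g2$sex == "male")
  tab <- rbind(c(sum(x1), sum(1 - x1)), c(sum(x2), sum(1 - x2)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  rows[[length(rows) + 1L]] <- data.frame(
    covariate = "sex_male",
    hypertensive_mean = mean(x1), hypertensive_sd = NA_real_,
    normotensive_mean = mean(x2), normotensive_sd = NA_real_,
    statistic = unname(ct$statistic), test = "chi_square",
    p_value = ct$p.value,
    smd = smd(x1, x2, binary = TRUE),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  attr(out, "n_hypertensive") <- nrow(g1)
  attr(out, "n_normotensive") <- nrow(g2)
  class(out) <- c("balance_table", "data.frame")
  out
}

#' @export
print.balance_table <- function(x, digits = 3, ...) {
  cat(sprintf("Baseline characteristics: hypertensive (%d) vs normotensive (%d)\n",
              attr(x, "n_hypertensive"), attr(x, "n_normotensive")))
  for (i in seq_len(nrow(x))) {
    if (x$test[i] == "chi_square") {
      cat(sprintf("  %-10s %.2f vs %.2f   chi-square p = %.3g, SMD = %.3f\n",
                  x$covariate[i], x$hypertensive_mean[i], x$normotensive_mean[i],
                  x$p_value[i], x$smd[i]))
    } else {
      cat(sprintf("  %-10s %.1f ± %.1f vs %.1f ± %.1f   p = %.3g, SMD = %.3f\n",
                  x$covariate[i],
                  x$hypertensive_mean[i], x$hypertensive_sd[i],
                  x$normotensive_mean[i], x$normotensive_sd[i],
                  x$p_value[i], x$smd[i]))
    }
  }
  invisible(x)
}
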
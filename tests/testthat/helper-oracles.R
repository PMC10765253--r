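# Independent oracles, deliberately naive: direct summation, two-pass
# statistics, Newton-Raphson from scratch. They never call the code paths
# they check.

# one-sided periodogram by direct DFT summation, |X_k|^2 / n on bins
# k = 1 .. floor(n/2)
dft_power_oracle <- function(x) {
  n <- length(x)
  h <- n %/% 2
  sapply(seq_len(h), function(k) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    (re^2 + im^2) / n
  })
}

# least-squares line fit via explicit normal equations
linear_fit_oracle <- function(y) {
  t <- seq_along(y)
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.vector(X %*% beta)
}

# two-pass mean / sample sd
two_pass_stats <- function(x) {
  m <- mean(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# logistic regression by hand-rolled Newton-Raphson (IRLS)
irls_logistic_oracle <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# greedy 1:1 nearest-neighbour matching, treated processed in the given
# order, controls supplied in id-sorted order (first minimum wins ties);
# returns control index per treated (NA if none)
greedy_match_oracle <- function(lp_treated, lp_control) {
  used <- rep(FALSE, length(lp_control))
  out <- rep(NA_integer_, length(lp_treated))
  for (i in seq_along(lp_treated)) {
    cand <- which(!used)
    if (length(cand) == 0) break
    d <- abs(lp_control[cand] - lp_treated[i])
    j <- cand[which.min(d)]
    out[i] <- j
    used[j] <- TRUE
  }
  out
}

# Pearson chi-square statistic for a 2x2 table from the contingency formula
chisq_2x2_oracle <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# Type-II sum of squares by explicit model comparison: term adjusted for
# every other term that does not contain it.
type2_ss_oracle <- function(data, term) {
  rss <- function(f) sum(stats::residuals(stats::lm(f, data = data))^2)
  full_terms <- c("group", "region", "age", "bmi", "sex", "group:region")
  contains <- function(a, b) {
    all(strsplit(a, ":")[[1]] %in% strsplit(b, ":")[[1]])
  }
  others <- full_terms[!vapply(full_terms, function(o) contains(term, o), logical(1))]
  f_with <- stats::reformulate(c(others, term), response = "mean_z")
  f_without <- stats::reformulate(others, response = "mean_z")
  rss(f_without) - rss(f_with)
}

# noncentral-F tail probability by raw simulation from normal and
# chi-square building blocks
power_sim_oracle <- function(f, df1, df2, n_total, alpha, n_rep, seed) {
  set.seed(seed)
  lambda <- f^2 * n_total
  num <- (stats::rchisq(n_rep, df1 - 1) +
            (stats::rnorm(n_rep) + sqrt(lambda))^2) / df1
  den <- stats::rchisq(n_rep, df2) / df2
  fc <- stats::qf(1 - alpha, df1, df2)
  mean(num / den > fc)
}
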
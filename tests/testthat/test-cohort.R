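test_that("identical covariates give intercept-only propensities", {
  set.seed(21)
  n <- 40
  tab <- data.frame(
    id = sprintf("x%02d", 1:n),
    group = rep(c("hypertensive", "normotensive"), c(15, 25)),
    age = rep(55, n), sex = rep("male", n), bmi = rep(27, n),
    stringsAsFactors = FALSE
  )
  out <- fit_propensity(tab)
  expect_lt(max(abs(out$propensity - 15 / 40)), 1e-6)
})

test_that("propensity coefficients match a hand-rolled IRLS fit", {
  tab <- data.frame(
    id = sprintf("w%d", 1:8),
    group = c("hypertensive", "hypertensive", "hypertensive", "hypertensive",
              "normotensive", "normotensive", "normotensive", "normotensive"),
    age = c(49, 60, 57, 62, 58, 65, 49, 54),
    sex = c("female", "male", "female", "male",
            "female", "female", "male", "male"),
    bmi = c(21.5, 28.9, 28.8, 27.7, 24.1, 27.6, 31.3, 24.4),
    stringsAsFactors = FALSE
  )
  out <- fit_propensity(tab)
  X <- cbind(1, tab$age, as.integer(tab$sex == "male"), tab$bmi)
  beta <- irls_logistic_oracle(X, as.integer(tab$group == "hypertensive"))
  got <- unname(coef(attr(out, "propensity_model")))
  expect_lt(max(abs(got - beta)), 1e-6)
})

test_that("propensity is monotone in a positively weighted covariate", {
  set.seed(22)
  tab <- confounded_cohort(60, 60, seed = 22)
  out <- fit_propensity(tab)
  b_age <- coef(attr(out, "propensity_model"))["age"]
  expect_gt(b_age, 0)   # treated are older by design
  t2 <- tab; t2$age[1] <- t2$age[1] + 10
  out2 <- fit_propensity(t2)
  expect_gt(out2$propensity[1], out$propensity[1])
})

test_that("perfect separation is a diagnosed error", {
  tab <- data.frame(
    id = sprintf("s%d", 1:10),
    group = rep(c("hypertensive", "normotensive"), each = 5),
    age = c(70:74, 40:44), sex = rep("male", 10), bmi = rep(27, 10),
    stringsAsFactors = FALSE
  )
  expect_error(fit_propensity(tab), "separat")
})

test_that("nearest neighbours pair up as expected in a tiny example", {
  tab <- data.frame(
    id = c("t1", "t2", "c1", "c2"),
    group = c("hypertensive", "hypertensive", "normotensive", "normotensive"),
    age = 1:4, sex = rep("male", 4), bmi = rep(27, 4),
    propensity = c(0.6, 0.7, 0.61, 0.69),
    stringsAsFactors = FALSE
  )
  out <- match_cohort(tab)
  expect_true(all(out$matched))
  # highest-propensity treated goes first: 0.7 <-> 0.69, then 0.6 <-> 0.61
  expect_equal(out$pair[out$id == "t2"], out$pair[out$id == "c2"])
  expect_equal(out$pair[out$id == "t1"], out$pair[out$id == "c1"])
})

test_that("ties are broken deterministically by id", {
  tab <- data.frame(
    id = c("t2", "t1", "c2", "c1", "c3"),
    group = c("hypertensive", "hypertensive",
              "normotensive", "normotensive", "normotensive"),
    age = rep(50, 5), sex = rep("male", 5), bmi = rep(27, 5),
    propensity = rep(0.4, 5),
    stringsAsFactors = FALSE
  )
  out1 <- match_cohort(tab)
  out2 <- match_cohort(tab[c(2, 1, 5, 3, 4), ])
  expect_true(all(out1$matched[out1$group == "hypertensive"]))
  # t1 processed before t2 (id order at equal propensity), c1 is its donor
  expect_equal(out1$pair[out1$id == "t1"], out1$pair[out1$id == "c1"])
  m1 <- with(out1[order(out1$id), ], paste(id, pair))
  m2 <- with(out2[order(out2$id), ], paste(id, pair))
  expect_identical(m1, m2)
})

test_that("matching equals the brute-force greedy oracle and improves balance", {
  tab <- fit_propensity(confounded_cohort(25, 25, seed = 23))
  out <- match_cohort(tab)

  lp <- qlogis(tab$propensity)
  trt <- which(tab$group == "hypertensive")
  ctl <- which(tab$group == "normotensive")
  trt <- trt[order(-tab$propensity[trt], tab$id[trt])]
  ctl <- ctl[order(tab$id[ctl])]
  oracle <- greedy_match_oracle(lp[trt], lp[ctl])
  for (k in seq_along(trt)) {
    if (is.na(oracle[k])) next
    expect_equal(out$pair[trt[k]], out$pair[ctl[oracle[k]]])
  }

  # post-match SMD shrinks for every matched-on covariate
  pre <- balance_table(tab[, setdiff(names(tab), "matched")])
  post <- balance_table(out)
  for (v in c("age", "bmi", "sex_male")) {
    expect_lte(abs(post$smd[post$covariate == v]),
               abs(pre$smd[pre$covariate == v]) + 1e-12)
  }
})

test_that("matching invariants hold: cross-group pairs, donors used once", {
  out <- match_cohort(fit_propensity(confounded_cohort(30, 40, seed = 24)))
  pairs <- split(out$group[!is.na(out$pair)], out$pair[!is.na(out$pair)])
  expect_true(all(vapply(pairs, function(g) {
    length(g) == 2 && setequal(g, c("hypertensive", "normotensive"))
  }, logical(1))))
  ctl_used <- out$pair[out$group == "normotensive" & !is.na(out$pair)]
  expect_false(anyDuplicated(ctl_used) > 0)
})

test_that("a small donor pool leaves treated unmatched with a warning", {
  tab <- fit_propensity(confounded_cohort(20, 12, seed = 25))
  expect_warning(out <- match_cohort(tab), "unmatched")
  expect_equal(sum(out$matched[out$group == "hypertensive"]), 12L)
  expect_true(all(out$matched[out$group == "normotensive"]))
})

test_that("a tight caliper drops distant pairs", {
  tab <- fit_propensity(confounded_cohort(20, 20, seed = 26))
  free <- match_cohort(tab)
  strict <- suppressWarnings(match_cohort(tab, caliper = 0.05))
  expect_lte(sum(strict$matched), sum(free$matched))
})

test_that("identical groups are perfectly balanced", {
  both <- confounded_cohort(15, 15, seed = 27)
  half <- both[both$group == "hypertensive", ]
  twin <- half
  twin$id <- sub("H", "N", twin$id)
  twin$group <- "normotensive"
  tab <- rbind(half, twin)
  b <- balance_table(tab)
  expect_true(all(abs(b$smd) < 1e-12))
  expect_true(all(b$p_value[b$test == "welch_t"] > 1 - 1e-8))
})

test_that("the sex chi-square equals the contingency-table formula", {
  tab <- confounded_cohort(40, 40, seed = 28)
  b <- balance_table(tab)
  m <- rbind(
    table(factor(tab$sex[tab$group == "hypertensive"], c("male", "female"))),
    table(factor(tab$sex[tab$group == "normotensive"], c("male", "female")))
  )
  expect_equal(b$statistic[b$covariate == "sex_male"], chisq_2x2_oracle(m),
               tolerance = 1e-12)
})
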
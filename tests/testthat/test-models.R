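test_that("cohens_f_from_F reproduces the standard conversions", {
  expect_equal(cohens_f_from_F(8.37, 1, 77), 0.33, tolerance = 0.005)
  expect_lt(abs(cohens_f_from_F(4.71, 1, 78) - 0.25), 0.005)
  expect_equal(cohens_f_from_F(0, 1, 50), 0)
  expect_error(cohens_f_from_F(3, 0, 50), "freedom")
  expect_error(cohens_f_from_F(-1, 1, 50), "non-negative")
})

test_that("cohens_f agrees with the classical one-way ANOVA formula", {
  set.seed(606)
  g <- factor(rep(c("a", "b"), each = 30))
  y <- rnorm(60) + 0.8 * (g == "b")
  a <- anova(lm(y ~ g))
  f_from_F <- cohens_f_from_F(a$`F value`[1], a$Df[1], a$Df[2])
  # between/within variance ratio: f = sqrt(SS_b / SS_w)
  expect_equal(f_from_F, sqrt(a$`Sum Sq`[1] / a$`Sum Sq`[2]),
               tolerance = 1e-9)
})

test_that("roc_youden matches hand examples and handles reversal", {
  r <- roc_youden(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  perf <- roc_youden(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$youden, 1)
  rev <- roc_youden(-c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(rev$auc, 1 - r$auc)
  expect_error(roc_youden(c(1, 2), c(1, 1)), "2 values")
  expect_error(roc_youden(c(1, 2), c(1, 1), positive = 1),
               "both classes")
})

test_that("roc_youden AUC equals pairwise concordance for n <= 12", {
  set.seed(808)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(1:6, n, replace = TRUE)  # many ties
    expect_equal(roc_youden(s, y)$auc, auc_enum(s, y),
                 label = paste("case", i))
  }
})

test_that("roc_youden agrees with pROC and maximises Youden's J", {
  skip_if_not_installed("pROC")
  set.seed(909)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60, mean = y)
  r <- roc_youden(s, y)
  pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  best <- pROC::coords(pr, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(r$sensitivity + r$specificity,
               max(best$sensitivity + best$specificity),
               tolerance = 1e-9)
  # reported cutoff attains the maximum J over the whole curve
  expect_equal(r$youden, max(r$curve$youden))
  # tie flag: duplicate-score data with several optimal cutoffs
  tied <- roc_youden(c(1, 1, 2, 2, 3, 3), c(0, 0, 0, 1, 1, 1))
  expect_true(is.logical(tied$tie))
})

test_that("mixed ANOVA recovers a known group shift", {
  set.seed(321)
  n <- 20
  make <- function(group, shift) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      u <- rnorm(1, 0, 2)
      data.frame(participant_id = paste0(group, i), group = group,
                 cue = rep(c("ego", "allo"), each = 8),
                 trial_index = 1:16,
                 error = pmax(0, 10 + shift + u + rnorm(16, 0, 4)))
    }))
  }
  sc <- rbind(make("HC", 0), make("aMCI", 3))
  m <- fit_error_mixed_anova(sc)
  a <- m$anova
  expect_true(all(c("group", "cue", "group:cue") %in% a$term))
  expect_lt(a$p[a$term == "group"], 0.05)
  # denominator df for the between factor is near n_participants - 2
  expect_equal(a$df_den[a$term == "group"], 38, tolerance = 1)
  # f column is internally consistent with the F conversion
  expect_equal(a$f, cohens_f_from_F(a$F_value, a$df_num, a$df_den))
  # group coefficient sign: HC reference -> aMCI estimate positive
  ct <- m$coefficients
  expect_gt(ct$estimate[ct$term == "groupaMCI"], 0)
})

test_that("trial polynomial model recovers a linear trend", {
  set.seed(432)
  n <- 18
  sc <- do.call(rbind, lapply(seq_len(2 * n), function(i) {
    g <- if (i <= n) "HC" else "aMCI"
    u <- rnorm(1, 0, 1.5)
    data.frame(participant_id = paste0("p", i), group = g,
               cue = rep(c("ego", "allo"), 8),
               trial_index = 1:16,
               error = pmax(0, 20 - 0.5 * (1:16) + u + rnorm(16, 0, 3)))
  }))
  m <- fit_trial_polynomial_model(sc, degree = 2)
  ct <- m$coefficients
  lin <- ct[ct$term == "poly(trial_index, 2)1", ]
  expect_lt(lin$estimate, 0)
  expect_lt(lin$p, 0.05)
  a <- m$anova
  expect_true(any(grepl("poly", a$term)))
})

test_that("switching ANOVA drops first trials and keeps group effect", {
  sc <- tiny_scores(8, seed = 515)
  m <- fit_switching_anova(sc)
  expect_true("group:switch_label" %in% m$anova$term)
  n_used <- stats::nobs(m$fit)
  expect_equal(n_used, sum(sc$switch_label != "first_trial"))
})

test_that("Poisson binding model has the documented closed forms", {
  counts <- data.frame(participant_id = rep(paste0("p", 1:12), 2),
                       group = rep(rep(c("HC", "aMCI"), each = 6), 2),
                       cue = rep(c("ego", "allo"), each = 12),
                       n_trials = 8,
                       binding_count = 2)
  m <- fit_binding_poisson(counts)
  ct <- m$coefficients
  # all counts equal: group/cue effects are 0, intercept = log mean
  expect_equal(ct$estimate[ct$term == "(Intercept)"], log(2),
               tolerance = 1e-8)
  expect_equal(max(abs(ct$estimate[ct$term != "(Intercept)"])), 0,
               tolerance = 1e-8)
  # intercept-only on heterogeneous counts reproduces log of the mean
  set.seed(99)
  counts$binding_count <- rpois(24, 3)
  m0 <- stats::glm(binding_count ~ 1, stats::poisson(), counts)
  expect_equal(unname(coef(m0)), log(mean(counts$binding_count)),
               tolerance = 1e-8)
})

test_that("Poisson model recovers a simulated rate ratio of 2", {
  set.seed(220)
  n <- 40
  counts <- data.frame(
    participant_id = rep(paste0("p", 1:(2 * n)), each = 2),
    group = rep(c("HC", "aMCI"), each = 2 * n),
    cue = rep(c("ego", "allo"), 2 * n),
    n_trials = 8)
  lam <- ifelse(counts$group == "aMCI", 2, 1)
  counts$binding_count <- rpois(nrow(counts), lam)
  m <- fit_binding_poisson(counts)
  ct <- m$coefficients
  # treatment coding: HC is the reference level, aMCI effect = log 2
  est <- ct$estimate[ct$term == "groupaMCI"]
  expect_equal(est, log(2), tolerance = 0.25)
  expect_equal(ct$or[ct$term == "groupaMCI"], exp(est))
})

test_that("logistic diagnosis model reports OR = exp(beta) and signs", {
  set.seed(741)
  n <- 40
  d <- data.frame(group = rep(c("HC", "aMCI"), each = n))
  d$error_ego <- rnorm(2 * n, mean = ifelse(d$group == "aMCI", 24, 20),
                       sd = 3)
  d$error_allo <- rnorm(2 * n, mean = 21, sd = 3)
  m <- fit_logistic_diagnosis(d, c("error_ego", "error_allo"))
  ct <- m$coefficients
  expect_equal(ct$or, exp(ct$estimate))
  expect_gt(ct$estimate[ct$term == "error_ego"], 0)   # aMCI positive
  expect_lt(ct$p[ct$term == "error_ego"], 0.05)
  # only the egocentric predictor differs between groups
  expect_gt(ct$p[ct$term == "error_allo"], 0.05)
  expect_true(any(grepl("positive class: aMCI", m$notes)))
})

test_that("a predictor independent of the labels has OR near 1", {
  set.seed(852)
  d <- data.frame(group = rep(c("HC", "aMCI"), each = 100),
                  x = rnorm(200))
  m <- fit_logistic_diagnosis(d, "x")
  ct <- m$coefficients
  expect_lt(abs(ct$estimate[ct$term == "x"]), 0.4)
  expect_equal(ct$or[ct$term == "x"], 1, tolerance = 0.5)
})

test_that("perfect separation triggers the flagged ridge fallback", {
  skip_if_not_installed("glmnet")
  d <- data.frame(group = rep(c("HC", "aMCI"), each = 10),
                  x = c(rnorm(10, 0), rnorm(10, 50)))
  m <- fit_logistic_diagnosis(d, "x")
  expect_match(m$name, "ridge fallback")
  expect_true(any(grepl("separation", m$notes)))
  expect_gt(m$coefficients$estimate[m$coefficients$term == "x"], 0)
})

test_that("attractor models use participant and object random effects", {
  sc <- tiny_scores(6, seed = 626)
  m <- fit_attractor_model(sc, "landmark")
  re <- names(lme4::ranef(m$fit))
  expect_setequal(re, c("participant_id", "object_id"))
  expect_true("group" %in% m$anova$term)
  mc <- fit_attractor_model(sc, "center")
  expect_match(mc$name, "center")
})
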
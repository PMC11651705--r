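# Endpoint analysis: outcome classification, Fisher, KM, Cox, AUC,
# Spearman, counterfactual, sample size.

test_that("outcome classification finds the first threshold crossing", {
  v <- data.frame(day = c(90, 180, 270), igf1_sds = c(4.0, 2.6, 1.5))
  o <- classify_outcome(v, baseline_igf1_sds = 5)
  expect_true(o$controlled)
  expect_equal(o$time_to_control_days, 270)
  expect_equal(o$event, 1L)
  expect_false(o$partial_responder)
})

test_that("partial responders drop > 50% without normalizing", {
  v <- data.frame(day = c(90, 180, 270, 365), igf1_sds = c(9, 7, 5.5, 4.9))
  o <- classify_outcome(v, baseline_igf1_sds = 10)
  expect_false(o$controlled)
  expect_equal(o$time_to_control_days, 365)
  expect_true(o$partial_responder)
  # flat trajectory: neither controlled nor partial
  flat <- data.frame(day = c(90, 180), igf1_sds = c(6, 6))
  o2 <- classify_outcome(flat, baseline_igf1_sds = 6)
  expect_false(o2$controlled)
  expect_false(o2$partial_responder)
  expect_error(classify_outcome(data.frame(day = numeric(), igf1_sds = numeric()), 5),
               "insufficient data")
})

test_that("Fisher exact matches the enumeration oracle on assorted tables", {
  tabs <- list(matrix(c(25, 7, 19, 17), 2, byrow = TRUE),
               matrix(c(5, 5, 5, 5), 2),
               matrix(c(1, 9, 8, 2), 2),
               matrix(c(0, 6, 6, 0), 2),
               matrix(c(3, 0, 0, 4), 2))
  for (tab in tabs) {
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # zero margin: p = 1 by convention, flagged
  z <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("KM matches the hand product-limit computation", {
  # events at 90 and 180, one censored at 365
  km <- km_curve(time = c(90, 180, 365), event = c(1, 1, 0))
  expect_equal(km$surv[km$time == 90], 2 / 3)
  expect_equal(km$surv[km$time == 180], 1 / 3)
  # all controlled at day 90: step to 0
  km2 <- km_curve(rep(90, 4), rep(1, 4))
  expect_equal(km2$surv[km2$time == 90], 0)
  # no events: constant 1
  km3 <- km_curve(c(365, 365), c(0, 0))
  expect_true(all(km3$surv == 1))
  # non-increasing, starts at/below 1
  set.seed(3)
  km4 <- km_curve(sample(c(90, 180, 270, 365), 50, TRUE),
                  rbinom(50, 1, 0.6))
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_lte(max(km4$surv), 1)
})

test_that("KM at the horizon equals the uncontrolled fraction without early censoring", {
  time <- c(90, 90, 180, 270, 365, 365, 365)
  event <- c(1, 1, 1, 1, 0, 0, 0)
  km <- km_curve(time, event)
  expect_equal(min(km$surv), 3 / 7)
})

test_that("Cox arm effect matches grid maximization of the Breslow likelihood", {
  set.seed(41)
  n <- 40
  d <- data.frame(
    arm = rep(c("PERSONALIZED", "STANDARD"), each = n / 2),
    age = 50, sex = "M",
    time_to_control_days = sample(c(90, 180, 270, 365), n, TRUE),
    event = rbinom(n, 1, 0.7))
  fit <- cox_hr(d, adjust = character(0))
  x <- as.integer(d$arm == "PERSONALIZED")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_breslow_loglik, numeric(1),
               time = d$time_to_control_days, event = d$event, x = x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("identical arms give a hazard ratio near 1 with a covering CI", {
  set.seed(42)
  n <- 400
  d <- data.frame(
    arm = rep(c("PERSONALIZED", "STANDARD"), each = n / 2),
    age = rnorm(n, 55, 10), sex = sample(c("M", "F"), n, TRUE),
    time_to_control_days = sample(c(90, 180, 270, 365), n, TRUE),
    event = rbinom(n, 1, 0.6))
  fit <- cox_hr(d)
  expect_equal(fit$hazard_ratio, 1, tolerance = 0.35)
  expect_lt(fit$conf_low, 1)
  expect_gt(fit$conf_high, 1)
  expect_error(cox_hr(d[d$event == 0, ]), "two control events")
})

test_that("AUC equals exhaustive pair counting and honors the orientation", {
  # perfectly separated: controlled patients all carry lower GH_2h
  expect_equal(roc_auc(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE), n_boot = 50)$auc, 1)
  # identical scores: ties convention gives 1/2
  expect_equal(roc_auc(rep(3, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                       n_boot = 50)$auc, 0.5)
  # 4-point toy set vs brute force
  s <- c(0.5, 2.9, 1.7, 2.9)
  y <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(s, y, n_boot = 50)$auc, oracle_auc_pairs(s, y))
  set.seed(7)
  s2 <- rlnorm(30); y2 <- runif(30) < 0.5
  expect_equal(roc_auc(s2, y2, n_boot = 50)$auc, oracle_auc_pairs(s2, y2))
  # invariant under strictly monotone transforms
  expect_equal(roc_auc(log(s2), y2, n_boot = 50)$auc,
               roc_auc(s2, y2, n_boot = 50)$auc)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both outcome classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- rlnorm(60); y <- runif(60) < 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        direction = ">", quiet = TRUE)))
  expect_equal(roc_auc(s, y, n_boot = 50)$auc, ref, tolerance = 1e-12)
})

test_that("AUC bootstrap CI brackets the point estimate and is seeded", {
  set.seed(9)
  s <- rlnorm(80); y <- s * exp(rnorm(80)) < 1.5
  r1 <- roc_auc(s, y, n_boot = 500, seed = 4)
  r2 <- roc_auc(s, y, n_boot = 500, seed = 4)
  expect_identical(r1, r2)
  expect_lte(r1$conf_low, r1$auc)
  expect_gte(r1$conf_high, r1$auc)
})

test_that("Spearman matrix matches direct rank computation", {
  d <- data.frame(a = c(3, 1, 4, 1, 5), b = c(2, 7, 1, 8, 2),
                  c = c(9, 2, 6, 5, 3))
  m <- spearman_matrix(d)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  hand <- cor(rank(d$a), rank(d$b))
  expect_equal(m["a", "b"], hand)
  # rank invariance under strictly monotone transforms
  d2 <- data.frame(x = d$a, y = exp(d$a))
  expect_equal(spearman_matrix(d2)["x", "y"], 1)
  expect_warning(spearman_matrix(data.frame(u = 1:5, v = rep(2, 5))),
                 "constant")
})

test_that("counterfactual evaluation handles the degenerate corners", {
  # all sAOT responders, all observed controlled: carried over perfectly
  pts <- data.frame(
    patient_id = sprintf("S%02d", 1:6), arm = "STANDARD",
    surgical_status = "NAIVE", age = 50, sex = "M", bmi = 27,
    gh_basal = 10, gh_2h = 1.0, baseline_igf1_sds = 6,
    height = 15, length = 12, width = 11, t2_class = "ISOINTENSE",
    knosp_grade = 1L, cavernous_sinus_invasion = FALSE,
    ecadherin = "UNAVAILABLE", stringsAsFactors = FALSE)
  oc <- data.frame(patient_id = pts$patient_id, controlled = TRUE)
  r <- counterfactual_control_arm(pts, oc)
  expect_equal(r$predicted_controlled_prop, 1)
  expect_equal(r$overtreated_prop, 0)
  expect_equal(r$valid_prediction_prop, 1)
  # all predicted non-responders with zero efficacy and no observed control
  pts$gh_2h <- 8  # 20% drop from basal 10: predicted non-responders
  oc$controlled <- FALSE
  r0 <- counterfactual_control_arm(pts, oc, efficacy = 0)
  expect_equal(r0$predicted_controlled_prop, 0)
  expect_equal(r0$valid_prediction_prop, 1)
  expect_error(counterfactual_control_arm(pts, oc, efficacy = 1.2), "\\[0, 1\\]")
})

test_that("sampled counterfactuals converge to the expectation mode", {
  co <- generate_cohort(cohort_config(60, 60), seed = 31)
  p <- co$patients[co$patients$arm == "STANDARD", ]
  oc <- classify_outcomes(p, co$visits)
  ex <- counterfactual_control_arm(p, oc, efficacy = 0.72, mode = "expectation")
  ex2 <- counterfactual_control_arm(p, oc, efficacy = 0.72, mode = "expectation")
  expect_identical(ex[c(1:5)], ex2[c(1:5)])  # deterministic given inputs
  draws <- vapply(1:300, function(s) {
    counterfactual_control_arm(p, oc, efficacy = 0.72, mode = "sampled",
                               seed = s)$predicted_controlled_prop
  }, numeric(1))
  expect_equal(mean(draws), ex$predicted_controlled_prop, tolerance = 0.02)
})

test_that("sample size shrinks with the detectable difference and inflates for loss", {
  s30 <- sample_size_two_proportions(0.50, 0.80, loss_fraction = 0)
  expect_equal(s30$n_recruit, s30$n_min)
  s60 <- sample_size_two_proportions(0.30, 0.90)
  expect_lt(s60$n_min, s30$n_min)
  expect_equal(inflate_recruitment(66, 0.15), 76L)
  expect_equal(inflate_recruitment(66, 0), 66L)
  expect_error(sample_size_two_proportions(0.5, 0.5), "distinct")
  expect_error(sample_size_two_proportions(0.5, 0.8, alpha = 1.2), "alpha")
})
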
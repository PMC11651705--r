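# Trial endpoint analysis: outcome classification, exact test, Kaplan-Meier
# and Cox time-to-control, ROC AUC, Spearman matrix, counterfactual policy
# evaluation, and design-stage sample size.

#' Classify a patient's outcome from the visit trajectory
#'
#' Hormonal control is established at the first scheduled visit with
#' IGF1-SDS at or below `normal_threshold`; the event time is that visit
#' day. Patients never normalized are censored at the horizon; they are
#' partial responders when the final IGF1-SDS decreased by more than 50\%
#' of the baseline value.
#'
#' @param visits Data frame with columns `day` and `igf1_sds` for one
#'   patient, days on the visit grid.
#' @param baseline_igf1_sds Baseline IGF1-SDS.
#' @param normal_threshold SDS defining normalization, default 2.
#' @param horizon Follow-up horizon in days, default 365.
#' @return List of class `outcome_record`: `controlled`,
#'   `time_to_control_days`, `event` (1 control, 0 censored),
#'   `partial_responder`, `final_igf1_sds`.
#' @examples
#' v <- data.frame(day = c(90, 180, 270), igf1_sds = c(4.0, 2.6, 1.5))
#' classify_outcome(v, baseline_igf1_sds = 5)  # controlled at day 270
#' @export
classify_outcome <- function(visits, baseline_igf1_sds,
                             normal_threshold = 2, horizon = 365) {
  if (is.null(visits) || nrow(visits) == 0L) {
    stop("insufficient data: empty visit list")
  }
  visits <- visits[order(visits$day), , drop = FALSE]
  hit <- which(visits$igf1_sds <= normal_threshold)
  controlled <- length(hit) > 0L
  final <- visits$igf1_sds[nrow(visits)]
  partial <- !controlled &&
    (baseline_igf1_sds - final) > 0.5 * baseline_igf1_sds
  structure(
    list(controlled = controlled,
         time_to_control_days = if (controlled) visits$day[hit[1L]] else horizon,
         event = as.integer(controlled),
         partial_responder = partial,
         final_igf1_sds = final),
    class = "outcome_record"
  )
}

#' Classify outcomes for a whole cohort
#'
#' @param patients Patient table (needs `patient_id`, `arm`, `age`, `sex`,
#'   `baseline_igf1_sds`).
#' @param visits Long visit table (`patient_id`, `day`, `igf1_sds`).
#' @inheritParams classify_outcome
#' @return Data frame, one row per patient, with outcome fields joined to
#'   arm and adjustment covariates.
#' @export
classify_outcomes <- function(patients, visits, normal_threshold = 2,
                              horizon = 365) {
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    v <- visits[visits$patient_id == pid, c("day", "igf1_sds")]
    o <- classify_outcome(v, patients$baseline_igf1_sds[i],
                          normal_threshold, horizon)
    data.frame(patient_id = pid, arm = patients$arm[i],
               age = patients$age[i], sex = patients$sex[i],
               controlled = o$controlled,
               time_to_control_days = o$time_to_control_days,
               event = o$event, partial_responder = o$partial_responder,
               final_igf1_sds = o$final_igf1_sds,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arm-by-control contingency table
#'
#' @param outcomes Output of [classify_outcomes()].
#' @return 2x2 integer matrix, arms in rows, controlled/noncontrolled in
#'   columns.
#' @export
contingency_table <- function(outcomes) {
  tab <- table(factor(outcomes$arm, levels = c("PERSONALIZED", "STANDARD")),
               factor(outcomes$controlled, levels = c(TRUE, FALSE)))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(arm = c("PERSONALIZED", "STANDARD"),
                              controlled = c("yes", "no")))
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' one. A zero margin yields p = 1 by convention, flagged in the result.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List: `p_value`, `table`, `degenerate` (zero-margin flag).
#' @examples
#' fisher_exact(matrix(c(25, 7, 19, 17), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(table)$p.value
  list(p_value = min(p, 1), table = table, degenerate = degenerate)
}

#' Kaplan-Meier curve of remaining uncontrolled
#'
#' Product-limit estimate of the probability of remaining uncontrolled,
#' with patients never controlled censored at the horizon.
#'
#' @param time Event/censoring times in days.
#' @param event 1 = control achieved, 0 = censored.
#' @return Data frame: `time`, `n_risk`, `n_event`, `surv` (one row per
#'   distinct observed time).
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Age- and sex-adjusted Cox hazard ratio for treatment arm
#'
#' Proportional-hazards partial-likelihood fit (Breslow tie handling —
#' event times sit on a coarse 90-day grid, so ties are frequent) of
#' time-to-control on arm, age and sex; reports the arm hazard ratio with a
#' Wald 95\% confidence interval. A hazard ratio above 1 means the
#' personalized arm achieves control faster.
#'
#' @param outcomes Data frame with `time_to_control_days`, `event`, `arm`,
#'   and the adjustment covariates.
#' @param adjust Adjustment covariates; the default adjusts for age and sex.
#'   Use `character(0)` for an unadjusted arm effect.
#' @param conf_level Confidence level, default 0.95.
#' @return List: `hazard_ratio`, `conf_low`, `conf_high`, `coef`, `se`,
#'   `fit` (the underlying `coxph` object).
#' @export
cox_hr <- function(outcomes, adjust = c("age", "sex"), conf_level = 0.95) {
  if (sum(outcomes$event) < 2) stop("need at least two control events")
  d <- outcomes
  d$arm_personalized <- as.integer(d$arm == "PERSONALIZED")
  if ("sex" %in% adjust) {
    d$sex_male <- as.integer(d$sex == "M")
    adjust[adjust == "sex"] <- "sex_male"
  }
  rhs <- paste(c("arm_personalized", adjust), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time_to_control_days, event) ~", rhs)),
    data = d, ties = "breslow"
  )
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    stop("Cox fit did not converge")
  }
  beta <- stats::coef(fit)[["arm_personalized"]]
  se <- sqrt(stats::vcov(fit)["arm_personalized", "arm_personalized"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hazard_ratio = exp(beta),
       conf_low = exp(beta - z * se), conf_high = exp(beta + z * se),
       coef = beta, se = se, fit = fit)
}

#' Rank-based ROC AUC with bootstrap confidence interval
#'
#' AUC as the concordance probability that a controlled patient carries a
#' lower score than a noncontrolled one (ties count one half); orientation
#' is fixed so that lower scores predict control, matching the use of sAOT
#' GH_2h as the predictor. The confidence interval is a seeded bootstrap
#' percentile interval over patients.
#'
#' @param score Numeric predictor (e.g. harmonized GH_2h).
#' @param controlled Logical outcome.
#' @param n_boot Bootstrap replicates, default 2000.
#' @param conf_level Confidence level, default 0.95.
#' @param seed Seed for the bootstrap resampling.
#' @return List: `auc`, `conf_low`, `conf_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(score, controlled, n_boot = 2000, conf_level = 0.95,
                    seed = 1) {
  stopifnot(length(score) == length(controlled))
  if (!any(controlled) || all(controlled)) {
    stop("undefined AUC: both outcome classes must be present")
  }
  auc_point <- function(s, y) {
    # P(score_pos < score_neg) + 0.5 P(tie), via the rank-sum identity
    r <- rank(s)
    n_pos <- sum(y); n_neg <- sum(!y)
    (sum(r[!y]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
  }
  a <- auc_point(score, controlled)
  set.seed(seed)
  boots <- replicate(n_boot, {
    i <- sample.int(length(score), replace = TRUE)
    if (any(controlled[i]) && !all(controlled[i])) auc_point(score[i], controlled[i])
    else NA_real_
  })
  qs <- stats::quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(auc = a, conf_low = qs[1], conf_high = qs[2],
       n_pos = sum(controlled), n_neg = sum(!controlled))
}

#' Spearman rank-correlation matrix
#'
#' Pairwise-complete Spearman correlations between named numeric columns;
#' constant columns give NA entries and a warning.
#'
#' @param data Data frame of numeric variables.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(data) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, logical(1))
  data <- data[num]
  const <- vapply(data, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) < 2L
  }, logical(1))
  if (any(const)) {
    warning("constant column(s) give undefined correlations: ",
            paste(names(data)[const], collapse = ", "))
  }
  suppressWarnings(
    stats::cor(data, method = "spearman", use = "pairwise.complete.obs")
  )
}

#' Counterfactual evaluation of the personalized rule on a standard arm
#'
#' Applies the personalized assignment to patients actually treated by the
#' standard protocol (fgSRLs first-line) and predicts what would have
#' happened: where the rule also picks fgSRL monotherapy the observed
#' outcome carries over; where it picks a pegvisomant-containing regimen
#' the predicted outcome is the configured efficacy (expectation mode) or a
#' seeded Bernoulli draw (sampled mode). A prediction is "valid" when the
#' predicted class (fgSRL-responder vs non-responder) agrees with the
#' observed control status on fgSRLs; "overtreated" patients would have
#' received pegvisomant although fgSRLs alone controlled them.
#'
#' @param patients Standard-arm patient table (as from [generate_cohort()]).
#' @param outcomes Matching [classify_outcomes()] rows (observed under
#'   fgSRL-based standard therapy).
#' @param efficacy Control probability of pegvisomant-containing regimens,
#'   in `[0, 1]`.
#' @param mode "expectation" (deterministic) or "sampled".
#' @param seed Seed for sampled mode.
#' @return List: `n`, `n_evaluable`, `predicted_controlled_prop`,
#'   `valid_prediction_prop`, `overtreated_prop`, and the per-patient
#'   `detail` data frame.
#' @export
counterfactual_control_arm <- function(patients, outcomes, efficacy = 0.72,
                                       mode = c("expectation", "sampled"),
                                       seed = 1) {
  mode <- match.arg(mode)
  if (efficacy < 0 || efficacy > 1) stop("efficacy must lie in [0, 1]")
  idx <- match(patients$patient_id, outcomes$patient_id)
  if (anyNA(idx)) stop("every patient needs an observed outcome")
  observed <- outcomes$controlled[idx]

  if (mode == "sampled") set.seed(seed)
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    row <- patients[i, ]
    rec <- try(record_from_row(row), silent = TRUE)
    if (inherits(rec, "try-error")) {
      return(data.frame(patient_id = row$patient_id, evaluable = FALSE,
                        modality = NA_character_, predicted = NA_real_,
                        valid = NA, overtreated = NA))
    }
    a <- try(assign_personalized(rec), silent = TRUE)
    if (inherits(a, "try-error")) {
      return(data.frame(patient_id = row$patient_id, evaluable = FALSE,
                        modality = NA_character_, predicted = NA_real_,
                        valid = NA, overtreated = NA))
    }
    pegv <- a$modality %in% c("FGSRL_PLUS_PEGV", "PEGV_MONO")
    predicted <- if (!pegv) {
      as.numeric(observed[i])
    } else if (mode == "expectation") {
      efficacy
    } else {
      as.numeric(stats::runif(1) < efficacy)
    }
    data.frame(patient_id = row$patient_id, evaluable = TRUE,
               modality = a$modality, predicted = predicted,
               valid = if (pegv) !observed[i] else observed[i],
               overtreated = pegv && observed[i],
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  ev <- detail[detail$evaluable, , drop = FALSE]
  list(n = nrow(patients), n_evaluable = nrow(ev),
       predicted_controlled_prop = mean(ev$predicted),
       valid_prediction_prop = mean(ev$valid),
       overtreated_prop = mean(ev$overtreated),
       detail = detail)
}

#' Two-proportion sample size with recruitment inflation
#'
#' Standard normal-approximation sample size for detecting a difference
#' between two independent proportions at two-sided level `alpha` with the
#' given power, plus the recruitment target inflated for the expected loss
#' to follow-up (`ceiling(n_min * (1 + loss_fraction))`).
#'
#' @param p1,p2 Assumed control proportions in the two arms.
#' @param alpha Two-sided significance level, default 0.05.
#' @param power Target power, default 0.8.
#' @param loss_fraction Expected loss to follow-up, default 0.
#' @return List: `n_per_arm`, `n_min` (total), `n_recruit` (total inflated).
#' @examples
#' inflate_recruitment(66, 0.15)  # 76
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8,
                                        loss_fraction = 0) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) >= 1) || p1 == p2) {
    stop("need distinct proportions strictly inside (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)")
  }
  if (loss_fraction < 0 || loss_fraction >= 1) {
    stop("loss_fraction must lie in [0, 1)")
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  n_arm <- ((z_a * sqrt(2 * pbar * (1 - pbar)) +
               z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2) / (p1 - p2)^2
  n_arm <- ceiling(n_arm)
  n_min <- 2 * n_arm
  list(n_per_arm = n_arm, n_min = n_min,
       n_recruit = inflate_recruitment(n_min, loss_fraction))
}

#' @rdname sample_size_two_proportions
#' @param n_min Minimum total sample size.
#' @export
inflate_recruitment <- function(n_min, loss_fraction) {
  if (loss_fraction < 0 || loss_fraction >= 1) {
    stop("loss_fraction must lie in [0, 1)")
  }
  as.integer(ceiling(n_min * (1 + loss_fraction)))
}

#' Assemble the two-arm trial endpoint summary
#'
#' Computes per-arm control proportions, the Fisher exact comparison, the
#' age- and sex-adjusted Cox hazard ratio, per-arm median time-to-control
#' with quartiles (censored patients entering at the horizon), and the ROC
#' AUC of GH_2h for predicting control among treatment-naive patients.
#'
#' @param patients Patient table.
#' @param outcomes Output of [classify_outcomes()].
#' @param auc_seed Seed for the AUC bootstrap.
#' @return List of class `trial_result`.
#' @export
trial_result <- function(patients, outcomes, auc_seed = 1) {
  arms <- c("PERSONALIZED", "STANDARD")
  per_arm <- lapply(arms, function(a) {
    o <- outcomes[outcomes$arm == a, ]
    q <- stats::quantile(o$time_to_control_days, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = nrow(o), n_controlled = sum(o$controlled),
         proportion = mean(o$controlled),
         ttc_quartiles = q)
  })
  names(per_arm) <- arms
  tab <- contingency_table(outcomes)
  fish <- fisher_exact(tab)
  cox <- cox_hr(outcomes)
  naive <- patients$surgical_status == "NAIVE"
  auc <- tryCatch(
    roc_auc(patients$gh_2h[naive],
            outcomes$controlled[match(patients$patient_id[naive],
                                      outcomes$patient_id)],
            seed = auc_seed),
    error = function(e) NULL
  )
  structure(
    list(per_arm = per_arm, table = tab, fisher_p = fish$p_value,
         hazard_ratio = cox$hazard_ratio,
         hr_conf = c(cox$conf_low, cox$conf_high),
         auc = auc),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  for (a in names(x$per_arm)) {
    p <- x$per_arm[[a]]
    cat(sprintf("%-12s n=%3d controlled=%3d (%d%%)  time-to-control median %d (%d-%d) d\n",
                a, p$n, p$n_controlled, round(100 * p$proportion),
                round(p$ttc_quartiles[2]), round(p$ttc_quartiles[1]),
                round(p$ttc_quartiles[3])))
  }
  cat(sprintf("Fisher exact (controlled x arm): p = %.4g\n", x$fisher_p))
  cat(sprintf("Cox HR (personalized vs standard, age/sex-adjusted): %.2f (%.2f-%.2f)\n",
              x$hazard_ratio, x$hr_conf[1], x$hr_conf[2]))
  if (!is.null(x$auc)) {
    cat(sprintf("GH_2h AUC for control (naive patients): %.1f%% (%.1f%%-%.1f%%)\n",
                100 * x$auc$auc, 100 * x$auc$conf_low, 100 * x$auc$conf_high))
  }
  invisible(x)
}
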
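# Synthetic two-arm cohort generator.
#
# Emulates the statistical structure of a biomarker-guided acromegaly trial
# population: skewed hormone marginals matched to published medians/IQRs via
# a Gaussian copula, a positive GH_2h-tumor-size rank correlation, sAOT
# classes coupled to fgSRL response, and IGF1-SDS visit trajectories on a
# 3-month grid declining to normalization for controlled patients.

#' Cohort generator configuration
#'
#' Defaults reproduce the study conditions of the emulated two-arm trial:
#' arm sizes 32 (personalized) and 36 (standard); arm-specific baseline
#' marginals (age, sex ratio, BMI, IGF1-SDS, basal GH, GH_2h, tumor
#' diameter, Knosp grade, T2-hypointense fraction, postsurgical fraction);
#' a latent Gaussian copula carrying the age-IGF1 and GH_2h-tumor-size
#' correlations; per-modality control probabilities conditional on the sAOT
#' class, calibrated so the arms land near 78\% and 53\% control; and
#' time-to-control distributions snapped to the 90-day visit grid within a
#' 365-day horizon.
#'
#' Skewed variables (basal GH, GH_2h, IGF1-SDS) follow a two-piece
#' log-normal matched exactly to the configured median and quartiles; age,
#' BMI and diameter are (truncated) normal.
#'
#' @param n_personalized,n_standard Arm sizes.
#' @param control_probs List with `fgsrl` (named vector of control
#'   probabilities under fgSRL-only regimens by sAOT response stratum:
#'   responders split by percent-drop concordance — a responder by GH_2h
#'   whose drop nevertheless stayed at or below 50\% is a "discordant"
#'   responder with poor predicted fgSRL response — plus the partial and
#'   non-responder classes), `pegv_containing` (control probability of
#'   pegvisomant-containing regimens) and `secondline` (probability that a
#'   first-line failure is rescued by modality escalation within the
#'   remaining follow-up).
#' @param ecad_missing_frac Fraction of postsurgical records with
#'   insufficient tissue for E-cadherin immunostaining.
#' @param visit_days Scheduled visit grid (days).
#' @param horizon Follow-up horizon (days); must be the last visit.
#' @param normal_threshold IGF1-SDS defining hormonal control.
#' @param titration_threshold IGF1-SDS above which doses escalate.
#' @param igf1_ref IGF-1 reference table ([igf1_reference_default()]).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_personalized = 32, n_standard = 36,
                          control_probs = list(
                            fgsrl = c(RESPONDER_CONCORDANT = 0.87,
                                      RESPONDER_DISCORDANT = 0.05,
                                      PARTIAL_RESPONDER = 0.05,
                                      NON_RESPONDER = 0.02),
                            pegv_containing = 0.72,
                            secondline = 0
                          ),
                          ecad_missing_frac = 1 / 3,
                          visit_days = c(90, 180, 270, 365),
                          horizon = 365,
                          normal_threshold = 2,
                          titration_threshold = 2.5,
                          igf1_ref = igf1_reference_default()) {
  if (n_personalized < 1 || n_standard < 1) stop("arm sizes must be >= 1")
  probs <- c(control_probs$fgsrl, control_probs$pegv_containing,
             control_probs$secondline, ecad_missing_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(fgsrl_response_keys() %in% names(control_probs$fgsrl))) {
    stop("control_probs$fgsrl must name all response strata: ",
         paste(fgsrl_response_keys(), collapse = ", "))
  }
  if (length(visit_days) < 1 || horizon < min(visit_days)) {
    stop("follow-up horizon shorter than one visit interval")
  }
  if (max(visit_days) != horizon) stop("last visit must fall on the horizon")

  # Latent copula correlations (order: age, size, gh_basal, gh_2h, igf1_sds).
  # gh_2h-size 0.58 targets the observed Spearman rho of about 0.56-0.58
  # between sAOT GH_2h and tumor diameter/volume; age-igf1 -0.43 the observed
  # negative age correlation of baseline IGF1-SDS.
  latent <- matrix(c(
    1.00, 0.00, 0.00, 0.00, -0.43,
    0.00, 1.00, 0.40, 0.58, 0.28,
    0.00, 0.40, 1.00, 0.60, 0.30,
    0.00, 0.58, 0.60, 1.00, 0.30,
    -0.43, 0.28, 0.30, 0.30, 1.00), 5, 5,
    dimnames = rep(list(c("age", "size", "gh_basal", "gh_2h", "igf1_sds")), 2))

  arms <- list(
    PERSONALIZED = list(
      n = n_personalized,
      age_mean = 52, age_sd = 15, male_prob = 22 / 32,
      bmi_mean = 28, bmi_sd = 4,
      igf1_sds_median = 6.1, igf1_sds_q = c(4.4, 8.1),
      gh_median = 4.6, gh_q = c(3.1, 16.2),
      gh2h_median = 1.3, gh2h_q = c(0.3, 2.2),
      diam_mean = 17, diam_sd = 8,
      knosp_mean = 2.0, knosp_sd = 1.5,
      t2_hypo_prob = 18 / 32,
      postsurgical_prob = 9 / 32,
      ttc_fgsrl_mean = 150, ttc_fgsrl_sd = 94
    ),
    STANDARD = list(
      n = n_standard,
      age_mean = 56, age_sd = 14, male_prob = 16 / 36,
      bmi_mean = 29, bmi_sd = 5,
      igf1_sds_median = 5.3, igf1_sds_q = c(4.4, 6.9),
      gh_median = 7.0, gh_q = c(2.8, 13.1),
      gh2h_median = 1.6, gh2h_q = c(0.4, 3.3),
      diam_mean = 16, diam_sd = 8,
      knosp_mean = 1.85, knosp_sd = 1.3,
      t2_hypo_prob = 12 / 36,
      postsurgical_prob = 10 / 36,
      ttc_fgsrl_mean = 158, ttc_fgsrl_sd = 88
    )
  )

  structure(
    list(arms = arms, latent_corr = latent, control_probs = control_probs,
         ecad_pos_prob = c(responder = 0.85, nonresponder = 0.15),
         ecad_missing_frac = ecad_missing_frac,
         ttc_pegv_mean = 260, ttc_pegv_sd = 90,
         visit_days = sort(visit_days), horizon = horizon,
         normal_threshold = normal_threshold,
         titration_threshold = titration_threshold,
         igf1_ref = igf1_ref),
    class = "cohort_config"
  )
}

#' fgSRL response strata used by the generator's outcome model
#'
#' sAOT responders are split by percent-drop concordance: a GH_2h responder
#' whose drop stayed at or below 50\% carries discordant test results and a
#' poor predicted fgSRL response.
#'
#' @return Character vector of stratum names.
#' @export
fgsrl_response_keys <- function() {
  c("RESPONDER_CONCORDANT", "RESPONDER_DISCORDANT",
    "PARTIAL_RESPONDER", "NON_RESPONDER")
}

#' @rdname fgsrl_response_keys
#' @param saot_class sAOT class vector.
#' @param pct_drop Percent GH drop vector.
#' @export
fgsrl_response_stratum <- function(saot_class, pct_drop) {
  ifelse(saot_class == "RESPONDER",
         ifelse(pct_drop > 50, "RESPONDER_CONCORDANT", "RESPONDER_DISCORDANT"),
         saot_class)
}

# Two-piece log-normal quantile transform matched exactly to the median and
# both quartiles: published summaries carry asymmetric IQRs on the log
# scale, which a single sdlog cannot reproduce.
qsplitlnorm <- function(u, median, q) {
  z <- stats::qnorm(u)
  sd_lo <- log(median / q[1]) / stats::qnorm(0.75)
  sd_hi <- log(q[2] / median) / stats::qnorm(0.75)
  median * exp(ifelse(z < 0, sd_lo, sd_hi) * z)
}

# truncated-normal quantile transform of a uniform
qtruncnorm <- function(u, mean, sd, lower, upper) {
  a <- stats::pnorm(lower, mean, sd)
  b <- stats::pnorm(upper, mean, sd)
  stats::qnorm(a + u * (b - a), mean, sd)
}

draw_arm_baseline <- function(arm_name, a, config) {
  n <- a$n
  # Gaussian copula for the correlated block
  L <- chol(config$latent_corr)
  z <- matrix(stats::rnorm(n * 5), n, 5) %*% L
  u <- stats::pnorm(z)
  colnames(u) <- colnames(config$latent_corr)

  age <- qtruncnorm(u[, "age"], a$age_mean, a$age_sd, 18, 80)
  diam <- qtruncnorm(u[, "size"], a$diam_mean, a$diam_sd, 4, 60)
  gh_basal <- qsplitlnorm(u[, "gh_basal"], a$gh_median, a$gh_q)
  gh_2h <- qsplitlnorm(u[, "gh_2h"], a$gh2h_median, a$gh2h_q)
  igf1_sds0 <- qsplitlnorm(u[, "igf1_sds"], a$igf1_sds_median, a$igf1_sds_q)

  sex <- ifelse(stats::runif(n) < a$male_prob, "M", "F")
  bmi <- stats::rnorm(n, a$bmi_mean, a$bmi_sd)
  t2 <- ifelse(stats::runif(n) < a$t2_hypo_prob, "HYPOINTENSE",
               ifelse(stats::runif(n) < 0.5, "ISOINTENSE", "HYPERINTENSE"))
  knosp <- pmin(4L, pmax(0L, as.integer(round(stats::rnorm(n, a$knosp_mean, a$knosp_sd)))))
  postsurgical <- stats::runif(n) < a$postsurgical_prob

  # tumor axes: the measured largest diameter plus two shorter axes
  f1 <- stats::runif(n, 0.65, 0.95)
  f2 <- stats::runif(n, 0.60, 0.90)

  data.frame(
    arm = arm_name,
    surgical_status = ifelse(postsurgical, "POSTSURGICAL", "NAIVE"),
    age = age, sex = sex, bmi = round(bmi, 1),
    baseline_igf1_sds = igf1_sds0,
    gh_basal = gh_basal, gh_2h = gh_2h,
    height = diam, length = diam * f1, width = diam * f2,
    t2_class = t2, knosp_grade = knosp,
    stringsAsFactors = FALSE
  )
}

record_from_row <- function(row) {
  patient_record(
    patient_id = row$patient_id, arm = row$arm,
    surgical_status = row$surgical_status,
    age = row$age, sex = row$sex, bmi = row$bmi,
    baseline_gh = row$gh_basal, baseline_igf1_sds = row$baseline_igf1_sds,
    saot = classify_saot(row$gh_basal, row$gh_2h),
    geometry = tumor_geometry(row$height, row$length, row$width,
                              t2_class = row$t2_class,
                              knosp_grade = row$knosp_grade),
    cavernous_sinus_invasion = row$cavernous_sinus_invasion,
    ecadherin = row$ecadherin
  )
}

#' Mark E-cadherin as unavailable in a fraction of postsurgical records
#'
#' Emulates insufficient tumor tissue for immunostaining; affected patients
#' in the personalized arm fall back to the presurgical algorithm.
#'
#' @param patients Patient table from [generate_cohort()].
#' @param fraction Fraction of postsurgical records to mark, in `[0, 1]`.
#' @return The patient table with `ecadherin` set to "UNAVAILABLE" in the
#'   selected rows.
#' @export
inject_missingness <- function(patients, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  post <- which(patients$surgical_status == "POSTSURGICAL")
  hit <- post[stats::runif(length(post)) < fraction]
  patients$ecadherin[hit] <- "UNAVAILABLE"
  patients
}

#' Generate a synthetic two-arm cohort
#'
#' Draws baseline records per arm, runs the arm's assignment engine, draws
#' each patient's latent fgSRL responsiveness and control outcome from the
#' configured conditional probabilities, and lays down IGF1-SDS visit
#' trajectories consistent with the drawn time-to-control: values stay
#' above the control threshold before the event visit and sit below it from
#' the event visit on, so outcome classification recovers the generating
#' truth exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return List of class `synthetic_cohort` with elements `patients`
#'   (one row per patient, including the treatment assignment and its
#'   rationale), `visits` (long table: patient_id, day, igf1_sds, igf1, gh),
#'   `truth` (per-patient latent responder status, assigned-modality control
#'   probability, controlled flag and true event day) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)

  base <- do.call(rbind, lapply(names(config$arms), function(arm_name) {
    draw_arm_baseline(arm_name, config$arms[[arm_name]], config)
  }))
  n <- nrow(base)
  base$patient_id <- sprintf("P%04d", seq_len(n))
  base$cavernous_sinus_invasion <- base$knosp_grade >= 3L

  # sAOT classification on the (harmonized-scale) generated GH values
  base$pct_drop <- 100 * (base$gh_basal - base$gh_2h) / base$gh_basal
  base$saot_class <- vapply(seq_len(n), function(i) {
    classify_saot(base$gh_basal[i], base$gh_2h[i])$saot_class
  }, character(1))

  # assay provenance: raw values on each center's assay scale; an assay is
  # only eligible when the raw value stays non-negative (intercepts of the
  # calibration lines floor the reportable harmonized range)
  cal <- gh_calibrations()
  base$assay_id <- vapply(seq_len(n), function(i) {
    ok <- cal$assay_id[cal$intercept <= min(base$gh_basal[i], base$gh_2h[i])]
    ok[sample.int(length(ok), 1L)]
  }, character(1))
  base$gh_basal_raw <- unharmonize_gh(base$gh_basal, base$assay_id, cal)
  base$gh_2h_raw <- unharmonize_gh(base$gh_2h, base$assay_id, cal)

  # E-cadherin: concordant with sAOT-predicted responsiveness, then a
  # fraction of postsurgical samples lost to insufficient tissue
  p_pos <- ifelse(base$saot_class == "RESPONDER",
                  config$ecad_pos_prob[["responder"]],
                  config$ecad_pos_prob[["nonresponder"]])
  base$ecadherin <- ifelse(base$surgical_status == "POSTSURGICAL",
                           ifelse(stats::runif(n) < p_pos, "POSITIVE", "NEGATIVE"),
                           "UNAVAILABLE")
  base <- inject_missingness(base, config$ecad_missing_frac)

  base$largest_diameter <- pmax(base$height, base$length, base$width)
  base$volume <- tumor_volume(base$height, base$length, base$width)
  base$baseline_igf1 <- igf1_from_sds(base$baseline_igf1_sds, base$age,
                                      base$sex, config$igf1_ref)

  # first-line assignment per arm
  assigns <- lapply(seq_len(n), function(i) {
    row <- base[i, ]
    if (row$arm == "PERSONALIZED") assign_personalized(record_from_row(row))
    else assign_standard(record_from_row(row))
  })
  base$modality <- vapply(assigns, `[[`, character(1), "modality")
  base$fgsrl_dose_level <- vapply(assigns, `[[`, character(1), "fgsrl_dose_level")
  base$pegv_dose <- vapply(assigns, `[[`, numeric(1), "pegv_dose")
  base$rationale <- vapply(assigns, function(a) paste(a$rationale, collapse = ";"),
                           character(1))

  # latent truth: would the patient control on fgSRLs alone, and does the
  # assigned modality control within the horizon
  p_fgsrl <- config$control_probs$fgsrl[fgsrl_response_stratum(base$saot_class,
                                                               base$pct_drop)]
  fgsrl_response <- stats::runif(n) < p_fgsrl
  pegv_regimen <- base$modality %in% c("FGSRL_PLUS_PEGV", "PEGV_MONO")
  p_assigned <- ifelse(pegv_regimen, config$control_probs$pegv_containing, p_fgsrl)
  controlled <- ifelse(pegv_regimen,
                       stats::runif(n) < config$control_probs$pegv_containing,
                       fgsrl_response)
  # late rescue of first-line failures by modality escalation
  rescue <- !controlled & stats::runif(n) < config$control_probs$secondline

  grid <- config$visit_days
  ttc_mean <- ifelse(pegv_regimen, config$ttc_pegv_mean,
                     ifelse(base$arm == "PERSONALIZED",
                            config$arms$PERSONALIZED$ttc_fgsrl_mean,
                            config$arms$STANDARD$ttc_fgsrl_mean))
  ttc_sd <- ifelse(pegv_regimen, config$ttc_pegv_sd,
                   ifelse(base$arm == "PERSONALIZED",
                          config$arms$PERSONALIZED$ttc_fgsrl_sd,
                          config$arms$STANDARD$ttc_fgsrl_sd))
  raw_t <- stats::rnorm(n, ttc_mean, ttc_sd)
  snap <- function(t) vapply(t, function(x) grid[which(grid >= x)[1]], numeric(1))
  event_day <- ifelse(controlled, snap(pmin(pmax(raw_t, 1), config$horizon)),
                      ifelse(rescue, config$horizon, NA_real_))
  controlled <- controlled | rescue

  truth <- data.frame(
    patient_id = base$patient_id,
    true_fgsrl_responder = fgsrl_response,
    assigned_modality = base$modality,
    assigned_control_prob = as.numeric(p_assigned),
    controlled = controlled,
    event_day = event_day,
    stringsAsFactors = FALSE
  )

  visits <- make_visit_trajectories(base, truth, config)

  structure(list(patients = base[, cohort_patient_columns()],
                 visits = visits, truth = truth, config = config,
                 seed = seed),
            class = "synthetic_cohort")
}

cohort_patient_columns <- function() {
  c("patient_id", "arm", "surgical_status", "age", "sex", "bmi",
    "assay_id", "gh_basal_raw", "gh_2h_raw", "gh_basal", "gh_2h",
    "pct_drop", "saot_class", "baseline_igf1", "baseline_igf1_sds",
    "height", "length", "width", "largest_diameter", "volume",
    "t2_class", "knosp_grade", "cavernous_sinus_invasion", "ecadherin",
    "modality", "fgsrl_dose_level", "pegv_dose", "rationale")
}

# Visit IGF1-SDS trajectories consistent with the drawn control truth:
# strictly above the control threshold before the event visit, below it at
# and after the event; uncontrolled patients decline to a plateau above the
# threshold (about half of them by > 50%, i.e. partial responders).
make_visit_trajectories <- function(base, truth, config) {
  grid <- config$visit_days
  thr <- config$normal_threshold
  out <- vector("list", nrow(base))
  for (i in seq_len(nrow(base))) {
    b <- base$baseline_igf1_sds[i]
    d <- truth$event_day[i]
    if (isTRUE(truth$controlled[i])) {
      plateau <- stats::runif(1, 0.6 * thr, 0.95 * thr)
      sds <- vapply(grid, function(t) {
        if (t < d) {
          pre <- max(thr + 0.55, b * (1 - 0.5 * t / d))
          pre + stats::runif(1, 0, 0.3)
        } else {
          min(plateau + stats::rnorm(1, 0, 0.05), thr - 0.05)
        }
      }, numeric(1))
    } else {
      r <- stats::rbeta(1, 2, 2)  # total fractional decline by horizon
      final <- max(thr + 0.55, b * (1 - r))
      sds <- vapply(grid, function(t) {
        v <- b + (final - b) * t / max(grid)
        max(thr + 0.52, v + stats::rnorm(1, 0, 0.1))
      }, numeric(1))
    }
    out[[i]] <- data.frame(patient_id = base$patient_id[i], day = grid,
                           igf1_sds = sds, stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, out)
  idx <- match(visits$patient_id, base$patient_id)
  visits$igf1 <- igf1_from_sds(visits$igf1_sds, base$age[idx], base$sex[idx],
                               config$igf1_ref)
  # GH tracks the IGF-1 trend multiplicatively with noise
  visits$gh <- base$gh_basal[idx] *
    (visits$igf1_sds / base$baseline_igf1_sds[idx]) *
    exp(stats::rnorm(nrow(visits), 0, 0.15))
  rownames(visits) <- NULL
  visits
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$patients$arm)
  cat(sprintf("synthetic cohort: %d patients (%s), seed %d\n",
              nrow(x$patients),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}
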
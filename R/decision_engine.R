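# Treatment-assignment engines and the dose-titration state machine.
#
# Personalized first-line assignment is driven by the sAOT class, T2-MRI
# signal, cavernous sinus invasion and (postsurgically) E-cadherin
# immunoexpression; the standard engine always starts fgSRLs at medium dose.

#' Construct a patient record
#'
#' One row of the cohort: baseline biomarkers, arm and surgical status, the
#' input to the treatment-assignment engines. GH values must already be
#' harmonized to the reference assay scale.
#'
#' @param patient_id Identifier.
#' @param arm "PERSONALIZED" or "STANDARD".
#' @param surgical_status "NAIVE" (treatment-naive at diagnosis) or
#'   "POSTSURGICAL" (persistent disease after surgery).
#' @param age Years (18-80).
#' @param sex "M"/"F".
#' @param bmi kg/m^2.
#' @param baseline_gh Harmonized GH, ng/mL.
#' @param baseline_igf1_sds Baseline IGF1-SDS.
#' @param saot A [classify_saot()] result, or `NULL` if not performed.
#' @param geometry A [tumor_geometry()] object.
#' @param cavernous_sinus_invasion Logical; when missing it is derived from
#'   Knosp grade >= 3.
#' @param ecadherin "POSITIVE", "NEGATIVE" or "UNAVAILABLE". Naive patients
#'   have no tissue, hence always "UNAVAILABLE".
#' @return List of class `patient_record`.
#' @export
patient_record <- function(patient_id, arm, surgical_status, age, sex, bmi,
                           baseline_gh, baseline_igf1_sds,
                           saot = NULL, geometry = NULL,
                           cavernous_sinus_invasion = NULL,
                           ecadherin = "UNAVAILABLE") {
  arm <- match.arg(arm, c("PERSONALIZED", "STANDARD"))
  surgical_status <- match.arg(surgical_status, c("NAIVE", "POSTSURGICAL"))
  ecadherin <- match.arg(ecadherin, c("POSITIVE", "NEGATIVE", "UNAVAILABLE"))
  if (surgical_status == "NAIVE" && ecadherin != "UNAVAILABLE") {
    stop("naive patients cannot have an E-cadherin result")
  }
  if (!is.null(saot) && !inherits(saot, "saot_result")) {
    stop("saot must be a classify_saot() result or NULL")
  }
  if (is.null(cavernous_sinus_invasion)) {
    cavernous_sinus_invasion <-
      !is.null(geometry) && geometry$knosp_grade >= 3L
  }
  structure(
    list(patient_id = patient_id, arm = arm,
         surgical_status = surgical_status,
         age = age, sex = sex, bmi = bmi,
         baseline_gh = baseline_gh, baseline_igf1_sds = baseline_igf1_sds,
         saot = saot, geometry = geometry,
         cavernous_sinus_invasion = isTRUE(cavernous_sinus_invasion),
         ecadherin = ecadherin),
    class = "patient_record"
  )
}

#' Treatment modalities
#' @export
treatment_modalities <- c("FGSRL_MONO", "FGSRL_PLUS_PEGV", "PEGV_MONO",
                          "FGSRL_PLUS_CABERGOLINE")

new_assignment <- function(modality, fgsrl_dose_level, pegv_dose, rationale) {
  stopifnot(modality %in% treatment_modalities,
            fgsrl_dose_level %in% c("none", "medium", "maximal"),
            length(rationale) >= 1L)
  if (modality == "PEGV_MONO" && fgsrl_dose_level != "none") {
    stop("pegvisomant monotherapy carries no fgSRL dose")
  }
  structure(
    list(modality = modality, fgsrl_dose_level = fgsrl_dose_level,
         pegv_dose = pegv_dose, rationale = rationale),
    class = "treatment_assignment"
  )
}

#' @export
print.treatment_assignment <- function(x, ...) {
  cat(sprintf("%s (fgSRL %s%s)\n  rules: %s\n", x$modality,
              x$fgsrl_dose_level,
              if (x$pegv_dose > 0) sprintf(", PEGV %.1f mg/kg/wk", x$pegv_dose) else "",
              paste(x$rationale, collapse = " -> ")),
      sep = "")
  invisible(x)
}

#' Personalized first-line treatment assignment
#'
#' Naive branch (by sAOT, T2 signal and sinus invasion):
#' \itemize{
#'   \item sAOT `RESPONDER` (GH_2h < 2.7 ng/mL): fgSRL monotherapy at medium
#'     dose — predicted fgSRL-responsive.
#'   \item `PARTIAL_RESPONDER` with a T2-hypointense tumor: fgSRLs +
#'     pegvisomant.
#'   \item Otherwise (predicted fgSRL-non-responsive, i.e. `NON_RESPONDER`,
#'     or `PARTIAL_RESPONDER` without T2 hypointensity): pegvisomant
#'     monotherapy — unless the MRI shows cavernous sinus invasion, in which
#'     case fgSRLs + pegvisomant (the tumor-directed component is retained
#'     for invasive tumors).
#' }
#' Postsurgical branch: E-cadherin positive tumors get fgSRL monotherapy,
#' negative get pegvisomant monotherapy; when immunostaining was not
#' feasible the naive (presurgical) branch applies.
#'
#' The returned `rationale` lists, in order, the rule identifiers that fired,
#' and replays deterministically.
#'
#' @param patient A [patient_record()].
#' @param pegv_start Starting pegvisomant dose, mg/kg/week.
#' @return A `treatment_assignment`.
#' @export
assign_personalized <- function(patient, pegv_start = 0.5) {
  stopifnot(inherits(patient, "patient_record"))
  trace <- character(0)

  if (patient$surgical_status == "POSTSURGICAL") {
    trace <- c(trace, "postsurgical_branch")
    if (patient$ecadherin == "POSITIVE") {
      return(new_assignment("FGSRL_MONO", "medium", 0,
                            c(trace, "ecadherin_positive->fgSRL_mono")))
    }
    if (patient$ecadherin == "NEGATIVE") {
      return(new_assignment("PEGV_MONO", "none", pegv_start,
                            c(trace, "ecadherin_negative->pegv_mono")))
    }
    trace <- c(trace, "ecadherin_unavailable->presurgical_fallback")
  } else {
    trace <- c(trace, "naive_branch")
  }

  if (is.null(patient$saot)) {
    stop("missing biomarker: naive branch requires an sAOT result for patient ",
         patient$patient_id)
  }
  cls <- patient$saot$saot_class

  if (cls == "RESPONDER") {
    return(new_assignment("FGSRL_MONO", "medium", 0,
                          c(trace, "saot_responder->fgSRL_mono")))
  }
  if (cls == "PARTIAL_RESPONDER" &&
      !is.null(patient$geometry) &&
      patient$geometry$t2_class == "HYPOINTENSE") {
    return(new_assignment("FGSRL_PLUS_PEGV", "medium", pegv_start,
                          c(trace, "saot_partial+T2_hypointense->combo")))
  }
  # Predicted fgSRL-non-responsive: NON_RESPONDER, or PARTIAL_RESPONDER
  # lacking the T2 hypointensity required for the combination (inferred rule).
  trace <- c(trace,
             if (cls == "NON_RESPONDER") "saot_non_responder"
             else "saot_partial_without_T2_hypo(inferred_non_responder)")
  if (patient$cavernous_sinus_invasion) {
    return(new_assignment("FGSRL_PLUS_PEGV", "medium", pegv_start,
                          c(trace, "cavernous_sinus_invasion->combo")))
  }
  new_assignment("PEGV_MONO", "none", pegv_start,
                 c(trace, "no_sinus_invasion->pegv_mono"))
}

#' Standard (guideline) first-line treatment assignment
#'
#' fgSRL monotherapy at intermediate dose for every patient, regardless of
#' biomarkers; other modalities only after demonstrated failure, through the
#' titration machinery.
#'
#' @param patient A [patient_record()].
#' @return A `treatment_assignment`.
#' @export
assign_standard <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  new_assignment("FGSRL_MONO", "medium", 0, "standard_first_line_fgSRL")
}

#' Export the personalized decision table
#'
#' Enumerates the full cross-product of biomarker states and records the
#' modality assigned to each, for audit.
#'
#' @return Data frame: one row per biomarker state with the assigned
#'   modality and collapsed rationale.
#' @export
decision_table <- function() {
  grid <- expand.grid(
    surgical_status = c("NAIVE", "POSTSURGICAL"),
    saot_class = saot_classes,
    t2_class = c("HYPOINTENSE", "ISOINTENSE", "HYPERINTENSE"),
    sinus_invasion = c(FALSE, TRUE),
    ecadherin = c("POSITIVE", "NEGATIVE", "UNAVAILABLE"),
    stringsAsFactors = FALSE
  )
  grid <- grid[!(grid$surgical_status == "NAIVE" & grid$ecadherin != "UNAVAILABLE"), ]
  rownames(grid) <- NULL
  gh <- c(RESPONDER = 1.0, PARTIAL_RESPONDER = 10 * 0.4, NON_RESPONDER = 10 * 0.7)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    p <- patient_record(
      patient_id = sprintf("dt%03d", i), arm = "PERSONALIZED",
      surgical_status = g$surgical_status, age = 50, sex = "M", bmi = 27,
      baseline_gh = 10, baseline_igf1_sds = 5,
      saot = classify_saot(10, gh[[g$saot_class]]),
      geometry = tumor_geometry(15, 14, 13, t2_class = g$t2_class,
                                knosp_grade = if (g$sinus_invasion) 3L else 1L),
      cavernous_sinus_invasion = g$sinus_invasion,
      ecadherin = g$ecadherin
    )
    a <- assign_personalized(p)
    data.frame(modality = a$modality,
               rationale = paste(a$rationale, collapse = ";"))
  })
  cbind(grid, do.call(rbind, res))
}

# ---------------------------------------------------------------------------
# Titration state machine

#' Initialize a titration state
#'
#' @param assignment First-line [assign_personalized()]/[assign_standard()]
#'   result.
#' @param arm "PERSONALIZED" or "STANDARD".
#' @return List of class `titration_state`.
#' @export
titration_state <- function(assignment, arm) {
  arm <- match.arg(arm, c("PERSONALIZED", "STANDARD"))
  structure(
    list(visit_day = 0, assignment = assignment, arm = arm,
         igf1_sds_at_visit = NA_real_,
         controlled = FALSE, event_day = NA_real_,
         max_fgsrl_since = if (assignment$fgsrl_dose_level == "maximal") 0 else NA_real_,
         cabergoline = FALSE, ceiling_reached = FALSE,
         surgery_referral = FALSE,
         log = character(0)),
    class = "titration_state"
  )
}

#' Advance the titration state machine by one scheduled visit
#'
#' Visits fall on a 90-day grid up to the 365-day horizon. At each visit:
#' if IGF1-SDS has normalized (`<= normal_threshold`) the control event is
#' recorded and the state becomes a fixed point. If IGF1-SDS exceeds the
#' titration trigger (2.5 SDS) doses escalate in order: fgSRL medium ->
#' maximal; then, in the personalized arm, pegvisomant is added (if absent)
#' or up-titrated in 0.5 mg/kg/week steps to the ceiling; in the standard
#' arm, modality escalates (default to fgSRLs + pegvisomant) only after six
#' months at maximal fgSRL dose, then pegvisomant up-titrates. For minor
#' IGF-1 elevation (2.5-3 SDS) cabergoline 1 mg/week may be added to fgSRLs
#' with probability `cabergoline_prob` (default 0: deterministic engine).
#' Requests beyond the pegvisomant ceiling set `ceiling_reached` rather than
#' erroring.
#'
#' @param state A [titration_state()].
#' @param visit_day Day of this visit (multiple of `visit_interval`).
#' @param igf1_sds_at_visit IGF1-SDS measured at the visit.
#' @param normal_threshold SDS defining normalization (control), default 2.
#' @param titration_threshold SDS above which doses escalate, default 2.5.
#' @param cabergoline_upper Upper SDS of the minor-elevation window, default 3.
#' @param pegv_ceiling Maximal pegvisomant dose, mg/kg/week, default 1.5.
#' @param pegv_step Pegvisomant up-titration step, mg/kg/week.
#' @param standard_escalation_delay Days at maximal fgSRL dose before the
#'   standard arm escalates modality, default 180 (six months).
#' @param standard_escalation_modality Escalation policy hook for the
#'   standard arm.
#' @param cabergoline_prob Probability the optional cabergoline add-on is
#'   adopted in the 2.5-3 SDS window.
#' @param visit_interval Days between scheduled visits, default 90.
#' @return Updated `titration_state`.
#' @export
titrate <- function(state, visit_day, igf1_sds_at_visit,
                    normal_threshold = 2, titration_threshold = 2.5,
                    cabergoline_upper = 3,
                    pegv_ceiling = 1.5, pegv_step = 0.5,
                    standard_escalation_delay = 180,
                    standard_escalation_modality = "FGSRL_PLUS_PEGV",
                    cabergoline_prob = 0,
                    visit_interval = 90) {
  stopifnot(inherits(state, "titration_state"))
  if (visit_day %% visit_interval != 0 && visit_day != 365) {
    stop("visit_day must lie on the ", visit_interval, "-day grid")
  }
  if (state$controlled) return(state)  # fixed point once the event fired

  state$visit_day <- visit_day
  state$igf1_sds_at_visit <- igf1_sds_at_visit

  if (igf1_sds_at_visit <= normal_threshold) {
    state$controlled <- TRUE
    state$event_day <- visit_day
    state$log <- c(state$log, sprintf("d%d:normalized", visit_day))
    return(state)
  }

  a <- state$assignment
  if (igf1_sds_at_visit > titration_threshold) {
    if (a$fgsrl_dose_level == "medium") {
      a$fgsrl_dose_level <- "maximal"
      state$max_fgsrl_since <- visit_day
      state$log <- c(state$log, sprintf("d%d:fgSRL->maximal", visit_day))
    } else if (state$arm == "PERSONALIZED") {
      if (a$modality %in% c("FGSRL_MONO", "FGSRL_PLUS_CABERGOLINE")) {
        a$modality <- "FGSRL_PLUS_PEGV"
        a$pegv_dose <- pegv_step
        state$log <- c(state$log, sprintf("d%d:add_pegvisomant", visit_day))
      } else if (a$pegv_dose < pegv_ceiling) {
        a$pegv_dose <- min(pegv_ceiling, a$pegv_dose + pegv_step)
        state$log <- c(state$log, sprintf("d%d:pegv->%.1f", visit_day, a$pegv_dose))
      } else {
        state$ceiling_reached <- TRUE
        state$log <- c(state$log, sprintf("d%d:pegv_ceiling", visit_day))
      }
    } else {  # STANDARD arm
      if (a$modality %in% c("FGSRL_MONO", "FGSRL_PLUS_CABERGOLINE")) {
        if (!is.na(state$max_fgsrl_since) &&
            visit_day - state$max_fgsrl_since >= standard_escalation_delay) {
          a$modality <- standard_escalation_modality
          if (a$modality == "PEGV_MONO") a$fgsrl_dose_level <- "none"
          a$pegv_dose <- pegv_step
          state$log <- c(state$log,
                         sprintf("d%d:escalate->%s", visit_day, a$modality))
        } else {
          state$log <- c(state$log, sprintf("d%d:hold_full_dose", visit_day))
        }
      } else if (a$pegv_dose < pegv_ceiling) {
        a$pegv_dose <- min(pegv_ceiling, a$pegv_dose + pegv_step)
        state$log <- c(state$log, sprintf("d%d:pegv->%.1f", visit_day, a$pegv_dose))
      } else {
        state$ceiling_reached <- TRUE
        state$log <- c(state$log, sprintf("d%d:pegv_ceiling", visit_day))
      }
    }
  }

  if (igf1_sds_at_visit >= titration_threshold &&
      igf1_sds_at_visit <= cabergoline_upper &&
      a$modality %in% c("FGSRL_MONO", "FGSRL_PLUS_CABERGOLINE") &&
      cabergoline_prob > 0 && stats::runif(1) < cabergoline_prob) {
    a$modality <- "FGSRL_PLUS_CABERGOLINE"
    state$cabergoline <- TRUE
    state$log <- c(state$log, sprintf("d%d:add_cabergoline", visit_day))
  }

  state$assignment <- a
  state
}

#' Run the titration machine over a visit schedule
#'
#' @param assignment First-line assignment.
#' @param arm Trial arm.
#' @param visit_days Scheduled visit days (e.g. `c(90, 180, 270, 365)`).
#' @param igf1_sds IGF1-SDS measured at each visit (same length).
#' @param ... Passed to [titrate()].
#' @return Final `titration_state`; if control was never achieved,
#'   `surgery_referral` is set (end-of-study failure).
#' @export
simulate_titration <- function(assignment, arm, visit_days, igf1_sds, ...) {
  stopifnot(length(visit_days) == length(igf1_sds))
  state <- titration_state(assignment, arm)
  for (k in seq_along(visit_days)) {
    state <- titrate(state, visit_days[k], igf1_sds[k], ...)
    if (state$controlled) break
  }
  if (!state$controlled) state$surgery_referral <- TRUE
  state
}
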
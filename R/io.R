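# Cohort file I/O and the end-to-end pipeline.
#
# Dialect: comma-separated UTF-8 with a header row; provenance (package
# version, seed, config hash) in leading "#" comment lines; missing values
# as empty fields.

# FNV-1a over the deparsed config: a stable short provenance hash with no
# external dependency.
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "igf1_ref")]),
               collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

cohort_header <- function(cohort) {
  c(sprintf("# acropred %s", as.character(utils::packageVersion("acropred"))),
    sprintf("# seed: %d", cohort$seed),
    sprintf("# config: %s", config_hash(cohort$config)))
}

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `visits.csv` and `truth.csv` into `dir`, each with
#' a provenance comment header (package version, generating seed, config
#' hash).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- cohort_header(cohort)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "truth.csv"))
  tabs <- list(cohort$patients, cohort$visits, cohort$truth)
  for (k in seq_along(paths)) {
    con <- file(paths[k], "w", encoding = "UTF-8")
    writeLines(hdr, con)
    utils::write.csv(tabs[[k]], con, row.names = FALSE, na = "")
    close(con)
  }
  invisible(paths)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates units on read: GH and IGF-1 concentrations must be
#' non-negative, visit days must lie on the visit grid, and every visit row
#' must belong to a patient. Unknown columns are preserved.
#'
#' @param dir Directory containing `patients.csv` and `visits.csv` (and
#'   optionally `truth.csv`).
#' @param visit_interval Grid spacing for visit-day validation, default 90.
#' @return List with `patients`, `visits` and (if present) `truth`.
#' @export
read_cohort <- function(dir, visit_interval = 90) {
  p_path <- file.path(dir, "patients.csv")
  v_path <- file.path(dir, "visits.csv")
  if (!file.exists(p_path)) stop("no patients.csv under ", dir)
  patients <- utils::read.csv(p_path, comment.char = "#",
                              stringsAsFactors = FALSE)
  if (nrow(patients) == 0L) stop("empty cohort: no patient rows")
  for (col in c("gh_basal", "gh_2h", "baseline_igf1")) {
    if (col %in% names(patients)) {
      bad <- which(!is.na(patients[[col]]) & patients[[col]] < 0)
      if (length(bad)) {
        stop(sprintf("validation error: negative %s in patient row %d",
                     col, bad[1]))
      }
    }
  }
  visits <- NULL
  if (file.exists(v_path)) {
    visits <- utils::read.csv(v_path, comment.char = "#",
                              stringsAsFactors = FALSE)
    orphan <- setdiff(visits$patient_id, patients$patient_id)
    if (length(orphan)) {
      stop("visit rows reference unknown patients: ",
           paste(utils::head(orphan, 3), collapse = ", "))
    }
    off <- visits$day[visits$day %% visit_interval != 0 & visits$day != 365]
    if (length(off)) stop("visit days off the grid: ",
                          paste(utils::head(off, 3), collapse = ", "))
  }
  out <- list(patients = patients, visits = visits)
  t_path <- file.path(dir, "truth.csv")
  if (file.exists(t_path)) {
    out$truth <- utils::read.csv(t_path, comment.char = "#",
                                 stringsAsFactors = FALSE)
  }
  out
}

#' Run the full pipeline: generate, assign, titrate, classify, analyze
#'
#' Generates a synthetic cohort (assignment engines run inside the
#' generator), replays the titration state machine over each patient's
#' visit trajectory, classifies outcomes, and assembles the endpoint
#' summary. Fully deterministic given `seed`: stage seeds are derived from
#' the root seed so stages are independently re-runnable.
#'
#' @param config A [cohort_config()].
#' @param seed Root seed.
#' @param out_dir Optional directory; when given, cohort CSVs and a
#'   key-value report file are written there.
#' @return List of class `pipeline_run`: `cohort`, `outcomes`, `titration`
#'   (final state per patient), `result` (a `trial_result`).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  seeds <- derive_seeds(seed, c("generate", "analyze"))

  cohort <- generate_cohort(config, seed = seeds[["generate"]])
  patients <- cohort$patients

  titration <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    v <- cohort$visits[cohort$visits$patient_id == pid, ]
    a <- new_assignment(patients$modality[i], patients$fgsrl_dose_level[i],
                        patients$pegv_dose[i],
                        strsplit(patients$rationale[i], ";", fixed = TRUE)[[1]])
    simulate_titration(a, patients$arm[i], v$day, v$igf1_sds,
                       normal_threshold = config$normal_threshold,
                       titration_threshold = config$titration_threshold)
  })
  names(titration) <- patients$patient_id

  outcomes <- classify_outcomes(patients, cohort$visits,
                                normal_threshold = config$normal_threshold,
                                horizon = config$horizon)
  result <- trial_result(patients, outcomes, auc_seed = seeds[["analyze"]])

  run <- structure(list(cohort = cohort, outcomes = outcomes,
                        titration = titration, result = result,
                        seed = seed),
                   class = "pipeline_run")
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    write_report(run, file.path(out_dir, "report.txt"))
  }
  run
}

# independent per-stage seeds below 2^31, derived from the root seed
derive_seeds <- function(seed, stages) {
  s <- (as.numeric(seed) * 48271 + seq_along(stages) * 16807) %% 2147483647
  stats::setNames(as.integer(pmax(s, 1)), stages)
}

#' Write a key-value endpoint report
#'
#' @param run A [run_pipeline()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(run, path) {
  r <- run$result
  lines <- c(
    sprintf("seed\t%d", run$seed),
    sprintf("n_personalized\t%d", r$per_arm$PERSONALIZED$n),
    sprintf("n_standard\t%d", r$per_arm$STANDARD$n),
    sprintf("controlled_personalized\t%d", r$per_arm$PERSONALIZED$n_controlled),
    sprintf("controlled_standard\t%d", r$per_arm$STANDARD$n_controlled),
    sprintf("prop_personalized\t%.6f", r$per_arm$PERSONALIZED$proportion),
    sprintf("prop_standard\t%.6f", r$per_arm$STANDARD$proportion),
    sprintf("fisher_p\t%.6g", r$fisher_p),
    sprintf("hazard_ratio\t%.6f", r$hazard_ratio),
    sprintf("hr_conf_low\t%.6f", r$hr_conf[1]),
    sprintf("hr_conf_high\t%.6f", r$hr_conf[2]),
    sprintf("ttc_median_personalized\t%g", r$per_arm$PERSONALIZED$ttc_quartiles[2]),
    sprintf("ttc_median_standard\t%g", r$per_arm$STANDARD$ttc_quartiles[2])
  )
  if (!is.null(r$auc)) {
    lines <- c(lines, sprintf("auc_gh2h\t%.6f", r$auc$auc))
  }
  writeLines(lines, path)
  invisible(path)
}
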
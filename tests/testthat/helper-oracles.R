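# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (enumeration, hand formula, grid search) kept separate from
# the package implementation it checks.

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins: sum probabilities no larger than the observed
# table's (with a relative fudge for floating-point ties, as in fisher.test).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand-coded personalized decision table, written independently as plain
# nested conditions (not a transcription of the engine's code path).
oracle_assign <- function(surgical_status, saot_class, t2_class,
                          sinus_invasion, ecadherin) {
  if (surgical_status == "POSTSURGICAL" && ecadherin == "POSITIVE") {
    return("FGSRL_MONO")
  }
  if (surgical_status == "POSTSURGICAL" && ecadherin == "NEGATIVE") {
    return("PEGV_MONO")
  }
  # naive, or postsurgical without tissue -> presurgical rules
  if (saot_class == "RESPONDER") return("FGSRL_MONO")
  if (saot_class == "PARTIAL_RESPONDER" && t2_class == "HYPOINTENSE") {
    return("FGSRL_PLUS_PEGV")
  }
  # predicted non-responder to fgSRLs
  if (sinus_invasion) "FGSRL_PLUS_PEGV" else "PEGV_MONO"
}

# AUC by exhaustive pair counting: concordant pairs (controlled patient has
# the lower score) count 1, ties 1/2.
oracle_auc_pairs <- function(score, controlled) {
  pos <- score[controlled]
  neg <- score[!controlled]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Breslow partial log-likelihood for a single covariate, evaluated directly.
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(sort(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + beta * sum(x[d]) - length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# Small deterministic patient-record factory for engine tests.
make_patient <- function(surgical_status = "NAIVE", gh_basal = 10,
                         gh_2h = 1.0, t2_class = "ISOINTENSE",
                         sinus_invasion = FALSE, ecadherin = "UNAVAILABLE",
                         arm = "PERSONALIZED", saot = TRUE) {
  patient_record(
    patient_id = "T001", arm = arm, surgical_status = surgical_status,
    age = 50, sex = "M", bmi = 27, baseline_gh = gh_basal,
    baseline_igf1_sds = 6,
    saot = if (saot) classify_saot(gh_basal, gh_2h) else NULL,
    geometry = tumor_geometry(15, 12, 11, t2_class = t2_class,
                              knosp_grade = if (sinus_invasion) 3L else 1L),
    cavernous_sinus_invasion = sinus_invasion,
    ecadherin = ecadherin
  )
}
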
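# Treatment-assignment engines and the titration state machine.

test_that("personalized assignment follows the published branch structure", {
  # naive responder -> fgSRL monotherapy
  a <- assign_personalized(make_patient(gh_2h = 1.3))
  expect_identical(a$modality, "FGSRL_MONO")
  expect_identical(a$fgsrl_dose_level, "medium")
  # partial responder + T2 hypointense -> combination
  a <- assign_personalized(make_patient(gh_2h = 5, gh_basal = 20,
                                        t2_class = "HYPOINTENSE"))
  expect_identical(a$modality, "FGSRL_PLUS_PEGV")
  expect_equal(a$pegv_dose, 0.5)
  # non-responder with sinus invasion -> combination (override)
  a <- assign_personalized(make_patient(gh_2h = 5, gh_basal = 7,
                                        sinus_invasion = TRUE))
  expect_identical(a$modality, "FGSRL_PLUS_PEGV")
  # non-responder without invasion -> pegvisomant monotherapy
  a <- assign_personalized(make_patient(gh_2h = 5, gh_basal = 7))
  expect_identical(a$modality, "PEGV_MONO")
  expect_identical(a$fgsrl_dose_level, "none")
  # postsurgical by E-cadherin
  expect_identical(
    assign_personalized(make_patient("POSTSURGICAL", ecadherin = "NEGATIVE"))$modality,
    "PEGV_MONO")
  expect_identical(
    assign_personalized(make_patient("POSTSURGICAL", gh_2h = 9,
                                     ecadherin = "POSITIVE"))$modality,
    "FGSRL_MONO")
  # postsurgical without tissue falls back to the presurgical rules
  a <- assign_personalized(make_patient("POSTSURGICAL", gh_2h = 1.0,
                                        ecadherin = "UNAVAILABLE"))
  expect_identical(a$modality, "FGSRL_MONO")
  expect_true(any(grepl("presurgical_fallback", a$rationale)))
})

test_that("personalized assignment matches the hand-coded decision table", {
  dt <- decision_table()
  expect_lt(nrow(dt), 100)
  t0 <- Sys.time()
  for (i in seq_len(nrow(dt))) {
    expect_identical(
      dt$modality[i],
      oracle_assign(dt$surgical_status[i], dt$saot_class[i], dt$t2_class[i],
                    dt$sinus_invasion[i], dt$ecadherin[i]),
      info = paste(dt[i, 1:5], collapse = "/"))
  }
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})

test_that("assignments are deterministic with a non-empty replayable rationale", {
  p <- make_patient(gh_2h = 5, gh_basal = 20, t2_class = "HYPERINTENSE")
  a1 <- assign_personalized(p)
  a2 <- assign_personalized(p)
  expect_identical(a1, a2)
  expect_gte(length(a1$rationale), 1)
  # the inferred partial-without-hypointensity rule is traceable
  expect_true(any(grepl("inferred", a1$rationale)))
})

test_that("standard assignment is constant regardless of biomarkers", {
  ps <- list(make_patient(arm = "STANDARD"),
             make_patient("POSTSURGICAL", arm = "STANDARD", ecadherin = "NEGATIVE"),
             make_patient(arm = "STANDARD", gh_2h = 9, gh_basal = 10),
             make_patient(arm = "STANDARD", saot = FALSE))
  for (p in ps) {
    a <- assign_standard(p)
    expect_identical(a$modality, "FGSRL_MONO")
    expect_identical(a$fgsrl_dose_level, "medium")
  }
})

test_that("naive patients without an sAOT cannot be assigned", {
  expect_error(assign_personalized(make_patient(saot = FALSE)),
               "missing biomarker")
})

test_that("titration escalates fgSRL dose then adds/up-titrates pegvisomant", {
  a <- assign_standard(make_patient(arm = "STANDARD"))
  s <- titration_state(a, "STANDARD")
  s <- titrate(s, 90, 4.0)
  expect_identical(s$assignment$fgsrl_dose_level, "maximal")
  # holds full dose until six months at maximal, then escalates modality
  s <- titrate(s, 180, 4.0)
  expect_identical(s$assignment$modality, "FGSRL_MONO")
  s <- titrate(s, 270, 4.0)
  expect_identical(s$assignment$modality, "FGSRL_PLUS_PEGV")
  expect_equal(s$assignment$pegv_dose, 0.5)
  s <- titrate(s, 365, 4.0)
  expect_equal(s$assignment$pegv_dose, 1.0)
})

test_that("normalized IGF1-SDS freezes the state and records the event", {
  a <- assign_personalized(make_patient(gh_2h = 1.0))
  s <- titration_state(a, "PERSONALIZED")
  s <- titrate(s, 90, 1.0)
  expect_true(s$controlled)
  expect_equal(s$event_day, 90)
  frozen <- titrate(s, 180, 9.9)
  expect_identical(frozen, s)
})

test_that("personalized fgSRL failures add pegvisomant up to the ceiling", {
  a <- assign_personalized(make_patient(gh_2h = 1.0))  # FGSRL_MONO medium
  s <- titration_state(a, "PERSONALIZED")
  s <- titrate(s, 90, 5)    # -> maximal fgSRL
  s <- titrate(s, 180, 5)   # -> add pegvisomant
  expect_identical(s$assignment$modality, "FGSRL_PLUS_PEGV")
  s <- titrate(s, 270, 5)   # 1.0
  s <- titrate(s, 365, 5)   # 1.5 (ceiling)
  expect_equal(s$assignment$pegv_dose, 1.5)
  expect_false(s$ceiling_reached)
  s2 <- titrate(s, 365, 5)
  expect_true(s2$ceiling_reached)
})

test_that("dose levels never decrease while uncontrolled", {
  lv <- c(none = 0, medium = 1, maximal = 2)
  set.seed(11)
  for (rep in 1:20) {
    a <- assign_personalized(make_patient(gh_2h = runif(1, 0.2, 8),
                                          gh_basal = runif(1, 5, 20)))
    s <- titration_state(a, "PERSONALIZED")
    prev_f <- lv[[s$assignment$fgsrl_dose_level]]
    prev_p <- s$assignment$pegv_dose
    for (d in c(90, 180, 270, 365)) {
      s <- titrate(s, d, runif(1, 2.2, 6))
      f <- lv[[s$assignment$fgsrl_dose_level]]
      expect_gte(f, prev_f)
      expect_gte(s$assignment$pegv_dose, prev_p)
      prev_f <- f; prev_p <- s$assignment$pegv_dose
    }
  }
})

test_that("off-grid visits are rejected", {
  s <- titration_state(assign_standard(make_patient(arm = "STANDARD")), "STANDARD")
  expect_error(titrate(s, 100, 3), "grid")
})

test_that("simulate_titration flags end-of-study failures for surgery referral", {
  a <- assign_standard(make_patient(arm = "STANDARD"))
  s <- simulate_titration(a, "STANDARD", c(90, 180, 270, 365), c(6, 5, 5, 4))
  expect_false(s$controlled)
  expect_true(s$surgery_referral)
  s <- simulate_titration(a, "STANDARD", c(90, 180, 270, 365), c(6, 1.5, 1.5, 1.5))
  expect_true(s$controlled)
  expect_equal(s$event_day, 180)
  expect_false(s$surgery_referral)
})
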
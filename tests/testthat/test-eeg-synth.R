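test_that("subject parameter draws are seed-reproducible and linked as specified", {
  pop <- erp_population()
  a <- draw_subject_params(pop, seed = 5)
  b <- draw_subject_params(pop, seed = 5)
  expect_identical(a, b)
  expect_named(a$amp$N1, c("SUCC_EMO", "SUCC_NEU", "UNSUCC_EMO", "UNSUCC_NEU"))
  expect_named(a$amp$Pe, c("EMO", "NEU"))

  # zero residual: the level regression is an exact linear identity
  pop0 <- erp_population(level_resid_sd = 0)
  n <- 24
  n1 <- p3 <- pe <- numeric(n)
  set.seed(6)
  for (i in seq_len(n)) {
    sp <- draw_subject_params(pop0)
    # pooled failed-stop level: condition-difference terms cancel in the mean
    n1[i] <- mean(sp$amp$N1[c("UNSUCC_EMO", "UNSUCC_NEU")])
    p3[i] <- mean(sp$amp$P3[c("UNSUCC_EMO", "UNSUCC_NEU")])
    pe[i] <- mean(sp$amp$Pe)
  }
  fit <- ols_regression_standardized(pe, cbind(N1 = n1, P3 = p3))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # back-transform the standardized betas to the raw scale: they must equal
  # the generating coefficients (scaled by the component level SDs) exactly
  raw_p3 <- fit$beta[["P3"]] * stats::sd(pe) / stats::sd(p3)
  raw_n1 <- fit$beta[["N1"]] * stats::sd(pe) / stats::sd(n1)
  expect_equal(raw_p3, 0.82 * pop0$pe$level_sd / pop0$p3$level_sd,
               tolerance = 1e-9)
  expect_equal(raw_n1, -0.22 * pop0$pe$level_sd / pop0$n1$level_sd,
               tolerance = 1e-9)
})

test_that("a noiseless stop epoch equals the analytic template sum", {
  cfg <- small_config()
  sess <- simulate_session(cfg, race_params(), seed = 31)
  sp <- make_subject_params(go_evoked = 0) # isolate the stop-locked components
  rec <- synthesize_session_eeg(sess, sp, zero_noise(), seed = 32)
  ep <- extract_epochs(rec, "stop")
  tpl <- default_templates()

  # response-locked components can bleed into the stop epoch on error trials;
  # pick a successful stop (no response) for the pure reconstruction
  t_ms <- ep$times
  succ <- which(ep$labels$trial_type == "SUCC")[1]
  lab <- ep$labels[succ, ]
  cell <- paste0("SUCC_", lab$condition)
  expected <- outer(tpl$N1$topography,
                    gauss_at(t_ms, sp$amp$N1[[cell]], sp$lat$N1, tpl$N1$fwhm_ms)) +
    outer(tpl$P3$topography,
          gauss_at(t_ms, sp$amp$P3[[cell]], sp$lat$P3[[lab$condition]],
                   tpl$P3$fwhm_ms))
  bsel <- ep$samples >= ms_to_sample(-100, 256) & ep$samples <= ms_to_sample(0, 256)
  expected <- expected - rowMeans(expected[, bsel, drop = FALSE])
  got <- ep$data[succ, , ]
  # generator truncates kernels at +/- 2 FWHM; agreement to that truncation
  expect_lt(max(abs(got - expected)), 1e-3)
})

test_that("hit trials carry no error components and successful stops no response", {
  sess <- simulate_session(small_config(), race_params(), seed = 41)
  sp <- make_subject_params(go_evoked = 0)
  rec <- synthesize_session_eeg(sess, sp, zero_noise(), seed = 42)
  succ_idx <- sess$trials$trial_index[sess$trials$outcome == "SUCC_STOP"]
  resp_ev <- rec$events[rec$events$code == "RESPONSE", ]
  expect_false(any(resp_ev$trial_index %in% succ_idx))

  ep <- extract_epochs(rec, "response")
  hit <- subset_epochs(ep, ep$labels$trial_type == "HIT")
  # with the go wave off and zero noise, hit response epochs are silent except
  # possible stop-component bleed, which cannot occur on go trials
  expect_lt(max(abs(hit$data)), 1e-9)
  err <- subset_epochs(ep, ep$labels$trial_type == "ERROR")
  expect_gt(max(abs(err$data)), 1)
})

test_that("scores are linear in the planted amplitudes with noise off", {
  sess <- simulate_session(small_config(), race_params(), seed = 51)
  sp1 <- make_subject_params()
  sp2 <- make_subject_params(n1 = 2 * sp1$amp$N1, p3 = 2 * sp1$amp$P3,
                             ern = 2 * sp1$amp$ERN, pe = 2 * sp1$amp$Pe,
                             go_evoked = 2 * sp1$amp$GoEvoked)
  comps <- default_component_definitions()
  score <- function(sp) {
    rec <- synthesize_session_eeg(sess, sp, zero_noise(), seed = 52)
    ep <- extract_epochs(rec, "stop")
    un <- average_by_ssd_equal_weight(
      subset_epochs(ep, ep$labels$trial_type == "UNSUCC"))
    re <- extract_epochs(rec, "response")
    er <- average_epochs(subset_epochs(re, re$labels$trial_type == "ERROR"))
    c(mean_amplitude(un, comps$N1), mean_amplitude(un, comps$P3),
      mean_amplitude(er, comps$ERN), mean_amplitude(er, comps$Pe))
  }
  expect_equal(score(sp2), 2 * score(sp1), tolerance = 1e-9)
})

test_that("planted P3 latency difference between conditions is recovered", {
  sess <- simulate_session(session_config(), race_params(), seed = 61)
  # go wave and error components off: a pure read-out of the planted P3 peaks
  sp <- make_subject_params(go_evoked = 0, ern = c(EMO = 0, NEU = 0),
                            pe = c(EMO = 0, NEU = 0),
                            p3_lat = c(EMO = 337.4, NEU = 368.7))
  rec <- synthesize_session_eeg(sess, sp, zero_noise(), seed = 62)
  ep <- extract_epochs(rec, "stop")
  comps <- default_component_definitions()
  lat <- vapply(c("EMO", "NEU"), function(cond) {
    sub <- subset_epochs(ep, ep$labels$trial_type == "UNSUCC" &
                           ep$labels$condition == cond)
    peak_latency(average_by_ssd_equal_weight(sub), comps$P3)
  }, numeric(1))
  period <- 1000 / 256
  expect_lt(abs(lat[["EMO"]] - 337.4), period)
  expect_lt(abs(lat[["NEU"]] - 368.7), period)
  expect_lt(abs((lat[["NEU"]] - lat[["EMO"]]) - 31.3), period)
})

test_that("injected artifacts are rejected at close to the nominal rate", {
  sess <- simulate_session(session_config(), race_params(), seed = 71)
  sp <- make_subject_params()
  noise <- noise_config(white_sd_uV = 1, pink_sd_uV = 2,
                        artifact_probability = 0.06)
  rej <- numeric(3)
  tot <- numeric(3)
  for (r in 1:3) {
    rec <- synthesize_session_eeg(sess, sp, noise, seed = 100 + r)
    res <- reject_artifacts(extract_epochs(rec, "stop"))
    rej[r] <- sum(res$log$rejected)
    tot[r] <- nrow(res$log)
  }
  rate <- sum(rej) / sum(tot)
  # 300 stop epochs: binomial 99.9% interval around 0.06 is about +/- 0.045
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.105)
})
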
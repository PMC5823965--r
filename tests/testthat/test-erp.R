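test_that("stop-locked epochs have the mapped sample count and zero baseline", {
  sess <- simulate_session(small_config(), race_params(), seed = 3)
  sp <- make_subject_params()
  rec <- synthesize_session_eeg(sess, sp, noise_config(), seed = 5)
  ep <- extract_epochs(rec, "stop")
  # -100..700 ms at 256 Hz: samples round(-25.6)..round(179.2) = -26..179
  expect_equal(ep$samples[1], -26L)
  expect_equal(ep$samples[length(ep$samples)], 179L)
  expect_equal(length(ep$samples), 206L)
  expect_equal(n_epochs(ep), sum(sess$trials$is_stop))
  # per-channel baseline mean is zero after correction
  bsel <- which(ep$samples >= -26 & ep$samples <= 0)
  bl <- apply(ep$data[, , bsel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # labels carry the staircase SSDs and trial types
  expect_true(all(ep$labels$ssd %in% seq(100, 400, 50)))
  expect_setequal(unique(ep$labels$trial_type), c("SUCC", "UNSUCC"))
})

test_that("events too close to a recording edge are skipped with a warning", {
  ch <- eeg_channels()
  data <- matrix(0, length(ch), 400, dimnames = list(ch, NULL))
  trials <- data.frame(trial_index = 1:2, is_stop = TRUE,
                       condition = c("EMO", "NEU"), ssd = c(150, 150),
                       outcome = c("SUCC_STOP", "SUCC_STOP"),
                       go_rt = NA_real_, stringsAsFactors = FALSE)
  events <- data.frame(sample = c(3L, 200L), code = c("STOP_EMO", "STOP_NEU"),
                       trial_index = 1:2, stringsAsFactors = FALSE)
  rec <- make_recording(data, events, trials)
  expect_warning(ep <- extract_epochs(rec, "stop", window_ms = c(-100, 700)),
                 "skipped")
  expect_equal(n_epochs(ep), 1L)
  expect_equal(ep$labels$trial_index, 2L)
  # all events unusable -> error
  rec$events <- events[1, , drop = FALSE]
  expect_warning(expect_error(extract_epochs(rec, "stop"), "zero extractable"))
})

test_that("amplitude rejection is strict at the threshold, conserving and idempotent", {
  set.seed(9)
  n <- 12
  dat <- array(stats::rnorm(n * 2 * 20, 0, 5), dim = c(n, 2, 20))
  dat[3, 1, 7] <- 70     # above +65: rejected
  dat[5, 2, 2] <- -70    # below -65: rejected
  dat[8, 1, 1] <- 65     # exactly 65: kept (strict inequality)
  dat[1, , ] <- pmin(pmax(dat[1, , ], -64), 64)
  ep <- epoch_set(dat, 0:19, c("Cz", "Pz"),
                  data.frame(trial_index = 1:n, ssd = 150), "stop", 256)
  res <- reject_artifacts(ep)
  expect_equal(nrow(res$log), n)
  expect_equal(n_epochs(res$kept) + sum(res$log$rejected), n)
  expect_true(all(res$log$rejected[c(3, 5)]))
  expect_false(res$log$rejected[8])
  expect_false(res$log$rejected[1])
  # idempotent
  res2 <- reject_artifacts(res$kept)
  expect_equal(n_epochs(res2$kept), n_epochs(res$kept))
  expect_false(any(res2$log$rejected))
  expect_error(reject_artifacts(ep, threshold_uV = 0))
})

test_that("per-SSD collapsing weights bins equally, not by epoch count", {
  # 30 epochs at 2 uV in one bin, 10 at 4 uV in another
  dat <- array(0, dim = c(40, 1, 4))
  dat[1:30, , ] <- 2
  dat[31:40, , ] <- 4
  ep <- epoch_set(dat, 0:3, "Cz",
                  data.frame(ssd = rep(c(100, 200), c(30, 10))), "stop", 256)
  erp <- average_by_ssd_equal_weight(ep)
  expect_equal(unique(as.vector(erp$data)), 3)       # not the pooled 2.5
  expect_equal(as.vector(average_epochs(ep)$data), rep(2.5, 4))
  expect_equal(erp$bins$n, c(30L, 10L))

  # single qualifying bin: result equals that bin's subaverage
  erp1 <- average_by_ssd_equal_weight(ep, min_per_bin = 20)
  expect_equal(unique(as.vector(erp1$data)), 2)
  expect_error(average_by_ssd_equal_weight(ep, min_per_bin = 50), "min_per_bin")

  # duplicating every epoch within one bin leaves the collapsed result unchanged
  dat2 <- array(0, dim = c(70, 1, 4))
  dat2[1:60, , ] <- 2   # first bin duplicated
  dat2[61:70, , ] <- 4
  ep2 <- epoch_set(dat2, 0:3, "Cz",
                   data.frame(ssd = rep(c(100, 200), c(60, 10))), "stop", 256)
  expect_equal(average_by_ssd_equal_weight(ep2)$data, erp$data)
})

test_that("mean amplitude averages the cluster-window grid inclusively", {
  # 2 channels x 4 samples toy grid at 1000 Hz (1 sample per ms)
  grid <- rbind(Cz = 1:4, Pz = 5:8)
  erp <- erp_waveform(grid, 0:3, c("Cz", "Pz"), 1000, n_epochs = 1)
  full <- component_definition("toy", "stop", c(0, 3), c("Cz", "Pz"), +1)
  expect_equal(mean_amplitude(erp, full), 4.5)
  # scaling the waveform scales the score
  erp2 <- erp_waveform(3 * grid, 0:3, c("Cz", "Pz"), 1000, n_epochs = 1)
  expect_equal(mean_amplitude(erp2, full), 13.5)
  # constant waveform scores its constant
  erp3 <- erp_waveform(matrix(5, 2, 4, dimnames = list(c("Cz", "Pz"), NULL)),
                       0:3, c("Cz", "Pz"), 1000, n_epochs = 1)
  expect_equal(mean_amplitude(erp3, full), 5)
  missing <- component_definition("toy", "stop", c(0, 3), c("Cz", "Fz"), +1)
  expect_error(mean_amplitude(erp, missing), "missing")
})

test_that("peak latency finds the polarity-appropriate extremum, earliest on ties", {
  srate <- 256
  samples <- ms_to_sample(-100, srate):ms_to_sample(700, srate)
  t_ms <- samples * 1000 / srate
  pos <- matrix(gauss_at(t_ms, 10, 340, 120), nrow = 1,
                dimnames = list("Cz", NULL))
  erp <- erp_waveform(pos, samples, "Cz", srate, 1)
  p3 <- component_definition("P3", "stop", c(270, 400), "Cz", +1)
  expect_lt(abs(peak_latency(erp, p3) - 340), 1000 / srate)

  neg <- erp_waveform(-pos, samples, "Cz", srate, 1)
  n_def <- component_definition("neg", "stop", c(270, 400), "Cz", -1)
  expect_lt(abs(peak_latency(neg, n_def) - 340), 1000 / srate)

  flat <- erp_waveform(matrix(1, 1, length(samples),
                              dimnames = list("Cz", NULL)),
                       samples, "Cz", srate, 1)
  # documented tie rule: earliest sample of the mapped window
  expect_equal(peak_latency(flat, p3), ms_to_sample(270, srate) * 1000 / srate)
})

test_that("standard component definitions match the analysis windows and clusters", {
  comps <- default_component_definitions()
  expect_equal(comps$N1$window_ms, c(120, 190))
  expect_equal(comps$P3$window_ms, c(270, 400))
  expect_equal(comps$ERN$window_ms, c(0, 80))
  expect_equal(comps$Pe$window_ms, c(120, 270))
  expect_setequal(comps$N1$cluster, c("FC1", "FC2", "C3", "C4", "Cz", "CP1", "CP2"))
  expect_setequal(comps$P3$cluster, c("Cz", "CP1", "CP2", "P3", "P4", "Pz"))
  expect_setequal(comps$ERN$cluster,
                  c("F3", "F4", "Fz", "FC1", "FC2", "C3", "C4", "Cz"))
  expect_identical(comps$Pe$cluster, comps$P3$cluster)
  expect_true(all(vapply(comps, function(cp)
    all(cp$cluster %in% eeg_channels()), logical(1))))
})
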
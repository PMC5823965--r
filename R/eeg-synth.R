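#' The 32-channel montage used by the recordings
#'
#' Standard extended 10-20 sites of a 32-electrode active cap.
#' @return character vector of 32 channel names.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8",
    "FC1", "FC2", "FC5", "FC6", "T7", "T8", "C3", "C4",
    "CP1", "CP2", "CP5", "CP6", "P3", "P4", "P7", "P8",
    "PO3", "PO4", "O1", "O2", "Fz", "Cz", "Pz", "Oz")
}

# two-level scalp weight map: 1 over the component's analysis cluster,
# a small baseline elsewhere (no forward head model)
topography_map <- function(cluster, baseline = 0.25) {
  ch <- eeg_channels()
  bad <- setdiff(cluster, ch)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))
  w <- stats::setNames(rep(baseline, length(ch)), ch)
  w[cluster] <- 1
  w
}

#' Component wave-shape templates used by the EEG generator
#'
#' Each planted component is a Gaussian bump in time (parameterized by peak
#' latency and full width at half maximum) scaled by a fixed scalp weight map
#' that is maximal over the component's analysis cluster. Peak latencies and
#' amplitudes are supplied per subject by \code{\link{draw_subject_params}};
#' the templates fix the lock event, shape and topography.
#'
#' @return a named list of templates (\code{GoEvoked}, \code{N1}, \code{P3},
#'   \code{ERN}, \code{Pe}), each with fields \code{lock}
#'   (\code{"go"}/\code{"stop"}/\code{"response"}), \code{fwhm_ms},
#'   \code{polarity} and \code{topography}.
#' @export
default_templates <- function() {
  list(
    GoEvoked = list(lock = "go", peak_ms = 250, fwhm_ms = 250, polarity = +1,
                    topography = topography_map(
                      c("FC1", "FC2", "Cz", "C3", "C4", "CP1", "CP2",
                        "Pz", "P3", "P4"), baseline = 0.35)),
    N1 = list(lock = "stop", fwhm_ms = 70, polarity = -1,
              topography = topography_map(
                c("FC1", "FC2", "C3", "C4", "Cz", "CP1", "CP2"))),
    P3 = list(lock = "stop", fwhm_ms = 130, polarity = +1,
              topography = topography_map(
                c("Cz", "CP1", "CP2", "P3", "P4", "Pz"))),
    ERN = list(lock = "response", fwhm_ms = 60, polarity = -1,
               topography = topography_map(
                 c("F3", "F4", "Fz", "FC1", "FC2", "C3", "C4", "Cz"))),
    Pe = list(lock = "response", fwhm_ms = 150, polarity = +1,
              topography = topography_map(
                c("Cz", "CP1", "CP2", "P3", "P4", "Pz")))
  )
}

#' Between-subject population of ERP generating parameters
#'
#' Cell means follow the amplitude pattern characteristic of emotional
#' stop-signal experiments: N1 and P3 larger (N1 more negative, P3 more
#' positive) for aversive than neutral stop signals and for successful than
#' failed stops; ERN comparable across error conditions; Pe larger after
#' aversive errors. Between-subject structure is split into a shared *level*
#' (driving the cross-subject regression of Pe on failed-stop N1 and P3) and
#' a *condition difference* (driving the regression of the emotional Pe
#' enhancement on the N1/P3 enhancements). Residual SDs are derived from the
#' linking betas and predictor correlation so that the generating R-squared
#' of the level model is about 0.66 and of the difference model about 0.32.
#'
#' @param level_beta_p3,level_beta_n1 standardized linking coefficients of the
#'   subject Pe level on the subject P3 and N1 levels.
#' @param level_predictor_r correlation between subject N1 and P3 levels.
#' @param diff_beta_p3,diff_beta_n1,diff_predictor_r same, for the
#'   condition-difference model.
#' @param level_resid_sd,diff_resid_sd residual SD of the standardized Pe
#'   level/difference; \code{NULL} derives them so the standardized generating
#'   model has unit variance (R-squared = beta' R beta).
#' @return an object of class \code{"erp_population"}.
#' @export
erp_population <- function(level_beta_p3 = 0.82, level_beta_n1 = -0.22,
                           level_predictor_r = 0.16,
                           diff_beta_p3 = 0.60, diff_beta_n1 = -0.22,
                           diff_predictor_r = 0.33,
                           level_resid_sd = NULL, diff_resid_sd = NULL) {
  r2 <- function(b1, b2, r) b1^2 + b2^2 + 2 * b1 * b2 * r
  lv_r2 <- r2(level_beta_p3, level_beta_n1, level_predictor_r)
  df_r2 <- r2(diff_beta_p3, diff_beta_n1, diff_predictor_r)
  if (is.null(level_resid_sd)) level_resid_sd <- sqrt(max(0, 1 - lv_r2))
  if (is.null(diff_resid_sd)) diff_resid_sd <- sqrt(max(0, 1 - df_r2))
  if (level_resid_sd < 0 || diff_resid_sd < 0)
    stop("residual SDs must be non-negative")
  structure(list(
    # microvolt cell means (stop-locked cells: trial type x condition)
    n1 = list(mean = c(SUCC_EMO = -6.1, SUCC_NEU = -5.1,
                       UNSUCC_EMO = -4.3, UNSUCC_NEU = -1.3),
              level_sd = 5, diff_sd = 2.5),
    p3 = list(mean = c(SUCC_EMO = 21.9, SUCC_NEU = 18.8,
                       UNSUCC_EMO = 20.0, UNSUCC_NEU = 13.6),
              level_sd = 6, diff_sd = 3),
    ern = list(mean = c(EMO = -4.1, NEU = -4.6), level_sd = 5, diff_sd = 2),
    pe = list(mean = c(EMO = 11.0, NEU = 6.4), level_sd = 5.5, diff_sd = 3),
    go_evoked = list(mean = 6, sd = 1.5),
    level_link = list(beta_p3 = level_beta_p3, beta_n1 = level_beta_n1,
                      predictor_r = level_predictor_r,
                      resid_sd = level_resid_sd, r2 = lv_r2),
    diff_link = list(beta_p3 = diff_beta_p3, beta_n1 = diff_beta_n1,
                     predictor_r = diff_predictor_r,
                     resid_sd = diff_resid_sd, r2 = df_r2),
    latency = list(
      n1_peak = 155, ern_peak = 40,
      p3 = list(mean = c(EMO = 337.4, NEU = 368.7),
                sd = c(EMO = 16.0, NEU = 17.1),
                ssrt_r = c(EMO = 0.60, NEU = 0.38)),
      pe = list(mean = c(EMO = 190.5, NEU = 217.9),
                sd = c(EMO = 27.0, NEU = 30.3),
                ssrt_r = c(EMO = -0.32, NEU = -0.25)))
  ), class = "erp_population")
}

bvn <- function(r) MASS::mvrnorm(1, c(0, 0), matrix(c(1, r, r, 1), 2))

#' Draw one participant's ERP generating parameters
#'
#' Subject-level standardized N1 and P3 levels are drawn from a bivariate
#' normal with the population predictor correlation; the subject Pe level is
#' their linear combination (linking betas) plus normal residual. The same
#' construction, with its own betas, yields the emotional-minus-neutral
#' condition differences. Cell amplitudes are the population cell means plus
#' \code{level_sd * level} plus \code{+/- diff_sd * diff / 2}. Peak latencies
#' of the failed-stop P3 and error Pe are tied to the subject's standardized
#' stopping speed via the population latency-SSRT correlations.
#'
#' @param population an \code{"erp_population"}.
#' @param stop_z named numeric (\code{EMO}, \code{NEU}): the subject's
#'   standardized stop-latency deviation per condition (0 = population mean);
#'   a single number is recycled to both conditions.
#' @param seed optional integer seed.
#' @return an object of class \code{"erp_subject_params"} with elements
#'   \code{amp} (per-component cell amplitudes, microvolts), \code{lat}
#'   (per-component peak latencies, ms) and \code{z} (the underlying
#'   standardized draws).
#' @export
draw_subject_params <- function(population, stop_z = c(EMO = 0, NEU = 0),
                                seed = NULL) {
  if (!inherits(population, "erp_population"))
    stop("population must be an erp_population")
  if (!is.null(seed)) set.seed(seed)
  if (length(stop_z) == 1L) stop_z <- c(EMO = unname(stop_z), NEU = unname(stop_z))
  p <- population

  lz <- bvn(p$level_link$predictor_r) # (N1, P3) levels
  z_n1 <- lz[1]; z_p3 <- lz[2]
  z_pe <- p$level_link$beta_p3 * z_p3 + p$level_link$beta_n1 * z_n1 +
    stats::rnorm(1, 0, p$level_link$resid_sd)
  dz <- bvn(p$diff_link$predictor_r)
  d_n1 <- dz[1]; d_p3 <- dz[2]
  d_pe <- p$diff_link$beta_p3 * d_p3 + p$diff_link$beta_n1 * d_n1 +
    stats::rnorm(1, 0, p$diff_link$resid_sd)
  z_ern <- stats::rnorm(1); d_ern <- stats::rnorm(1)

  cells4 <- function(spec, z, d) {
    half <- c(SUCC_EMO = 0.5, SUCC_NEU = -0.5,
              UNSUCC_EMO = 0.5, UNSUCC_NEU = -0.5)
    spec$mean + spec$level_sd * z + spec$diff_sd * d * half
  }
  cells2 <- function(spec, z, d) {
    spec$mean + spec$level_sd * z + spec$diff_sd * d * c(EMO = 0.5, NEU = -0.5)
  }
  amp <- list(
    N1 = cells4(p$n1, z_n1, d_n1),
    P3 = cells4(p$p3, z_p3, d_p3),
    ERN = cells2(p$ern, z_ern, d_ern),
    Pe = cells2(p$pe, z_pe, d_pe),
    GoEvoked = p$go_evoked$mean + p$go_evoked$sd * stats::rnorm(1))

  latdraw <- function(spec) {
    vapply(c("EMO", "NEU"), function(cond) {
      r <- spec$ssrt_r[[cond]]
      spec$mean[[cond]] + spec$sd[[cond]] *
        (r * stop_z[[cond]] + sqrt(max(0, 1 - r^2)) * stats::rnorm(1))
    }, numeric(1))
  }
  lat <- list(N1 = p$latency$n1_peak, ERN = p$latency$ern_peak,
              P3 = latdraw(p$latency$p3), Pe = latdraw(p$latency$pe))

  structure(list(amp = amp, lat = lat,
                 z = list(level = c(N1 = z_n1, P3 = z_p3, Pe = z_pe, ERN = z_ern),
                          diff = c(N1 = d_n1, P3 = d_p3, Pe = d_pe, ERN = d_ern))),
            class = "erp_subject_params")
}

#' Noise and artifact settings for the EEG generator
#'
#' Background activity is a mixture of 1/f ("pink") and white noise; large
#' transient artifacts (well above the rejection threshold) are injected on a
#' random fraction of trials to exercise artifact rejection.
#'
#' @param white_sd_uV SD of the white noise component (microvolts).
#' @param pink_sd_uV SD of the 1/f noise component (microvolts).
#' @param artifact_probability per-trial probability of an injected artifact.
#' @param artifact_amplitude_uV artifact magnitude; must exceed the 65-uV
#'   rejection threshold to be exercised.
#' @return an object of class \code{"eeg_noise_config"}.
#' @export
noise_config <- function(white_sd_uV = 1.5, pink_sd_uV = 3,
                         artifact_probability = 0.06,
                         artifact_amplitude_uV = 100) {
  if (white_sd_uV < 0 || pink_sd_uV < 0) stop("noise SDs must be >= 0")
  if (artifact_probability < 0 || artifact_probability > 1)
    stop("artifact_probability must lie in [0, 1]")
  if (artifact_probability > 0 && artifact_amplitude_uV <= 65)
    stop("artifact_amplitude_uV must exceed the 65-uV rejection threshold")
  structure(list(white_sd_uV = white_sd_uV, pink_sd_uV = pink_sd_uV,
                 artifact_probability = artifact_probability,
                 artifact_amplitude_uV = artifact_amplitude_uV),
            class = "eeg_noise_config")
}

# 1/f-amplitude noise by spectral shaping of white noise, rescaled to unit SD
pink_noise <- function(n, sd = 1) {
  if (sd == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # fold to two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  sd * (x - mean(x)) / stats::sd(x)
}

# Gaussian bump (peak amplitude `amp`, FWHM in ms): sample range and the
# channels x samples increment; the caller subset-adds it (avoids copying the
# full recording on every component)
gauss_bump <- function(n_total, topo, center_sample, amp, peak_ms, fwhm_ms,
                       srate) {
  half <- ceiling(2 * fwhm_ms * srate / 1000)
  peak_s <- center_sample + round(peak_ms * srate / 1000)
  ks <- (peak_s - half):(peak_s + half)
  ks <- ks[ks >= 1L & ks <= n_total]
  if (length(ks) == 0L) return(NULL)
  t_ms <- (ks - center_sample) * 1000 / srate
  g <- amp * exp(-4 * log(2) * ((t_ms - peak_ms) / fwhm_ms)^2)
  list(ks = ks, inc = outer(topo, g))
}

#' Synthesize one session's continuous 32-channel EEG
#'
#' Lays the session's trials end to end on a 256-Hz time axis (each trial is
#' fixation + response window long) and plants, per trial: a go-locked evoked
#' wave on every trial; stop-locked N1 and P3 bumps on stop trials with
#' cell-specific (trial type x condition) amplitude and condition-specific P3
#' peak latency; and response-locked ERN and Pe bumps on failed-stop (error)
#' trials only. Correct-response trials contain no error components and
#' successful stops carry no response marker. Pink and white background noise
#' and occasional suprathreshold artifacts are added on top. Event markers
#' are written at go onset, stop onset (condition-coded) and the response
#' sample.
#'
#' @param session an \code{"sst_session"}.
#' @param subject an \code{"erp_subject_params"}.
#' @param noise an \code{"eeg_noise_config"}.
#' @param templates component templates, see \code{\link{default_templates}}.
#' @param seed optional integer seed.
#' @return an object of class \code{"eeg_recording"}: list with
#'   \code{channels}, \code{srate} (Hz), \code{data} (channels x samples,
#'   microvolts), \code{events} (data.frame \code{sample}, \code{code},
#'   \code{trial_index}), \code{trials} (the session trial table) and
#'   \code{trial_samples}.
#' @export
synthesize_session_eeg <- function(session, subject,
                                   noise = noise_config(),
                                   templates = default_templates(),
                                   seed = NULL) {
  if (!inherits(session, "sst_session")) stop("session must be an sst_session")
  if (!inherits(subject, "erp_subject_params"))
    stop("subject must be an erp_subject_params")
  if (!is.null(seed)) set.seed(seed)
  srate <- 256
  ch <- eeg_channels()
  cfg <- session$config
  tr <- session$trials
  n_trials <- nrow(tr)
  trial_ms <- cfg$fixation_ms + cfg$response_deadline_ms
  spt <- round(trial_ms * srate / 1000)
  n_samp <- n_trials * spt + srate # 1-s tail so late epochs fit

  data <- matrix(0, nrow = length(ch), ncol = n_samp,
                 dimnames = list(ch, NULL))
  if (noise$pink_sd_uV > 0 || noise$white_sd_uV > 0) {
    for (c_i in seq_along(ch)) {
      v <- numeric(n_samp)
      if (noise$pink_sd_uV > 0) v <- v + pink_noise(n_samp, noise$pink_sd_uV)
      if (noise$white_sd_uV > 0) v <- v + stats::rnorm(n_samp, 0, noise$white_sd_uV)
      data[c_i, ] <- v
    }
  }

  ev_sample <- integer(0); ev_code <- character(0); ev_trial <- integer(0)
  push <- function(s, code, i) {
    ev_sample[[length(ev_sample) + 1L]] <<- as.integer(s)
    ev_code[[length(ev_code) + 1L]] <<- code
    ev_trial[[length(ev_trial) + 1L]] <<- i
  }

  fix_s <- round(cfg$fixation_ms * srate / 1000)
  # queue of planted bumps; applied in one pass to avoid repeated copies
  bumps <- list(tpl = list(), center = numeric(0), amp = numeric(0),
                peak = numeric(0))
  plant <- function(tpl, center, amp, peak_ms) {
    k <- length(bumps$tpl) + 1L
    bumps$tpl[[k]] <<- tpl
    bumps$center[k] <<- center
    bumps$amp[k] <<- amp
    bumps$peak[k] <<- peak_ms
  }
  for (i in seq_len(n_trials)) {
    t0 <- (i - 1L) * spt
    go_s <- t0 + fix_s + 1L # first sample at/after go onset (1-based)
    push(go_s, "GO", i)
    plant(templates$GoEvoked, go_s, subject$amp$GoEvoked,
          templates$GoEvoked$peak_ms)
    if (tr$is_stop[i]) {
      cond <- tr$condition[i]
      stop_s <- go_s + round(tr$ssd[i] * srate / 1000)
      push(stop_s, paste0("STOP_", cond), i)
      cell <- paste0(ifelse(tr$outcome[i] == "SUCC_STOP", "SUCC", "UNSUCC"),
                     "_", cond)
      plant(templates$N1, stop_s, subject$amp$N1[[cell]], subject$lat$N1)
      plant(templates$P3, stop_s, subject$amp$P3[[cell]],
            subject$lat$P3[[cond]])
    }
    if (!is.na(tr$go_rt[i])) {
      resp_s <- go_s + round(tr$go_rt[i] * srate / 1000)
      push(resp_s, "RESPONSE", i)
      if (tr$outcome[i] == "UNSUCC_STOP") {
        cond <- tr$condition[i]
        plant(templates$ERN, resp_s, subject$amp$ERN[[cond]],
              subject$lat$ERN)
        plant(templates$Pe, resp_s, subject$amp$Pe[[cond]],
              subject$lat$Pe[[cond]])
      }
    }
    if (noise$artifact_probability > 0 &&
        stats::runif(1) < noise$artifact_probability) {
      # artifacts land inside the trial's analysis segment (for stop trials,
      # within the stop-locked epoch span), so the nominal per-trial artifact
      # probability equals the expected rejected fraction of analysed epochs
      a_ch <- sample.int(length(ch), 1)
      width <- round(0.05 * srate)
      a_on <- if (tr$is_stop[i]) {
        go_s + round(tr$ssd[i] * srate / 1000) +
          sample.int(round(0.6 * srate), 1)
      } else {
        t0 + sample.int(spt - width, 1)
      }
      a_end <- min(a_on + width, n_samp)
      sgn <- sample(c(-1, 1), 1)
      data[a_ch, a_on:a_end] <- data[a_ch, a_on:a_end] +
        sgn * noise$artifact_amplitude_uV
    }
  }

  for (k in seq_along(bumps$tpl)) {
    b <- gauss_bump(n_samp, bumps$tpl[[k]]$topography, bumps$center[k],
                    bumps$amp[k], bumps$peak[k], bumps$tpl[[k]]$fwhm_ms,
                    srate)
    if (!is.null(b)) data[, b$ks] <- data[, b$ks] + b$inc
  }

  structure(list(channels = ch, srate = srate, data = data,
                 events = data.frame(sample = ev_sample, code = ev_code,
                                     trial_index = ev_trial,
                                     stringsAsFactors = FALSE),
                 trials = tr, trial_samples = spt),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", length(x$channels), "channels x", ncol(x$data),
      "samples @", x$srate, "Hz;", nrow(x$events), "events\n")
  invisible(x)
}
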
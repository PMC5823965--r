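# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# minimal trial table with only the columns the behavioural functions use
make_stop_trials <- function(conditions, ssds, outcomes) {
  k <- length(conditions)
  data.frame(trial_index = seq_len(k), block = 1L, arrow = "left",
             is_stop = TRUE, condition = conditions, sound_id = NA_integer_,
             ssd = ssds, go_rt = NA_real_, response = NA_character_,
             outcome = outcomes, stringsAsFactors = FALSE)
}

# hand-built subject ERP parameters (bypasses the population draw)
make_subject_params <- function(n1 = c(SUCC_EMO = -6, SUCC_NEU = -5,
                                       UNSUCC_EMO = -4, UNSUCC_NEU = -1.5),
                                p3 = c(SUCC_EMO = 22, SUCC_NEU = 19,
                                       UNSUCC_EMO = 20, UNSUCC_NEU = 14),
                                ern = c(EMO = -4, NEU = -4.5),
                                pe = c(EMO = 11, NEU = 6.5),
                                go_evoked = 6,
                                p3_lat = c(EMO = 337.4, NEU = 368.7),
                                pe_lat = c(EMO = 190.5, NEU = 217.9)) {
  structure(list(
    amp = list(N1 = n1, P3 = p3, ERN = ern, Pe = pe, GoEvoked = go_evoked),
    lat = list(N1 = 155, ERN = 40, P3 = p3_lat, Pe = pe_lat),
    z = list()), class = "erp_subject_params")
}

zero_noise <- function() noise_config(white_sd_uV = 0, pink_sd_uV = 0,
                                      artifact_probability = 0)

# small but balance-valid session design: 80 trials, 20 stop (10 per condition,
# 2 per sound, 1 per sound x arrow)
small_config <- function(...) session_config(n_blocks = 2, trials_per_block = 40, ...)

# independent Gaussian-bump evaluator (same parameterization the generator
# documents: peak amplitude, FWHM), used to compute analytic expectations
gauss_at <- function(t_ms, amp, peak_ms, fwhm_ms) {
  amp * exp(-4 * log(2) * ((t_ms - peak_ms) / fwhm_ms)^2)
}

# hand-built continuous recording for epoching edge cases
make_recording <- function(data, events, trials, srate = 256) {
  structure(list(channels = rownames(data), srate = srate, data = data,
                 events = events, trials = trials,
                 trial_samples = ncol(data)),
            class = "eeg_recording")
}
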
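#' Configuration of a stop-signal session
#'
#' Describes one session of the auditory stop-signal task: a primary
#' binary-choice (left/right arrow) go task with an auditory stop signal on a
#' fixed fraction of trials. The stop-signal delay (SSD) is controlled by a
#' one-up/one-down staircase shared between the two stop-signal conditions
#' (aversive "EMO" and neutral "NEU" sounds).
#'
#' The defaults reproduce the standard design: 8 blocks of 50 trials, 25%
#' stop trials, SSD staircase from 100 to 400 ms in 50-ms steps starting at
#' 150 ms, five sounds per condition each presented equally often with the
#' left and the right arrow.
#'
#' @param n_blocks number of experimental blocks.
#' @param trials_per_block trials per block.
#' @param stop_fraction fraction of trials carrying a stop signal.
#' @param ssd_min,ssd_max,ssd_step,ssd_init staircase lattice (ms): bounds,
#'   step size, and the SSD of the first stop trial.
#' @param n_sounds_per_condition distinct stop sounds per condition.
#' @param fixation_ms fixation-cross duration at trial start (ms).
#' @param go_duration_ms,stop_duration_ms stimulus durations (ms).
#' @param response_deadline_ms response window after go onset (ms); a response
#'   later than this counts as an omission. The trial ends (next fixation
#'   starts) at \code{fixation_ms + response_deadline_ms}.
#' @return an object of class \code{"sst_config"} (a validated list).
#' @examples
#' cfg <- session_config()
#' cfg$n_blocks * cfg$trials_per_block # 400 trials
#' @export
session_config <- function(n_blocks = 8L, trials_per_block = 50L,
                           stop_fraction = 0.25,
                           ssd_min = 100, ssd_max = 400, ssd_step = 50,
                           ssd_init = 150,
                           n_sounds_per_condition = 5L,
                           fixation_ms = 800, go_duration_ms = 100,
                           stop_duration_ms = 100,
                           response_deadline_ms = 1200) {
  cfg <- structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    stop_fraction = stop_fraction,
    ssd_min = ssd_min, ssd_max = ssd_max, ssd_step = ssd_step,
    ssd_init = ssd_init,
    n_sounds_per_condition = as.integer(n_sounds_per_condition),
    fixation_ms = fixation_ms, go_duration_ms = go_duration_ms,
    stop_duration_ms = stop_duration_ms,
    response_deadline_ms = response_deadline_ms
  ), class = "sst_config")
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  with(cfg, {
    if (n_blocks < 1L || trials_per_block < 1L)
      stop("n_blocks and trials_per_block must be positive")
    if (stop_fraction <= 0 || stop_fraction >= 1)
      stop("stop_fraction must lie strictly between 0 and 1")
    if (!(ssd_min <= ssd_init && ssd_init <= ssd_max))
      stop("ssd_init must lie within [ssd_min, ssd_max]")
    if (ssd_step <= 0) stop("ssd_step must be positive")
    k <- (ssd_max - ssd_min) / ssd_step
    if (abs(k - round(k)) > 1e-9)
      stop("(ssd_max - ssd_min) must be divisible by ssd_step")
    j <- (ssd_init - ssd_min) / ssd_step
    if (abs(j - round(j)) > 1e-9)
      stop("ssd_init must lie on the staircase lattice")
    n_trials <- n_blocks * trials_per_block
    n_stop <- stop_fraction * n_trials
    if (abs(n_stop - round(n_stop)) > 1e-9)
      stop("stop_fraction * total trials must be an integer")
    n_stop <- round(n_stop)
    if (n_stop %% 2L != 0L)
      stop("stop-trial count must be even (two equally frequent conditions)")
    per_cond <- n_stop / 2L
    if (per_cond %% n_sounds_per_condition != 0L)
      stop("per-condition stop-trial count must be divisible by the number of sounds")
    if ((per_cond / n_sounds_per_condition) %% 2L != 0L)
      stop("per-sound presentation count must be even (equal left/right arrow split)")
    if (response_deadline_ms <= 0) stop("response_deadline_ms must be positive")
    invisible(NULL)
  })
}

#' Number of trials and stop trials implied by a configuration
#' @param config an \code{"sst_config"} object.
#' @return a list with elements \code{n_trials}, \code{n_stop},
#'   \code{ssd_values} (the reachable SSD lattice).
#' @export
session_counts <- function(config) {
  n_trials <- config$n_blocks * config$trials_per_block
  list(n_trials = n_trials,
       n_stop = as.integer(round(config$stop_fraction * n_trials)),
       ssd_values = seq(config$ssd_min, config$ssd_max, by = config$ssd_step))
}

#' Race-model parameters for one simulated participant
#'
#' The go process finishes after an ex-Gaussian latency (normal with mean
#' \code{go_mu} and SD \code{go_sigma} plus an exponential tail with mean
#' \code{go_tau}). The stop process finishes \code{stop latency} ms after
#' stop-signal onset, drawn from a normal distribution (truncated at 1 ms)
#' whose mean depends on the stop-signal condition. A response is emitted on a
#' stop trial iff the go process finishes strictly before SSD + stop latency
#' (independent horse-race model; ties favour stopping).
#'
#' Defaults give a mean go RT near 375 ms and a 15-ms stopping advantage for
#' the aversive condition, the pattern the task is designed to probe.
#'
#' @param go_mu,go_sigma,go_tau ex-Gaussian go-RT parameters (ms).
#' @param stop_mean_emo,stop_mean_neu mean stop-process latency per condition (ms).
#' @param stop_sd trial-to-trial SD of the stop latency (ms).
#' @param p_go_omission probability of a missing go response.
#' @param p_go_error probability of a wrong-key go response.
#' @return an object of class \code{"sst_race_params"}.
#' @export
race_params <- function(go_mu = 330, go_sigma = 40, go_tau = 45,
                        stop_mean_emo = 202, stop_mean_neu = 217,
                        stop_sd = 30,
                        p_go_omission = 0, p_go_error = 0.016) {
  if (any(c(go_mu, go_sigma, go_tau) < 0) || go_mu <= 0)
    stop("go-RT parameters must be non-negative with go_mu > 0")
  if (stop_mean_emo <= 0 || stop_mean_neu <= 0 || stop_sd < 0)
    stop("stop latencies must be positive")
  if (p_go_omission < 0 || p_go_omission > 1 || p_go_error < 0 || p_go_error > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
                 stop_mean_emo = stop_mean_emo, stop_mean_neu = stop_mean_neu,
                 stop_sd = stop_sd,
                 p_go_omission = p_go_omission, p_go_error = p_go_error),
            class = "sst_race_params")
}
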
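#' Build a balanced stop-trial schedule
#'
#' Chooses which trials carry a stop signal and assigns each stop trial a
#' condition (EMO/NEU), a sound and an arrow, under the design's balance
#' constraints: exactly \code{stop_fraction} of all trials are stop trials,
#' each condition holds half of them, every sound occurs equally often and is
#' split equally between left and right arrows, and the four ordered condition
#' pairs formed by consecutive stop trials are as equal in count as integer
#' arithmetic permits (with K stop trials there are K-1 ordered pairs, so
#' perfect 25/25/25/25 balance is impossible; counts differ by at most one).
#'
#' @param config an \code{"sst_config"} object.
#' @param seed optional integer seed; if \code{NULL} the current RNG state is
#'   used.
#' @return a data.frame with one row per stop trial, in trial order, and
#'   columns \code{trial_index}, \code{condition}, \code{sound_id},
#'   \code{arrow}. Sounds 1..k are the aversive set, k+1..2k the neutral set.
#' @export
build_stop_schedule <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- session_counts(config)
  positions <- sort(sample.int(cnt$n_trials, cnt$n_stop))
  condition <- balanced_condition_sequence(cnt$n_stop)

  k <- config$n_sounds_per_condition
  per_arrow <- (cnt$n_stop / 2L) / k / 2L
  sound_id <- integer(cnt$n_stop)
  arrow <- character(cnt$n_stop)
  for (cond in c("EMO", "NEU")) {
    ids <- if (cond == "EMO") seq_len(k) else k + seq_len(k)
    slots <- expand.grid(sound_id = ids, arrow = c("left", "right"),
                         rep = seq_len(per_arrow), stringsAsFactors = FALSE)
    slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
    sel <- which(condition == cond)
    sound_id[sel] <- slots$sound_id
    arrow[sel] <- slots$arrow
  }
  data.frame(trial_index = positions, condition = condition,
             sound_id = sound_id, arrow = arrow, stringsAsFactors = FALSE)
}

# Random condition sequence of length K (even), 50/50 EMO/NEU, with the four
# ordered consecutive-pair counts as equal as possible. Degree arithmetic
# forces the off-by-one pair to be a self-pair (EMO,EMO) or (NEU,NEU); the
# sequence is an Eulerian path on the 2-node transition multigraph, realised
# as a random walk with a feasibility check at every step.
balanced_condition_sequence <- function(K) {
  conds <- c("EMO", "NEU")
  if (K == 2L) return(sample(conds))
  stopifnot(K >= 2L, K %% 2L == 0L)
  base <- (K - 1L) %/% 4L
  rem <- (K - 1L) %% 4L # odd: 1 or 3 for even K
  s <- sample(conds, 1L)
  counts <- matrix(0L, 2L, 2L, dimnames = list(conds, conds))
  if (rem == 3L) {
    counts[, ] <- base + 1L
    counts[s, s] <- base
    start <- s
  } else {
    counts[, ] <- base
    counts[s, s] <- base + 1L
    start <- setdiff(conds, s)
  }
  out <- character(K)
  out[1L] <- start
  cur <- start
  for (i in 2L:K) {
    placed <- FALSE
    for (d in sample(conds)) {
      if (counts[cur, d] > 0L) {
        counts[cur, d] <- counts[cur, d] - 1L
        if (eulerian_feasible(counts, d)) {
          out[i] <- d
          cur <- d
          placed <- TRUE
          break
        }
        counts[cur, d] <- counts[cur, d] + 1L
      }
    }
    if (!placed) stop("internal error: condition sequence construction failed")
  }
  out
}

# Can the remaining transition multigraph be exhausted by a path starting at
# `at`? Two-node special case: degree conditions plus reachability.
eulerian_feasible <- function(m, at) {
  if (sum(m) == 0L) return(TRUE)
  other <- setdiff(rownames(m), at)
  if (sum(m[at, ]) == 0L) return(FALSE)
  d_at <- sum(m[at, ]) - sum(m[, at])
  d_other <- sum(m[other, ]) - sum(m[, other])
  if (!(d_at %in% c(0L, 1L)) || !(d_other %in% c(0L, -1L))) return(FALSE)
  if (m[at, other] + m[other, at] == 0L && m[other, other] > 0L) return(FALSE)
  TRUE
}

#' One-up/one-down staircase update of the stop-signal delay
#'
#' After a successful inhibition the SSD of the next stop trial increases by
#' one step (stopping is made harder); after a failed inhibition it decreases
#' by one step. Values are clamped to the staircase bounds.
#'
#' @param ssd current SSD (ms); must lie on the staircase lattice.
#' @param outcome \code{"SUCC_STOP"} or \code{"UNSUCC_STOP"}.
#' @param config an \code{"sst_config"} object.
#' @return the next SSD (ms).
#' @examples
#' cfg <- session_config()
#' staircase_update(150, "SUCC_STOP", cfg)   # 200
#' staircase_update(400, "SUCC_STOP", cfg)   # clamped at 400
#' @export
staircase_update <- function(ssd, outcome, config) {
  lattice <- session_counts(config)$ssd_values
  if (!isTRUE(any(abs(lattice - ssd) < 1e-9)))
    stop("ssd is not a legal staircase value")
  outcome <- match.arg(outcome, c("SUCC_STOP", "UNSUCC_STOP"))
  step <- if (outcome == "SUCC_STOP") config$ssd_step else -config$ssd_step
  min(max(ssd + step, config$ssd_min), config$ssd_max)
}

#' Resolve one stop trial under the independent horse-race model
#'
#' The go and stop processes race independently: a response is emitted
#' (unsuccessful stop) iff the go process finishes strictly before
#' \code{ssd + stop_latency}. Ties are resolved in favour of stopping.
#'
#' @param ssd stop-signal delay (ms).
#' @param go_rt finishing time of the go process (ms from go onset).
#' @param stop_latency finishing time of the stop process (ms from stop onset).
#' @return \code{"SUCC_STOP"} or \code{"UNSUCC_STOP"}.
#' @export
race_trial <- function(ssd, go_rt, stop_latency) {
  stopifnot(ssd > 0, go_rt > 0, stop_latency > 0)
  if (go_rt < ssd + stop_latency) "UNSUCC_STOP" else "SUCC_STOP"
}

# ex-Gaussian go latencies
rexgauss <- function(n, mu, sigma, tau) {
  x <- stats::rnorm(n, mu, sigma)
  if (tau > 0) x <- x + stats::rexp(n, rate = 1 / tau)
  x
}

# normal truncated below at `lower` (rejection sampling; the defaults place
# the truncation point > 6 SD below the mean, so resampling is rare)
rtnorm_lower <- function(n, mean, sd, lower = 1) {
  if (sd == 0) return(rep(max(mean, lower), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Simulate one session of the emotional stop-signal task
#'
#' Runs the full trial sequence: go trials draw an ex-Gaussian go RT (with
#' optional omission and wrong-key probabilities), stop trials are resolved by
#' \code{\link{race_trial}} with the condition-specific stop latency, and a
#' single SSD staircase (shared by both conditions) threads through all stop
#' trials in order, starting at \code{ssd_init}. A go process finishing after
#' the response deadline counts as an omission; an omitted go process on a
#' stop trial yields a successful stop (no response occurred).
#'
#' @param config an \code{"sst_config"} object.
#' @param params an \code{"sst_race_params"} object.
#' @param seed optional integer seed.
#' @return an object of class \code{"sst_session"}: a list with elements
#'   \code{config}, \code{params}, \code{seed} and \code{trials}, a data.frame
#'   with one row per trial and columns \code{trial_index}, \code{block},
#'   \code{arrow}, \code{is_stop}, \code{condition}, \code{sound_id},
#'   \code{ssd}, \code{go_rt} (observed RT; \code{NA} when no response
#'   occurred), \code{response} and \code{outcome} (\code{HIT},
#'   \code{GO_ERROR}, \code{GO_OMISSION}, \code{SUCC_STOP},
#'   \code{UNSUCC_STOP}).
#' @export
simulate_session <- function(config, params, seed = NULL) {
  if (!inherits(config, "sst_config")) stop("config must be an sst_config")
  if (!inherits(params, "sst_race_params")) stop("params must be sst_race_params")
  if (!is.null(seed)) set.seed(seed)
  cnt <- session_counts(config)
  n <- cnt$n_trials
  sched <- build_stop_schedule(config)

  arrow <- sample(c("left", "right"), n, replace = TRUE)
  arrow[sched$trial_index] <- sched$arrow
  is_stop <- logical(n)
  is_stop[sched$trial_index] <- TRUE
  condition <- rep(NA_character_, n)
  condition[sched$trial_index] <- sched$condition
  sound_id <- rep(NA_integer_, n)
  sound_id[sched$trial_index] <- sched$sound_id

  go_proc <- rexgauss(n, params$go_mu, params$go_sigma, params$go_tau)
  go_proc <- pmax(go_proc, 1)
  omit <- stats::runif(n) < params$p_go_omission
  wrong <- stats::runif(n) < params$p_go_error
  stop_lat <- rep(NA_real_, n)
  stop_lat[sched$trial_index] <- rtnorm_lower(
    nrow(sched),
    ifelse(sched$condition == "EMO", params$stop_mean_emo, params$stop_mean_neu),
    params$stop_sd)

  deadline <- config$response_deadline_ms
  outcome <- character(n)
  go_rt <- rep(NA_real_, n)
  response <- rep(NA_character_, n)
  ssd <- rep(NA_real_, n)

  flip <- function(a) ifelse(a == "left", "right", "left")
  ssd_cur <- config$ssd_init
  for (i in seq_len(n)) {
    responded <- !omit[i] && go_proc[i] <= deadline
    if (!is_stop[i]) {
      if (!responded) {
        outcome[i] <- "GO_OMISSION"
      } else {
        go_rt[i] <- go_proc[i]
        if (wrong[i]) {
          outcome[i] <- "GO_ERROR"
          response[i] <- flip(arrow[i])
        } else {
          outcome[i] <- "HIT"
          response[i] <- arrow[i]
        }
      }
    } else {
      ssd[i] <- ssd_cur
      if (responded && race_trial(ssd_cur, go_proc[i], stop_lat[i]) == "UNSUCC_STOP") {
        outcome[i] <- "UNSUCC_STOP"
        go_rt[i] <- go_proc[i]
        response[i] <- if (wrong[i]) flip(arrow[i]) else arrow[i]
      } else {
        outcome[i] <- "SUCC_STOP"
      }
      ssd_cur <- staircase_update(ssd_cur, outcome[i], config)
    }
  }

  trials <- data.frame(
    trial_index = seq_len(n),
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    arrow = arrow, is_stop = is_stop, condition = condition,
    sound_id = sound_id, ssd = ssd, go_rt = go_rt, response = response,
    outcome = outcome, stringsAsFactors = FALSE)

  structure(list(config = config, params = params, seed = seed,
                 trials = trials),
            class = "sst_session")
}

#' @export
print.sst_session <- function(x, ...) {
  tab <- table(x$trials$outcome)
  cat("Stop-signal session:", nrow(x$trials), "trials (",
      sum(x$trials$is_stop), "stop )\n")
  print(tab)
  invisible(x)
}

#' Between-subject population for a simulated cohort
#'
#' Describes how per-participant race-model parameters vary across a cohort.
#' Each participant's go-RT mean, spread and tail, and a common shift of both
#' stop-latency means (plus small condition-specific jitter), are drawn from
#' normal distributions around the stated population values. Setting all
#' `*_sd` fields to zero makes every participant identical.
#'
#' @param go_mu,go_mu_sd population mean/SD of the go-RT Gaussian mean (ms).
#' @param go_sigma,go_sigma_sd population mean/SD of the go-RT Gaussian SD (ms).
#' @param go_tau,go_tau_sd population mean/SD of the go-RT exponential tail (ms).
#' @param stop_mean_emo,stop_mean_neu population mean stop latency per condition (ms).
#' @param stop_between_sd between-subject SD of a shift applied to both
#'   condition means (ms).
#' @param stop_cond_jitter_sd between-subject SD of independent per-condition
#'   deviations (ms).
#' @param stop_sd within-subject trial-to-trial stop-latency SD (ms).
#' @param p_go_omission,p_go_error shared response-lapse probabilities.
#' @return an object of class \code{"sst_population"}.
#' @export
cohort_population <- function(go_mu = 330, go_mu_sd = 35,
                              go_sigma = 40, go_sigma_sd = 5,
                              go_tau = 45, go_tau_sd = 10,
                              stop_mean_emo = 202, stop_mean_neu = 217,
                              stop_between_sd = 20, stop_cond_jitter_sd = 4,
                              stop_sd = 30,
                              p_go_omission = 0, p_go_error = 0.016) {
  structure(as.list(environment()), class = "sst_population")
}

#' Draw one participant's race-model parameters from a population
#' @param population an \code{"sst_population"} object.
#' @return an \code{"sst_race_params"} object with attribute
#'   \code{"stop_shift"}, the standardized common stop-latency shift (used to
#'   couple ERP latencies to stopping speed downstream).
#' @export
draw_race_params <- function(population) {
  p <- population
  shift <- stats::rnorm(1, 0, p$stop_between_sd)
  jit <- stats::rnorm(2, 0, p$stop_cond_jitter_sd)
  rp <- race_params(
    go_mu = max(50, stats::rnorm(1, p$go_mu, p$go_mu_sd)),
    go_sigma = max(5, stats::rnorm(1, p$go_sigma, p$go_sigma_sd)),
    go_tau = max(1, stats::rnorm(1, p$go_tau, p$go_tau_sd)),
    stop_mean_emo = max(20, p$stop_mean_emo + shift + jit[1]),
    stop_mean_neu = max(20, p$stop_mean_neu + shift + jit[2]),
    stop_sd = p$stop_sd,
    p_go_omission = p$p_go_omission, p_go_error = p$p_go_error)
  attr(rp, "stop_shift") <-
    if (p$stop_between_sd > 0) shift / p$stop_between_sd else 0
  rp
}

#' Simulate a cohort of stop-signal sessions
#'
#' @param n_subjects number of participants (default 32, the usual sample size
#'   for detecting a medium within-subject effect with power > 80%).
#' @param population an \code{"sst_population"} object.
#' @param config an \code{"sst_config"} shared by all participants.
#' @param seed optional integer master seed; per-subject seeds are derived
#'   from it.
#' @return an object of class \code{"sst_cohort"}: a list of
#'   \code{"sst_session"} objects with a \code{subject} element added.
#' @export
simulate_cohort <- function(n_subjects = 32, population = cohort_population(),
                            config = session_config(), seed = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sessions <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    rp <- draw_race_params(population)
    sess <- simulate_session(config, rp, seed = sample.int(2147483646L, 1))
    sess$subject <- s
    sessions[[s]] <- sess
  }
  structure(sessions, class = "sst_cohort")
}
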
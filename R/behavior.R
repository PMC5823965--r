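#' @keywords internal
as_trial_table <- function(x) {
  if (inherits(x, "sst_session")) return(x$trials)
  if (is.data.frame(x)) return(x)
  stop("expected an sst_session or a trial-table data.frame")
}

stop_trials <- function(x) {
  tr <- as_trial_table(x)
  tr[tr$is_stop, , drop = FALSE]
}

#' Percentage of successfully inhibited stop trials
#'
#' @param session an \code{"sst_session"} or a trial-table data.frame.
#' @param scope \code{"global"} (all stop trials) or one condition
#'   (\code{"EMO"}, \code{"NEU"}).
#' @return inhibition rate in percent.
#' @export
inhibition_rate <- function(session, scope = c("global", "EMO", "NEU")) {
  scope <- match.arg(scope)
  st <- stop_trials(session)
  if (scope != "global") st <- st[st$condition == scope, , drop = FALSE]
  if (nrow(st) == 0L) stop("no stop trials in scope '", scope, "'")
  100 * mean(st$outcome == "SUCC_STOP")
}

#' Mean stop-signal delay
#'
#' The global mean is taken over all realized SSDs, including the initial
#' one. The condition-wise means follow the staircase bookkeeping used with a
#' staircase common to both conditions: the mean SSD attributed to a
#' condition is the mean of the SSD values realized on the stop trial that
#' *immediately follows* each stop trial of that condition (regardless of the
#' follower's own condition). The session's last stop trial contributes no
#' follower; the initial SSD belongs only to the global mean.
#'
#' @inheritParams inhibition_rate
#' @return mean SSD (ms).
#' @export
mean_ssd <- function(session, scope = c("global", "EMO", "NEU")) {
  scope <- match.arg(scope)
  st <- stop_trials(session)
  if (nrow(st) == 0L) stop("session contains no stop trials")
  if (scope == "global") return(mean(st$ssd))
  idx <- which(st$condition == scope)
  idx <- idx[idx < nrow(st)] # last stop trial has no follower
  if (length(idx) == 0L)
    stop("no qualifying SSDs for condition '", scope, "'")
  mean(st$ssd[idx + 1L])
}

#' Integration-method SSRT from a go-RT distribution
#'
#' Implements the rank-order integration estimator: the no-stop-signal go RTs
#' are rank ordered and the n-th smallest is selected, with
#' \code{n = ceiling(p_respond * N)} clamped to \code{[1, N]} (the
#' conventional choice; \code{rank_rule} exposes \code{"floor"} and
#' \code{"round"} alternatives). The SSRT is that quantile minus the mean SSD.
#'
#' @param go_rts numeric vector of go RTs (ms) from no-stop-signal trials.
#' @param p_respond probability of responding on stop trials, in [0, 1].
#' @param mean_ssd mean stop-signal delay (ms) for the matching scope.
#' @param rank_rule how to map \code{p_respond * N} to a rank.
#' @return a list with \code{n}, \code{nth_rt} and \code{ssrt} (ms).
#' @examples
#' estimate_ssrt(seq(210, 390, by = 20), p_respond = 0.5, mean_ssd = 150)
#' @export
estimate_ssrt <- function(go_rts, p_respond, mean_ssd,
                          rank_rule = c("ceiling", "floor", "round")) {
  rank_rule <- match.arg(rank_rule)
  if (length(go_rts) == 0L) stop("go_rts must be non-empty")
  if (is.na(p_respond) || p_respond < 0 || p_respond > 1)
    stop("p_respond must lie in [0, 1]")
  N <- length(go_rts)
  n <- switch(rank_rule,
              ceiling = ceiling(p_respond * N),
              floor = floor(p_respond * N),
              round = round(p_respond * N))
  n <- min(max(n, 1L), N)
  nth <- sort(go_rts)[n]
  list(n = as.integer(n), nth_rt = nth, ssrt = nth - mean_ssd)
}

#' Behavioral summary of one session
#'
#' Computes the quantities reported for stop-signal behaviour: mean correct
#' go RT, go error rate, global and condition-wise inhibition rates,
#' probabilities of responding, mean SSDs, n-th go RTs and SSRTs. The go-RT
#' distribution entering the SSRT estimator is taken from no-stop-signal
#' trials with a response; by default wrong-key responses are included
#' (\code{include_go_errors = FALSE} restricts it to correct responses).
#' Condition-wise SSRTs use the condition-wise probability of responding and
#' the condition-wise mean SSD, with the same global go-RT distribution.
#'
#' @param session an \code{"sst_session"} or trial-table data.frame.
#' @param include_go_errors include wrong-key go responses in the go-RT
#'   distribution used for the SSRT quantile.
#' @param rank_rule passed to \code{\link{estimate_ssrt}}.
#' @return a one-row data.frame of class \code{"sst_behavioral_summary"}.
#' @export
behavioral_summary <- function(session, include_go_errors = TRUE,
                               rank_rule = "ceiling") {
  tr <- as_trial_table(session)
  go <- tr[!tr$is_stop, , drop = FALSE]
  if (nrow(go) == 0L) stop("session contains no go trials")
  keep <- if (include_go_errors) c("HIT", "GO_ERROR") else "HIT"
  go_rts <- go$go_rt[go$outcome %in% keep & !is.na(go$go_rt)]
  if (length(go_rts) == 0L) stop("no usable go RTs")

  out <- data.frame(
    n_go = nrow(go),
    n_stop = sum(tr$is_stop),
    mean_go_rt = mean(go$go_rt[go$outcome == "HIT"], na.rm = TRUE),
    go_error_rate = 100 * mean(go$outcome == "GO_ERROR"),
    go_omission_rate = 100 * mean(go$outcome == "GO_OMISSION"))

  for (scope in c("global", "EMO", "NEU")) {
    suffix <- tolower(scope)
    ir <- inhibition_rate(tr, scope)
    ms <- mean_ssd(tr, scope)
    p_resp <- 1 - ir / 100
    est <- estimate_ssrt(go_rts, p_resp, ms, rank_rule)
    out[[paste0("inhibition_rate_", suffix)]] <- ir
    out[[paste0("p_respond_", suffix)]] <- p_resp
    out[[paste0("mean_ssd_", suffix)]] <- ms
    out[[paste0("nth_rt_", suffix)]] <- est$nth_rt
    out[[paste0("ssrt_", suffix)]] <- est$ssrt
  }
  class(out) <- c("sst_behavioral_summary", "data.frame")
  out
}

#' Behavioral summaries for a whole cohort
#'
#' @param cohort an \code{"sst_cohort"} (list of sessions).
#' @param ... passed to \code{\link{behavioral_summary}}.
#' @return a data.frame with one row per participant (column \code{subject}).
#' @export
cohort_behavioral_summary <- function(cohort, ...) {
  rows <- lapply(seq_along(cohort), function(s) {
    b <- behavioral_summary(cohort[[s]], ...)
    cbind(subject = if (!is.null(cohort[[s]]$subject)) cohort[[s]]$subject else s,
          b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
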
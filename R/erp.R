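#' Map a time in milliseconds to a sample offset
#'
#' The convention used throughout the package: time t ms maps to sample
#' \code{round(t * srate / 1000)} relative to the lock event, which is sample
#' 0 of the epoch time axis; windows are inclusive at both mapped endpoints.
#'
#' @param t_ms time(s) in ms.
#' @param srate sampling rate in Hz.
#' @return integer sample offset(s).
#' @export
ms_to_sample <- function(t_ms, srate) as.integer(round(t_ms * srate / 1000))

#' Construct an epoch set
#'
#' Low-level constructor for the container returned by
#' \code{\link{extract_epochs}}; exported so that epoch sets can be built
#' programmatically (e.g. in simulations or tests).
#'
#' @param data numeric array, trials x channels x time.
#' @param samples integer vector of sample offsets relative to the lock event
#'   (one per time point).
#' @param channels channel names (length = dim 2).
#' @param labels data.frame with one row per epoch (typically columns
#'   \code{trial_index}, \code{trial_type}, \code{condition}, \code{ssd}).
#' @param lock lock event: \code{"stop"}, \code{"response"} or \code{"go"}.
#' @param srate sampling rate (Hz).
#' @param baseline_ms baseline window used for correction (ms pair), or NULL.
#' @return an object of class \code{"erp_epochs"}.
#' @export
epoch_set <- function(data, samples, channels, labels, lock, srate,
                      baseline_ms = NULL) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[1] == nrow(labels),
            dim(data)[2] == length(channels),
            dim(data)[3] == length(samples))
  structure(list(data = data, samples = as.integer(samples),
                 times = samples * 1000 / srate,
                 channels = channels, labels = labels, lock = lock,
                 srate = srate, baseline_ms = baseline_ms),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat("Epoch set (", x$lock, "-locked): ", dim(x$data)[1], " epochs x ",
      length(x$channels), " channels x ", length(x$samples), " samples @ ",
      x$srate, " Hz\n", sep = "")
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs an \code{"erp_epochs"} object.
#' @return integer count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by epoch index
#' @param epochs an \code{"erp_epochs"} object.
#' @param idx integer or logical index over epochs.
#' @return the subsetted \code{"erp_epochs"} object.
#' @export
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$samples,
            epochs$channels, epochs$labels[idx, , drop = FALSE],
            epochs$lock, epochs$srate, epochs$baseline_ms)
}

default_epoch_window <- function(lock) {
  switch(lock,
         stop = list(window = c(-100, 700), baseline = c(-100, 0)),
         response = list(window = c(-150, 600), baseline = c(-150, -50)),
         go = list(window = c(-100, 700), baseline = c(-100, 0)))
}

#' Extract baseline-corrected epochs from a continuous recording
#'
#' Cuts segments around every event of the requested lock type
#' (stop-signal onset, response, or go onset) and subtracts, per channel, the
#' mean over the baseline window. Defaults follow the standard windows:
#' stop-locked -100..700 ms with -100..0 ms baseline; response-locked
#' -150..600 ms with -150..-50 ms baseline. Events too close to a recording
#' edge are skipped with a warning.
#'
#' Epoch labels carry the trial index, condition, realized SSD and a
#' \code{trial_type} factor: \code{SUCC}/\code{UNSUCC} for stop-locked
#' epochs; \code{HIT}/\code{ERROR}/\code{GO_ERROR} for response-locked epochs
#' (\code{ERROR} = failed inhibition).
#'
#' @param recording an \code{"eeg_recording"}.
#' @param lock \code{"stop"}, \code{"response"} or \code{"go"}.
#' @param window_ms epoch window (ms pair relative to the lock event);
#'   \code{NULL} for the lock-specific default.
#' @param baseline_ms baseline window (ms pair); \code{NULL} for the default.
#' @return an \code{"erp_epochs"} object.
#' @export
extract_epochs <- function(recording, lock = c("stop", "response", "go"),
                           window_ms = NULL, baseline_ms = NULL) {
  lock <- match.arg(lock)
  defs <- default_epoch_window(lock)
  if (is.null(window_ms)) window_ms <- defs$window
  if (is.null(baseline_ms)) baseline_ms <- defs$baseline
  if (baseline_ms[1] < window_ms[1] || baseline_ms[2] > window_ms[2])
    stop("baseline window must lie within the epoch window")
  srate <- recording$srate
  codes <- switch(lock, stop = c("STOP_EMO", "STOP_NEU"),
                  response = "RESPONSE", go = "GO")
  ev <- recording$events[recording$events$code %in% codes, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no events of lock type '", lock, "' in recording")

  s0 <- ms_to_sample(window_ms[1], srate)
  s1 <- ms_to_sample(window_ms[2], srate)
  offs <- s0:s1
  ok <- ev$sample + s0 >= 1L & ev$sample + s1 <= ncol(recording$data)
  if (any(!ok))
    warning(sum(!ok), " epoch(s) skipped: event too close to a recording edge")
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0L) stop("zero extractable epochs")

  n <- nrow(ev)
  nch <- length(recording$channels)
  dat <- array(NA_real_, dim = c(n, nch, length(offs)))
  for (e in seq_len(n))
    dat[e, , ] <- recording$data[, ev$sample[e] + offs, drop = FALSE]

  # baseline correction per channel
  b0 <- ms_to_sample(baseline_ms[1], srate)
  b1 <- ms_to_sample(baseline_ms[2], srate)
  bsel <- which(offs >= b0 & offs <= b1)
  bl <- apply(dat[, , bsel, drop = FALSE], c(1, 2), mean)
  dat <- dat - as.vector(bl) # recycles over the 3rd dimension

  trl <- recording$trials
  m <- match(ev$trial_index, trl$trial_index)
  trial_type <- switch(lock,
    stop = ifelse(trl$outcome[m] == "SUCC_STOP", "SUCC", "UNSUCC"),
    response = ifelse(trl$outcome[m] == "UNSUCC_STOP", "ERROR",
                      ifelse(trl$outcome[m] == "GO_ERROR", "GO_ERROR", "HIT")),
    go = rep("GO", length(m)))
  labels <- data.frame(trial_index = ev$trial_index,
                       trial_type = trial_type,
                       condition = trl$condition[m],
                       ssd = trl$ssd[m],
                       outcome = trl$outcome[m],
                       stringsAsFactors = FALSE)
  epoch_set(dat, offs, recording$channels, labels, lock, srate, baseline_ms)
}

#' Threshold-based artifact rejection
#'
#' An epoch is rejected iff any channel at any sample exceeds
#' \code{+threshold_uV} or falls below \code{-threshold_uV} (strict
#' inequality: the default rejects amplitudes beyond +/- 65 uV). Rejection is
#' fully automatic and idempotent.
#'
#' @param epochs an \code{"erp_epochs"} object.
#' @param threshold_uV rejection threshold (microvolts), > 0.
#' @return a list with \code{kept} (the retained \code{"erp_epochs"}) and
#'   \code{log}, a data.frame with one row per input epoch (\code{epoch},
#'   \code{max_abs_uV}, \code{rejected}).
#' @export
reject_artifacts <- function(epochs, threshold_uV = 65) {
  stopifnot(threshold_uV > 0)
  amax <- apply(abs(epochs$data), 1, max)
  rejected <- amax > threshold_uV
  log <- data.frame(epoch = seq_along(amax), max_abs_uV = amax,
                    rejected = rejected)
  list(kept = subset_epochs(epochs, !rejected), log = log)
}

#' Construct an ERP waveform object
#'
#' @param data numeric matrix, channels x time (microvolts).
#' @param samples sample offsets relative to the lock event.
#' @param channels channel names.
#' @param srate sampling rate (Hz).
#' @param n_epochs number of contributing epochs.
#' @param bins optional data.frame of per-SSD bin provenance.
#' @param lock lock event label.
#' @return an object of class \code{"erp_waveform"}.
#' @export
erp_waveform <- function(data, samples, channels, srate, n_epochs,
                         bins = NULL, lock = NULL) {
  stopifnot(nrow(data) == length(channels), ncol(data) == length(samples),
            n_epochs >= 1)
  structure(list(data = data, samples = as.integer(samples),
                 times = samples * 1000 / srate, channels = channels,
                 srate = srate, n_epochs = n_epochs, bins = bins,
                 lock = lock),
            class = "erp_waveform")
}

#' Plain (pooled) epoch average
#' @param epochs an \code{"erp_epochs"} object.
#' @return an \code{"erp_waveform"}; every epoch weighted equally.
#' @export
average_epochs <- function(epochs) {
  if (n_epochs(epochs) < 1L) stop("no epochs to average")
  avg <- apply(epochs$data, c(2, 3), mean)
  dimnames(avg) <- list(epochs$channels, NULL)
  erp_waveform(avg, epochs$samples, epochs$channels, epochs$srate,
               n_epochs(epochs), lock = epochs$lock)
}

#' Equal-weight per-SSD subaveraging
#'
#' Computes the mean waveform within each stop-signal-delay bin (bins with
#' fewer than \code{min_per_bin} epochs are dropped) and then averages the
#' bin means with equal weight, regardless of bin counts. Because the
#' go-evoked overlap inside a stop-locked epoch is a pure function of the
#' SSD, this equates the expected overlap between conditions that share the
#' same SSD lattice but differ in how often each delay was visited, removing
#' the differential-overlap distortion that naive pooled averaging exhibits.
#'
#' @param epochs an \code{"erp_epochs"} object whose labels carry \code{ssd}.
#' @param min_per_bin minimum epochs for a bin to qualify (default 1).
#' @return an \code{"erp_waveform"} whose \code{bins} element lists the SSD
#'   bins used and their epoch counts.
#' @export
average_by_ssd_equal_weight <- function(epochs, min_per_bin = 1) {
  ssd <- epochs$labels$ssd
  if (all(is.na(ssd))) stop("epochs carry no SSD labels")
  groups <- split(seq_along(ssd), ssd)
  groups <- groups[vapply(groups, length, 1L) >= min_per_bin]
  if (length(groups) == 0L) stop("no SSD bin meets min_per_bin")
  nch <- length(epochs$channels)
  nt <- length(epochs$samples)
  acc <- matrix(0, nch, nt)
  bins <- data.frame(ssd = as.numeric(names(groups)),
                     n = vapply(groups, length, 1L), row.names = NULL)
  for (g in groups)
    acc <- acc + apply(epochs$data[g, , , drop = FALSE], c(2, 3), mean)
  avg <- acc / length(groups)
  dimnames(avg) <- list(epochs$channels, NULL)
  erp_waveform(avg, epochs$samples, epochs$channels, epochs$srate,
               sum(bins$n), bins = bins, lock = epochs$lock)
}

#' Definition of a scored ERP component
#'
#' @param name component name.
#' @param lock lock event (\code{"stop"} or \code{"response"}).
#' @param window_ms scoring window (ms pair, inclusive at mapped endpoints).
#' @param cluster electrode names averaged for scoring.
#' @param polarity +1 for positive components, -1 for negative ones (used by
#'   peak search).
#' @return an object of class \code{"erp_component"}.
#' @export
component_definition <- function(name, lock, window_ms, cluster, polarity) {
  stopifnot(length(window_ms) == 2L, window_ms[1] < window_ms[2],
            polarity %in% c(-1, 1))
  structure(list(name = name, lock = lock, window_ms = window_ms,
                 cluster = cluster, polarity = polarity),
            class = "erp_component")
}

#' Standard component definitions
#'
#' N1 (stop-locked, 120-190 ms, central cluster, negative), P3 (stop-locked,
#' 270-400 ms, centro-parietal, positive), ERN (response-locked, 0-80 ms,
#' fronto-central, negative) and Pe (response-locked, 120-270 ms,
#' centro-parietal, positive).
#'
#' @return named list of \code{"erp_component"} objects.
#' @export
default_component_definitions <- function() {
  list(
    N1 = component_definition("N1", "stop", c(120, 190),
      c("FC1", "FC2", "C3", "C4", "Cz", "CP1", "CP2"), -1),
    P3 = component_definition("P3", "stop", c(270, 400),
      c("Cz", "CP1", "CP2", "P3", "P4", "Pz"), +1),
    ERN = component_definition("ERN", "response", c(0, 80),
      c("F3", "F4", "Fz", "FC1", "FC2", "C3", "C4", "Cz"), -1),
    Pe = component_definition("Pe", "response", c(120, 270),
      c("Cz", "CP1", "CP2", "P3", "P4", "Pz"), +1)
  )
}

component_selection <- function(erp, comp) {
  chidx <- match(comp$cluster, erp$channels)
  if (anyNA(chidx))
    stop("cluster channel(s) missing from waveform: ",
         paste(comp$cluster[is.na(chidx)], collapse = ", "))
  w0 <- ms_to_sample(comp$window_ms[1], erp$srate)
  w1 <- ms_to_sample(comp$window_ms[2], erp$srate)
  tsel <- which(erp$samples >= w0 & erp$samples <= w1)
  if (length(tsel) == 0L) stop("component window outside the epoch span")
  list(chidx = chidx, tsel = tsel)
}

#' Mean amplitude of a component
#'
#' Mean voltage over the component's electrode cluster and scoring window
#' (inclusive at both mapped endpoints).
#'
#' @param erp an \code{"erp_waveform"}.
#' @param comp an \code{"erp_component"}.
#' @return mean amplitude in microvolts.
#' @export
mean_amplitude <- function(erp, comp) {
  sel <- component_selection(erp, comp)
  mean(erp$data[sel$chidx, sel$tsel])
}

#' Peak latency of a component
#'
#' Latency of the polarity-appropriate extremum of the cluster-mean waveform
#' within the scoring window (the maximum for positive components, the
#' minimum for negative ones). Plateau ties resolve to the earliest sample.
#'
#' @inheritParams mean_amplitude
#' @return latency in ms relative to the lock event.
#' @export
peak_latency <- function(erp, comp) {
  sel <- component_selection(erp, comp)
  trace <- colMeans(erp$data[sel$chidx, , drop = FALSE])
  v <- comp$polarity * trace[sel$tsel]
  erp$times[sel$tsel][which.max(v)]
}
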
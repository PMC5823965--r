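#' Configuration of the full simulate-and-analyse pipeline
#'
#' Bundles every setting of the end-to-end run: cohort size, master seed,
#' session design, race-model population, ERP generating population, noise
#' settings, component definitions and analysis options. The master seed
#' deterministically derives all per-subject seeds.
#'
#' @param n_subjects cohort size.
#' @param master_seed integer master seed.
#' @param session an \code{"sst_config"}.
#' @param population an \code{"sst_population"}.
#' @param erp an \code{"erp_population"}.
#' @param noise an \code{"eeg_noise_config"}.
#' @param templates component templates for the generator.
#' @param components component definitions for scoring.
#' @param min_per_bin minimum epochs per SSD bin in equal-weight averaging.
#' @param include_go_errors include wrong-key go responses in the SSRT go-RT
#'   distribution.
#' @param out_dir optional directory; when given, all report tables are
#'   written there as CSV.
#' @return an object of class \code{"sst_pipeline_config"}.
#' @export
pipeline_config <- function(n_subjects = 32, master_seed = 1,
                            session = session_config(),
                            population = cohort_population(),
                            erp = erp_population(),
                            noise = noise_config(),
                            templates = default_templates(),
                            components = default_component_definitions(),
                            min_per_bin = 1, include_go_errors = TRUE,
                            out_dir = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2 for the group statistics")
  structure(as.list(environment()), class = "sst_pipeline_config")
}

score_cell <- function(epochs, sel, equal_weight, min_per_bin) {
  sub <- subset_epochs(epochs, sel)
  if (n_epochs(sub) == 0L) return(NULL)
  erp <- if (equal_weight) average_by_ssd_equal_weight(sub, min_per_bin)
         else average_epochs(sub)
  erp
}

#' Run the full simulate-and-analyse pipeline
#'
#' For each simulated participant: run the behavioural session, estimate the
#' behavioural summary (SSRT etc.), draw ERP generating parameters (tied to
#' the participant's stopping speed), synthesize the session EEG, epoch it
#' stop-locked and response-locked, reject artifacts at +/- 65 uV, build the
#' four stop-signal cells (SUCC/UNSUCC x EMO/NEU) by per-SSD equal-weight
#' collapsing and the three response cells (HIT, EMO error, NEU error), and
#' score N1/P3/ERN/Pe amplitudes and P3/Pe peak latencies. Then run the group
#' statistics: paired contrasts of the behavioural measures, 2 x 2
#' repeated-measures ANOVAs for N1 and P3, one-way contrasts for ERN and Pe,
#' the two cross-subject regressions (failed-stop amplitudes predicting the
#' error Pe, and emotional-minus-neutral difference measures), and the
#' SSRT-latency correlation comparison via the dependent-correlation Z test.
#'
#' @param config an \code{"sst_pipeline_config"}.
#' @return an object of class \code{"sst_report"}: a list of data.frames
#'   (\code{behavioral}, \code{behavioral_tests}, \code{amplitudes},
#'   \code{effects}, \code{regression}, \code{regression_models},
#'   \code{correlations}, \code{normality}) plus \code{seeds}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "sst_pipeline_config"))
    stop("config must be an sst_pipeline_config")
  set.seed(config$master_seed)
  ns <- config$n_subjects
  seeds <- matrix(sample.int(2147483646L, ns * 3L), ncol = 3L,
                  dimnames = list(NULL, c("behavior", "erp_params", "eeg")))
  pop <- config$population
  stop_total_sd <- sqrt(pop$stop_between_sd^2 + pop$stop_cond_jitter_sd^2)

  behav <- vector("list", ns)
  amp_rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    rp <- draw_race_params(pop)
    sess <- simulate_session(config$session, rp, seed = seeds[s, "behavior"])
    b <- behavioral_summary(sess, include_go_errors = config$include_go_errors)
    behav[[s]] <- cbind(subject = s, b)

    stop_z <- if (stop_total_sd > 0) {
      c(EMO = (rp$stop_mean_emo - pop$stop_mean_emo) / stop_total_sd,
        NEU = (rp$stop_mean_neu - pop$stop_mean_neu) / stop_total_sd)
    } else c(EMO = 0, NEU = 0)
    spar <- draw_subject_params(config$erp, stop_z,
                                seed = seeds[s, "erp_params"])
    rec <- synthesize_session_eeg(sess, spar, config$noise,
                                  config$templates, seed = seeds[s, "eeg"])

    st <- reject_artifacts(extract_epochs(rec, "stop"))$kept
    rs <- reject_artifacts(extract_epochs(rec, "response"))$kept
    comps <- config$components
    rows <- list()
    addrow <- function(component, cell, amplitude, latency = NA_real_,
                       n_ep = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s, component = component, cell = cell,
        amplitude = amplitude, latency = latency, n_epochs = n_ep,
        stringsAsFactors = FALSE)
    }
    for (tt in c("SUCC", "UNSUCC")) for (cond in c("EMO", "NEU")) {
      sel <- st$labels$trial_type == tt & st$labels$condition == cond
      erp <- score_cell(st, sel, TRUE, config$min_per_bin)
      if (is.null(erp))
        stop("subject ", s, ": no artifact-free epochs in stop cell ",
             tt, "/", cond)
      cell <- paste0(tt, "_", cond)
      addrow("N1", cell, mean_amplitude(erp, comps$N1),
             peak_latency(erp, comps$N1), erp$n_epochs)
      addrow("P3", cell, mean_amplitude(erp, comps$P3),
             peak_latency(erp, comps$P3), erp$n_epochs)
    }
    # pooled failed-stop waveform for the cross-subject regressions
    sel_un <- st$labels$trial_type == "UNSUCC"
    erp_un <- score_cell(st, sel_un, TRUE, config$min_per_bin)
    addrow("N1", "UNSUCC", mean_amplitude(erp_un, comps$N1),
           peak_latency(erp_un, comps$N1), erp_un$n_epochs)
    addrow("P3", "UNSUCC", mean_amplitude(erp_un, comps$P3),
           peak_latency(erp_un, comps$P3), erp_un$n_epochs)

    sel_hit <- rs$labels$trial_type == "HIT"
    erp_hit <- score_cell(rs, sel_hit, FALSE, 1)
    if (is.null(erp_hit)) stop("subject ", s, ": no HIT response epochs")
    addrow("ERN", "HIT", mean_amplitude(erp_hit, comps$ERN),
           peak_latency(erp_hit, comps$ERN), erp_hit$n_epochs)
    addrow("Pe", "HIT", mean_amplitude(erp_hit, comps$Pe),
           peak_latency(erp_hit, comps$Pe), erp_hit$n_epochs)
    sel_err <- rs$labels$trial_type == "ERROR"
    erp_err <- score_cell(rs, sel_err, FALSE, 1)
    if (is.null(erp_err)) stop("subject ", s, ": no error response epochs")
    addrow("ERN", "ERROR", mean_amplitude(erp_err, comps$ERN),
           peak_latency(erp_err, comps$ERN), erp_err$n_epochs)
    addrow("Pe", "ERROR", mean_amplitude(erp_err, comps$Pe),
           peak_latency(erp_err, comps$Pe), erp_err$n_epochs)
    for (cond in c("EMO", "NEU")) {
      sel <- rs$labels$trial_type == "ERROR" & rs$labels$condition == cond
      erp <- score_cell(rs, sel, FALSE, 1)
      if (is.null(erp))
        stop("subject ", s, ": no error response epochs in condition ", cond)
      cell <- paste0("ERROR_", cond)
      addrow("ERN", cell, mean_amplitude(erp, comps$ERN),
             peak_latency(erp, comps$ERN), erp$n_epochs)
      addrow("Pe", cell, mean_amplitude(erp, comps$Pe),
             peak_latency(erp, comps$Pe), erp$n_epochs)
    }
    amp_rows[[s]] <- do.call(rbind, rows)
  }
  behavioral <- do.call(rbind, behav)
  rownames(behavioral) <- NULL
  amplitudes <- do.call(rbind, amp_rows)
  rownames(amplitudes) <- NULL

  report <- c(list(behavioral = behavioral, amplitudes = amplitudes),
              pipeline_statistics(behavioral, amplitudes, ns))
  report$seeds <- data.frame(subject = seq_len(ns), seeds)
  report$master_seed <- config$master_seed
  class(report) <- "sst_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

amp_of <- function(amplitudes, component, cell, what = "amplitude") {
  sub <- amplitudes[amplitudes$component == component &
                    amplitudes$cell == cell, , drop = FALSE]
  sub <- sub[order(sub$subject), , drop = FALSE]
  sub[[what]]
}

pipeline_statistics <- function(behavioral, amplitudes, ns) {
  trow <- function(measure, tt) {
    data.frame(measure = measure, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = tt$mean_diff, d_av = tt$d_av, d_z = tt$d_z,
               stringsAsFactors = FALSE)
  }
  behavioral_tests <- rbind(
    trow("inhibition_rate EMO - NEU",
         paired_t(behavioral$inhibition_rate_emo, behavioral$inhibition_rate_neu)),
    trow("mean_ssd EMO - NEU",
         paired_t(behavioral$mean_ssd_emo, behavioral$mean_ssd_neu)),
    trow("ssrt EMO - NEU",
         paired_t(behavioral$ssrt_emo, behavioral$ssrt_neu)))

  # 2 x 2 rm-ANOVAs: trial type (SUCC/UNSUCC) x condition (EMO/NEU)
  effects <- list()
  for (comp in c("N1", "P3")) {
    arr <- array(NA_real_, dim = c(ns, 2, 2),
                 dimnames = list(NULL, c("SUCC", "UNSUCC"), c("EMO", "NEU")))
    for (tt in c("SUCC", "UNSUCC")) for (cond in c("EMO", "NEU"))
      arr[, tt, cond] <- amp_of(amplitudes, comp, paste0(tt, "_", cond))
    an <- rm_anova_2x2(arr, c("Trial Type", "Stop-Signal Condition"))
    an <- cbind(component = comp, an)
    effects[[comp]] <- an
  }
  # one-way (2-level) contrasts for the response-locked components
  oneway <- function(comp, contrast, x, y) {
    tt <- paired_t(x, y)
    f <- tt$t^2
    data.frame(component = comp, effect = contrast, F = f, df1 = 1L,
               df2 = tt$df, p = tt$p,
               partial_eta_sq = partial_eta_sq(f, 1, tt$df),
               stringsAsFactors = FALSE)
  }
  for (comp in c("ERN", "Pe")) {
    effects[[paste0(comp, "_resp")]] <- oneway(
      comp, "Response Type",
      amp_of(amplitudes, comp, "HIT"), amp_of(amplitudes, comp, "ERROR"))
    effects[[paste0(comp, "_cond")]] <- oneway(
      comp, "Error Response Condition",
      amp_of(amplitudes, comp, "ERROR_EMO"),
      amp_of(amplitudes, comp, "ERROR_NEU"))
  }
  effects <- do.call(rbind, effects)
  rownames(effects) <- NULL

  # cross-subject regressions
  n1_un <- amp_of(amplitudes, "N1", "UNSUCC")
  p3_un <- amp_of(amplitudes, "P3", "UNSUCC")
  pe_err <- amp_of(amplitudes, "Pe", "ERROR")
  m1 <- ols_regression_standardized(pe_err, cbind(N1 = n1_un, P3 = p3_un))
  d_n1 <- amp_of(amplitudes, "N1", "UNSUCC_EMO") -
    amp_of(amplitudes, "N1", "UNSUCC_NEU")
  d_p3 <- amp_of(amplitudes, "P3", "UNSUCC_EMO") -
    amp_of(amplitudes, "P3", "UNSUCC_NEU")
  d_pe <- amp_of(amplitudes, "Pe", "ERROR_EMO") -
    amp_of(amplitudes, "Pe", "ERROR_NEU")
  m2 <- ols_regression_standardized(d_pe, cbind(N1_diff = d_n1, P3_diff = d_p3))
  regrow <- function(model, fit) {
    data.frame(model = model, term = names(fit$beta), beta = unname(fit$beta),
               t = unname(fit$t), p = unname(fit$p), stringsAsFactors = FALSE)
  }
  regression <- rbind(regrow("amplitudes", m1), regrow("differences", m2))
  regression_models <- data.frame(
    model = c("amplitudes", "differences"),
    r_squared = c(m1$r_squared, m2$r_squared),
    F = c(m1$F, m2$F), df1 = c(m1$df1, m2$df1), df2 = c(m1$df2, m2$df2),
    p = c(m1$p_model, m2$p_model),
    predictor_r = c(pearson_r(n1_un, p3_un)$r, pearson_r(d_n1, d_p3)$r),
    stringsAsFactors = FALSE)

  # SSRT vs component peak latencies, and their comparison
  corr_rows <- list()
  for (cond in c("EMO", "NEU")) {
    ssrt <- behavioral[[paste0("ssrt_", tolower(cond))]]
    p3_lat <- amp_of(amplitudes, "P3", paste0("UNSUCC_", cond), "latency")
    pe_lat <- amp_of(amplitudes, "Pe", paste0("ERROR_", cond), "latency")
    r_p3 <- pearson_r(ssrt, p3_lat)
    r_pe <- pearson_r(ssrt, pe_lat)
    r23 <- pearson_r(p3_lat, pe_lat)
    st <- steiger_z(r_p3$r, r_pe$r, r23$r, ns)
    corr_rows[[cond]] <- data.frame(
      condition = cond, r_ssrt_p3_latency = r_p3$r, p_p3 = r_p3$p,
      r_ssrt_pe_latency = r_pe$r, p_pe = r_pe$p, r_p3_pe = r23$r,
      steiger_Z = st$Z, steiger_p = st$p, stringsAsFactors = FALSE)
  }
  correlations <- do.call(rbind, corr_rows)
  rownames(correlations) <- NULL

  norm_of <- function(name, x) {
    ks <- ks_normality(x)
    data.frame(variable = name, D = ks$D, p = ks$p, stringsAsFactors = FALSE)
  }
  normality <- rbind(
    norm_of("ssrt_emo", behavioral$ssrt_emo),
    norm_of("ssrt_neu", behavioral$ssrt_neu),
    norm_of("pe_error_amplitude", pe_err),
    norm_of("p3_unsucc_amplitude", p3_un),
    norm_of("n1_unsucc_amplitude", n1_un))

  list(behavioral_tests = behavioral_tests, effects = effects,
       regression = regression, regression_models = regression_models,
       correlations = correlations, normality = normality)
}

#' Write all report tables as CSV files
#'
#' @param report an \code{"sst_report"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("behavioral", "behavioral_tests", "amplitudes", "effects",
            "regression", "regression_models", "correlations", "normality",
            "seeds")
  paths <- character(0)
  for (tb in tabs) {
    if (is.null(report[[tb]])) next
    path <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(report[[tb]], path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @export
print.sst_report <- function(x, ...) {
  cat("Stop-signal ERP pipeline report (", nrow(x$behavioral),
      " subjects )\n\nBehavioral contrasts:\n", sep = "")
  print(x$behavioral_tests, digits = 3)
  cat("\nERP effects:\n")
  print(x$effects, digits = 3)
  cat("\nRegression models:\n")
  print(x$regression_models, digits = 3)
  cat("\nSSRT-latency correlations:\n")
  print(x$correlations, digits = 3)
  invisible(x)
}
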
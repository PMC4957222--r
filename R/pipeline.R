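pool_names <- function() {
  lay <- nirs_layout()
  c("brain_ac", "muscle_ac", "brain_pd", "muscle_pd",
    paste0("brain_ac_d", sprintf("%.1f", unique(lay$distance_cm))),
    paste0("brain_ac_w", unique(lay$wavelength_nm)),
    "ecg", "ecg_low", "ecg_high")
}

# Resolve an analysis pool to a single signal vector. NIRS pools average the
# member columns (with equal trial counts this equals pooling the trials,
# because epoch extraction and averaging are linear); ECG pools are the raw
# or band-passed ECG on the EEG clock.
pool_signal <- function(rec, pool) {
  lay <- nirs_layout()
  pick <- function(sensor, measure, distance = NULL, wavelength = NULL) {
    sel <- lay$sensor == sensor & lay$measure == measure
    if (!is.null(distance)) sel <- sel & lay$distance_cm == distance
    if (!is.null(wavelength)) sel <- sel & lay$wavelength_nm == wavelength
    rowMeans(rec$nirs[, lay$name[sel], drop = FALSE])
  }
  nirs <- function(x) list(signal = x, fs = rec$fs_nirs_nominal, nirs = TRUE)
  ecgp <- function(x) list(signal = x, fs = rec$fs_eeg, nirs = FALSE)
  if (pool == "brain_ac") return(nirs(pick("brain", "AC")))
  if (pool == "muscle_ac") return(nirs(pick("muscle", "AC")))
  if (pool == "brain_pd") return(nirs(pick("brain", "PD")))
  if (pool == "muscle_pd") return(nirs(pick("muscle", "PD")))
  if (grepl("^brain_ac_d", pool))
    return(nirs(pick("brain", "AC",
                     distance = as.numeric(sub("brain_ac_d", "", pool)))))
  if (grepl("^brain_ac_w", pool))
    return(nirs(pick("brain", "AC",
                     wavelength = as.numeric(sub("brain_ac_w", "", pool)))))
  if (pool == "ecg") return(ecgp(rec$ecg))
  if (pool == "ecg_low") return(ecgp(filter_ecg(rec$ecg, rec$fs_eeg,
                                                c(0.3, 10))))
  if (pool == "ecg_high") return(ecgp(filter_ecg(rec$ecg, rec$fs_eeg,
                                                 c(10, 40))))
  stop_pw("unknown analysis pool '%s'", pool)
}

#' Run the full single-night analysis
#'
#' Simulates (or loads) a night, detects slow waves, estimates the N3 heart
#' rate from the ECG, builds the trigger-based EEG-to-NIRS synchronization,
#' and runs the bounded-lag sine-correlation permutation test for every
#' requested (signal pool, landmark) cell.
#'
#' @param config a list (or path to a YAML file) with sections:
#'   `sim` (arguments to [sim_config()]) or `io$dir` (a directory written by
#'   [write_recording()]); optional `detect` ([detection_criteria()]
#'   arguments); `stats` with `pools` (see details; default
#'   `c("brain_ac", "muscle_ac", "brain_pd", "ecg")`), `landmarks` (default
#'   `"onset"`), `n_perm` (default 500), `window_s`, `max_lag_s`, `seed`.
#'   Available pools: pooled AC/PD per sensor, per-distance and
#'   per-wavelength brain AC, and raw/0.3-10 Hz/10-40 Hz ECG
#'   (`pool_names()` lists them).
#' @return object of class `night_result`: `wave_stats`, `hr`, `phase_lock`
#'   (named list keyed `pool.landmark`), `waves`, `sync`, `truth` (when
#'   simulated), `provenance`.
#' @export
run_night <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_pw("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  truth <- NULL
  if (!is.null(config$io$dir)) {
    rec <- read_recording(config$io$dir)
  } else {
    scfg <- do.call(sim_config, config$sim %||% list())
    simres <- simulate_recording(scfg)
    rec <- simres$recording
    truth <- simres$truth
  }
  criteria <- do.call(detection_criteria, config$detect %||% list())
  stats_cfg <- config$stats %||% list()
  pools <- stats_cfg$pools %||% c("brain_ac", "muscle_ac", "brain_pd", "ecg")
  landmarks <- stats_cfg$landmarks %||% "onset"
  n_perm <- stats_cfg$n_perm %||% 500
  window_s <- stats_cfg$window_s %||% c(3, 3)
  base_seed <- stats_cfg$seed %||% 1L

  waves <- detect_slow_waves(rec, criteria)
  if (!nrow(waves)) stop_pw("detection stage: no slow waves found")
  beats <- detect_r_peaks(rec$ecg, rec$fs_eeg)
  hr <- tryCatch(mean_heart_rate(beats, rec$hypnogram, "N3"),
                 error = function(e) {
                   warning("no usable N3 beats; falling back to N2+N3")
                   mean_heart_rate(beats, rec$hypnogram, c("N2", "N3"))
                 })
  sync <- build_sync_map(rec$triggers[["start"]], rec$triggers[["end"]],
                         nrow(rec$nirs), rec$fs_nirs_nominal)
  mask <- stage_mask(rec$hypnogram, nrow(rec$eeg), rec$fs_eeg,
                     c("N2", "N3"), rec$artifacts)
  allowed_times <- (which(mask) - 1) / rec$fs_eeg

  grid <- list()
  cell_i <- 0L
  for (pool in pools) {
    sig <- pool_signal(rec, pool)
    template <- make_sine_template(hr$mean_hz, window_s, sig$fs)
    for (lm in landmarks) {
      cell_i <- cell_i + 1L
      grid[[paste(pool, lm, sep = ".")]] <-
        permutation_test(sig$signal, sig$fs, lock_to_landmark(waves, lm),
                         template, allowed_times,
                         sync = if (sig$nirs) sync else NULL,
                         n_perm = n_perm, window_s = window_s,
                         max_lag_s = stats_cfg$max_lag_s,
                         seed = base_seed + cell_i)
    }
  }
  structure(list(
    wave_stats = list(n_waves = nrow(waves),
                      waves_per_min = attr(waves, "waves_per_min"),
                      median_neg_peak_uV = median(waves$neg_peak_uV),
                      theta_uV = attr(waves, "theta")),
    hr = hr, phase_lock = grid, waves = waves, sync = sync, truth = truth,
    provenance = list(pools = pools, landmarks = landmarks, n_perm = n_perm,
                      window_s = window_s, seed = base_seed,
                      sim_seed = if (!is.null(truth)) truth$config$seed,
                      version = as.character(utils::packageVersion("pulsewave")))),
    class = "night_result")
}

#' @export
print.night_result <- function(x, ...) {
  cat(sprintf("<night_result> %d waves (%.1f/min, median %.1f uV), HR %.1f bpm\n",
              x$wave_stats$n_waves, x$wave_stats$waves_per_min,
              x$wave_stats$median_neg_peak_uV, x$hr$mean_bpm))
  for (nm in names(x$phase_lock)) {
    pl <- x$phase_lock[[nm]]
    cat(sprintf("  %-22s r = %6.3f  delay = %5.0f ms  p = %.4g\n",
                nm, pl$r, 1000 * pl$lag_s, pl$p_value))
  }
  invisible(x)
}

# One-way repeated-measures ANOVA with Greenhouse-Geisser correction;
# Y is nights x conditions.
rm_anova_gg <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  colm <- colMeans(Y); rowm <- rowMeans(Y)
  ss_cond <- n * sum((colm - grand)^2)
  resid <- Y - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  ss_err <- sum(resid^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f_stat <- (ss_cond / df1) / (ss_err / df2)
  S <- cov(Y)
  S_dc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  eps <- sum(diag(S_dc))^2 / ((k - 1) * sum(S_dc^2))
  eps <- min(1, max(eps, 1 / (k - 1)))
  list(F = f_stat, df1 = eps * df1, df2 = eps * df2, epsilon = eps,
       p = stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE))
}

#' Group-level statistics over several nights
#'
#' Collects the per-night sine-correlation coefficients into a table, runs
#' paired t-tests between requested measure pairs, Pearson correlations
#' between measures across nights, and (when all four per-distance brain-AC
#' cells are present) a one-way repeated-measures ANOVA across source-
#' detector distances with Greenhouse-Geisser sphericity correction.
#'
#' @param nights list of `night_result`s (at least 3).
#' @param paired_comparisons list of 2-element character vectors of
#'   `phase_lock` keys, e.g. `list(c("brain_ac.onset", "muscle_ac.onset"))`.
#' @param correlations like `paired_comparisons`, for Pearson correlations.
#' @return object of class `group_result`: `r_table` (nights x keys),
#'   `paired_tests` (t, df, p per comparison), `cross_measure_correlations`
#'   (r, p), `distance_anova` (or NULL).
#' @export
run_group <- function(nights, paired_comparisons = list(),
                      correlations = list()) {
  if (length(nights) < 3L) stop_pw("need at least 3 nights")
  keys <- names(nights[[1]]$phase_lock)
  if (!all(vapply(nights, function(x)
    identical(names(x$phase_lock), keys), TRUE)))
    stop_pw("nights carry mismatched analysis grids")
  r_table <- as.data.frame(lapply(keys, function(k)
    vapply(nights, function(x) x$phase_lock[[k]]$r, 0)))
  names(r_table) <- keys
  run_pair <- function(pair, fun) {
    if (!all(pair %in% keys)) stop_pw("unknown key in comparison: %s",
                                      paste(pair, collapse = " vs "))
    fun(r_table[[pair[1]]], r_table[[pair[2]]])
  }
  paired <- lapply(paired_comparisons, run_pair, fun = function(a, b) {
    d <- a - b
    if (all(d == 0)) return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                                 note = "zero difference vector"))
    tt <- t.test(a, b, paired = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  })
  names(paired) <- vapply(paired_comparisons, paste, "", collapse = "_vs_")
  cors <- lapply(correlations, run_pair, fun = function(a, b) {
    ct <- cor.test(a, b)
    list(r = unname(ct$estimate), p = ct$p.value)
  })
  names(cors) <- vapply(correlations, paste, "", collapse = "_vs_")
  dist_keys <- grep("^brain_ac_d", keys, value = TRUE)
  dist_anova <- if (length(dist_keys) == 4L)
    rm_anova_gg(as.matrix(r_table[, dist_keys])) else NULL
  structure(list(r_table = r_table, paired_tests = paired,
                 cross_measure_correlations = cors,
                 distance_anova = dist_anova),
            class = "group_result")
}

#' Render a plain-text report for one or more nights
#'
#' Markdown summary of wave statistics, heart rate and each phase-locking
#' cell; every number is traceable to the result object. Regeneration from
#' the same results is byte-identical.
#'
#' @param results a `night_result`, `group_result`, or list of either.
#' @param file output path, or "" for stdout.
#' @return the report lines, invisibly.
#' @export
report <- function(results, file = "") {
  if (inherits(results, "night_result") || inherits(results, "group_result"))
    results <- list(results)
  lines <- c("# pulsewave report", "")
  if (!length(results)) lines <- c(lines, "no analyses configured")
  for (res in results) {
    if (inherits(res, "night_result")) {
      lines <- c(lines, "## Night", sprintf(
        "- %d slow waves (%.2f / min), median negative peak %.1f uV",
        res$wave_stats$n_waves, res$wave_stats$waves_per_min,
        res$wave_stats$median_neg_peak_uV),
        sprintf("- heart rate %.2f bpm (%s, %d beats)", res$hr$mean_bpm,
                res$hr$stage_used, res$hr$n_beats), "")
      if (length(res$phase_lock)) {
        lines <- c(lines, "| pool.landmark | r | delay (ms) | p |",
                   "|---|---|---|---|")
        for (nm in names(res$phase_lock)) {
          pl <- res$phase_lock[[nm]]
          lines <- c(lines, sprintf("| %s | %.3f | %.0f | %.4g |", nm, pl$r,
                                    1000 * pl$lag_s, pl$p_value))
        }
        lines <- c(lines, "")
      } else lines <- c(lines, "no analyses configured", "")
    } else if (inherits(res, "group_result")) {
      lines <- c(lines, "## Group")
      for (nm in names(res$paired_tests)) {
        pt <- res$paired_tests[[nm]]
        lines <- c(lines, sprintf("- paired t (%s): t(%g) = %.3f, p = %.4g",
                                  nm, pt$df, pt$t, pt$p))
      }
      for (nm in names(res$cross_measure_correlations)) {
        ct <- res$cross_measure_correlations[[nm]]
        lines <- c(lines, sprintf("- correlation (%s): r = %.3f, p = %.4g",
                                  nm, ct$r, ct$p))
      }
      if (!is.null(res$distance_anova)) {
        da <- res$distance_anova
        lines <- c(lines, sprintf(
          "- distance ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g (GG eps %.3f)",
          da$df1, da$df2, da$F, da$p, da$epsilon))
      }
      lines <- c(lines, "")
    }
  }
  if (nzchar(file)) writeLines(lines, file) else writeLines(lines)
  invisible(lines)
}
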
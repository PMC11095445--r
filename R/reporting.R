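# Group summaries, the standard one-way comparison across swimming modes,
# and the end-to-end pipeline with a machine-readable JSON report.

#' Per-group mean and sample SD
#'
#' Classical "mean +/- SD, n" summaries per group. SD uses the n-1
#' denominator and is `NA` (not applicable) for single-element groups.
#'
#' @param values Named list: group label -> numeric vector (all non-empty).
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(values) {
  if (!length(values) || is.null(names(values)))
    hk_stop("values must be a non-empty named list", "hk_input_error")
  for (g in names(values))
    if (!length(values[[g]]))
      hk_stop(sprintf("group '%s' is empty", g), "hk_input_error")
  do.call(rbind, lapply(names(values), function(g) {
    v <- values[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }))
}

#' One-way fixed-effects ANOVA across groups
#'
#' Standard reporting utility (via [stats::aov()]) for comparisons such as
#' zooid number across swimming modes. When the between-group mean square is
#' zero (all groups identical), F = 0 and p = 1.
#'
#' @param values Named list: group label -> numeric vector (>= 2 groups,
#'   each with >= 2 values).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(values) {
  if (length(values) < 2)
    hk_stop("need >= 2 groups", "hk_input_error")
  sizes <- lengths(values)
  if (any(sizes < 2))
    hk_stop("every group needs >= 2 values", "hk_input_error")
  df <- data.frame(value = unlist(values, use.names = FALSE),
                   group = factor(rep(names(values), sizes)))
  tab <- summary(aov(value ~ group, data = df))[[1]]
  msb <- tab["group", "Mean Sq"]
  out <- list(F = tab["group", "F value"], p = tab["group", "Pr(>F)"],
              df_between = tab["group", "Df"],
              df_within = tab["Residuals", "Df"])
  if (isTRUE(all.equal(msb, 0)) || msb == 0) {
    out$F <- 0; out$p <- 1
  }
  out
}

#' Run the full kinematics pipeline
#'
#' Read -> motion-correct -> spin kinematics + windowed helix fits ->
#' swimming-mode classification -> angle-series statistics, with every
#' default and threshold echoed into the report (full provenance).
#'
#' @param config Named list, or path to a YAML/JSON file, with elements:
#'   `tracks` (CSV path) or `recording` (a [colony_recording()]);
#'   `frame_rate` (needed with `tracks` when no sidecar);
#'   `marker_id` (off-axis marker; defaults to the first
#'   `off_axis_marker` track, if any); `zooid_length` (mm, default from the
#'   recording metadata, else 10); optional `tau`, `window`, `overlap`,
#'   `direction_floor`, `angle_series` (path), `seed` (default 1), `out`
#'   (JSON report path).
#' @return A `helixkin_report` list with `params` and `results`; written as
#'   JSON when `config$out` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  rec <- config$recording
  if (is.null(rec)) {
    if (is.null(config$tracks))
      hk_stop("config must name 'tracks' (CSV path) or supply 'recording'",
              "hk_config_error")
    if (!file.exists(config$tracks))
      hk_stop(sprintf("config 'tracks' file not found: %s", config$tracks),
              "hk_config_error")
    rec <- read_tracks(config$tracks, frame_rate = config$frame_rate)
  }
  zooid_length <- config$zooid_length %||%
    (if (is.finite(rec$zooid_length %||% NA)) rec$zooid_length else 10)
  seed <- config$seed %||% 1L
  params <- list(colony_id = rec$colony_id, frame_rate = rec$frame_rate,
                 zooid_length = zooid_length, tau = config$tau,
                 window = config$window, overlap = config$overlap %||% 0.5,
                 direction_floor = config$direction_floor %||% 0,
                 seed = seed, convention = hk_convention())
  corrected <- correct_recording(rec)
  zids <- names(Filter(function(tr) tr$role == "zooid_gut", rec$tracks))
  zadj <- corrected[zids]
  results <- list()

  if (!length(zadj))
    hk_stop("recording has no zooid_gut tracks", "hk_config_error")
  zord <- vapply(zids, function(id)
    rec$tracks[[id]]$zooid_index %||% NA_integer_, integer(1))
  frontal <- zadj[[if (all(is.na(zord))) 1L else which.min(zord)]]
  results$swim_speed_mm_s <- swim_speed(frontal)
  results$net_speed_mm_s <- net_speed(frontal)

  marker_id <- config$marker_id %||%
    names(Filter(function(tr) tr$role == "off_axis_marker", rec$tracks))[1]
  if (!is.null(marker_id) && !is.na(marker_id)) {
    ph <- phase_angle_series(corrected[[marker_id]],
                             if (length(zadj) >= 2) zadj else
                               fit_helix(frontal)$axis)
    sm <- angular_velocity(ph)
    # mean |omega_i| is positively biased by folded digitization noise when
    # the per-frame phase step is small; the median is robust to it
    results$spin <- list(
      mean_abs_omega_rad_s = sm$mean_abs_omega,
      median_omega_rad_s = sm$median_omega,
      median_omega_deg_s = sm$median_omega * 180 / pi,
      handedness = spin_direction(sm, floor = params$direction_floor))
  }

  mode <- classify_trajectory(frontal, zooid_length, window = config$window,
                              overlap = params$overlap, tau = config$tau)
  params$tau <- mode$tau
  params$window <- attr(attr(mode, "fits"), "window_duration")
  fits <- attr(mode, "fits")
  helical_fits <- Filter(function(f) f$rotating, fits)
  results$mode <- list(mode = mode$mode,
                       fractions = as.list(mode$fractions),
                       n_windows = nrow(mode$window_labels))
  if (length(helical_fits)) {
    results$helix <- list(
      orbit_radius_mm = median(vapply(helical_fits, `[[`, 1, "orbit_radius")),
      pitch_mm_per_turn = median(vapply(helical_fits, `[[`, 1, "pitch")),
      angular_frequency_rad_s =
        median(vapply(helical_fits, `[[`, 1, "angular_frequency")),
      handedness = helical_fits[[1]]$handedness)
  }

  if (!is.null(config$angle_series)) {
    st <- series_stats(read_angle_series(config$angle_series))
    results$siphon_angle <- st[c("max", "min", "mean", "sd", "n",
                                 "percent_decrease")]
  }

  report <- structure(list(params = params, results = results),
                      class = "helixkin_report")
  if (!is.null(config$out))
    jsonlite::write_json(unclass(report), config$out, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null",
                         pretty = TRUE)
  report
}

#' @export
print.helixkin_report <- function(x, ...) {
  cat(sprintf("<helixkin_report> colony '%s'\n", x$params$colony_id))
  cat(sprintf("  mode: %s | swim speed %.1f mm/s (net %.1f)\n",
              x$results$mode$mode, x$results$swim_speed_mm_s,
              x$results$net_speed_mm_s))
  if (!is.null(x$results$spin))
    cat(sprintf("  spin: median omega %.3g rad/s (mean |omega| %.3g), handedness %s\n",
                x$results$spin$median_omega_rad_s,
                x$results$spin$mean_abs_omega_rad_s,
                x$results$spin$handedness))
  if (!is.null(x$results$helix))
    cat(sprintf("  helix: radius %.2f mm, pitch %.1f mm/turn, %s\n",
                x$results$helix$orbit_radius_mm,
                x$results$helix$pitch_mm_per_turn,
                x$results$helix$handedness))
  cat(sprintf("  tau = %.3g mm, window = %.3g s\n", x$params$tau,
              x$params$window %||% NA))
  invisible(x)
}
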
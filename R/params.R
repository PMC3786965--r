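#' Group-level statistics for the manual ethogram
#'
#' Per-cell (6 treatment groups x 2 strains) mean and standard error of the
#' frequency (and, where scored, duration) of each manually scored
#' behaviour, as reported for the vasectomy--buprenorphine study design
#' (n = 4 animals per cell). These are the calibration targets for the
#' synthetic-cohort generator.
#'
#' @return A tibble with columns `behavior`, `group`, `strain`,
#'   `mean_freq`, `sem_freq`, `mean_dur`, `sem_dur`.
#' @export
manual_behaviour_params <- function() {
  readr::read_csv(
    system.file("extdata", "manual_group_params.csv", package = "painscore"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Synthetic group-level statistics for the automated ethogram
#'
#' No per-cell table was reported for the automated (home-cage video)
#' ethogram, so these defaults are synthetic: base frequencies are chosen
#' so that the overall mean of each behaviour lands near its reported
#' Low/Medium/High frequency band anchor (10, 50, 100 events per session),
#' surgery halves activity and roughly doubles grooming, and high-dose
#' buprenorphine depresses activity in C3H controls while partially
#' restoring it in operated C57 mice. Magnitudes are package choices, not
#' reported values.
#'
#' @return A tibble in the same layout as [manual_behaviour_params()].
#' @export
automated_behaviour_params <- function() {
  base <- c(
    "Jumping" = 10, "Come Down" = 14,
    "Rear Up" = 55, "Walk Left" = 62, "Walk Right" = 68,
    "Come Down From Partially Reared" = 110,
    "Come Down To Partially Reared" = 115,
    "Rear Up From Partially Reared" = 120,
    "Remain Low" = 125, "Remain Partially Reared" = 130,
    "Sniff" = 135, "Walk Slow" = 140,
    "Groom" = 8
  )
  cells <- design_cells()
  purrr::map_dfr(names(base), function(b) {
    m <- purrr::pmap_dbl(cells, function(strain, surgery, drug, group) {
      mult <-
        if (b == "Groom") {
          if (surgery == "V") 2.2 else 1
        } else {
          act <- if (surgery == "V") 0.55 else 1.05
          if (drug == "BupH") {
            act <- if (surgery == "A") {
              if (strain == "C3H") act * 0.55 else act * 0.9
            } else {
              if (strain == "C57") act * 1.45 else act
            }
          }
          act
        }
      base[[b]] * mult
    })
    tibble(behavior = b, group = cells$group, strain = cells$strain,
           mean_freq = m, sem_freq = 0.2 * m,
           mean_dur = NA_real_, sem_dur = NA_real_)
  })
}

#' Cohort-level simulation parameters
#'
#' Bundles the behaviour statistics with the physiology parameters of the
#' study: baseline faecal corticosterone of about 30.3 (C57) and 31.5 (C3H)
#' ng/g, baseline body weight of about 26.5 g, a slight post-procedure
#' weight gain in controls (+1.3%) against a modest loss after surgery
#' (-3.7%), and group multipliers taking corticosterone from baseline to
#' its 9-hour peak. Peak multipliers and noise scales are generator
#' defaults (surgery cells above control cells), not reported values.
#'
#' @param behavior Behaviour statistics tibble
#'   (see [manual_behaviour_params()]).
#' @param n_paper Animals per strain x group cell behind the printed SEMs
#'   (4); converts SEM to between-animal variance via `var = n_paper * sem^2`.
#' @param cort_baseline_mean,cort_baseline_sd Named per-strain baseline
#'   corticosterone mean and between-animal sd (ng/g faeces).
#' @param cort_peak_multiplier Named per-group multiplicative change from
#'   baseline to peak.
#' @param cort_noise_sdlog Log-scale sd of the multiplicative lognormal
#'   noise on the peak (mean-one noise).
#' @param weight_baseline_mean,weight_baseline_sd Baseline body weight (g).
#' @param weight_change_pct Named per-surgery-level mean percent weight
#'   change from baseline to 24 h.
#' @param weight_change_sd Per-animal sd of the percent change.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(behavior = manual_behaviour_params(),
                          n_paper = 4,
                          cort_baseline_mean = c(C57 = 30.3, C3H = 31.5),
                          cort_baseline_sd = c(C57 = 3.6 * sqrt(24),
                                               C3H = 2.5 * sqrt(24)),
                          cort_peak_multiplier = c(ASa = 1.8, ABupL = 1.8,
                                                   ABupH = 2.2, VSa = 3.5,
                                                   VBupL = 3.8, VBupH = 4.2),
                          cort_noise_sdlog = 0.5,
                          weight_baseline_mean = 26.5,
                          weight_baseline_sd = 2,
                          weight_change_pct = c(A = 1.3, V = -3.7),
                          weight_change_sd = 3) {
  behavior <- as_tibble(behavior)
  cells <- design_cells()
  have <- behavior |> dplyr::distinct(.data$group, .data$strain)
  if (nrow(dplyr::anti_join(cells[c("group", "strain")], have,
                            by = c("group", "strain"))) > 0) {
    abort("behaviour parameters must cover all 12 strain x group cells")
  }
  num <- c(behavior$mean_freq, behavior$sem_freq, n_paper,
           cort_baseline_mean, cort_baseline_sd, cort_peak_multiplier,
           cort_noise_sdlog, weight_baseline_mean, weight_baseline_sd,
           weight_change_pct, weight_change_sd)
  if (any(!is.finite(num)) || any(behavior$sem_freq < 0) ||
      any(behavior$mean_freq < 0)) {
    abort("all cohort parameters must be finite; means and sems non-negative")
  }
  if (any(cort_peak_multiplier <= 0)) {
    abort("corticosterone peak multipliers must be strictly positive")
  }
  structure(
    list(behavior = behavior, n_paper = n_paper,
         cort_baseline_mean = cort_baseline_mean,
         cort_baseline_sd = cort_baseline_sd,
         cort_peak_multiplier = cort_peak_multiplier,
         cort_noise_sdlog = cort_noise_sdlog,
         weight_baseline_mean = weight_baseline_mean,
         weight_baseline_sd = weight_baseline_sd,
         weight_change_pct = weight_change_pct,
         weight_change_sd = weight_change_sd),
    class = "cohort_params"
  )
}

#' Default calibrated cohort parameters
#'
#' @param arm `"manual"` for the observer-scored ethogram calibrated to the
#'   reported per-cell statistics, `"automated"` for the synthetic
#'   home-cage-video defaults.
#' @return A `cohort_params` object.
#' @export
default_cohort_params <- function(arm = c("manual", "automated")) {
  arm <- match.arg(arm)
  cohort_params(behavior = switch(arm,
                                  manual = manual_behaviour_params(),
                                  automated = automated_behaviour_params()))
}

#' Strip all randomness from cohort parameters
#'
#' Sets every SEM/sd/noise scale to zero and every corticosterone multiplier
#' to one, so a simulated cohort is fully deterministic: counts equal the
#' rounded cell means and the corticosterone peak equals its baseline.
#' Useful for pinning down the generator in tests.
#'
#' @param params A `cohort_params` object.
#' @return A `cohort_params` object with zero dispersion.
#' @export
zero_variance_params <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  params$behavior$sem_freq <- 0
  params$behavior$sem_dur <- ifelse(is.na(params$behavior$sem_dur), NA, 0)
  params$cort_baseline_sd[] <- 0
  params$cort_peak_multiplier[] <- 1
  params$cort_noise_sdlog <- 0
  params$weight_baseline_sd <- 0
  params$weight_change_sd <- 0
  params
}

#' Pool cohort parameters into a no-effect (null) configuration
#'
#' Every strain x group cell receives the same per-behaviour mean and SEM
#' (the across-cell average, with SEMs pooled as root-mean-square), a common
#' corticosterone multiplier and a common weight change, so no factor has
#' any true effect. Used to verify false-positive control of the inference
#' layer.
#'
#' @param params A `cohort_params` object.
#' @return A `cohort_params` object with identical cells.
#' @export
null_cohort_params <- function(params = default_cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  pooled <- params$behavior |>
    dplyr::group_by(.data$behavior) |>
    dplyr::summarise(
      mean_freq = mean(.data$mean_freq),
      sem_freq = sqrt(mean(.data$sem_freq^2)),
      mean_dur = mean(.data$mean_dur),
      sem_dur = sqrt(mean(.data$sem_dur^2)),
      .groups = "drop"
    )
  cells <- design_cells()
  params$behavior <- pooled |>
    dplyr::mutate(order = dplyr::row_number()) |>
    tidyr::expand_grid(cells[c("group", "strain")]) |>
    dplyr::arrange(.data$order) |>
    dplyr::select("behavior", "group", "strain", "mean_freq", "sem_freq",
                  "mean_dur", "sem_dur")
  m <- mean(params$cort_baseline_mean)
  s <- mean(params$cort_baseline_sd)
  params$cort_baseline_mean[] <- m
  params$cort_baseline_sd[] <- s
  params$cort_peak_multiplier[] <- mean(params$cort_peak_multiplier)
  params$weight_change_pct[] <- mean(params$weight_change_pct)
  params
}
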
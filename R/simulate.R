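# Counter-based substreams: each (behaviour, cell) pair gets its own seed
# derived from the global seed, so adding a behaviour to the catalog leaves
# every other behaviour's draws untouched.
substream_seed <- function(seed, i, j) {
  as.integer((abs(seed) + 10007 * i + 997 * j) %% 2147483647)
}

# Counts with mean mu and variance sigma2: negative binomial when
# overdispersed, Poisson when sigma2 <= mu, deterministic when sigma2 == 0,
# structural zeros when mu == 0.
draw_counts <- function(n, mu, sigma2) {
  if (mu == 0) return(rep(0L, n))
  if (sigma2 <= 0) return(rep(as.integer(round(mu)), n))
  if (sigma2 <= mu) return(stats::rpois(n, mu))
  size <- mu^2 / (sigma2 - mu)
  stats::rnbinom(n, size = size, mu = mu)
}

# Durations conditional on counts: gamma with cell-level coefficient of
# variation, per-animal mean scaled by count/mean count so time tracks
# event number; zero whenever the count is zero.
draw_durations <- function(counts, mean_freq, mean_dur, var_dur) {
  out <- numeric(length(counts))
  pos <- counts > 0
  if (!any(pos) || is.na(mean_dur) || mean_dur == 0) return(out)
  m_k <- mean_dur * counts[pos] / mean_freq
  if (is.na(var_dur) || var_dur <= 0) {
    out[pos] <- m_k
  } else {
    shape <- mean_dur^2 / var_dur
    out[pos] <- stats::rgamma(length(m_k), shape = shape, rate = shape / m_k)
  }
  out
}

#' Simulate a synthetic cohort from group-level parameters
#'
#' Draws per-animal behaviour counts for every strain x group design cell
#' from a negative binomial with mean equal to the cell mean and variance
#' reconstructed from the printed SEM (`var = n_paper * sem^2`; Poisson when
#' that variance does not exceed the mean; exact zeros for zero-mean cells).
#' Durations, where parameterised, are gamma-distributed conditional on the
#' count. Physiology (body weights, baseline and 9-hour peak faecal
#' corticosterone) is filled per animal. Identical seeds give bit-identical
#' cohorts.
#'
#' @param params A [cohort_params()] object.
#' @param n_per_cell Animals per strain x group cell (study value 4).
#' @param seed Integer seed; all randomness derives from it.
#' @return An `ethogram` whose animal table carries the physiology columns.
#' @export
simulate_cohort <- function(params = default_cohort_params(),
                            n_per_cell = 4, seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.numeric(n_per_cell) || length(n_per_cell) != 1 ||
      !is.finite(n_per_cell) || n_per_cell < 1) {
    abort("n_per_cell must be a positive integer")
  }
  n_per_cell <- as.integer(n_per_cell)
  cells <- design_cells()
  behaviours <- unique(params$behavior$behavior)
  n_animals <- nrow(cells) * n_per_cell

  animals <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ] |>
    dplyr::mutate(
      animal_id = sprintf("%s_%s_%03d", .data$strain, .data$group,
                          rep(seq_len(n_per_cell), times = nrow(cells)))
    ) |>
    dplyr::select("animal_id", "strain", "surgery", "drug", "group")

  freq <- matrix(0, n_animals, length(behaviours),
                 dimnames = list(animals$animal_id, behaviours))
  has_dur <- any(!is.na(params$behavior$mean_dur))
  dur <- if (has_dur) freq else NULL

  par_key <- paste(params$behavior$behavior, params$behavior$group,
                   params$behavior$strain)
  for (i in seq_along(behaviours)) {
    for (j in seq_len(nrow(cells))) {
      row <- params$behavior[
        match(paste(behaviours[i], cells$group[j], cells$strain[j]), par_key), ]
      if (nrow(row) == 0 || is.na(row$mean_freq)) {
        abort(sprintf("missing parameters for behaviour '%s' in cell %s/%s",
                      behaviours[i], cells$group[j], cells$strain[j]))
      }
      set.seed(substream_seed(seed, i, j))
      idx <- ((j - 1) * n_per_cell + 1):(j * n_per_cell)
      counts <- draw_counts(n_per_cell, row$mean_freq,
                            params$n_paper * row$sem_freq^2)
      freq[idx, i] <- counts
      if (has_dur && !is.na(row$mean_dur)) {
        dur[idx, i] <- draw_durations(
          counts, row$mean_freq, row$mean_dur,
          params$n_paper * row$sem_dur^2
        )
      }
    }
  }

  phys <- purrr::map_dfr(seq_len(nrow(cells)), function(j) {
    set.seed(substream_seed(seed, 499979, j))
    strain <- cells$strain[j]
    wb <- stats::rnorm(n_per_cell, params$weight_baseline_mean,
                       params$weight_baseline_sd)
    wb <- pmax(wb, 1)
    pct <- stats::rnorm(n_per_cell,
                        params$weight_change_pct[[cells$surgery[j]]],
                        params$weight_change_sd)
    cb_mean <- params$cort_baseline_mean[[strain]]
    cb_sd <- params$cort_baseline_sd[[strain]]
    cb <- if (cb_sd > 0) {
      sdlog <- sqrt(log(1 + cb_sd^2 / cb_mean^2))
      stats::rlnorm(n_per_cell, log(cb_mean) - sdlog^2 / 2, sdlog)
    } else rep(cb_mean, n_per_cell)
    noise <- if (params$cort_noise_sdlog > 0) {
      exp(stats::rnorm(n_per_cell, -params$cort_noise_sdlog^2 / 2,
                       params$cort_noise_sdlog))
    } else rep(1, n_per_cell)
    tibble(
      weight_baseline = wb,
      weight_24h = wb * (1 + pct / 100),
      cort_baseline = cb,
      cort_peak = cb * params$cort_peak_multiplier[[cells$group[j]]] * noise
    )
  })
  animals <- dplyr::bind_cols(animals, phys)

  ethogram(animals, freq, dur = dur,
           catalog = tibble(behavior = behaviours,
                            modality = ifelse(
                              behaviours %in%
                                params$behavior$behavior[!is.na(params$behavior$mean_dur)],
                              "both", "frequency"),
                            source = "synthetic"))
}

#' Simulate a null cohort with no group, surgery or strain effect
#'
#' All 12 design cells share one pooled parameter set (see
#' [null_cohort_params()]), so any downstream rejection of a factor effect
#' is a false positive. Used for type-I-error checks of the factorial
#' ANOVA and the discriminant significance tests.
#'
#' @param params A `cohort_params` object to pool, or an already pooled one.
#' @param n_per_cell Animals per cell (>= 2 for downstream tests).
#' @param seed Integer seed.
#' @return An `ethogram`.
#' @export
simulate_null_cohort <- function(params = default_cohort_params(),
                                 n_per_cell = 4, seed = 1) {
  if (n_per_cell < 2) abort("n_per_cell must be at least 2 for a null cohort")
  simulate_cohort(null_cohort_params(params), n_per_cell = n_per_cell,
                  seed = seed)
}
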
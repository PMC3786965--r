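#' Pipeline configuration
#'
#' @param input Path to a long-format ethogram CSV, or `NULL` to simulate.
#' @param simulate Logical; generate a synthetic cohort instead of reading
#'   `input`. Exactly one of the two modes must be active.
#' @param params `cohort_params` for simulate mode (default: the calibrated
#'   manual-arm parameters; the automated arm uses its own defaults).
#' @param n_per_cell Animals per design cell in simulate mode.
#' @param seed Integer seed for simulate mode.
#' @param arm `"manual"`, `"automated"` or `"both"`.
#' @param cutoff Loading threshold for subset selection.
#' @param fold_limit Fold limit for magnitude exclusion.
#' @param memberships `"default"` to score the pinned composite
#'   memberships (see [default_memberships()]), or `"selection"` to derive
#'   Score 1/2 membership from the data via selection + magnitude
#'   exclusion.
#' @param family Bonferroni family for post-hocs.
#' @param alpha Significance level.
#' @param out_dir Output directory for tables, logs and the manifest;
#'   `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = is.null(input),
                            params = NULL, n_per_cell = 4, seed = 1,
                            arm = c("manual", "automated", "both"),
                            cutoff = 0.1, fold_limit = 2.0,
                            memberships = c("default", "selection"),
                            family = c("all_pairs", "vs_reference"),
                            alpha = 0.05, out_dir = NULL) {
  arm <- match.arg(arm)
  memberships <- match.arg(memberships)
  family <- match.arg(family)
  if (is.null(input) == !simulate) {
    abort("exactly one of 'input' or simulate mode must be active")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  structure(
    list(input = input, simulate = simulate, params = params,
         n_per_cell = n_per_cell, seed = seed, arm = arm, cutoff = cutoff,
         fold_limit = fold_limit, memberships = memberships,
         family = family, alpha = alpha, out_dir = out_dir),
    class = "pipeline_config"
  )
}

run_arm <- function(eth, arm, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' (%s arm) failed: %s",
                    name, arm, conditionMessage(e)))
    })
  }
  # stage 1: screening DA on the surgery grouping
  da1 <- stage("screening-da", fit_cda(eth, grouping = "surgery"))
  selection <- stage("subset-selection",
                     select_subsets(da1, cutoff = config$cutoff,
                                    alpha = config$alpha))
  selection <- stage("magnitude-exclusion",
                     apply_magnitude_exclusion(selection, eth,
                                               fold_limit = config$fold_limit))

  # stage 2: derived per-animal measures
  measures <- if (arm == "manual") {
    mem <- if (config$memberships == "selection") {
      list(score1 = selection$positive, score2 = selection$negative,
           standalone = selection$excluded_high_magnitude)
    } else default_memberships()
    stage("derived-measures", derived_measures(eth, "manual",
                                               memberships = mem))
  } else {
    stage("derived-measures", derived_measures(eth, "automated"))
  }

  # stage 3: second DA on the 6-group treatment factor over the derived
  # measures (Score 1/2 + standalone, or band composites + grooming)
  da2_vars <- if (arm == "manual") {
    intersect(c("score1", "score2", "abnormal_walk", "walk_normal", "stop"),
              names(measures))
  } else {
    intersect(c("band_low", "band_medium", "band_high", "grooming"),
              names(measures))
  }
  da2 <- stage("treatment-da",
               fit_cda(measures[c("animal_id", "group", da2_vars)],
                       grouping = "group"))

  # stage 4: factorial inference per derived measure
  resp <- if (arm == "manual") da2_vars else
    intersect(c("g_behave", "grooming"), names(measures))
  anovas <- purrr::map(resp, function(r) {
    stage(paste0("anova-", r),
          factorial_anova(measures, r, terms = c("strain", "surgery", "drug")))
  })
  names(anovas) <- resp
  posthocs <- purrr::map(resp, function(r) {
    stage(paste0("posthoc-", r),
          bonferroni_posthoc(measures, r, "group", family = config$family))
  })
  names(posthocs) <- resp

  list(da1 = da1, selection = selection, measures = measures, da2 = da2,
       anovas = anovas, posthocs = posthocs, da2_vars = da2_vars)
}

#' Run the full pain-assessment analysis pipeline
#'
#' Executes, per analysis arm: screening discriminant analysis on the
#' surgery grouping; loading-threshold subset selection with magnitude
#' exclusion; composite scoring; a second discriminant analysis on the six
#' treatment groups over the derived measures; factorial
#' Strain x Surgery x Drug ANOVA with Bonferroni post-hocs per measure.
#' Physiology is analysed once: percent body-weight change, corticosterone
#' outlier exclusion and log change (with ANOVA and post-hocs), and Pearson
#' correlations between each derived measure and peak corticosterone.
#' Writes CSV tables, the exclusion log and a JSON run manifest when
#' `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A `pain_report` list, invisibly when written to disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  arms <- if (config$arm == "both") c("manual", "automated") else config$arm

  cohorts <- list()
  if (config$simulate) {
    for (a in arms) {
      p <- config$params
      if (is.null(p)) p <- default_cohort_params(a)
      cohorts[[a]] <- simulate_cohort(p, n_per_cell = config$n_per_cell,
                                      seed = config$seed)
    }
  } else {
    eth <- read_ethogram(config$input)
    for (a in arms) cohorts[[a]] <- eth
  }

  results <- purrr::imap(cohorts, function(eth, a) run_arm(eth, a, config))

  # physiology from the first cohort's animal table
  animals <- cohorts[[1]]$animals
  weight <- NULL
  if (all(c("weight_baseline", "weight_24h") %in% names(animals))) {
    weight <- weight_pct_change(animals)
    weight_anova <- factorial_anova(weight, "weight_pct_change",
                                    terms = c("strain", "surgery", "drug"))
    weight_posthoc <- bonferroni_posthoc(weight, "weight_pct_change",
                                         "group", family = config$family)
  } else weight_anova <- weight_posthoc <- NULL

  cort <- cort_anova <- cort_posthoc <- NULL
  exclusion_log <- tibble(animal_id = character(), reason = character())
  if (all(c("cort_baseline", "cort_peak") %in% names(animals))) {
    flt <- filter_cort_outliers(animals)
    exclusion_log <- flt$log
    if (nrow(flt$kept) > 0) {
      cort <- cort_log_change(flt$kept)
      cort_anova <- factorial_anova(cort, "cort_log_change",
                                    terms = c("strain", "surgery"))
      cort_posthoc <- bonferroni_posthoc(cort, "cort_log_change", "group",
                                         family = config$family)
    }
  }

  correlations <- purrr::imap_dfr(results, function(res, a) {
    if (is.null(cort)) return(tibble())
    msr <- dplyr::inner_join(
      res$measures[c("animal_id", res$da2_vars)],
      cort[c("animal_id", "cort_peak")], by = "animal_id")
    purrr::map_dfr(res$da2_vars, function(v) {
      dplyr::bind_cols(tibble(arm = a, measure = v),
                       correlate_behaviour_cort(msr, v))
    })
  })

  report <- structure(
    list(config = config, arms = results, weight = weight,
         weight_anova = weight_anova, weight_posthoc = weight_posthoc,
         cort = cort, cort_anova = cort_anova, cort_posthoc = cort_posthoc,
         exclusion_log = exclusion_log, correlations = correlations),
    class = "pain_report"
  )

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    return(invisible(report))
  }
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  for (a in names(report$arms)) {
    res <- report$arms[[a]]
    export_cda(res$da1, dir, prefix = paste0(a, "_da1"))
    export_cda(res$da2, dir, prefix = paste0(a, "_da2"))
    readr::write_csv(res$selection$loadings,
                     file.path(dir, paste0(a, "_selection.csv")),
                     progress = FALSE)
    readr::write_csv(res$measures,
                     file.path(dir, paste0(a, "_measures.csv")),
                     progress = FALSE)
    for (r in names(res$anovas)) {
      readr::write_csv(tidy(res$anovas[[r]]),
                       file.path(dir, sprintf("%s_anova_%s.csv", a, r)),
                       progress = FALSE)
      readr::write_csv(res$posthocs[[r]],
                       file.path(dir, sprintf("%s_posthoc_%s.csv", a, r)),
                       progress = FALSE)
    }
  }
  if (!is.null(report$weight)) {
    readr::write_csv(tidy(report$weight_anova),
                     file.path(dir, "weight_anova.csv"), progress = FALSE)
  }
  if (!is.null(report$cort_anova)) {
    readr::write_csv(tidy(report$cort_anova),
                     file.path(dir, "cort_anova.csv"), progress = FALSE)
  }
  readr::write_csv(report$exclusion_log,
                   file.path(dir, "exclusion_log.csv"), progress = FALSE)
  if (nrow(report$correlations) > 0) {
    readr::write_csv(report$correlations,
                     file.path(dir, "correlations.csv"), progress = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("painscore")),
    seed = cfg$seed,
    n_per_cell = cfg$n_per_cell,
    arm = cfg$arm,
    simulate = cfg$simulate,
    cutoff = cfg$cutoff,
    fold_limit = cfg$fold_limit,
    memberships = cfg$memberships,
    family = cfg$family,
    alpha = cfg$alpha
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pain_report <- function(x, ...) {
  cat("Pain-assessment pipeline report\n")
  for (a in names(x$arms)) {
    res <- x$arms[[a]]
    g <- glance(res$da2)
    cat(sprintf(
      "- %s arm: DA2 %d functions (Wilks p = %.3g); measures: %s\n",
      a, g$n_functions, g$p_value, paste(res$da2_vars, collapse = ", ")))
  }
  if (nrow(x$exclusion_log) > 0) {
    cat(sprintf("- corticosterone exclusions: %d\n", nrow(x$exclusion_log)))
  }
  invisible(x)
}
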
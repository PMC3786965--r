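#' Default composite-score memberships for the manual ethogram
#'
#' Score 1 (pain-specific) averages writhing, Press2, rear leg lift, wound
#' licking and wound scratching; Score 2 (normal behaviour) averages high
#' rearing, head licking, head/other scratching, digging and normal
#' posture. Abnormal walking, normal walking and stopping are analysed as
#' standalone measures because their overall frequencies dwarf their subset
#' peers.
#'
#' @return A named list with elements `score1`, `score2`, `standalone`.
#' @export
default_memberships <- function() {
  list(
    score1 = c("Writhe", "Press2", "Rear Leg Lift", "Lick Wound",
               "Scratch Wound"),
    score2 = c("High Rear", "Lick Head", "Scratch Head", "Scratch Other",
               "Dig", "Normal Posture"),
    standalone = c("Abnormal Walk", "Walk Normal", "Stop")
  )
}

# Pure thresholding of a named loading vector: >= +cutoff positive,
# <= -cutoff negative, everything else dropped.
threshold_loadings <- function(loadings, cutoff = 0.1) {
  stopifnot(cutoff > 0)
  list(
    positive = names(loadings)[loadings >= cutoff],
    negative = names(loadings)[loadings <= -cutoff]
  )
}

#' Select behaviour subsets from discriminant structure correlations
#'
#' Behaviours whose structure correlation with the chosen canonical
#' function is at least `+cutoff` form the positive subset (increased in
#' response to surgery when the fit groups on surgery); those at or below
#' `-cutoff` form the negative subset. The threshold is applied to the
#' signed correlation r (the reported "R2" cut-off is signed, so it is a
#' correlation, not a squared one). Selection refuses — returning empty
#' subsets with `significant = FALSE` and a warning — when the chosen
#' function's sequential Wilks test is not significant at `alpha`.
#'
#' @param fit A `cda_fit`.
#' @param cutoff Positive loading threshold (default 0.1, inclusive).
#' @param function_index Which canonical function drives selection
#'   (default 1).
#' @param alpha Significance gate on the function's Wilks test.
#' @return An object of class `subset_selection`: a list with `loadings`
#'   (tibble behaviour/loading/subset), `positive`, `negative`,
#'   `excluded_high_magnitude` (empty until
#'   [apply_magnitude_exclusion()]), `function_index`, `significant`,
#'   `cutoff`.
#' @export
select_subsets <- function(fit, cutoff = 0.1, function_index = 1,
                           alpha = 0.05) {
  stopifnot(inherits(fit, "cda_fit"))
  if (function_index < 1 || function_index > nrow(fit$functions)) {
    abort(sprintf("function_index %d out of range (fit has %d functions)",
                  function_index, nrow(fit$functions)))
  }
  loadings <- fit$structure[, function_index]
  names(loadings) <- rownames(fit$structure)
  p_fun <- fit$functions$p_value[function_index]
  significant <- is.finite(p_fun) && p_fun < alpha
  sel <- if (significant) threshold_loadings(loadings, cutoff) else {
    warn(sprintf(
      "function %d is not significant (Wilks p = %.3g >= %.2g); no behaviours selected",
      function_index, p_fun, alpha))
    list(positive = character(), negative = character())
  }
  structure(
    list(
      loadings = tibble(
        behavior = names(loadings),
        loading = unname(loadings),
        subset = dplyr::case_when(
          !significant ~ "dropped",
          loadings >= cutoff ~ "positive",
          loadings <= -cutoff ~ "negative",
          TRUE ~ "dropped"
        )
      ),
      positive = sel$positive,
      negative = sel$negative,
      excluded_high_magnitude = character(),
      function_index = function_index,
      significant = significant,
      cutoff = cutoff
    ),
    class = "subset_selection"
  )
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf("Subset selection on Function %d (|r| >= %.2g)%s\n",
              x$function_index, x$cutoff,
              if (x$significant) "" else " [function not significant]"))
  cat("positive:", paste(x$positive, collapse = ", "), "\n")
  cat("negative:", paste(x$negative, collapse = ", "), "\n")
  if (length(x$excluded_high_magnitude) > 0) {
    cat("excluded (high magnitude):",
        paste(x$excluded_high_magnitude, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Move excessively frequent behaviours out of composite averaging
#'
#' Within each selected subset, a behaviour whose overall mean frequency
#' exceeds `fold_limit` times the median of its subset's overall means is
#' moved to `excluded_high_magnitude`: it is kept for standalone analysis
#' but removed from composite averaging, so that one high-magnitude act
#' (e.g. abnormal walking) cannot dominate the composite. A single-member
#' subset is never pruned.
#'
#' @param selection A `subset_selection`.
#' @param x The `ethogram` the selection was derived from.
#' @param fold_limit Fold-change limit relative to the subset median
#'   (default 2).
#' @return The updated `subset_selection`.
#' @export
apply_magnitude_exclusion <- function(selection, x, fold_limit = 2.0) {
  stopifnot(inherits(selection, "subset_selection"), inherits(x, "ethogram"))
  overall <- colMeans(x$freq)
  prune <- function(members) {
    if (length(members) < 2) return(list(keep = members, drop = character()))
    m <- overall[members]
    lim <- fold_limit * stats::median(m)
    list(keep = members[m <= lim], drop = members[m > lim])
  }
  pos <- prune(selection$positive)
  neg <- prune(selection$negative)
  selection$positive <- pos$keep
  selection$negative <- neg$keep
  selection$excluded_high_magnitude <- c(pos$drop, neg$drop)
  selection
}

#' Composite behaviour score: mean frequency over member behaviours
#'
#' @param x An `ethogram`.
#' @param members Character vector of behaviour names (all must exist).
#' @param name Column name for the score.
#' @return A tibble with `animal_id` and the per-animal arithmetic mean of
#'   the member behaviours' frequencies.
#' @export
compute_composite <- function(x, members, name = "score") {
  stopifnot(inherits(x, "ethogram"))
  unknown <- setdiff(members, colnames(x$freq))
  if (length(unknown) > 0) {
    abort(paste0("unknown behaviour(s): ", paste(unknown, collapse = ", ")))
  }
  tibble(
    animal_id = x$animals$animal_id,
    !!name := unname(rowMeans(x$freq[, members, drop = FALSE]))
  )
}

#' Band behaviours by their typical session frequency
#'
#' Each behaviour is assigned to the Low, Medium or High band whose anchor
#' frequency (10, 50, 100 events per session by default) is nearest its
#' overall mean on a log scale; the implied decision boundaries for new
#' data are the geometric midpoints between anchors (sqrt(10*50) ~ 22.4,
#' sqrt(50*100) ~ 70.7), with boundary values assigned upward. A behaviour
#' never observed is assigned Low and flagged.
#'
#' @param x An `ethogram`.
#' @param behaviors Behaviours to band (default: all in the catalog).
#' @param anchors The three band anchor frequencies, ascending.
#' @return An object of class `frequency_bands`: a list with `assignment`
#'   (tibble behaviour/mean_frequency/band/flag), `anchors`, `boundaries`.
#' @export
assign_frequency_bands <- function(x, behaviors = NULL,
                                   anchors = c(10, 50, 100)) {
  stopifnot(inherits(x, "ethogram"), length(anchors) == 3,
            all(diff(anchors) > 0))
  if (is.null(behaviors)) behaviors <- colnames(x$freq)
  unknown <- setdiff(behaviors, colnames(x$freq))
  if (length(unknown) > 0) {
    abort(paste0("unknown behaviour(s): ", paste(unknown, collapse = ", ")))
  }
  boundaries <- sqrt(anchors[-3] * anchors[-1])
  overall <- colMeans(x$freq[, behaviors, drop = FALSE])
  band <- ifelse(overall < boundaries[1], "Low",
                 ifelse(overall < boundaries[2], "Medium", "High"))
  flag <- overall == 0
  band[flag] <- "Low"
  structure(
    list(
      assignment = tibble(behavior = behaviors,
                          mean_frequency = unname(overall),
                          band = factor(unname(band),
                                        levels = c("Low", "Medium", "High")),
                          zero_flag = unname(flag)),
      anchors = anchors,
      boundaries = boundaries
    ),
    class = "frequency_bands"
  )
}

#' @export
print.frequency_bands <- function(x, ...) {
  cat(sprintf("Frequency bands (anchors %s; boundaries %.2f / %.2f)\n",
              paste(x$anchors, collapse = "/"),
              x$boundaries[1], x$boundaries[2]))
  print(as.data.frame(x$assignment))
  invisible(x)
}

#' Per-animal band sums for banded behaviours
#'
#' @param x An `ethogram`.
#' @param bands A `frequency_bands` object.
#' @return A tibble with `animal_id`, `band_low`, `band_medium`,
#'   `band_high`: the per-animal total frequency within each band.
#' @export
band_totals <- function(x, bands) {
  stopifnot(inherits(x, "ethogram"), inherits(bands, "frequency_bands"))
  sums <- function(lev) {
    b <- bands$assignment$behavior[bands$assignment$band == lev]
    if (length(b) == 0) return(rep(0, nrow(x$freq)))
    rowSums(x$freq[, b, drop = FALSE])
  }
  tibble(
    animal_id = x$animals$animal_id,
    band_low = sums("Low"),
    band_medium = sums("Medium"),
    band_high = sums("High")
  )
}

#' Geometric activity summary G-behave
#'
#' One-tenth of the geometric mean of the incremented band totals:
#' \deqn{G = 10^{\log_{10}\{(L+1)(M+1)(H+1)\}/3 - 1}.}
#' Zero activity in all bands gives the floor value 0.1; equal totals of 9
#' in each band give exactly 1. Strictly increasing and symmetric in each
#' argument.
#'
#' @param low,medium,high Non-negative band totals (vectorised).
#' @return Numeric vector of G-behave values.
#' @export
compute_gbehave <- function(low, medium, high) {
  v <- c(low, medium, high)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("band totals must be finite and non-negative")
  }
  10^(log10((low + 1) * (medium + 1) * (high + 1)) / 3 - 1)
}

#' Derived per-animal measures for one analysis arm
#'
#' For the manual arm: composite Score 1 and Score 2 plus the standalone
#' measures (abnormal walking, normal walking, stop). For the automated
#' arm: Low/Medium/High band totals, G-behave and grooming.
#'
#' @param x An `ethogram`.
#' @param arm `"manual"` or `"automated"`.
#' @param memberships Score memberships for the manual arm
#'   (default [default_memberships()]).
#' @param bands Optional precomputed `frequency_bands` for the automated
#'   arm; computed from the data when `NULL`.
#' @return A tibble of per-animal derived measures joined to the design
#'   factors.
#' @export
derived_measures <- function(x, arm = c("manual", "automated"),
                             memberships = default_memberships(),
                             bands = NULL) {
  stopifnot(inherits(x, "ethogram"))
  arm <- match.arg(arm)
  base <- x$animals[intersect(c("animal_id", "strain", "surgery", "drug",
                                "group", "weight_baseline", "weight_24h",
                                "cort_baseline", "cort_peak"),
                              names(x$animals))]
  if (arm == "manual") {
    out <- base |>
      dplyr::left_join(compute_composite(x, memberships$score1, "score1"),
                       by = "animal_id") |>
      dplyr::left_join(compute_composite(x, memberships$score2, "score2"),
                       by = "animal_id")
    for (b in memberships$standalone) {
      if (b %in% colnames(x$freq)) {
        nm <- tolower(gsub(" ", "_", b))
        out[[nm]] <- x$freq[, b]
      }
    }
    out
  } else {
    banded <- setdiff(colnames(x$freq), "Groom")
    if (is.null(bands)) bands <- assign_frequency_bands(x, banded)
    out <- base |>
      dplyr::left_join(band_totals(x, bands), by = "animal_id") |>
      dplyr::mutate(g_behave = compute_gbehave(.data$band_low,
                                               .data$band_medium,
                                               .data$band_high))
    if ("Groom" %in% colnames(x$freq)) out$grooming <- x$freq[, "Groom"]
    out
  }
}
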
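#' Factorial fixed-effects ANOVA for a derived measure
#'
#' Least-squares fit of `response ~ terms` (main effects plus any
#' interactions given with `:` or `*`), with sum-to-zero factor coding and
#' Type III sums of squares — the convention of SPSS-style univariate GLM;
#' in the fully balanced 2 x 2 x 3 design Types I-III coincide. The
#' `group` factor (6 treatment cells) is the `surgery:drug` product and is
#' aliased with models that already contain both; requesting such a model
#' is an explicit error rather than a silent drop.
#'
#' @param data Data frame with the response and factor columns (e.g. the
#'   output of [derived_measures()]).
#' @param response Name of the response column.
#' @param terms Character vector of model terms, e.g.
#'   `c("strain", "surgery", "drug")` or
#'   `c("strain", "surgery", "drug", "surgery:drug")`.
#' @return An `anova_table`: a tibble with `term`, `df_num`, `df_den`,
#'   `statistic` (F), `p_value`, plus attributes `response` and
#'   `degenerate`.
#' @export
factorial_anova <- function(data, response,
                            terms = c("strain", "surgery", "drug")) {
  data <- as_tibble(data)
  if (!response %in% names(data)) {
    abort(sprintf("response column '%s' not found", response))
  }
  vars <- unique(unlist(strsplit(terms, "[:*]")))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("factor column(s) not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[c(response, vars)]), ]
  y <- data[[response]]
  if (!all(is.finite(y))) abort("response must be finite")
  for (v in vars) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2) {
      abort(sprintf("factor '%s' needs at least 2 levels", v))
    }
  }
  if (stats::var(y) == 0) {
    # no variance to partition: flag rather than fabricate statistics
    tab <- tibble(term = terms, df_num = NA_integer_, df_den = NA_integer_,
                  statistic = 0, p_value = 1)
    attr(tab, "response") <- response
    attr(tab, "degenerate") <- TRUE
    class(tab) <- c("anova_table", class(tab))
    return(tab)
  }
  fml <- stats::reformulate(terms, response = as.name(response))
  contr <- stats::setNames(
    rep(list("contr.sum"), length(vars)), vars)
  fit <- stats::lm(fml, data = data, contrasts = contr)
  if (any(is.na(stats::coef(fit)))) {
    al <- stats::alias(fit)$Complete
    offenders <- if (!is.null(al)) rownames(al) else
      names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort(paste0("aliased model terms (collinear design): ",
                 paste(offenders, collapse = ", ")),
          class = "painscore_error_alias")
  }
  a3 <- car::Anova(fit, type = "III")
  rn <- rownames(a3)
  keep <- !rn %in% c("(Intercept)", "Residuals")
  df_den <- a3[rn == "Residuals", "Df"]
  tab <- tibble(
    term = rn[keep],
    df_num = as.integer(a3[keep, "Df"]),
    df_den = as.integer(df_den),
    statistic = a3[keep, "F value"],
    p_value = a3[keep, "Pr(>F)"]
  )
  attr(tab, "response") <- response
  attr(tab, "degenerate") <- FALSE
  class(tab) <- c("anova_table", class(tab))
  tab
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise two-sample t comparisons between factor levels using the
#' pooled residual mean square of the one-way fit as the error term, with
#' `adjusted_p = min(1, raw_p * family_size)` over the chosen family: all
#' pairs (6 groups give 15 comparisons) or each level against one
#' reference. Levels with fewer than 2 animals are flagged, not computed.
#'
#' @param data Data frame with the response and factor columns.
#' @param response Name of the response column.
#' @param factor Name of the factor column (e.g. `"group"`).
#' @param family `"all_pairs"` or `"vs_reference"`.
#' @param reference Reference level when `family = "vs_reference"`.
#' @return A `posthoc_table` tibble: `level_a`, `level_b`, `estimate`
#'   (mean difference a - b), `raw_p`, `adjusted_p`, `family_size`,
#'   `computed`.
#' @export
bonferroni_posthoc <- function(data, response, factor,
                               family = c("all_pairs", "vs_reference"),
                               reference = NULL) {
  family <- match.arg(family)
  data <- as_tibble(data)
  stopifnot(response %in% names(data), factor %in% names(data))
  data <- data[stats::complete.cases(data[c(response, factor)]), ]
  f <- droplevels(base::factor(data[[factor]]))
  if (nlevels(f) < 2) abort("factor needs at least 2 levels")
  y <- data[[response]]
  lv <- levels(f)
  nl <- as.vector(table(f))
  means <- tapply(y, f, mean)
  # pooled one-way residual mean square
  ss_within <- sum(tapply(y, f, function(v) sum((v - mean(v))^2)))
  df_den <- length(y) - nlevels(f)
  mse <- ss_within / df_den

  pairs <- if (family == "all_pairs") {
    utils::combn(lv, 2, simplify = FALSE)
  } else {
    if (is.null(reference) || !reference %in% lv) {
      abort("a valid reference level is required for family = 'vs_reference'")
    }
    lapply(setdiff(lv, reference), function(l) c(l, reference))
  }
  m <- length(pairs)
  rows <- purrr::map_dfr(pairs, function(pr) {
    ia <- match(pr[1], lv); ib <- match(pr[2], lv)
    ok <- nl[ia] >= 2 && nl[ib] >= 2 && mse > 0
    if (ok) {
      se <- sqrt(mse * (1 / nl[ia] + 1 / nl[ib]))
      tval <- (means[ia] - means[ib]) / se
      raw <- 2 * stats::pt(abs(tval), df_den, lower.tail = FALSE)
    } else {
      raw <- NA_real_
    }
    tibble(level_a = pr[1], level_b = pr[2],
           estimate = unname(means[ia] - means[ib]),
           raw_p = unname(raw),
           adjusted_p = unname(pmin(1, raw * m)),
           family_size = m,
           computed = ok)
  })
  class(rows) <- c("posthoc_table", class(rows))
  rows
}

#' Percent body-weight change from baseline to 24 h
#'
#' `100 * (weight_24h - weight_baseline) / weight_baseline` per animal;
#' animals missing either weight are flagged (`NA`) and excluded from any
#' group mean computed downstream.
#'
#' @param data Data frame with `weight_baseline` and `weight_24h` columns
#'   (e.g. an ethogram's animal table).
#' @return The input tibble with a `weight_pct_change` column.
#' @export
weight_pct_change <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("weight_baseline", "weight_24h") %in% names(data)))
  wb <- data$weight_baseline
  w24 <- data$weight_24h
  bad <- !is.na(wb) & wb <= 0
  if (any(bad)) abort("baseline weight must be positive")
  data$weight_pct_change <- 100 * (w24 - wb) / wb
  data
}

#' Exclude animals with unusable corticosterone samples
#'
#' Removes animals whose baseline faecal corticosterone exceeds
#' `baseline_limit` (strictly; a baseline exactly at the limit is kept) —
#' screening out extreme baseline outliers — and animals missing either
#' sample ("invalid sample"). Every exclusion is logged with its reason.
#'
#' @param data Data frame with `cort_baseline` and `cort_peak` columns.
#' @param baseline_limit Exclusion threshold in ng/g faeces (default 800).
#' @return A list with `kept` (tibble), `excluded` (tibble with a `reason`
#'   column), and `log` (animal_id + reason only).
#' @export
filter_cort_outliers <- function(data, baseline_limit = 800) {
  data <- as_tibble(data)
  stopifnot(all(c("cort_baseline", "cort_peak") %in% names(data)))
  reason <- dplyr::case_when(
    is.na(data$cort_baseline) | is.na(data$cort_peak) ~ "invalid sample",
    data$cort_baseline > baseline_limit ~
      sprintf("baseline > %g ng/g", baseline_limit),
    TRUE ~ NA_character_
  )
  excluded <- data[!is.na(reason), ]
  excluded$reason <- reason[!is.na(reason)]
  list(
    kept = data[is.na(reason), ],
    excluded = excluded,
    log = tibble(animal_id = if ("animal_id" %in% names(excluded))
      excluded$animal_id else as.character(which(!is.na(reason))),
      reason = excluded$reason)
  )
}

#' Log change in corticosterone from baseline to peak
#'
#' `log10(peak / baseline)` per animal; the corticosterone response is
#' analysed on the log scale throughout because the raw concentrations are
#' right-skewed.
#'
#' @param data Data frame with positive `cort_baseline` and `cort_peak`
#'   columns, or two numeric vectors via `baseline` and `peak`.
#' @param baseline,peak Optional numeric vectors overriding the columns.
#' @return With a data frame: the tibble plus a `cort_log_change` column.
#'   With vectors: the numeric vector of log changes.
#' @export
cort_log_change <- function(data = NULL, baseline = NULL, peak = NULL) {
  if (is.null(baseline)) {
    data <- as_tibble(data)
    stopifnot(all(c("cort_baseline", "cort_peak") %in% names(data)))
    baseline <- data$cort_baseline
    peak <- data$cort_peak
  }
  ok <- !is.na(baseline) & !is.na(peak)
  if (any(ok & (baseline <= 0 | peak <= 0))) {
    abort("corticosterone values must be positive to log-transform")
  }
  lc <- ifelse(ok, log10(peak / baseline), NA_real_)
  if (is.null(data)) return(lc)
  data$cort_log_change <- lc
  data
}

#' Pearson correlation between a behaviour score and peak corticosterone
#'
#' @param data Data frame holding the two columns.
#' @param score Name of the behaviour-score column.
#' @param cort Name of the corticosterone column (default `"cort_peak"`).
#' @return A one-row tibble: `r`, `p_value`, `n`, `computed` (`FALSE` with
#'   `NA` statistics when either vector has zero variance or fewer than 3
#'   pairs remain).
#' @export
correlate_behaviour_cort <- function(data, score, cort = "cort_peak") {
  data <- as_tibble(data)
  stopifnot(score %in% names(data), cort %in% names(data))
  ok <- stats::complete.cases(data[c(score, cort)])
  x <- data[[score]][ok]
  y <- data[[cort]][ok]
  if (length(x) < 3 || stats::var(x) == 0 || stats::var(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                  computed = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
         computed = TRUE)
}

#' Tidy an ANOVA table (drop the class, keep the tibble)
#' @param x An `anova_table`.
#' @param ... Unused.
#' @method tidy anova_table
#' @export
tidy.anova_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "anova_table")
  out
}

#' One-line summary of an ANOVA table
#' @param x An `anova_table`.
#' @param ... Unused.
#' @method glance anova_table
#' @export
glance.anova_table <- function(x, ...) {
  tibble(response = attr(x, "response"),
         n_terms = nrow(x),
         degenerate = attr(x, "degenerate"),
         min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}
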
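#' @importFrom rlang .data abort warn :=
#' @importFrom tibble tibble as_tibble
NULL

STRAINS <- c("C57", "C3H")
SURGERIES <- c("A", "V")
DRUGS <- c("Sa", "BupL", "BupH")
GROUP_LABELS <- as.vector(outer(SURGERIES, DRUGS, paste0))

#' Design cells of the vasectomy--buprenorphine study
#'
#' The study design crosses two inbred strains (C57, C3H) with surgery
#' (A = anaesthesia-only control, V = vasectomy) and drug treatment
#' (Sa = saline, BupL = 0.01 mg/kg buprenorphine, BupH = 0.05 mg/kg),
#' giving six treatment groups per strain.
#'
#' @return A tibble with one row per strain x group design cell.
#' @export
design_cells <- function() {
  tidyr::expand_grid(
    strain = STRAINS,
    surgery = SURGERIES,
    drug = DRUGS
  ) |>
    dplyr::mutate(group = paste0(.data$surgery, .data$drug))
}

validate_animals <- function(animals) {
  req <- c("animal_id", "strain", "surgery", "drug")
  missing_cols <- setdiff(req, names(animals))
  if (length(missing_cols) > 0) {
    abort(paste0("animal table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_enum <- function(col, allowed) {
    bad <- which(!animals[[col]] %in% allowed)
    if (length(bad) > 0) {
      abort(sprintf(
        "invalid %s value '%s' (animal '%s', row %d); allowed: %s",
        col, animals[[col]][bad[1]], animals$animal_id[bad[1]], bad[1],
        paste(allowed, collapse = ", ")
      ), class = "painscore_error_enum")
    }
  }
  check_enum("strain", STRAINS)
  check_enum("surgery", SURGERIES)
  check_enum("drug", DRUGS)
  if (anyDuplicated(animals$animal_id)) {
    abort("duplicate animal_id values in animal table")
  }
  for (col in c("weight_baseline", "weight_24h", "cort_baseline", "cort_peak")) {
    if (col %in% names(animals)) {
      v <- animals[[col]]
      bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
      if (length(bad) > 0) {
        abort(sprintf("%s must be strictly positive and finite (animal '%s')",
                      col, animals$animal_id[bad[1]]))
      }
    }
  }
  animals$group <- paste0(animals$surgery, animals$drug)
  animals
}

#' Construct an ethogram observation object
#'
#' An `ethogram` bundles the per-animal metadata, the behaviour catalog and
#' the animals x behaviours frequency matrix (plus an optional duration
#' matrix) for one observation session. Frequencies are session counts and
#' must be non-negative; a behaviour with zero count for an animal must have
#' zero duration.
#'
#' @param animals Tibble with columns `animal_id`, `strain` (C57/C3H),
#'   `surgery` (A/V), `drug` (Sa/BupL/BupH) and optional physiology columns
#'   `weight_baseline`, `weight_24h`, `cort_baseline`, `cort_peak`.
#' @param freq Numeric matrix, animals x behaviours, non-negative counts.
#' @param dur Optional numeric matrix of durations (seconds), same shape.
#' @param catalog Optional behaviour catalog tibble (`behavior`, `modality`,
#'   `source`); defaults to a frequency-only catalog built from `freq`
#'   column names.
#' @return An object of class `ethogram`.
#' @export
ethogram <- function(animals, freq, dur = NULL, catalog = NULL) {
  animals <- validate_animals(as_tibble(animals))
  freq <- as.matrix(freq)
  if (is.null(catalog)) {
    catalog <- tibble(
      behavior = colnames(freq),
      modality = if (is.null(dur)) "frequency" else "both",
      source = "manual"
    )
  }
  if (anyDuplicated(catalog$behavior)) {
    abort("behaviour names must be unique within a catalog")
  }
  if (nrow(freq) != nrow(animals)) {
    abort("frequency matrix rows must match number of animals")
  }
  if (!identical(colnames(freq), catalog$behavior)) {
    if (!setequal(colnames(freq), catalog$behavior)) {
      abort("frequency matrix columns must match catalog behaviours")
    }
    freq <- freq[, catalog$behavior, drop = FALSE]
  }
  if (any(!is.finite(freq)) || any(freq < 0)) {
    abort("frequencies must be finite and non-negative")
  }
  rownames(freq) <- animals$animal_id
  if (!is.null(dur)) {
    dur <- as.matrix(dur)
    if (!identical(dim(dur), dim(freq))) {
      abort("duration matrix must have the same shape as the frequency matrix")
    }
    if (!identical(colnames(dur), catalog$behavior)) {
      dur <- dur[, catalog$behavior, drop = FALSE]
    }
    if (any(!is.finite(dur)) || any(dur < 0)) {
      abort("durations must be finite and non-negative")
    }
    if (any(dur[freq == 0] != 0)) {
      abort("a behaviour with frequency 0 must have duration 0")
    }
    rownames(dur) <- animals$animal_id
  }
  structure(
    list(animals = animals, catalog = as_tibble(catalog),
         freq = freq, dur = dur),
    class = "ethogram"
  )
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d animals x %d behaviours%s\n",
              nrow(x$freq), ncol(x$freq),
              if (is.null(x$dur)) "" else " (with durations)"))
  cat("groups:", paste(sort(unique(x$animals$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ethogram <- function(x) dim(x$freq)

#' Convert an ethogram to a long tibble
#'
#' One row per animal x behaviour, the canonical long CSV layout
#' (`animal_id`, `strain`, `surgery`, `drug`, `behavior`, `frequency`,
#' `duration` where recorded), with physiology columns carried alongside
#' when present.
#'
#' @param x An `ethogram`.
#' @param ... Unused.
#' @return A tibble in long format.
#' @method as_tibble ethogram
#' @export
as_tibble.ethogram <- function(x, ...) {
  if (nrow(x$freq) == 0 || ncol(x$freq) == 0) {
    return(tibble(animal_id = character(), strain = character(),
                  surgery = character(), drug = character(),
                  behavior = character(), frequency = numeric()))
  }
  long <- as_tibble(x$freq) |>
    dplyr::mutate(animal_id = x$animals$animal_id, .before = 1) |>
    tidyr::pivot_longer(-"animal_id", names_to = "behavior",
                        values_to = "frequency")
  if (!is.null(x$dur)) {
    durl <- as_tibble(x$dur) |>
      dplyr::mutate(animal_id = x$animals$animal_id, .before = 1) |>
      tidyr::pivot_longer(-"animal_id", names_to = "behavior",
                          values_to = "duration")
    long <- dplyr::left_join(long, durl, by = c("animal_id", "behavior"))
  }
  meta_cols <- intersect(
    c("animal_id", "strain", "surgery", "drug",
      "weight_baseline", "weight_24h", "cort_baseline", "cort_peak"),
    names(x$animals)
  )
  dplyr::left_join(long, x$animals[meta_cols], by = "animal_id") |>
    dplyr::relocate("strain", "surgery", "drug", .after = "animal_id")
}

#' Build an ethogram from a long-format table
#'
#' @param df Data frame with columns `animal_id`, `strain`, `surgery`,
#'   `drug`, `behavior`, `frequency` and optionally `duration` plus
#'   physiology columns. Missing (animal, behaviour) pairs are filled with
#'   zero frequency (and zero duration).
#' @param catalog Optional behaviour catalog fixing column order; defaults
#'   to behaviours in order of first appearance.
#' @return An `ethogram`.
#' @export
as_ethogram <- function(df, catalog = NULL) {
  df <- as_tibble(df)
  req <- c("animal_id", "strain", "surgery", "drug", "behavior", "frequency")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("long table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(.data$animal_id, .data$behavior) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (animal, behaviour) pair: ('%s', '%s')",
                  dup$animal_id[1], dup$behavior[1]))
  }
  bad <- which(!is.finite(df$frequency) | df$frequency < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or non-finite frequency at row %d (animal '%s')",
                  bad[1], df$animal_id[bad[1]]))
  }
  behaviours <- if (is.null(catalog)) unique(df$behavior) else catalog$behavior
  unknown <- setdiff(df$behavior, behaviours)
  if (length(unknown) > 0) {
    abort(paste0("behaviour(s) not in catalog: ", paste(unknown, collapse = ", ")))
  }
  meta_cols <- intersect(
    c("animal_id", "strain", "surgery", "drug",
      "weight_baseline", "weight_24h", "cort_baseline", "cort_peak"),
    names(df)
  )
  animals <- df |>
    dplyr::distinct(dplyr::pick(dplyr::all_of(meta_cols)))
  if (anyDuplicated(animals$animal_id)) {
    abort("inconsistent metadata across rows of the same animal")
  }
  wide <- function(col) {
    w <- df |>
      dplyr::select("animal_id", "behavior", dplyr::all_of(col)) |>
      tidyr::pivot_wider(names_from = "behavior",
                         values_from = dplyr::all_of(col),
                         values_fill = 0)
    m <- as.matrix(w[setdiff(names(w), "animal_id")])
    # behaviours never seen in the file are legal when a catalog fixes them
    absent <- setdiff(behaviours, colnames(m))
    if (length(absent) > 0) {
      m <- cbind(m, matrix(0, nrow(m), length(absent),
                           dimnames = list(NULL, absent)))
    }
    m <- m[match(animals$animal_id, w$animal_id), behaviours, drop = FALSE]
    rownames(m) <- animals$animal_id
    m
  }
  freq <- wide("frequency")
  dur <- NULL
  if ("duration" %in% names(df) && !all(is.na(df$duration))) {
    df$duration[is.na(df$duration)] <- 0
    dur <- wide("duration")
  }
  ethogram(animals, freq, dur = dur, catalog = catalog)
}

#' Read an ethogram from a long-format CSV file
#'
#' The file must have header columns `animal_id`, `strain`, `surgery`,
#' `drug`, `behavior`, `frequency` and optionally `duration` (plus optional
#' physiology columns). Unknown factor tokens, duplicate (animal, behaviour)
#' pairs and negative counts are validation errors.
#'
#' @param path Path to a CSV file.
#' @param catalog Optional behaviour catalog (see [as_ethogram()]).
#' @return An `ethogram`. A zero-row file yields an empty ethogram.
#' @export
read_ethogram <- function(path, catalog = NULL) {
  # base read.csv parses doubles via strtod (correctly rounded), so a file
  # written with %.17g reads back to the identical double
  df <- as_tibble(utils::read.csv(path, check.names = FALSE,
                                  stringsAsFactors = FALSE))
  if (nrow(df) == 0) {
    return(empty_ethogram(catalog))
  }
  as_ethogram(df, catalog = catalog)
}

empty_ethogram <- function(catalog = NULL) {
  behaviours <- if (is.null(catalog)) character() else catalog$behavior
  animals <- tibble(animal_id = character(), strain = character(),
                    surgery = character(), drug = character())
  freq <- matrix(numeric(), nrow = 0, ncol = length(behaviours),
                 dimnames = list(NULL, behaviours))
  structure(
    list(animals = dplyr::mutate(animals, group = character()),
         catalog = if (is.null(catalog)) {
           tibble(behavior = character(), modality = character(),
                  source = character())
         } else as_tibble(catalog),
         freq = freq, dur = NULL),
    class = "ethogram"
  )
}

#' Write an ethogram to a long-format CSV file
#'
#' Inverse of [read_ethogram()]: the written file reads back to an identical
#' ethogram (counts as integers, durations at full double precision).
#'
#' @param x An `ethogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(x, path) {
  stopifnot(inherits(x, "ethogram"))
  long <- as_tibble(x)
  if (nrow(long) > 0) {
    long$frequency <- as.integer(round(long$frequency))
    # %.17g guarantees exact double round-trip through text
    fmt17 <- function(v) ifelse(is.na(v), NA, sprintf("%.17g", v))
    for (col in intersect(c("duration", "weight_baseline", "weight_24h",
                            "cort_baseline", "cort_peak"), names(long))) {
      long[[col]] <- fmt17(long[[col]])
    }
  }
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Subset an ethogram by a design factor
#'
#' Supports the per-strain and per-group re-analyses: returns the sub-matrix
#' of animals at one level of `strain`, `surgery`, `drug` or `group`,
#' preserving behaviour order. An empty result warns rather than errors.
#'
#' @param x An `ethogram`.
#' @param factor One of `"strain"`, `"surgery"`, `"drug"`, `"group"`.
#' @param level The level to keep.
#' @return An `ethogram` containing the matching animals.
#' @export
subset_by_factor <- function(x, factor, level) {
  stopifnot(inherits(x, "ethogram"))
  factor <- match.arg(factor, c("strain", "surgery", "drug", "group"))
  allowed <- switch(factor, strain = STRAINS, surgery = SURGERIES,
                    drug = DRUGS, group = GROUP_LABELS)
  if (!level %in% allowed) {
    abort(sprintf("'%s' is not a valid level of %s (allowed: %s)",
                  level, factor, paste(allowed, collapse = ", ")))
  }
  keep <- x$animals[[factor]] == level
  if (!any(keep)) {
    warn(sprintf("no animals with %s == '%s'; returning empty ethogram",
                 factor, level))
  }
  structure(
    list(animals = x$animals[keep, , drop = FALSE],
         catalog = x$catalog,
         freq = x$freq[keep, , drop = FALSE],
         dur = if (is.null(x$dur)) NULL else x$dur[keep, , drop = FALSE]),
    class = "ethogram"
  )
}

#' Manual-scoring behaviour catalog
#'
#' The ethogram scored by a human observer from 6-minute video: 14
#' behaviours, ten of which also carry durations. Pain-associated acts
#' (writhing, Press2, rear leg lift, wound licking/scratching, abnormal
#' walking) sit alongside normal maintenance behaviours.
#'
#' @return A tibble with columns `behavior`, `modality`, `source`.
#' @export
manual_catalog <- function() {
  readr::read_csv(
    system.file("extdata", "manual_catalog.csv", package = "painscore"),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Automated-scoring behaviour catalog
#'
#' Behaviours recognised by an automated home-cage video system from
#' 20-minute recordings: twelve activity measures later banded by typical
#' frequency, plus grooming.
#'
#' @return A tibble with columns `behavior`, `modality`, `source`.
#' @export
automated_catalog <- function() {
  readr::read_csv(
    system.file("extdata", "automated_catalog.csv", package = "painscore"),
    show_col_types = FALSE, progress = FALSE
  )
}
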
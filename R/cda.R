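#' Canonical discriminant analysis of an ethogram
#'
#' Solves the generalized eigenproblem of the between-group scatter matrix
#' against the pooled within-group scatter matrix, \eqn{W^{+} B\,a =
#' \lambda a}, yielding up to `min(groups - 1, variables)` canonical
#' functions. Eigenvalues quantify each function's share of between-group
#' separation; per-animal scores are scaled so the pooled within-group
#' variance of each function is 1 and centred on the grand mean. A
#' rank-revealing pseudo-inverse (eigenvalue threshold `tol` relative to
#' the largest within-scatter eigenvalue, plus an optional ridge) keeps the
#' solution defined when more behaviours than error degrees of freedom are
#' entered. Sequential Wilks' lambda tests (Bartlett's chi-square
#' approximation) and pooled within-group structure correlations are
#' attached to the fit.
#'
#' Function signs are arbitrary in the eigenproblem, so each one is fixed
#' deterministically: oriented so the last group level (V when grouping on
#' surgery) scores above the first, i.e. the canonical axis increases with
#' surgery; when that contrast is exactly zero the largest-magnitude
#' structure correlation is made positive instead.
#'
#' @param x An `ethogram`, or a data frame holding one grouping column and
#'   numeric variable columns.
#' @param grouping For an ethogram: one of `"surgery"`, `"group"`,
#'   `"strain"`, `"drug"`. For a data frame: the name of the grouping
#'   column.
#' @param variables Optional character vector restricting the variables
#'   entered; defaults to every behaviour (ethogram) or every numeric
#'   column (data frame).
#' @param use For ethograms: enter `"frequency"` (default), `"duration"`,
#'   or `"both"` matrices.
#' @param tol Relative eigenvalue threshold of the within-scatter
#'   pseudo-inverse.
#' @param ridge Optional ridge added to the within-scatter diagonal
#'   (fraction of its mean diagonal); 0 by default.
#' @param structure Convention for structure correlations: pooled
#'   `"within"`-group (default) or `"total"`-sample.
#' @return An object of class `cda_fit` with elements `functions` (tibble:
#'   eigenvalue, pct_variance, wilks_lambda, chi_square, df, p_value),
#'   `coefficients`, `structure`, `scores`, `groups`, `dropped`,
#'   `effective_rank`.
#' @export
fit_cda <- function(x, grouping, variables = NULL,
                    use = c("frequency", "duration", "both"),
                    tol = 1e-10, ridge = 0,
                    structure = c("within", "total")) {
  use <- match.arg(use)
  structure <- match.arg(structure)
  if (inherits(x, "ethogram")) {
    grouping <- match.arg(grouping, c("surgery", "group", "strain", "drug"))
    g <- factor(x$animals[[grouping]])
    X <- switch(use,
      frequency = x$freq,
      duration = {
        if (is.null(x$dur)) abort("ethogram has no duration matrix")
        x$dur
      },
      both = {
        if (is.null(x$dur)) abort("ethogram has no duration matrix")
        d <- x$dur
        colnames(d) <- paste0(colnames(d), " (dur)")
        cbind(x$freq, d)
      }
    )
    ids <- x$animals$animal_id
  } else {
    x <- as_tibble(x)
    if (!grouping %in% names(x)) {
      abort(sprintf("grouping column '%s' not found", grouping))
    }
    g <- factor(x[[grouping]])
    numcols <- names(x)[vapply(x, is.numeric, logical(1))]
    numcols <- setdiff(numcols, grouping)
    X <- as.matrix(x[numcols])
    ids <- if ("animal_id" %in% names(x)) x[["animal_id"]] else
      as.character(seq_len(nrow(x)))
    rownames(X) <- ids
  }
  if (!is.null(variables)) {
    missing_v <- setdiff(variables, colnames(X))
    if (length(missing_v) > 0) {
      abort(paste0("unknown variable(s): ", paste(missing_v, collapse = ", ")))
    }
    X <- X[, variables, drop = FALSE]
  }
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 animals")

  n <- nrow(X)
  cda_core(X, g, ids, grouping, tol, ridge, structure)
}

cda_core <- function(X, g, ids, grouping, tol, ridge, structure_type) {
  n <- nrow(X)
  k <- nlevels(g)
  grand <- colMeans(X)
  gm <- rowsum(X, g) / as.vector(table(g))   # group means, rows = levels

  # pooled within-group scatter and its per-variable variance
  Xc_within <- X - gm[g, , drop = FALSE]
  W <- crossprod(Xc_within)
  wvar <- diag(W)
  zero_var <- wvar <= .Machine$double.eps * max(wvar, 1)
  dropped <- colnames(X)[zero_var]
  if (all(zero_var)) {
    abort(paste0(
      "no variable has nonzero pooled within-group variance: ",
      paste(colnames(X), collapse = ", ")
    ), class = "painscore_error_novariance")
  }
  if (any(zero_var)) {
    warn(paste0("dropping zero within-group-variance variable(s): ",
                paste(dropped, collapse = ", ")))
    X <- X[, !zero_var, drop = FALSE]
    gm <- gm[, !zero_var, drop = FALSE]
    grand <- grand[!zero_var]
    Xc_within <- Xc_within[, !zero_var, drop = FALSE]
    W <- W[!zero_var, !zero_var, drop = FALSE]
  }
  p <- ncol(X)
  ng <- as.vector(table(g))
  Mdev <- sweep(gm, 2, grand)
  B <- crossprod(Mdev * sqrt(ng))

  if (ridge > 0) W <- W + diag(ridge * mean(diag(W)), p)

  ew <- eigen(W, symmetric = TRUE)
  keep <- ew$values > tol * max(ew$values)
  effective_rank <- sum(keep)
  if (effective_rank == 0) {
    abort("within-group scatter is numerically zero",
          class = "painscore_error_singular")
  }
  U <- ew$vectors[, keep, drop = FALSE]
  dhalf <- 1 / sqrt(ew$values[keep])
  # whiten, then eigendecompose the between-scatter in the whitened basis
  M <- crossprod(U %*% diag(dhalf, effective_rank),
                 B %*% (U %*% diag(dhalf, effective_rank)))
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)

  n_fun <- min(k - 1, p, effective_rank)
  lambda <- pmax(em$values[seq_len(n_fun)], 0)
  A <- (U %*% diag(dhalf, effective_rank)) %*%
    em$vectors[, seq_len(n_fun), drop = FALSE]
  # scale so pooled within-group variance of scores is 1: a' (W/(n-k)) a = 1
  A <- A * sqrt(n - k)
  rownames(A) <- colnames(X)

  scores <- sweep(X, 2, grand) %*% A
  colnames(scores) <- paste0("Function", seq_len(n_fun))
  colnames(A) <- colnames(scores)
  rownames(scores) <- ids

  strc <- structure_cor(X, scores, g, type = structure_type)

  # orient each function so the last group level (e.g. V over A) scores
  # higher than the first — the "increases with surgery" polarity; fall
  # back to largest-|loading|-positive when the contrast is exactly zero
  smeans <- rowsum(scores, g) / as.vector(table(g))
  for (f in seq_len(n_fun)) {
    contrast <- smeans[k, f] - smeans[1, f]
    flip <- if (contrast != 0) contrast < 0 else {
      top <- which.max(abs(strc[, f]))
      length(top) == 1 && strc[top, f] < 0
    }
    if (flip) {
      A[, f] <- -A[, f]
      scores[, f] <- -scores[, f]
      strc[, f] <- -strc[, f]
    }
  }

  pct <- if (sum(lambda) > 0) 100 * lambda / sum(lambda) else rep(0, n_fun)
  wl <- sequential_wilks_stats(lambda, n = n, p = p, k = k)

  fit <- structure(
    list(
      functions = tibble(
        fn = seq_len(n_fun),
        eigenvalue = lambda,
        pct_variance = pct,
        wilks_lambda = wl$lambda,
        chi_square = wl$chi_square,
        df = wl$df,
        p_value = wl$p_value
      ),
      coefficients = A,
      structure = strc,
      scores = scores,
      grouping = grouping,
      groups = g,
      group_means = gm,
      grand_mean = grand,
      dropped = dropped,
      effective_rank = effective_rank,
      n = n,
      data = X
    ),
    class = "cda_fit"
  )
  fit
}

# Sequential ("peel-off") Wilks' lambda tests: for each starting function
# f, Lambda_f = prod_{j >= f} 1/(1 + lambda_j), tested by Bartlett's
# chi-square approximation with df = (p - f + 1)(k - f).
sequential_wilks_stats <- function(lambda, n, p, k) {
  n_fun <- length(lambda)
  L <- vapply(seq_len(n_fun),
              function(f) prod(1 / (1 + lambda[f:n_fun])), numeric(1))
  cfac <- n - 1 - (p + k) / 2
  chi <- pmax(-cfac * log(L), 0)
  df <- (p - seq_len(n_fun) + 1) * (k - seq_len(n_fun))
  pv <- stats::pchisq(chi, df, lower.tail = FALSE)
  list(lambda = L, chi_square = chi, df = df, p_value = pv)
}

#' Sequential Wilks' lambda tests of a discriminant fit
#'
#' Re-derives, for each function `f`, the joint test that functions
#' `f..K` carry no group separation: \eqn{\Lambda_f = \prod_{j \ge f}
#' 1/(1+\lambda_j)} with Bartlett's chi-square approximation
#' \eqn{\chi^2 = -(n - 1 - (p+k)/2)\,\log\Lambda_f} on
#' \eqn{(p-f+1)(k-f)} degrees of freedom.
#'
#' @param fit A `cda_fit`.
#' @return The function summary tibble with `wilks_lambda`, `chi_square`,
#'   `df`, `p_value` columns (as also stored on the fit).
#' @export
sequential_wilks <- function(fit) {
  stopifnot(inherits(fit, "cda_fit"))
  fit$functions
}

structure_cor <- function(X, scores, g, type = c("within", "total")) {
  type <- match.arg(type)
  if (type == "within") {
    gmX <- rowsum(X, g) / as.vector(table(g))
    gmS <- rowsum(scores, g) / as.vector(table(g))
    Xc <- X - gmX[g, , drop = FALSE]
    Sc <- scores - gmS[g, , drop = FALSE]
  } else {
    Xc <- sweep(X, 2, colMeans(X))
    Sc <- sweep(scores, 2, colMeans(scores))
  }
  sx <- sqrt(colSums(Xc^2))
  ss <- sqrt(colSums(Sc^2))
  r <- crossprod(Xc, Sc)
  # zero-variance variables (possible under "total" or degenerate scores)
  denom <- outer(sx, ss)
  r <- ifelse(denom > 0, r / denom, 0)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(colnames(X), colnames(scores))
  r
}

#' Structure correlations of a discriminant fit
#'
#' The correlation between each entered variable and the animals' scores on
#' each canonical function — the selection statistic for pain-specific
#' versus normal behaviours. The default convention pools within-group
#' (variables and scores centred on their group means); the total-sample
#' correlation is available for comparison. Variables with zero variance
#' are reported as 0.
#'
#' @param fit A `cda_fit`.
#' @param type `"within"` (pooled within-group, default) or `"total"`.
#' @return A variable x function matrix of correlations in `[-1, 1]`.
#' @export
structure_correlations <- function(fit, type = c("within", "total")) {
  stopifnot(inherits(fit, "cda_fit"))
  type <- match.arg(type)
  if (type == "within") return(fit$structure)
  structure_cor(fit$data, fit$scores, fit$groups, type = "total")
}

#' @export
print.cda_fit <- function(x, ...) {
  cat(sprintf("Canonical discriminant analysis on '%s' (%d groups, n = %d)\n",
              x$grouping, nlevels(x$groups), x$n))
  if (length(x$dropped) > 0) {
    cat("dropped (zero within-group variance):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  print(as.data.frame(x$functions), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the canonical-function summary of a discriminant fit
#'
#' @param x A `cda_fit`.
#' @param ... Unused.
#' @return One row per canonical function: eigenvalue, percent of
#'   between-group variance, sequential Wilks' lambda with its chi-square,
#'   df and p-value.
#' @method tidy cda_fit
#' @export
tidy.cda_fit <- function(x, ...) x$functions

#' One-line summary of a discriminant fit
#'
#' @param x A `cda_fit`.
#' @param ... Unused.
#' @return A one-row tibble: n, number of groups, functions, the overall
#'   Wilks' lambda and its p-value, and the effective rank of the
#'   within-group scatter.
#' @method glance cda_fit
#' @export
glance.cda_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_groups = nlevels(x$groups),
    n_functions = nrow(x$functions),
    wilks_lambda = x$functions$wilks_lambda[1],
    p_value = x$functions$p_value[1],
    effective_rank = x$effective_rank,
    n_dropped = length(x$dropped)
  )
}

#' Per-animal discriminant scores as a tibble
#'
#' @param fit A `cda_fit`.
#' @return A tibble with `animal_id`, the grouping level and one column per
#'   canonical function.
#' @export
da_scores <- function(fit) {
  stopifnot(inherits(fit, "cda_fit"))
  dplyr::bind_cols(
    tibble(animal_id = rownames(fit$scores),
           !!fit$grouping := as.character(fit$groups)),
    as_tibble(fit$scores)
  )
}

#' Export a discriminant fit as CSV tables
#'
#' Writes three tables with stable column names: the function summary, the
#' structure correlations and the per-animal scores.
#'
#' @param fit A `cda_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
export_cda <- function(fit, dir, prefix = "cda") {
  stopifnot(inherits(fit, "cda_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("functions", "structure", "scores"),
                                 ".csv"))
  readr::write_csv(fit$functions, paths[1], progress = FALSE)
  readr::write_csv(
    dplyr::bind_cols(tibble(behavior = rownames(fit$structure)),
                     as_tibble(fit$structure)),
    paths[2], progress = FALSE)
  readr::write_csv(da_scores(fit), paths[3], progress = FALSE)
  invisible(paths)
}
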
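test_that("fit matches the brute-force scatter eigenproblem", {
  for (seed in 1:4) {
    dat <- random_gaussian_groups(k = 3, p = 4, n_per_group = 10, seed = seed)
    df <- tibble::as_tibble(dat$X)
    df$grp <- dat$g
    fit <- fit_cda(df, "grp")
    oracle <- brute_cda(dat$X, dat$g)
    expect_equal(fit$functions$eigenvalue, oracle$eigenvalues,
                 tolerance = 1e-8)
    expect_equal(fit$functions$wilks_lambda, oracle$wilks, tolerance = 1e-8)
    expect_matching_scores(fit$scores, oracle$scores, tol = 1e-6)
  }
})

test_that("fit matches the reference discriminant implementation", {
  dat <- random_gaussian_groups(k = 4, p = 6, n_per_group = 12, seed = 99)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit <- fit_cda(df, "grp")
  ref <- MASS::lda(dat$X, dat$g)
  k <- 4; n <- nrow(dat$X)
  # reference singular values relate to scatter eigenvalues by (k-1)/(n-k)
  expect_equal(fit$functions$eigenvalue,
               (ref$svd^2 * (k - 1) / (n - k))[seq_len(k - 1)],
               tolerance = 1e-6)
  refscores <- predict(ref, dat$X)$x
  expect_matching_scores(fit$scores, refscores, tol = 1e-6)
})

test_that("six groups with informative variables yield exactly 5 functions", {
  dat <- random_gaussian_groups(k = 6, p = 8, n_per_group = 8, seed = 3)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit <- fit_cda(df, "grp")
  expect_equal(nrow(fit$functions), 5L)
  expect_equal(sum(fit$functions$pct_variance), 100, tolerance = 1e-9)
  expect_true(all(diff(fit$functions$eigenvalue) <= 1e-12))
})

test_that("one separating variable dominates a two-group fit", {
  set.seed(21)
  n <- 40
  X <- cbind(sep = c(rnorm(20), rnorm(20) + 4),
             noise1 = rnorm(n), noise2 = rnorm(n))
  df <- tibble::as_tibble(X)
  df$grp <- rep(c("a", "b"), each = 20)
  fit <- fit_cda(df, "grp")
  expect_equal(nrow(fit$functions), 1L)
  expect_equal(fit$functions$pct_variance, 100)
  expect_equal(rownames(fit$structure)[which.max(abs(fit$structure[, 1]))],
               "sep")
})

test_that("identical group means give Wilks 1, chi-square 0, p 1", {
  set.seed(5)
  block <- matrix(rnorm(20), 10, 2)
  X <- rbind(block, block)  # second group is an exact copy
  df <- tibble::as_tibble(X, .name_repair = ~ c("v1", "v2"))
  df$grp <- rep(c("a", "b"), each = 10)
  fit <- fit_cda(df, "grp")
  expect_equal(fit$functions$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(fit$functions$chi_square, 0, tolerance = 1e-10)
  expect_equal(fit$functions$p_value, 1, tolerance = 1e-10)
})

test_that("two-group Wilks lambda is the Hotelling T-squared transform", {
  set.seed(77)
  n1 <- 15; n2 <- 17; p <- 4
  X <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = 0.8), n2, p))
  g <- rep(c("a", "b"), c(n1, n2))
  df <- tibble::as_tibble(X, .name_repair = ~ paste0("v", 1:p))
  df$grp <- g
  fit <- fit_cda(df, "grp")
  n <- n1 + n2
  # closed-form two-sample Hotelling T2 from pooled covariance
  d <- colMeans(X[g == "a", ]) - colMeans(X[g == "b", ])
  S <- (crossprod(sweep(X[g == "a", ], 2, colMeans(X[g == "a", ]))) +
          crossprod(sweep(X[g == "b", ], 2, colMeans(X[g == "b", ])))) /
    (n - 2)
  T2 <- (n1 * n2 / n) * drop(t(d) %*% solve(S) %*% d)
  expect_equal(fit$functions$wilks_lambda, 1 / (1 + T2 / (n - 2)),
               tolerance = 1e-10)
  # exact F transform of Lambda reproduces the Hotelling p-value
  Fstat <- T2 * (n - p - 1) / ((n - 2) * p)
  p_hotelling <- stats::pf(Fstat, p, n - p - 1, lower.tail = FALSE)
  lam <- fit$functions$wilks_lambda
  F_from_lambda <- ((1 - lam) / lam) * (n - p - 1) / p
  p_from_lambda <- stats::pf(F_from_lambda, p, n - p - 1, lower.tail = FALSE)
  expect_equal(p_from_lambda, p_hotelling, tolerance = 1e-10)
})

test_that("Wilks lambda equals the eigenvalue product identity exactly", {
  dat <- random_gaussian_groups(k = 5, p = 6, n_per_group = 9, seed = 41)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit <- fit_cda(df, "grp")
  lam <- fit$functions$eigenvalue
  for (f in seq_along(lam)) {
    expect_equal(fit$functions$wilks_lambda[f],
                 prod(1 / (1 + lam[f:length(lam)])), tolerance = 1e-12)
  }
})

test_that("positive rescaling of a variable changes nothing but coefficients", {
  dat <- random_gaussian_groups(k = 3, p = 5, n_per_group = 10, seed = 8)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit1 <- fit_cda(df, "grp")
  df2 <- df
  df2$V2 <- df2$V2 * 37.5
  fit2 <- fit_cda(df2, "grp")
  expect_equal(fit1$functions$eigenvalue, fit2$functions$eigenvalue,
               tolerance = 1e-8)
  expect_equal(fit1$functions$p_value, fit2$functions$p_value,
               tolerance = 1e-8)
  expect_equal(fit1$structure, fit2$structure, tolerance = 1e-8)
  expect_equal(fit1$coefficients["V2", ] / 37.5, fit2$coefficients["V2", ],
               tolerance = 1e-8)
})

test_that("rotating the pure-noise subspace leaves eigenvalues unchanged", {
  set.seed(14)
  n <- 60
  sep <- c(rnorm(20), rnorm(20) + 3, rnorm(20) - 3)
  noise <- matrix(rnorm(2 * n), n, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  mk <- function(nz) {
    df <- tibble::as_tibble(cbind(sep = sep, nz),
                            .name_repair = ~ c("sep", "n1", "n2"))
    df$grp <- rep(c("a", "b", "c"), each = 20)
    fit_cda(df, "grp")
  }
  expect_equal(mk(noise)$functions$eigenvalue,
               mk(noise %*% R)$functions$eigenvalue, tolerance = 1e-8)
})

test_that("structure correlations agree with the direct pooled formula", {
  dat <- random_gaussian_groups(k = 3, p = 4, n_per_group = 8, seed = 55)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit <- fit_cda(df, "grp")
  g <- factor(dat$g)
  # independent elementwise computation
  for (v in seq_len(4)) {
    for (f in seq_len(2)) {
      xc <- unlist(tapply(dat$X[, v], g, function(z) z - mean(z)))
      sc <- unlist(tapply(fit$scores[, f], g, function(z) z - mean(z)))
      r <- sum(xc * sc) / sqrt(sum(xc^2) * sum(sc^2))
      expect_equal(unname(fit$structure[v, f]), r, tolerance = 1e-10)
    }
  }
})

test_that("a variable equal to the scores correlates perfectly; negation flips", {
  dat <- random_gaussian_groups(k = 3, p = 3, n_per_group = 10, seed = 60)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit0 <- fit_cda(df, "grp")
  df$self <- fit0$scores[, 1]
  fit <- fit_cda(df, "grp")
  expect_equal(unname(abs(fit$structure["self", 1])), 1, tolerance = 1e-8)
  df$V1 <- -df$V1
  fit_neg <- fit_cda(df, "grp")
  expect_equal(unname(fit_neg$structure["V1", 1]),
               -unname(fit$structure["V1", 1]), tolerance = 1e-8)
})

test_that("zero within-group-variance variables are dropped with a warning", {
  dat <- random_gaussian_groups(k = 3, p = 3, n_per_group = 10, seed = 71)
  df <- tibble::as_tibble(dat$X)
  df$flat <- 5
  df$grp <- dat$g
  expect_warning(fit <- fit_cda(df, "grp"), "flat")
  expect_equal(fit$dropped, "flat")
  expect_false("flat" %in% rownames(fit$structure))
  df_all_flat <- tibble::tibble(a = rep(1, 30), b = rep(2, 30),
                                grp = dat$g)
  expect_error(fit_cda(df_all_flat, "grp"),
               class = "painscore_error_novariance")
})

test_that("degenerate groupings error informatively", {
  dat <- random_gaussian_groups(k = 2, p = 3, n_per_group = 10, seed = 2)
  df <- tibble::as_tibble(dat$X)
  df$grp <- "only"
  expect_error(fit_cda(df, "grp"), "2 groups")
  df$grp <- c("a", rep("b", 19))
  expect_error(fit_cda(df, "grp"), "at least 2 animals")
})

test_that("tidy/glance/scores accessors expose the fit", {
  dat <- random_gaussian_groups(k = 3, p = 4, n_per_group = 8, seed = 83)
  df <- tibble::as_tibble(dat$X)
  df$grp <- dat$g
  fit <- fit_cda(df, "grp")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("fn", "eigenvalue", "pct_variance", "wilks_lambda",
                     "chi_square", "df", "p_value"))
  gl <- glance(fit)
  expect_equal(gl$n_functions, 2L)
  sc <- da_scores(fit)
  expect_equal(nrow(sc), 24L)
  expect_identical(sequential_wilks(fit), fit$functions)
})
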
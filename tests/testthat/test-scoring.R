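make_score_ethogram <- function(freq_rows, behaviours) {
  animals <- make_animals(1)[seq_len(nrow(freq_rows)), ]
  freq <- as.matrix(freq_rows)
  colnames(freq) <- behaviours
  rownames(freq) <- animals$animal_id
  ethogram(animals, freq)
}

test_that("loading threshold splits signed correlates at the stated cutoff", {
  loadings <- c(a = 0.6, b = 0.35, c = -0.59, d = -0.46, e = -0.3, f = 0.05)
  sel <- painscore:::threshold_loadings(loadings, 0.1)
  expect_setequal(sel$positive, c("a", "b"))
  expect_setequal(sel$negative, c("c", "d", "e"))
  # threshold is inclusive on both sides
  sel2 <- painscore:::threshold_loadings(c(x = 0.1, y = -0.1, z = 0.0999), 0.1)
  expect_equal(sel2$positive, "x")
  expect_equal(sel2$negative, "y")
})

test_that("selection on a strong surgery effect recovers both subsets", {
  eth <- simulate_cohort(n_per_cell = 20, seed = 17)
  fit <- fit_cda(eth, "surgery")
  sel <- select_subsets(fit)
  expect_true(sel$significant)
  expect_true(all(c("Lick Wound", "Abnormal Walk") %in% sel$positive))
  expect_true(all(c("Walk Normal", "Stop", "Dig") %in% sel$negative))
  expect_length(intersect(sel$positive, sel$negative), 0)
  expect_true(all(abs(sel$loadings$loading[
    sel$loadings$subset != "dropped"]) >= 0.1))
})

test_that("selection refuses when the driving function is not significant", {
  prm <- null_cohort_params(default_cohort_params())
  eth <- simulate_cohort(prm, n_per_cell = 3, seed = 301)
  fit <- fit_cda(eth, "surgery")
  expect_gt(fit$functions$p_value[1], 0.05)
  expect_warning(sel <- select_subsets(fit), "not significant")
  expect_length(sel$positive, 0)
  expect_length(sel$negative, 0)
  expect_false(sel$significant)
})

test_that("function index out of range errors", {
  eth <- simulate_cohort(n_per_cell = 4, seed = 1)
  fit <- fit_cda(eth, "surgery")
  expect_error(select_subsets(fit, function_index = 2), "out of range")
})

test_that("magnitude exclusion moves only outsized behaviours", {
  freq <- rbind(c(2, 3, 4, 40), c(3, 2, 5, 44))
  eth <- make_score_ethogram(freq, c("w", "x", "y", "walklike"))
  sel <- structure(list(positive = c("w", "x", "y", "walklike"),
                        negative = character(),
                        excluded_high_magnitude = character()),
                   class = "subset_selection")
  out <- apply_magnitude_exclusion(sel, eth, fold_limit = 2)
  expect_equal(out$excluded_high_magnitude, "walklike")
  expect_setequal(out$positive, c("w", "x", "y"))

  # all members within two-fold of the subset median: unchanged
  eth2 <- make_score_ethogram(rbind(c(2, 3, 4), c(3, 2, 5)),
                              c("w", "x", "y"))
  sel2 <- structure(list(positive = c("w", "x", "y"), negative = character(),
                         excluded_high_magnitude = character()),
                    class = "subset_selection")
  out2 <- apply_magnitude_exclusion(sel2, eth2)
  expect_length(out2$excluded_high_magnitude, 0)

  # a single-member subset is never pruned
  sel3 <- structure(list(positive = "walklike", negative = character(),
                         excluded_high_magnitude = character()),
                    class = "subset_selection")
  out3 <- apply_magnitude_exclusion(sel3, eth)
  expect_equal(out3$positive, "walklike")
})

test_that("composite scores reproduce hand arithmetic on printed cell means", {
  members <- default_memberships()$score1
  freq <- rbind(asa = c(0, 0, 0, 2.8, 0), vsa = c(3.3, 0.5, 1.3, 17, 0.3))
  eth <- make_score_ethogram(freq, members)
  got <- compute_composite(eth, members, "score1")
  expect_equal(got$score1, c(0.56, 4.48))
  zero <- make_score_ethogram(rbind(c(0, 0, 0, 0, 0)), members)
  expect_equal(compute_composite(zero, members)$score[1], 0)
  expect_error(compute_composite(eth, c("Writhe", "NoSuch")), "NoSuch")
})

test_that("composites are permutation-invariant and linear", {
  eth <- random_ethogram(n_per_cell = 2, n_behav = 5, seed = 10)
  members <- c("B1", "B3", "B4")
  a <- compute_composite(eth, members)$score
  b <- compute_composite(eth, rev(members))$score
  expect_equal(a, b)
  eth2 <- eth
  eth2$freq <- eth$freq * 2 + 1
  expect_equal(compute_composite(eth2, members)$score, 2 * a + 1)
})

test_that("band assignment follows log-scale proximity with upward ties", {
  freq <- rbind(c(9, 48, 103, 0), c(9, 48, 103, 0))
  eth <- make_score_ethogram(freq, c("lo", "mid", "hi", "never"))
  bands <- assign_frequency_bands(eth)
  asg <- setNames(as.character(bands$assignment$band),
                  bands$assignment$behavior)
  expect_equal(unname(asg[c("lo", "mid", "hi")]),
               c("Low", "Medium", "High"))
  expect_equal(unname(asg["never"]), "Low")
  expect_true(bands$assignment$zero_flag[4])
  expect_equal(bands$boundaries, c(sqrt(500), sqrt(5000)))
  # exact boundary assigns upward
  b1 <- sqrt(500)
  ethb <- make_score_ethogram(rbind(b1, b1), "edge")
  expect_equal(as.character(
    assign_frequency_bands(ethb)$assignment$band), "Medium")
})

test_that("automated defaults band into 2 Low, 3 Medium, 7 High", {
  eth <- simulate_cohort(default_cohort_params("automated"),
                         n_per_cell = 50, seed = 23)
  bands <- assign_frequency_bands(eth, setdiff(colnames(eth$freq), "Groom"))
  tab <- table(bands$assignment$band)
  expect_equal(unname(tab["Low"]), 2L)
  expect_equal(unname(tab["Medium"]), 3L)
  expect_equal(unname(tab["High"]), 7L)
  expect_setequal(
    bands$assignment$behavior[bands$assignment$band == "Low"],
    c("Jumping", "Come Down"))
  expect_setequal(
    bands$assignment$behavior[bands$assignment$band == "Medium"],
    c("Rear Up", "Walk Left", "Walk Right"))
})

test_that("G-behave matches its closed form and is symmetric and monotone", {
  expect_equal(compute_gbehave(0, 0, 0), 0.1)
  expect_equal(compute_gbehave(9, 9, 9), 1.0)
  # one-tenth of the geometric mean of the incremented totals 10/50/100
  expect_equal(round(compute_gbehave(9, 49, 99), 4), 3.684)
  expect_equal(compute_gbehave(9, 49, 99),
               (10 * 50 * 100)^(1 / 3) / 10, tolerance = 1e-12)
  expect_equal(compute_gbehave(3, 7, 11), compute_gbehave(11, 3, 7))
  g0 <- compute_gbehave(5, 5, 5)
  expect_gt(compute_gbehave(6, 5, 5), g0)
  expect_gt(compute_gbehave(5, 6, 5), g0)
  expect_gt(compute_gbehave(5, 5, 6), g0)
  expect_error(compute_gbehave(-1, 0, 0), "non-negative")
})

test_that("derived measures expose the documented columns per arm", {
  man <- derived_measures(simulate_cohort(n_per_cell = 3, seed = 4), "manual")
  expect_true(all(c("score1", "score2", "abnormal_walk", "walk_normal",
                    "stop") %in% names(man)))
  auto <- derived_measures(
    simulate_cohort(default_cohort_params("automated"), 3, seed = 4),
    "automated")
  expect_true(all(c("band_low", "band_medium", "band_high", "g_behave",
                    "grooming") %in% names(auto)))
  expect_equal(auto$g_behave,
               compute_gbehave(auto$band_low, auto$band_medium,
                               auto$band_high))
})
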
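test_that("point splits are near-equal, exhaustive and reproducible", {
  sets <- list(a = point_set(1:10, 1:10, "a"),
               b = point_set(1:11, 1:11, "b"),
               empty = point_set(label = "empty"))
  s1 <- split_points(sets, K = 2, seed = 3)
  expect_equal(sort(vapply(s1$a, length, integer(1))), c(5L, 5L))
  expect_equal(sort(vapply(s1$b, length, integer(1))), c(5L, 6L))
  expect_equal(vapply(s1$empty, length, integer(1)), c(0L, 0L))
  ## union restores the input
  expect_setequal(c(s1$b[[1]]$x, s1$b[[2]]$x), 1:11)
  ## deterministic per seed
  s2 <- split_points(sets, K = 2, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1, split_points(sets, K = 2, seed = 4)))
})

test_that("R^2 between density maps follows its definition", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r2_density(obs, obs), 1)
  expect_equal(r2_density(rep(mean(obs), 4), obs), 0)
  expect_equal(r2_density(c(1, 2, 3, 5), obs), 0.8)
  expect_lt(r2_density(rev(obs), obs), 0) # worse than the mean
  expect_error(r2_density(obs, rep(2, 4)), "zero variance")
  expect_error(r2_density(obs, 1:5), "length")
})

test_that("signal-only cities cross-validate almost perfectly", {
  ## abundant POIs and crimes: split-half density noise is small
  classes <- data.frame(
    class_name = SIGNAL_CLASSES,
    n_points = c(300, 300, 300),
    layout = "clustered")
  area <- study_area(0, 0, 3000, 40)
  kern <- kernel_spec("exponential", 75)
  spec <- synthetic_city_spec(area, classes,
                              c(1, 0.6, 0.4) |> setNames(SIGNAL_CLASSES),
                              kern, n_crimes = 6000, seed = 21)
  bundle <- generate_city(spec)
  res <- cross_validate_city(bundle, cv_config(K = 2, n_repeats = 2,
                                               seed = 22, k_select = 3),
                             kern)
  expect_gt(res$proposed$mean_r2, 0.9)
  expect_length(res$proposed$per_run_r2, 4) # K x n_repeats
  expect_equal(res$proposed$mean_r2, mean(res$proposed$per_run_r2))
  expect_equal(res$proposed$sd_r2, sd(res$proposed$per_run_r2))
})

test_that("the sparse model outperforms the baseline on the clutter fixture", {
  fx <- selection_fixture()
  res <- cross_validate_city(fx$bundle, cv_config(K = 2, n_repeats = 2,
                                                  seed = 31), fx$kernel)
  expect_gt(res$proposed$mean_r2, res$baseline$mean_r2)
  expect_true(all(res$proposed$per_run_r2 <= 1))
  expect_equal(lengths(res$proposed$per_run_selected), rep(10L, 4))
})

test_that("repeats draw from per-repeat sub-streams", {
  fx <- selection_fixture()
  cfg1 <- cv_config(K = 2, n_repeats = 1, seed = 41)
  cfg2 <- cv_config(K = 2, n_repeats = 2, seed = 41)
  r1 <- cross_validate_city(fx$bundle, cfg1, fx$kernel)
  r2 <- cross_validate_city(fx$bundle, cfg2, fx$kernel)
  expect_identical(r1$proposed$per_run_r2,
                   r2$proposed$per_run_r2[1:2])
  expect_identical(r1$baseline$per_run_r2, r2$baseline$per_run_r2[1:2])
})

test_that("leave-one-city-out generalises between exchangeable cities", {
  ## two cities drawn from the same generative truth, one with shuffled
  ## weights: the exchangeable pair transfers, the perturbed one degrades
  mk <- function(seed, weights) {
    spec <- benchmark_city_spec(seed, n_cells_per_side = 40,
                                n_crimes = 1200, n_clutter = 12)
    spec$true_weights[SIGNAL_CLASSES] <- weights
    b <- generate_city(spec, city_name = paste0("city", seed))
    b
  }
  b1 <- mk(51, c(1, 0.6, 0.4))
  b2 <- mk(52, c(1, 0.6, 0.4))
  b3 <- mk(53, c(0, 0, 0) + c(0.05, 0.05, 1.6)) # different weight profile
  cfg <- cv_config(K = 2, n_repeats = 1, seed = 50, k_select = 10)
  kern <- kernel_spec("exponential", 75)
  loco <- leave_one_city_out(list(b1, b2, b3), cfg, kern)
  expect_equal(loco$city, c("city51", "city52", "city53"))
  r2 <- setNames(loco$r2, loco$city)
  ## cities sharing the generative truth transfer; the deviant one degrades
  expect_lt(r2[["city53"]], min(r2[["city51"]], r2[["city52"]]))
  ## and scores far below its own city-specific model
  cv3 <- cross_validate_city(b3, cfg, kern)
  expect_lt(r2[["city53"]], cv3$proposed$mean_r2)
  fits <- attr(loco, "fits")
  expect_length(fits, 3)
  expect_true(all(vapply(fits, inherits, logical(1), "model_fit")))
})

test_that("penalty sweeps report full, empty and shrinking supports", {
  fx <- selection_fixture()
  amax <- lasso_alpha_max(fx$basis, fx$y)
  alphas <- c(0, amax * c(1e-3, 1e-2, 0.1, 0.5, 1.1))
  tab <- alpha_sweep(fx$bundle, alphas, cv_config(K = 2, n_repeats = 1,
                                                  seed = 61), fx$kernel)
  expect_equal(nrow(tab), length(alphas))
  expect_equal(tab$mean_support[1], 20) # alpha = 0: every column survives
  expect_equal(tab$mean_support[nrow(tab)], 0)
  expect_lte(tab$mean_r2[nrow(tab)], 0) # intercept-only prediction
  expect_true(all(diff(tab$mean_support) <= 0))
})

test_that("bandwidth sweeps evaluate every requested bandwidth", {
  fx <- selection_fixture()
  hs <- 3000 / c(60, 40, 20)
  tab <- bandwidth_sweep(fx$bundle, hs, cv_config(K = 2, n_repeats = 1,
                                                  seed = 71))
  expect_equal(tab$bandwidth, hs)
  expect_true(all(is.finite(tab$mean_r2)))
  single <- bandwidth_sweep(fx$bundle, 75, cv_config(K = 2, n_repeats = 1,
                                                     seed = 72))
  expect_equal(nrow(single), 1)
})

test_that("selected-class occurrence counts match a manual tally", {
  fits <- list(c("Pubs", "Nightclubs", "Cafes"),
               c("Pubs", "Bus Stops"),
               c("Pubs", "Nightclubs"))
  tab <- count_selected_classes(fits)
  expect_equal(tab$class, c("Pubs", "Nightclubs", "Bus Stops", "Cafes"))
  expect_equal(tab$count, c(3L, 2L, 1L, 1L))
  empty <- count_selected_classes(list())
  expect_equal(nrow(empty), 0)
})

test_that("improvement percentages follow the rounding conventions", {
  imp <- improvement_stats(0.2968, 0.6091, "Bristol")
  expect_equal(imp$per_city$improvement_pct, 105)
  expect_equal(improvement_stats(0.5, 0.5, "X")$per_city$improvement_pct, 0)
  expect_error(improvement_stats(c(0.4, 0), c(0.5, 0.5), c("A", "B")),
               "positive")
  expect_error(improvement_stats(0.4, c(0.5, 0.6), c("A", "B")), "aligned")
})

test_that("displacement summaries use mid-median and nearest-rank p90", {
  z <- displacement_summary(rep(0, 5))
  expect_equal(c(z$mean, z$median, z$p90), c(0, 0, 0))
  s <- displacement_summary(seq(10, 100, by = 10), bin_width = 5)
  expect_equal(s$mean, 55)
  expect_equal(s$median, 55)
  expect_equal(s$p90, 90)
  expect_equal(sum(s$bins$count), 10)
  expect_true(all(s$bins$upper - s$bins$lower == 5))
  const <- displacement_summary(rep(30, 25))
  expect_equal(c(const$mean, const$median, const$p90), c(30, 30, 30))
})
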
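# A dense one-exposure design with a noiseless linear surface h(z) = 2 z:
# GP conditioning at tight residual variance must interpolate, so quantile
# contrasts have a closed form.
linear_surface_fit <- function(n = 80, slope = 2, n_draws = 50) {
  z <- seq(-2, 2, length.out = n)
  df <- data.frame(y = slope * z, z = z)
  d <- mixture_data(df, outcome = "y", exposures = "z")
  fixed_draw_fit(d, "standard", beta = 0, sigma2 = 1e-6,
                 lambda = 4 / 1e-6, r = 1 / 4, n_draws = n_draws)
}

test_that("empirical quantile points use type-7 interpolation per exposure", {
  d <- mixture_data(data.frame(y = c(0.1, -0.2, 0.3), z = c(1, 2, 3)),
                    outcome = "y", exposures = "z")
  expect_equal(unname(quantile_points(d, 0.5)), 2)
  expect_equal(unname(quantile_points(d, 0.25)), 1.5)
  expect_equal(unname(quantile_points(d, 0.75)), 2.5)
})

test_that("pooled and by-group quantiles agree for identical group distributions", {
  vals <- c(0.5, 1.2, 2.0, 3.3, 4.1)
  df <- data.frame(y = rnorm(10), z = rep(vals, 2),
                   g = rep(c("a", "b"), each = 5))
  d <- mixture_data(df, "y", "z", modifier = "g")
  for (q in c(0.25, 0.5, 0.75)) {
    expect_equal(quantile_points(d, q),
                 quantile_points(d, q, scope = "by_group", group = 1))
    expect_equal(quantile_points(d, q, scope = "by_group", group = 1),
                 quantile_points(d, q, scope = "by_group", group = 2))
  }
})

test_that("identical contrast endpoints give exactly zero draws", {
  fit <- linear_surface_fit()
  e <- total_mixture_effect(fit, q1 = 0.5, q2 = 0.5)
  expect_true(all(e$draws == 0))
  expect_identical(e$lower, 0)
  expect_identical(e$upper, 0)
  cs <- sample_h_contrast(fit, 0.7, 0.7)
  expect_true(all(cs == 0))
})

test_that("GP conditioning recovers a known linear surface's contrasts", {
  fit <- linear_surface_fit(slope = 2)
  cs <- sample_h_contrast(fit, point_a = 0.5, point_b = -0.5)
  expect_lt(abs(mean(cs) - 2), 0.05)
  # single-exposure IQR contrast: slope times the quantile gap
  e <- single_exposure_effect(fit, m = 1)
  gap <- unname(quantile_points(fit$dataset, 0.75) -
                  quantile_points(fit$dataset, 0.25))
  expect_lt(abs(e$mean - 2 * gap), 0.05)
  # total effect equals the sum of per-exposure linear effects (M = 1 here)
  et <- total_mixture_effect(fit, q1 = 0.25, q2 = 0.75)
  expect_lt(abs(et$mean - 2 * gap), 0.05)
})

test_that("reversing the contrast quantiles negates every draw exactly", {
  d <- tiny_dataset(n = 30, P = 2, seed = 31)
  fit <- kmr(d, "group_separable", control = fast_control(seed = 3))
  a <- total_mixture_effect(fit, q1 = 0.25, q2 = 0.75, group = 2)
  b <- total_mixture_effect(fit, q1 = 0.75, q2 = 0.25, group = 2)
  expect_identical(a$draws, -b$draws)
  s1 <- single_exposure_effect(fit, m = 2, q1 = 0.25, q2 = 0.75, group = 1)
  s2 <- single_exposure_effect(fit, m = 2, q1 = 0.75, q2 = 0.25, group = 1)
  expect_identical(s1$draws, -s2$draws)
})

test_that("the shared-surface variant returns identical effects for all groups", {
  d <- tiny_dataset(n = 30, P = 2, seed = 32)
  fit <- kmr(d, "standard", control = fast_control(seed = 4))
  e1 <- total_mixture_effect(fit, group = 1)
  e2 <- total_mixture_effect(fit, group = 2)
  expect_equal(e1$draws, e2$draws)
})

test_that("credible intervals nest: the 80% interval sits inside the 95%", {
  d <- tiny_dataset(n = 30, P = 2, seed = 33)
  fit <- kmr(d, "group_separable", control = fast_control(seed = 5))
  e <- total_mixture_effect(fit, group = 1)
  q80 <- quantile(e$draws, c(0.1, 0.9), type = 7)
  expect_gte(q80[[1]], e$lower)
  expect_lte(q80[[2]], e$upper)
})

test_that("group-separable contrasts ignore the other group's outcomes", {
  d <- tiny_dataset(n = 40, P = 2, seed = 34)
  d2 <- d
  idx2 <- which(d$w == 2)
  d2$y[idx2] <- d$y[rev(idx2)]  # permute group 2 outcomes only
  beta <- rep(0.3, ncol(gskmr:::kmr_design(d, include_modifier = TRUE)))
  fa <- fixed_draw_fit(d, "group_separable", beta = beta, sigma2 = 1,
                       lambda = c(1, 2), r = c(0.5, 0.5, 0.5))
  fb <- fixed_draw_fit(d2, "group_separable", beta = beta, sigma2 = 1,
                       lambda = c(1, 2), r = c(0.5, 0.5, 0.5))
  ea <- total_mixture_effect(fa, group = 1)
  eb <- total_mixture_effect(fb, group = 1)
  expect_identical(ea$draws, eb$draws)
  # while group 2's own effect does change
  ga <- total_mixture_effect(fa, group = 2)
  gb <- total_mixture_effect(fb, group = 2)
  expect_false(isTRUE(all.equal(ga$draws, gb$draws)))
})

test_that("between-group differences subtract draw-wise with checks", {
  dr <- rnorm(500)
  q <- list(kind = "total_mixture", q1 = 0.25, q2 = 0.75, scope = "pooled")
  ea <- gskmr:::new_effect(dr, q, "a")
  eb <- gskmr:::new_effect(dr, q, "b")
  diff <- between_group_difference(ea, eb)
  expect_true(all(diff$draws == 0))
  expect_equal(diff$group, c("a", "b"))

  ec <- gskmr:::new_effect(rnorm(400), q, "c")
  expect_error(between_group_difference(ea, ec), "draw counts")
  eq2 <- gskmr:::new_effect(dr, modifyList(q, list(q2 = 0.9)), "d")
  expect_error(between_group_difference(ea, eq2), "different query")
})

test_that("independent-chain differences add variances (width ~ sqrt(2))", {
  set.seed(41)
  n <- 20000
  q <- list(kind = "total_mixture", q1 = 0.25, q2 = 0.75, scope = "pooled")
  ea <- gskmr:::new_effect(rnorm(n, 1, 1), q, "a")
  eb <- gskmr:::new_effect(rnorm(n, 0, 1), q, "b")
  diff <- between_group_difference(ea, eb, paired = FALSE)
  w_single <- ea$upper - ea$lower
  w_diff <- diff$upper - diff$lower
  expect_lt(abs(w_diff / w_single - sqrt(2)), 0.05)
  expect_lt(abs(diff$mean - 1), 0.05)
})

test_that("exposure-response curves are consistent with point effects", {
  fit <- linear_surface_fit(slope = 2)
  cv <- exposure_response_curve(fit, m = 1, grid = c(0.25, 0.5, 0.75))
  expect_equal(nrow(cv), 3L)
  # one-point grid degenerates to a single surface evaluation
  cv1 <- exposure_response_curve(fit, m = 1, grid = 0.5)
  expect_equal(nrow(cv1), 1L)
  # differencing the curve endpoints reproduces the IQR effect
  e <- single_exposure_effect(fit, m = 1)
  expect_lt(abs((cv$mean[3] - cv$mean[1]) - e$mean), 0.05)
})

test_that("a flat surface yields a near-constant curve", {
  set.seed(42)
  z <- seq(-2, 2, length.out = 60)
  d <- mixture_data(data.frame(y = rnorm(60, 0, 0.1), z = z),
                    outcome = "y", exposures = "z")
  fit <- fixed_draw_fit(d, "standard", beta = 0, sigma2 = 1,
                        lambda = 0.1, r = 0.25, n_draws = 100)
  cv <- exposure_response_curve(fit, m = 1)
  expect_lt(max(cv$mean) - min(cv$mean), 0.25)
})

test_that("effect tables collect queries, estimates and intervals", {
  fit <- linear_surface_fit()
  effs <- list(total_mixture_effect(fit, q2 = 0.75),
               single_exposure_effect(fit, m = 1))
  tab <- effect_table(effs)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("group", "kind", "mean", "lower", "upper") %in%
                    names(tab)))
  expect_true(all(tab$lower <= tab$upper))
})
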
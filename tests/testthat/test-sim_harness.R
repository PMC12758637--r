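fabricate_estimates <- function(truth, center = truth$truth, half = 0) {
  data.frame(effect_type = truth$effect_type, group = truth$group,
             key = truth$key, est = center,
             lower = center - half, upper = center + half)
}

test_that("replicate scoring has the right degenerate behavior", {
  spec <- builtin_scenario("two_level_A", seed = 4)
  spec$group_sizes <- c(25L, 25L)
  truth <- generate_dataset(spec)$truth

  exact <- evaluate_fit(fabricate_estimates(truth), truth)
  expect_true(all(exact$rmse == 0))
  expect_true(all(exact$coverage == 1))
  expect_true(all(exact$width == 0))

  wide <- evaluate_fit(fabricate_estimates(truth, center = truth$truth + 1,
                                           half = 1e6), truth)
  expect_true(all(wide$coverage == 1))

  bad <- fabricate_estimates(truth)
  bad$key[1] <- "not-a-key"
  expect_error(evaluate_fit(bad, truth), "misaligned")
})

test_that("interval coverage of fabricated normal draws is near nominal", {
  spec <- builtin_scenario("two_level_A", seed = 4)
  spec$group_sizes <- c(25L, 25L)
  truth <- generate_dataset(spec)$truth
  set.seed(71)
  cvg <- vapply(1:1000, function(i) {
    est <- truth$truth + rnorm(nrow(truth))
    e <- data.frame(effect_type = truth$effect_type, group = truth$group,
                    key = truth$key, est = est,
                    lower = est + qnorm(0.025), upper = est + qnorm(0.975))
    mean(evaluate_fit(e, truth)$coverage)
  }, numeric(1))
  expect_lt(abs(mean(cvg) - 0.95), 0.01)
  # the estimator's spread is binomial-consistent for one effect row
  n_rows <- sum(truth$effect_type == "group_total")
  expect_lt(sd(cvg), 2 * sqrt(0.95 * 0.05 / n_rows))
})

test_that("a tiny scenario run emits the full metrics table deterministically", {
  spec <- scenario_spec(c(30L, 30L), scales = c(1, 0), seed = 1)
  ctl <- kmr_control(iter = 300, burnin = 150, seed = 1)
  tab <- run_scenario(spec, models = "group_separable", reps = 2,
                      control = ctl, master_seed = 5, scenario_id = "tiny")
  expect_s3_class(tab, "metrics_table")
  expect_setequal(unique(tab$effect_type),
                  c("surface", "group_total", "group_single",
                    "diff_total", "diff_single"))
  expect_true(all(tab$coverage >= 0 & tab$coverage <= 1))
  expect_true(all(tab$width >= 0))
  expect_true(all(tab$rmse >= 0))
  expect_true(all(tab$reps == 2))

  tab2 <- run_scenario(spec, models = "group_separable", reps = 2,
                       control = ctl, master_seed = 5, scenario_id = "tiny")
  expect_identical(tab, tab2)
})

test_that("the exposure-only model emits no between-group rows", {
  spec <- scenario_spec(c(30L, 30L), scales = c(1, 0), seed = 1)
  ctl <- kmr_control(iter = 300, burnin = 150, seed = 1)
  tab <- run_scenario(spec, models = "exposure_only", reps = 1,
                      control = ctl, master_seed = 3)
  expect_false(any(grepl("^diff", tab$effect_type)))
  # but it is scored per group against group-specific truths
  expect_true(all(c("group_total", "group_single", "surface") %in%
                    tab$effect_type))
})

test_that("unknown models are rejected with the valid list", {
  spec <- scenario_spec(c(30L, 30L), seed = 1)
  expect_error(run_scenario(spec, models = "mystery", reps = 1),
               "exposure_only")
})

test_that("model comparison reports are ordered, round-trip through CSV", {
  spec <- scenario_spec(c(30L, 30L), scales = c(1, 0), seed = 1)
  ctl <- kmr_control(iter = 200, burnin = 100, seed = 1)
  tab <- run_scenario(spec, models = c("group_separable", "exposure_only"),
                      reps = 1, control = ctl, master_seed = 9,
                      scenario_id = "s1")
  rep <- compare_models(tab)
  expect_s3_class(rep, "kmr_report")
  # effect-type blocks in canonical order, models ordered within block
  expect_equal(rep$effect_type,
               sort(rep$effect_type)[order(match(sort(rep$effect_type),
                                                 gskmr:::effect_type_order))],
               ignore_attr = TRUE)
  first_block <- rep[rep$effect_type == "surface", "model"]
  expect_equal(first_block,
               intersect(gskmr:::kmr_models, first_block))

  path <- tempfile(fileext = ".csv")
  write.csv(rep, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$s1.rmse, rep$s1.rmse, tolerance = 1e-12)
  unlink(path)

  empty <- compare_models(tab[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("checkpointed runs resume from partial results", {
  spec <- scenario_spec(c(30L, 30L), scales = c(1, 0), seed = 1)
  ctl <- kmr_control(iter = 200, burnin = 100, seed = 1)
  ckdir <- tempfile("ck")
  tab1 <- run_scenario(spec, models = "group_separable", reps = 2,
                       control = ctl, master_seed = 5,
                       checkpoint_dir = ckdir)
  expect_length(list.files(ckdir), 2L)
  # rerun reuses the checkpoints (results identical)
  tab2 <- run_scenario(spec, models = "group_separable", reps = 2,
                       control = ctl, master_seed = 5,
                       checkpoint_dir = ckdir)
  expect_equal(tab1$rmse, tab2$rmse, tolerance = 1e-12)
  unlink(ckdir, recursive = TRUE)
})
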
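slow <- fish_preset("slow_dome")
fast <- fish_preset("fast_dome")

test_that("production efficiency is bounded by the assimilated fraction", {
  set.seed(3)
  w <- exp(runif(60, log(0.1), log(400)))
  Ts <- runif(60, 5, 25.5)
  tau <- runif(60, 0.01, 1)
  for (params in list(slow, fast)) {
    eff <- production_efficiency(w, Ts, tau, params)
    expect_true(all(eff < 1 - 0.15 - 0.25))
  }
  expect_true(is.na(production_efficiency(10, 15, 0, slow)))
})

test_that("efficiency declines past its peak as activity rises", {
  tau <- seq(0.05, 1, by = 0.01)
  for (params in list(slow, fast)) {
    eff <- production_efficiency(10, 15, tau, params)
    peak <- which.max(eff)
    expect_true(all(diff(eff[peak:length(eff)]) < 0))
  }
})

test_that("Gilliam ratio is the behavioural objective scaled by weight", {
  sol <- optimal_activity(10, 15, slow)
  expect_equal(gilliam_ratio(10, 15, sol$tau_star, slow),
               sol$objective / 10, tolerance = 1e-12)
  # sign follows P; declining in the activity-risk coefficient
  expect_lt(gilliam_ratio(10, 15, 0, slow), 0)
  p_risky <- fish_preset("slow_dome"); p_risky$traits$mu <- 12
  expect_lt(gilliam_ratio(10, 15, 0.5, p_risky),
            gilliam_ratio(10, 15, 0.5, slow))
})

test_that("scenario sweep has the factorial structure and flags, no gaps", {
  sw <- run_sweep(strategies = "slow", mos_regimes = c("dome", "nodome"),
                  T_grid = c(10, 15, 20, 25.5), food_multipliers = 1,
                  sizes = c(10, 80), include_life_history = FALSE)
  expect_equal(nrow(sw), 2 * 4 * 2)
  expect_false(any(is.na(sw$tau_star)))
  expect_true(all(sw$PM_rel <= 1 + 1e-12))
  expect_true(all(sw$efficiency < 0.6, na.rm = TRUE))
  # rising-MOS cells are never oxygen limited below the lethal temperature
  expect_false(any(sw$limited_by_oxygen[sw$mos_regime == "nodome"]))
})

test_that("identical configuration yields byte-identical CSV output", {
  sw1 <- run_sweep(strategies = "fast", mos_regimes = "dome",
                   T_grid = c(12, 18), food_multipliers = c(2 / 3, 1),
                   sizes = 10, include_life_history = FALSE)
  sw2 <- run_sweep(strategies = "fast", mos_regimes = "dome",
                   T_grid = c(12, 18), food_multipliers = c(2 / 3, 1),
                   sizes = 10, include_life_history = FALSE)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_scenario_csv(sw1, f1, params = fish_preset("fast_dome"))
  write_scenario_csv(sw2, f2, params = fish_preset("fast_dome"))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # header records the resolved parameters; table parses back
  lines <- readLines(f1)
  expect_true(any(grepl("^# fast_dome traits", lines)))
  back <- utils::read.csv(f1, comment.char = "#")
  expect_equal(nrow(back), nrow(sw1))
})

test_that("sweep plot method returns a ggplot", {
  sw <- run_sweep(strategies = "slow", mos_regimes = "dome",
                  T_grid = c(10, 15, 20), food_multipliers = 1,
                  sizes = 10, include_life_history = FALSE)
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("command-line interface emits a parseable budget row", {
  cli <- system.file("cli", "finscope", package = "finscope")
  expect_true(nzchar(cli))
  out <- tempfile(fileext = ".csv")
  res <- system2("Rscript", c(cli, "rates", "--preset", "slow_dome",
                              "--w", "10", "--T", "15", "--tau", "0.5",
                              "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  row <- utils::read.csv(out, comment.char = "#")
  expect_equal(row$P, energy_gain(10, 15, 0.5, slow), tolerance = 1e-10)
})
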
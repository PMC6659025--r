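slow <- fish_preset("slow_dome")

test_that("allocation is the logistic reaction norm with the right anchors", {
  mrn <- mrn_params(w_star = 50, c_mrn = 0.5)
  expect_equal(allocation(50, mrn), 0.5)
  expect_equal(allocation(60, mrn), 1 / (1 + exp(-5)), tolerance = 1e-14)
  expect_equal(allocation(1e6, mrn), 1)
  expect_lt(allocation(1e-6, mrn), 1e-10)
  # sloped norm shifts the midpoint with age
  mrn_s <- mrn_params(w_star = 50, c_mrn = 0.5, slope = 10)
  expect_equal(allocation(70, mrn_s, age = 2), 0.5)
  expect_error(allocation(10, mrn_params()), "w_star")
})

test_that("without allocation, growth plateaus at the energy-limited root", {
  # low food keeps the asymptote small enough to reach within the horizon
  g <- grow(slow, 15, food = 2 / 3, w_star = 1e6, t_horizon = 150)
  # independent oracle: root of P(w, tau*(w)) = 0
  Pstar <- function(w) optimal_activity(w, 15, slow, food = 2 / 3)$P
  root <- uniroot(Pstar, c(50, 2000), tol = 1e-8)$root
  expect_lt(abs(attr(g, "w_inf") - root) / root, 0.01)
  # weight is non-decreasing and lengths follow the cubic condition factor
  expect_true(all(diff(g$w) > -1e-8))
  expect_equal(g$L, (g$w / 0.01)^(1 / 3), tolerance = 1e-12)
})

test_that("survival matches the closed form when mortality is forced constant", {
  p <- fish_preset("slow_dome")
  p$traits$q <- 1 # weight exponent vanishes from mortality
  p$traits$mu <- 1e-9 # activity contribution negligible
  g <- grow(p, 15, w_star = 1e6, t_horizon = 20)
  expect_equal(g$S, exp(-p$traits$rho * g$t), tolerance = 1e-6)
  expect_equal(g$S[1], 1)
  expect_true(all(diff(g$S) <= 0))
})

test_that("fitness vanishes when the norm midpoint exceeds attainable size", {
  out <- lifetime_fitness(slow, 15, w_star = 1e6)
  expect_equal(out$R0, 0)
})

test_that("R0 has converged long before the default horizon", {
  p <- calibrated_preset("slow_dome")
  r50 <- lifetime_fitness(p, 15, t_horizon = 50)$R0
  r100 <- lifetime_fitness(p, 15, t_horizon = 100)$R0
  expect_lt(abs(r100 - r50) / r100, 1e-3)
  pf <- calibrated_preset("fast_dome")
  f50 <- lifetime_fitness(pf, 15, t_horizon = 50)$R0
  f100 <- lifetime_fitness(pf, 15, t_horizon = 100)$R0
  expect_lt(abs(f100 - f50) / f100, 1e-3)
})

test_that("lethal or oxygen-infeasible conditions give degenerate trajectories", {
  g <- grow(slow, 26, w_star = 100) # MOS is zero at T_max
  expect_true(attr(g, "degenerate"))
  expect_equal(attr(g, "R0"), 0)
  expect_equal(g$S[nrow(g)], 0)
  expect_error(grow(slow, 27, w_star = 100), "lethal")
  expect_error(grow(slow, 15), "w_star")
})

test_that("reaction-norm calibration is idempotent and internally consistent", {
  p <- calibrated_preset("slow_dome")
  cal <- attr(p, "calibration")
  expect_true(cal$converged)
  # below the energy-limited asymptote
  expect_lt(p$mrn$w_star, finscope:::energy_asymptote(slow, 15))
  # refined optimum within one scan cell of the grid argmax
  scan <- cal$scan
  i <- which.max(scan$R0)
  expect_gte(p$mrn$w_star, scan$w_star[max(1, i - 1)])
  expect_lte(p$mrn$w_star, scan$w_star[min(nrow(scan), i + 1)])
  # the refined point is at least as fit as every scanned candidate
  expect_gte(lifetime_fitness(p, 15)$R0, max(scan$R0) * (1 - 1e-3))
  # idempotence: deterministic pipeline
  p2 <- calibrate_wstar(p)
  expect_equal(p2$mrn$w_star, p$mrn$w_star)
})

test_that("maturation age tracks the 50% allocation crossing", {
  p <- calibrated_preset("slow_dome")
  g <- grow(p, 15, times = seq(0, 40, by = 0.05))
  mat <- glance(g)$maturation_age
  expect_false(is.na(mat))
  # weight at the maturation age is the reaction-norm midpoint
  w_at <- approx(g$t, g$w, xout = mat)$y
  expect_lt(abs(w_at - p$mrn$w_star) / p$mrn$w_star, 0.01)
  # warmer water speeds early growth, shifting maturation along the flat norm
  g18 <- grow(p, 18, times = seq(0, 40, by = 0.05))
  expect_false(glance(g18)$maturation_age == mat)
})

test_that("trajectory accessors: tidy, glance, autoplot", {
  p <- calibrated_preset("slow_dome")
  g <- grow(p, 15)
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("t", "w", "L", "tau_star", "psi", "M", "S", "R0_cum"))
  gl <- glance(g)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$R0, attr(g, "R0"))
  expect_s3_class(autoplot(g), "ggplot")
})
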
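test_that("presets carry the trait-scenario table values", {
  slow <- fish_preset("slow_dome")
  fast <- fish_preset("fast_dome")
  expect_equal(
    unlist(slow$traits[c("k", "k_a", "n", "h", "rho", "mu")]),
    c(k = 1, k_a = 4, n = 0.88, h = 30, rho = 0.1, mu = 6))
  expect_equal(
    unlist(fast$traits[c("k", "k_a", "n", "h", "rho", "mu")]),
    c(k = 1.5, k_a = 2, n = 0.75, h = 60, rho = 1, mu = 1))
  # shared values across strategies
  for (p in list(slow, fast)) {
    expect_equal(unlist(p$traits[c("beta", "phi_e", "gamma_theta", "p", "q")]),
                 c(beta = 0.15, phi_e = 0.25, gamma_theta = 60,
                   p = 0.8, q = 0.8))
    expect_equal(unlist(p$thermal[c("E_a", "T0", "T_max", "C_crit", "C_50")]),
                 c(E_a = 0.52, T0 = 15, T_max = 26, C_crit = 2, C_50 = 4))
    expect_equal(unlist(p$mrn[c("c_mrn", "slope")]), c(c_mrn = 0.5, slope = 0))
  }
  expect_equal(slow$thermal$zeta, 0.5)
  expect_equal(fast$thermal$zeta, 1)
  # dome vs nodome MOS shapes
  expect_equal(unlist(fish_preset("slow_dome")$thermal[c("eta", "T_opt")]),
               c(eta = 3, T_opt = 20))
  expect_equal(unlist(fish_preset("slow_nodome")$thermal[c("eta", "T_opt")]),
               c(eta = 0.1, T_opt = 25))
  # uncalibrated reaction norm intercept
  expect_true(is.na(slow$mrn$w_star))
})

test_that("all presets pass the type invariants; unknown names error", {
  for (nm in c("slow_dome", "slow_nodome", "fast_dome", "fast_nodome")) {
    expect_silent(validate_params(fish_preset(nm)))
  }
  expect_error(fish_preset("medium_dome"), "unknown preset")
  expect_error(fish_preset(1), "unknown preset")
})

test_that("parameter invariants reject invalid values naming the field", {
  expect_error(trait_params(beta = 1.2), "beta")
  expect_error(trait_params(beta = 0.6, phi_e = 0.5), "beta")
  expect_error(trait_params(n = 1.2), "n")
  expect_error(trait_params(k = -1), "`k`")
  expect_error(thermal_params(T_opt = 27), "T_opt")
  expect_error(thermal_params(C_crit = 5), "C_crit")
  expect_error(mrn_params(c_mrn = 0), "c_mrn")
  expect_error(sim_settings(w0 = -1), "w0")
})

test_that("config files override presets field-wise and are validated", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("preset: slow_dome", "traits:", "  gamma_theta: 40"), path)
  p <- read_config(path)
  expect_equal(p$traits$gamma_theta, 40)
  expect_equal(p$traits$h, 30) # untouched preset value
  expect_equal(p$thermal$eta, 3)

  writeLines(c("preset: slow_dome", "traits:", "  beta: 1.2"), path)
  expect_error(read_config(path), "beta")

  # preset key only: identical to the preset constructor
  writeLines("preset: fast_nodome", path)
  p2 <- read_config(path)
  ref <- fish_preset("fast_nodome")
  expect_equal(p2$traits, ref$traits)
  expect_equal(p2$thermal, ref$thermal)
  expect_equal(p2$mrn, ref$mrn)

  writeLines(c("preset: slow_dome", "wrong_section:", "  a: 1"), path)
  expect_error(read_config(path), "unknown config key")
  writeLines(c("preset: slow_dome", "traits:", "  not_a_field: 1"), path)
  expect_error(read_config(path), "not_a_field")
  expect_error(read_config(tempfile()), "not found")
})

test_that("JSON configs are accepted too", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(preset = "fast_dome",
                            thermal_oxygen = list(l = 8)),
                       path, auto_unbox = TRUE)
  p <- read_config(path)
  expect_equal(p$thermal$l, 8)
  expect_equal(p$traits$h, 60)
})

test_that("write_config / read_config round-trips a bundle exactly", {
  p <- fish_preset("fast_dome")
  p$traits$gamma_theta <- 45
  p$mrn$w_star <- 123.4
  path <- tempfile(fileext = ".yaml")
  write_config(p, path)
  q <- read_config(path)
  expect_equal(q$traits, p$traits)
  expect_equal(q$thermal, p$thermal)
  expect_equal(q$mrn, p$mrn)
  expect_equal(q$sim, p$sim)
})
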
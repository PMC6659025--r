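# Naive, separately coded evaluator of the instantaneous rate equations.
# Deliberately written in a different style (scalar, Kelvin conversions and
# formulas inlined) and kept independent of the package internals: it is
# the oracle against which the vectorized implementations are checked.
naive_rates <- function(w, T_c, tau, traits, thermal, food = 1) {
  b <- 8.617e-5
  TK <- T_c + 273.15
  T0K <- thermal$T0 + 273.15
  cT <- exp(thermal$E_a * (TK - T0K) / (b * TK * T0K))

  encounter <- tau * (food * traits$gamma_theta) * w^traits$p
  maxcons <- traits$h * cT * w^traits$q
  f <- if (encounter == 0) 0 else encounter / (encounter + maxcons)

  P <- (1 - traits$beta - traits$phi_e) * f * maxcons -
    cT * traits$k * w^traits$n - tau * cT * traits$k_a * w

  C <- thermal$l * exp(-thermal$o2_decay * (T_c - 5))
  x <- (thermal$T_max - T_c) / (thermal$T_max - thermal$T_opt)
  lam <- thermal$zeta * x^thermal$eta * exp(thermal$eta * (1 - x))
  sat <- 1 - exp((C - thermal$C_crit) * log(0.5) /
                   (thermal$C_50 - thermal$C_crit))
  if (C < thermal$C_crit) sat <- 0
  S <- lam * sat * w^traits$n
  D <- thermal$omega * cT *
    (traits$beta * f * traits$h * w^traits$q +
       traits$k * w^traits$n + tau * traits$k_a * w)

  M <- (traits$rho + traits$mu * tau) * w^(traits$q - 1)

  list(f = f, P = P, S = S, D = D, P_O2 = S - D, M = M)
}

# Brute-force grid argmax of the Gilliam objective P/M over tau in [0, 1].
brute_force_tau <- function(w, T_c, params, food = 1, n = 1e5) {
  tau <- seq(0, 1, length.out = n)
  G <- energy_gain(w, T_c, tau, params, food = food) /
    mortality_rate(w, tau, params)
  tau[which.max(G)]
}
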
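# Internal: realized-activity cache over a weight grid at fixed (T, food).
#
# Re-optimizing tau inside the growth ODE right-hand side is the dominant
# cost of the model, so the Gilliam optimum, its capped realized value and
# the associated rates are precomputed on a log-spaced weight grid and
# interpolated. The per-weight optimum uses a dense tau grid with a
# parabolic refinement of the argmax (the grid localizes the maximum; one
# Newton-like parabola step recovers it to ~grid^2 accuracy), and the
# oxygen cap is the interpolated root of the (monotone in tau) scope.
activity_cache <- function(params, T_c, food = 1,
                           w_lo = NULL, w_hi = NULL,
                           n_w = NULL, n_tau = 1025) {
  tr <- params$traits
  th <- params$thermal
  n_w <- n_w %||% params$sim$cache_n
  w_lo <- w_lo %||% params$sim$w_floor
  stopifnot(w_hi > w_lo)
  cT <- arrhenius_factor(T_c, th)
  SO2 <- oxygen_supply(T_c, th)

  w <- exp(seq(log(w_lo), log(w_hi), length.out = n_w))
  tau <- seq(0, 1, length.out = n_tau)

  wp <- w^tr$p
  wq <- w^tr$q
  wn <- w^tr$n
  enc <- outer(food * tr$gamma_theta * wp, tau) # tau * encountered food
  cmax <- tr$h * cT * wq
  f <- enc / (enc + cmax) # cmax > 0 so f = 0 at tau = 0
  assim <- (1 - tr$beta - tr$phi_e)
  P <- assim * f * cmax - cT * tr$k * wn -
    outer(cT * tr$k_a * w, tau)
  M <- (tr$rho + outer(rep(tr$mu, n_w), tau)) * w^(tr$q - 1)
  D <- th$omega * cT * (tr$beta * f * tr$h * matrix(wq, n_w, n_tau) +
                          tr$k * wn + outer(tr$k_a * w, tau))
  scope <- SO2 * wn - D

  # oxygen cap: scope is strictly decreasing in tau
  feasible <- scope[, 1] >= 0
  n_ok <- rowSums(scope >= 0)
  tau_max <- rep(0, n_w)
  full <- n_ok == n_tau
  tau_max[full] <- 1
  part <- feasible & !full
  if (any(part)) {
    j <- n_ok[part]
    idx0 <- cbind(which(part), j)
    idx1 <- cbind(which(part), j + 1)
    s0 <- scope[idx0]
    s1 <- scope[idx1]
    tau_max[part] <- tau[j] + (tau[j + 1] - tau[j]) * s0 / (s0 - s1)
  }

  refine <- function(vals, i) {
    # parabolic refinement of a row-wise grid argmax
    i0 <- pmax(i - 1, 1)
    i1 <- pmin(i + 1, n_tau)
    rows <- seq_len(n_w)
    y0 <- vals[cbind(rows, i0)]
    y1 <- vals[cbind(rows, i)]
    y2 <- vals[cbind(rows, i1)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(denom) > 1e-300, 0.5 * (y0 - y2) / denom, 0)
    shift[i == 1 | i == n_tau] <- 0
    pmin(pmax(tau[i] + shift * (tau[2] - tau[1]), 0), 1)
  }

  G <- P / M
  i_opt <- max.col(G, ties.method = "first")
  tau_opt <- refine(G, i_opt)

  # realized: cap at tau_max; where nothing feasible is profitable,
  # minimize the loss (argmax P) instead of the ratio
  tau_star <- pmin(tau_opt, tau_max)
  Pmask <- P
  Pmask[outer(rep(1, n_w), tau) > tau_max + 1e-12] <- -Inf
  p_best <- apply(Pmask, 1, max)
  lossy <- feasible & (p_best <= 0)
  if (any(lossy)) {
    i_p <- max.col(Pmask, ties.method = "first")
    tau_p <- pmin(refine(P, i_p), tau_max)
    tau_star[lossy] <- tau_p[lossy]
  }
  tau_star[!feasible] <- 0

  # exact rates at the refined activity
  fs <- feeding_level(w, T_c, tau_star, params, food = food)
  Ps <- energy_gain(w, T_c, tau_star, params, food = food)
  Ms <- mortality_rate(w, tau_star, params)

  list(
    T = T_c, food = food, w = w, feasible_at = feasible,
    tau_star = approxfun(w, tau_star, rule = 2),
    tau_max = approxfun(w, tau_max, rule = 2),
    P = approxfun(w, Ps, rule = 2),
    M = approxfun(w, Ms, rule = 2),
    f = approxfun(w, fs, rule = 2),
    feasible = approxfun(w, as.numeric(feasible), method = "constant",
                         rule = 2)
  )
}

# Internal: largest weight at which any activity yields P > 0 (the
# energy-limited asymptote). Returns Inf if no such bound below `cap`.
energy_asymptote <- function(params, T_c, food = 1, cap = 1e7) {
  tr <- params$traits
  cT <- arrhenius_factor(T_c, params$thermal)
  tau <- seq(0, 1, length.out = 513)
  pmax_w <- function(w) {
    enc <- food * tr$gamma_theta * w^tr$p * tau
    cmax <- tr$h * cT * w^tr$q
    f <- enc / (enc + cmax)
    max((1 - tr$beta - tr$phi_e) * f * cmax - cT * tr$k * w^tr$n -
          tau * cT * tr$k_a * w)
  }
  w_grid <- exp(seq(log(params$sim$w_floor), log(cap), length.out = 160))
  vals <- vapply(w_grid, pmax_w, numeric(1))
  pos <- vals > 0
  if (!any(pos)) return(w_grid[1])
  last_pos <- max(which(pos))
  if (last_pos == length(w_grid)) return(Inf)
  uniroot(pmax_w, c(w_grid[last_pos], w_grid[last_pos + 1]), tol = 1e-6)$root
}
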
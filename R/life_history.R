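#' Allocation to reproduction along the maturation reaction norm
#'
#' A logistic share of surplus energy routed to reproduction,
#' \deqn{\psi(w, t) = \frac{1}{1 + e^{-c_{mrn}(w - (w^* + s\,t))}},}
#' equal to 0.5 at the reaction-norm midpoint. With the default flat norm
#' (`slope = 0`) allocation depends on size only; a non-zero slope shifts
#' the midpoint linearly with age.
#'
#' @param w Body weight (g), vectorized.
#' @param mrn An [mrn_params()] block (or `fish_params` bundle).
#' @param age Age in years (used only with a sloped norm).
#' @return Allocation fraction in `[0, 1]`.
#' @export
allocation <- function(w, mrn, age = 0) {
  if (inherits(mrn, "fish_params")) mrn <- mrn$mrn
  if (is.na(mrn$w_star)) {
    stop("`w_star` is NA: calibrate the reaction norm first ",
         "(see calibrate_wstar()) or set it explicitly", call. = FALSE)
  }
  mid <- mrn$w_star + mrn$slope * age
  1 / (1 + exp(-mrn$c_mrn * (w - mid)))
}

# Internal: integrate growth, survival and reproductive output on a
# prebuilt activity cache. States: weight w, cumulative hazard H, and
# accumulated reproductive output R (survival-weighted allocated energy,
# with negative contributions clipped -- starving fish do not unproduce
# offspring, though they may shrink down to the weight floor).
grow_on_cache <- function(cache, params, w_star, t_horizon, w0,
                          times = NULL, rtol = NULL) {
  mrn <- params$mrn
  mrn$w_star <- w_star
  w_floor <- params$sim$w_floor
  rtol <- rtol %||% params$sim$ode_rtol
  times <- times %||% seq(0, t_horizon, length.out = 201)
  psi_fun <- function(w, t) {
    1 / (1 + exp(-mrn$c_mrn * (w - (mrn$w_star + mrn$slope * t))))
  }
  rhs <- function(t, y, parms) {
    w <- max(y[1], w_floor)
    P <- cache$P(w)
    psi <- psi_fun(w, t)
    dw <- (1 - psi) * P
    if (y[1] <= w_floor && dw < 0) dw <- 0
    dH <- cache$M(w)
    dR <- psi * max(P, 0) * exp(-y[2])
    list(c(dw, dH, dR))
  }
  sol <- deSolve::lsoda(y = c(w = w0, H = 0, R = 0), times = times,
                        func = rhs, parms = NULL, rtol = rtol,
                        atol = c(1e-8 * max(w0, 1), 1e-10, 1e-12))
  sol <- as.data.frame(sol)
  w <- pmax(sol$w, w_floor)
  tibble(
    t = sol$time, w = w,
    psi = psi_fun(w, sol$time),
    tau_star = cache$tau_star(w),
    M = cache$M(w),
    S = exp(-sol$H),
    R0_cum = sol$R
  )
}

#' Simulate growth through ontogeny
#'
#' Integrates \eqn{dw/dt = (1 - \psi(w,t))\,P(w, T, \tau^*(w))} from the
#' initial weight, with the activity fraction re-optimized (via a cached
#' weight grid) at every evaluation, survival accumulated as
#' \eqn{S(t) = e^{-\int_0^t M\,ds}}, and reproductive output accumulated
#' alongside. Starving fish may shrink but not below the configured weight
#' floor. If resting metabolism already exceeds oxygen supply at the initial
#' weight the trajectory is degenerate (flagged; immediate death).
#'
#' @param params A `fish_params` bundle.
#' @param T_c Temperature (degrees C); must not exceed the lethal `T_max`.
#' @param food Multiplier on `gamma_theta`.
#' @param w_star Reaction-norm midpoint override (g); defaults to the
#'   bundle's calibrated value.
#' @param t_horizon,w0 Override the bundle's horizon / initial weight.
#' @param times Optional output time grid (years).
#' @return A tibble of class `fin_trajectory` with columns `t`, `w`, `L`
#'   (length, via the cubic condition factor), `tau_star`, `psi`, `M`, `S`
#'   and `R0_cum`, plus attributes `R0`, `w_inf`, `maturation_age`,
#'   `degenerate`, `T`, `food`, `w_star`.
#' @examples
#' \donttest{
#' p <- fish_preset("slow_dome")
#' g <- grow(p, T_c = 15, w_star = 250)
#' glance(g)
#' }
#' @export
grow <- function(params, T_c, food = 1, w_star = NULL, t_horizon = NULL,
                 w0 = NULL, times = NULL) {
  validate_params(params)
  th <- params$thermal
  if (T_c > th$T_max) {
    stop("temperature above the lethal temperature T_max = ", th$T_max,
         call. = FALSE)
  }
  w_star <- w_star %||% params$mrn$w_star
  if (is.na(w_star)) {
    stop("`w_star` is NA: run calibrate_wstar() first or pass `w_star`",
         call. = FALSE)
  }
  t_horizon <- t_horizon %||% params$sim$t_horizon
  w0 <- w0 %||% params$sim$w0
  cf <- params$sim$condition_factor

  w_inf_energy <- energy_asymptote(params, T_c, food = food)
  alloc_bound <- w_star + max(0, params$mrn$slope) * t_horizon +
    50 / params$mrn$c_mrn
  w_hi <- max(2 * w0, min(w_inf_energy * 1.05, alloc_bound))
  cache <- activity_cache(params, T_c, food = food, w_hi = w_hi)

  if (cache$feasible(w0) < 1) {
    out <- tibble(t = 0, w = w0, L = (w0 / cf)^(1 / 3),
                  tau_star = 0, psi = allocation_of(w0, 0, params, w_star),
                  M = Inf, S = 0, R0_cum = 0)
    return(new_trajectory(out, params, T_c, food, w_star, degenerate = TRUE))
  }

  traj <- grow_on_cache(cache, params, w_star, t_horizon, w0, times = times)
  traj$L <- (traj$w / cf)^(1 / 3)
  traj <- traj[, c("t", "w", "L", "tau_star", "psi", "M", "S", "R0_cum")]
  new_trajectory(traj, params, T_c, food, w_star, degenerate = FALSE)
}

allocation_of <- function(w, t, params, w_star) {
  mrn <- params$mrn
  1 / (1 + exp(-mrn$c_mrn * (w - (w_star + mrn$slope * t))))
}

new_trajectory <- function(df, params, T_c, food, w_star, degenerate) {
  mat_age <- NA_real_
  if (!degenerate && any(df$psi >= 0.5)) {
    i <- which(df$psi >= 0.5)[1]
    if (i == 1) {
      mat_age <- df$t[1]
    } else {
      # linear interpolation of the 0.5 crossing
      p0 <- df$psi[i - 1]; p1 <- df$psi[i]
      mat_age <- df$t[i - 1] + (0.5 - p0) / (p1 - p0) * (df$t[i] - df$t[i - 1])
    }
  }
  structure(
    df,
    class = c("fin_trajectory", class(tibble())),
    params = params, T = T_c, food = food, w_star = w_star,
    degenerate = degenerate,
    R0 = if (degenerate) 0 else df$R0_cum[nrow(df)],
    w_inf = df$w[nrow(df)],
    maturation_age = mat_age
  )
}

#' @export
print.fin_trajectory <- function(x, ...) {
  cat("<fin_trajectory> T =", attr(x, "T"), "C, food x", attr(x, "food"),
      ", w* =", format(attr(x, "w_star"), digits = 4), "g",
      if (attr(x, "degenerate")) " [degenerate: oxygen-infeasible]" else "",
      "\n")
  NextMethod()
}

#' @rdname grow
#' @param x A `fin_trajectory`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fin_trajectory <- function(x, ...) {
  as_tibble(x)
}

#' @rdname grow
#' @exportS3Method generics::glance
glance.fin_trajectory <- function(x, ...) {
  n <- nrow(x)
  tibble(
    T = attr(x, "T"), food = attr(x, "food"),
    w_star = attr(x, "w_star"),
    w_inf = attr(x, "w_inf"),
    L_inf = x$L[n],
    maturation_age = attr(x, "maturation_age"),
    R0 = attr(x, "R0"),
    S_final = x$S[n],
    degenerate = attr(x, "degenerate")
  )
}

#' Lifetime reproductive output R0
#'
#' The fitness measure: survival-weighted reproductive energy integrated
#' over life,
#' \deqn{R_0(T) = \int_0^\infty \psi(w(t))\,P(w(t), T, \tau^*)\,
#'       S_{0\to t}\,dt,}
#' accumulated along the growth trajectory (negative instantaneous
#' contributions are clipped at zero). R0 is in units of allocated energy
#' (g), so only comparisons across temperatures or scenarios are meaningful.
#'
#' @inheritParams grow
#' @return A one-row tibble: `T`, `food`, `w_star_used`, `R0`, `degenerate`.
#' @export
lifetime_fitness <- function(params, T_c, food = 1, w_star = NULL,
                             t_horizon = NULL) {
  g <- grow(params, T_c, food = food, w_star = w_star,
            t_horizon = t_horizon)
  tibble(T = T_c, food = food, w_star_used = attr(g, "w_star"),
         R0 = attr(g, "R0"), degenerate = attr(g, "degenerate"))
}

#' Calibrate the maturation reaction norm intercept
#'
#' Finds the midpoint weight `w_star` maximizing lifetime reproductive
#' output at the reference temperature (the bundle's `T0`, 15 C in the
#' presets) and baseline food, by a log-spaced grid scan refined
#' with golden-section search. The intercept is then held fixed as
#' temperature changes, mimicking a reaction norm evolved under historical
#' conditions.
#'
#' @param params A `fish_params` bundle.
#' @param food Food multiplier used for calibration (baseline 1).
#' @param T_ref Calibration temperature; defaults to the reference
#'   temperature `params$thermal$T0`.
#' @param n_grid Number of log-spaced grid points of the initial scan.
#' @param w_cap Optional upper bound of the scan (g); by default the scan
#'   runs up to the energy-limited asymptotic weight (the largest weight at
#'   which any activity level yields a positive energy gain).
#' @return `params` with `mrn$w_star` set; details (scan table, refined
#'   optimum, convergence flag) in `attr(, "calibration")`.
#' @export
calibrate_wstar <- function(params, food = 1, T_ref = NULL, n_grid = 48,
                            w_cap = Inf) {
  validate_params(params)
  T_ref <- T_ref %||% params$thermal$T0
  tol <- params$sim$wstar_tol
  w0 <- params$sim$w0
  t_horizon <- params$sim$t_horizon

  upper <- min(w_cap, energy_asymptote(params, T_ref, food = food))
  if (!is.finite(upper)) upper <- 1e6
  if (upper <= 1) {
    stop("no positive energy gain above 1 g at the reference temperature; ",
         "cannot calibrate a reaction norm", call. = FALSE)
  }
  cache <- activity_cache(params, T_ref, food = food,
                          w_hi = upper * 1.1 + 100)
  if (cache$feasible(w0) < 1) {
    stop("oxygen-infeasible at the initial weight at the reference ",
         "temperature; cannot calibrate", call. = FALSE)
  }
  times <- seq(0, t_horizon, length.out = 101)
  R0_of <- function(ws) {
    tr <- grow_on_cache(cache, params, ws, t_horizon, w0, times = times)
    tr$R0_cum[nrow(tr)]
  }
  grid <- exp(seq(log(1), log(upper), length.out = n_grid))
  vals <- vapply(grid, R0_of, numeric(1))
  i <- which.max(vals)
  converged <- TRUE
  if (max(vals) <= 0 || diff(range(vals)) < 1e-12 * max(abs(vals))) {
    # flat objective: smallest maximizer, flagged
    converged <- FALSE
    w_star <- grid[which(vals == max(vals))[1]]
  } else {
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(n_grid, i + 1)]
    w_star <- exp(golden_max(function(lw) R0_of(exp(lw)), log(lo), log(hi),
                             tol = tol))
    if (R0_of(grid[i]) > R0_of(w_star)) w_star <- grid[i]
  }
  params$mrn$w_star <- w_star
  attr(params, "calibration") <- list(
    w_star = w_star, T_ref = T_ref, food = food, converged = converged,
    R0 = max(vals), scan = tibble(w_star = grid, R0 = vals)
  )
  params
}
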
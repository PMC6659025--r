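# Golden-section maximization on [lo, hi]; f must be unimodal there.
golden_max <- function(f, lo, hi, tol = 1e-8) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  # prefer the smaller end of the final bracket on ties (risk-averse)
  xs <- c(a, x1, x2, b)
  fs <- c(f(a), f1, f2, f(b))
  xs[which.max(fs)]
}

#' Maximum sustainable activity under the oxygen constraint
#'
#' The largest activity fraction for which the aerobic scope is
#' non-negative. Since oxygen demand is strictly increasing in tau, the
#' boundary is the unique root of `P_O2(tau) = 0` on `[0, 1]`; if even the
#' full activity budget is covered the maximum is 1, and if resting
#' metabolism already exceeds supply the state is infeasible (flagged, not
#' an error).
#'
#' @inheritParams feeding_level
#' @param tol Root-finding tolerance on tau.
#' @return A list with `tau_max` and logical `feasible`.
#' @export
max_activity <- function(w, T_c, params, food = 1, tol = 1e-10) {
  scope <- function(tau) {
    oxygen_budget(w, T_c, tau, params, food = food)$P_O2
  }
  s0 <- scope(0)
  if (s0 < 0) return(list(tau_max = 0, feasible = FALSE))
  if (scope(1) >= 0) return(list(tau_max = 1, feasible = TRUE))
  root <- uniroot(scope, interval = c(0, 1), tol = tol)$root
  list(tau_max = root, feasible = TRUE)
}

#' Optimal activity by Gilliam's rule under the oxygen constraint
#'
#' Fish choose the activity fraction maximizing net energy gain over
#' mortality, \eqn{\tau^* = \mathrm{argmax}_\tau\, P(w,T,\tau)/M(w,\tau)},
#' capped at the oxygen-feasible maximum [max_activity()]. The unconstrained
#' optimum is located by a dense grid scan refined by golden-section search;
#' ties resolve to the smallest tau. When no feasible activity yields a
#' positive energy gain the ratio rewards dying fast, so the realized
#' activity instead minimizes the energy loss (argmax of P over the feasible
#' range), which is continuous with the P > 0 regime.
#'
#' @inheritParams feeding_level
#' @param n_grid Number of grid points of the initial scan (default from the
#'   bundle's `sim$tau_grid_n`).
#' @param tol Tolerance of the golden-section refinement.
#' @return A one-row tibble: `w`, `T`, `tau_opt` (unconstrained optimum),
#'   `tau_max`, `tau_star` (realized), `limited_by_oxygen`, `feasible`,
#'   `objective` (P/M at `tau_star`), `P`, `M`, `P_O2`.
#' @examples
#' optimal_activity(10, 15, fish_preset("slow_dome"))
#' @export
optimal_activity <- function(w, T_c, params, food = 1, n_grid = NULL,
                             tol = 1e-8) {
  n_grid <- n_grid %||%
    (if (inherits(params, "fish_params")) params$sim$tau_grid_n else 2001)
  ma <- max_activity(w, T_c, params, food = food)
  Pfun <- function(tau) energy_gain(w, T_c, tau, params, food = food)
  Gfun <- function(tau) Pfun(tau) / mortality_rate(w, tau, params)

  tau_grid <- seq(0, 1, length.out = n_grid)
  G <- Gfun(tau_grid)
  i <- which.max(G)
  lo <- tau_grid[max(1, i - 1)]
  hi <- tau_grid[min(n_grid, i + 1)]
  tau_opt <- if (hi > lo) golden_max(Gfun, lo, hi, tol = tol) else tau_grid[i]
  if (Gfun(tau_grid[i]) >= Gfun(tau_opt)) tau_opt <- tau_grid[i]

  if (!ma$feasible) {
    tau_star <- 0
  } else {
    feas <- tau_grid[tau_grid <= ma$tau_max]
    if (max(Pfun(feas)) > 0) {
      tau_star <- min(tau_opt, ma$tau_max)
    } else {
      # loss minimization: no feasible activity is profitable
      Pg <- Pfun(feas)
      j <- which.max(Pg)
      lo <- feas[max(1, j - 1)]
      hi <- min(feas[min(length(feas), j + 1)], ma$tau_max)
      tau_star <- if (hi > lo) golden_max(Pfun, lo, hi, tol = tol) else feas[j]
      if (Pfun(feas[j]) >= Pfun(tau_star)) tau_star <- feas[j]
    }
  }
  P <- Pfun(tau_star)
  M <- mortality_rate(w, tau_star, params)
  tibble(
    w = w, T = T_c, tau_opt = tau_opt, tau_max = ma$tau_max,
    tau_star = tau_star,
    limited_by_oxygen = tau_opt > ma$tau_max,
    feasible = ma$feasible,
    objective = P / M, P = P, M = M,
    P_O2 = oxygen_budget(w, T_c, tau_star, params, food = food)$P_O2
  )
}
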
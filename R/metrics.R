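#' Production efficiency
#'
#' Available energy relative to food consumption,
#' \eqn{P / (f\,h\,c(T)\,w^q)}. Algebraically bounded above by the
#' assimilated fraction \eqn{1 - \beta - \phi_e}; undefined (NA) when the
#' feeding level is zero.
#'
#' @inheritParams feeding_level
#' @return Dimensionless efficiency (NA where f = 0).
#' @export
production_efficiency <- function(w, T_c, tau, params, food = 1) {
  tr <- as_traits(params)
  f <- feeding_level(w, T_c, tau, params, food = food)
  cons <- f * tr$h * arrhenius_factor(T_c, params) * w^tr$q
  out <- energy_gain(w, T_c, tau, params, food = food) / cons
  out[f == 0] <- NA_real_
  out
}

#' Gilliam ratio P / (M w)
#'
#' The dimensionless short-sighted fitness proxy: net energy gain over
#' mortality, scaled by weight.
#'
#' @inheritParams feeding_level
#' @return Dimensionless ratio (sign follows P).
#' @export
gilliam_ratio <- function(w, T_c, tau, params, food = 1) {
  energy_gain(w, T_c, tau, params, food = food) /
    (mortality_rate(w, tau, params) * w)
}

#' Factorial scenario sweep
#'
#' Evaluates the performance metrics of the standard scenario analyses
#' over strategies x MOS regimes x temperatures x food levels x diagnostic
#' sizes: realized activity, feeding level, net energy gain, mortality, the
#' Gilliam ratio, production efficiency and the oxygen-limitation flag, plus
#' (optionally) asymptotic length and relative lifetime fitness per
#' environment. Within-group columns `*_rel` normalize each metric to its
#' maximum over temperatures, matching the figure panels' scope
#' (strategy x MOS regime x food, and size where applicable).
#'
#' @param strategies Character subset of `c("slow", "fast")`.
#' @param mos_regimes Character subset of `c("dome", "nodome")`.
#' @param T_grid Temperatures (degrees C); defaults to the preset grid.
#' @param food_multipliers Food multipliers; defaults to 2/3, 1, 4/3.
#' @param sizes Diagnostic weights in g (default 1.25, 10, 80).
#' @param include_life_history Also compute `L_inf`, `R0` and `R0_relative`
#'   per (strategy, regime, T, food): requires one reaction-norm calibration
#'   per strategy x regime and one growth integration per cell, so it
#'   dominates the runtime. Default TRUE.
#' @param params_fn Function mapping a preset name to a `fish_params`
#'   bundle, by default [fish_preset()]; override to sweep modified bundles.
#' @return A `scenario_result` tibble; deterministic for fixed inputs.
#' @export
run_sweep <- function(strategies = c("slow", "fast"),
                      mos_regimes = c("dome", "nodome"),
                      T_grid = NULL,
                      food_multipliers = NULL,
                      sizes = c(1.25, 10, 80),
                      include_life_history = TRUE,
                      params_fn = fish_preset) {
  strategies <- match.arg(strategies, c("slow", "fast"), several.ok = TRUE)
  mos_regimes <- match.arg(mos_regimes, c("dome", "nodome"),
                           several.ok = TRUE)
  groups <- tidyr::expand_grid(strategy = strategies,
                               mos_regime = mos_regimes)
  res <- purrr::pmap(groups, function(strategy, mos_regime) {
    params <- params_fn(paste(strategy, mos_regime, sep = "_"))
    Ts <- T_grid %||% params$sim$T_grid
    foods <- food_multipliers %||% params$sim$food_multipliers
    lh <- NULL
    if (include_life_history) {
      params <- calibrate_wstar(params)
      lh <- tidyr::expand_grid(T = Ts, food_multiplier = foods)
      lh_rows <- purrr::pmap(lh, function(T, food_multiplier) {
        g <- grow(params, T_c = T, food = food_multiplier)
        tibble(L_inf = glance(g)$L_inf, R0 = attr(g, "R0"))
      })
      lh <- dplyr::bind_cols(lh, dplyr::bind_rows(lh_rows))
      lh <- dplyr::mutate(
        dplyr::group_by(lh, .data$food_multiplier),
        R0_relative = if (max(.data$R0) > 0) .data$R0 / max(.data$R0) else 0)
      lh <- dplyr::ungroup(lh)
    }
    cells <- tidyr::expand_grid(T = Ts, food_multiplier = foods, w = sizes)
    act <- purrr::pmap(cells, function(T, food_multiplier, w) {
      a <- optimal_activity(w, T, params, food = food_multiplier)
      tibble(
        tau_star = a$tau_star, tau_max = a$tau_max,
        limited_by_oxygen = a$limited_by_oxygen, feasible = a$feasible,
        f = feeding_level(w, T, a$tau_star, params, food = food_multiplier),
        P = a$P, M = a$M,
        P_over_Mw = a$P / (a$M * w),
        efficiency = production_efficiency(w, T, a$tau_star, params,
                                           food = food_multiplier)
      )
    })
    out <- dplyr::bind_cols(
      tibble(strategy = strategy, mos_regime = mos_regime)[
        rep(1, nrow(cells)), ],
      cells, dplyr::bind_rows(act))
    if (!is.null(lh)) {
      out <- dplyr::left_join(out, lh, by = c("T", "food_multiplier"))
    }
    out
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$strategy, .data$mos_regime,
                    .data$food_multiplier, .data$w),
    P_rel = .data$P / max(abs(.data$P)),
    M_rel = .data$M / max(.data$M),
    PM_rel = .data$P_over_Mw / max(abs(.data$P_over_Mw)))
  out <- dplyr::ungroup(out)
  class(out) <- c("scenario_result", class(out))
  out
}

#' Write a scenario table as CSV with a reproducibility header
#'
#' Prepends `#`-commented lines recording the resolved parameter bundle(s)
#' so a result file is self-describing, then the plain CSV table.
#'
#' @param df A tibble (e.g. from [run_sweep()] or [tidy()]).
#' @param path Output path.
#' @param params Optional `fish_params` bundle (or list of bundles) to
#'   record in the header.
#' @return `path`, invisibly.
#' @export
write_scenario_csv <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(paste0("# finscope ",
                     as.character(utils::packageVersion("finscope"))))
  if (!is.null(params)) {
    if (inherits(params, "fish_params")) params <- list(params)
    for (p in params) {
      for (block in c("traits", "thermal", "mrn")) {
        vals <- paste(names(p[[block]]), unlist(lapply(p[[block]], format)),
                      sep = "=", collapse = " ")
        label <- if (is.na(p$preset)) "custom" else p$preset
        header <- c(header, paste0("# ", label, " ", block, ": ", vals))
      }
    }
  }
  writeLines(header, con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(path)
}
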
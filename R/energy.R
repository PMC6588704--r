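# Kinetic model of antagonistic lipid / carbohydrate metabolism.
#   dx/dt = -beta1 x + alpha1/(1 + y^n1) - alpha3/(1 + y^n3)
#   dy/dt = -beta2 y + alpha2/(1 + x^n2)        (variant "corrected")
#   dy/dt = -beta2 x + alpha2/(1 + x^n2)        (variant "as_printed")
# x = acyl-CoA, y = carbohydrate; ATP output z = 2.25 x + y because lipids
# yield ~2.25x the energy of the same quantity of carbohydrate.

LIPID_ENERGY_COEF <- 2.25

#' Kinetic parameters of the lipid/carbohydrate fuel model
#'
#' Defaults follow the published simulation design: consumption rates
#' `beta1 = beta2 = 1`, Hill coefficients 1, carbohydrate-pathway activity
#' `alpha2 = 5`; `alpha1` (ATGL lipid-hydrolysis activity) and `alpha3`
#' (ACOT7 acyl-CoA hydrolysis activity) are the biological dials. The
#' carbohydrate equation as printed in the source model couples y's
#' consumption to x (`variant = "as_printed"`); the default `"corrected"`
#' form uses `-beta2 * y`, which restores a self-limiting carbohydrate pool
#' and is consistent with the narrative that impairing lipid use promotes
#' carbohydrate use.
#'
#' @param alpha1 ATGL hydrolytic activity (lipid influx to acyl-CoA).
#' @param alpha3 ACOT7 hydrolytic activity (acyl-CoA drain).
#' @param alpha2 Carbohydrate-pathway activity.
#' @param beta1,beta2 Consumption rates of x and y (per unit time).
#' @param n1,n2,n3 Hill coefficients (>= 1).
#' @param variant `"corrected"` (default) or `"as_printed"`.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha1, alpha3, alpha2 = 5, beta1 = 1, beta2 = 1,
                           n1 = 1, n2 = 1, n3 = 1,
                           variant = c("corrected", "as_printed")) {
  variant <- match.arg(variant)
  vals <- c(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            beta1 = beta1, beta2 = beta2)
  if (any(vals < 0)) {
    abort("rates and activities must be non-negative",
          class = "convflight_domain_error")
  }
  if (any(c(n1, n2, n3) < 1)) {
    abort("Hill coefficients must be >= 1", class = "convflight_domain_error")
  }
  structure(as.list(c(vals, n1 = n1, n2 = n2, n3 = n3)),
            variant = variant, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>", paste(names(x), unlist(x), sep = "=", collapse = " "),
      "| variant:", attr(x, "variant"), "\n")
  invisible(x)
}

fuel_derivs <- function(t, state, p) {
  x <- max(state[1], 0); y <- max(state[2], 0)
  dx <- -p$beta1 * x + p$alpha1 / (1 + y^p$n1) - p$alpha3 / (1 + y^p$n3)
  dy <- if (attr(p, "variant") == "corrected") {
    -p$beta2 * y + p$alpha2 / (1 + x^p$n2)
  } else {
    -p$beta2 * x + p$alpha2 / (1 + x^p$n2)
  }
  if (state[1] <= 0 && dx < 0) dx <- 0
  if (state[2] <= 0 && dy < 0) dy <- 0
  list(c(dx, dy))
}

#' Integrate the fuel model
#'
#' Solves the two-variable kinetic system with a fixed fine-step
#' Runge-Kutta (deSolve's classical `rk4`, internal step `h`), which copes
#' with the derivative discontinuity introduced by clamping concentrations
#' at zero; fixed points of the scheme coincide exactly with the zeros of
#' the vector field, so terminal states are limited only by integration
#' time, not step size.
#'
#' @param params A [kinetic_params()] object.
#' @param init Named numeric `c(x = , y = )` initial concentrations
#'   (default both 0).
#' @param t_end End time (> 0).
#' @param dt Output time step.
#' @param h Internal integration step (default `min(dt, 0.01)`).
#' @return A tibble of class `fuel_trajectory` with columns `t`, `x`, `y`,
#'   `z` (ATP output `2.25 x + y`).
#' @export
integrate_fuel <- function(params, init = c(x = 0, y = 0), t_end = 50,
                           dt = 0.1, h = min(dt, 0.01)) {
  stopifnot(inherits(params, "kinetic_params"), t_end > 0)
  if (any(init < 0)) abort("initial state must be non-negative",
                           class = "convflight_domain_error")
  times <- seq(0, t_end, by = h)
  sol <- deSolve::ode(y = c(x = init[["x"]], y = init[["y"]]),
                      times = times, func = fuel_derivs, parms = params,
                      method = "rk4")
  out <- as_tibble(as.data.frame(sol)) |>
    dplyr::rename(t = "time") |>
    filter(abs(.data$t / dt - round(.data$t / dt)) < 1e-9) |>
    mutate(x = pmax(.data$x, 0), y = pmax(.data$y, 0),
           z = LIPID_ENERGY_COEF * .data$x + .data$y)
  class(out) <- c("fuel_trajectory", class(out))
  out
}

#' Plot a fuel-model trajectory
#' @param object A `fuel_trajectory`.
#' @param ... Unused.
#' @return A ggplot of x, y and z against time.
#' @export
autoplot.fuel_trajectory <- function(object, ...) {
  object |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "variable") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$t, y = .data$value,
                                 colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration / ATP output")
}

#' Steady state of the fuel model
#'
#' For the corrected variant with all Hill coefficients 1 the fixed point is
#' available in closed form: with net lipid influx
#' `delta = max(alpha1 - alpha3, 0)`, `x*` is the positive root of
#' `beta1 beta2 x^2 + (beta1 beta2 + beta1 alpha2 - delta beta2) x - delta beta2 = 0`
#' and `y* = alpha2 / (beta2 (1 + x*))`. Otherwise (or on request) the state
#' is found by integrating until the derivative norm falls below `tol`.
#'
#' @param params A [kinetic_params()] object.
#' @param method `"auto"` (closed form when available), `"closed_form"` or
#'   `"numeric"`.
#' @param init Initial state for the numeric route.
#' @param tol Convergence tolerance on the derivative norm.
#' @param max_time Give up (with an error) past this integration time.
#' @return Named list `x`, `y`, `z`, `method`.
#' @export
steady_state <- function(params, method = c("auto", "closed_form", "numeric"),
                         init = c(x = 0, y = 0), tol = 1e-10,
                         max_time = 1e4) {
  method <- match.arg(method)
  closed_ok <- attr(params, "variant") == "corrected" &&
    all(c(params$n1, params$n2, params$n3) == 1) &&
    params$beta1 > 0 && params$beta2 > 0
  if (method == "closed_form" && !closed_ok) {
    abort("closed form requires the corrected variant with unit Hill coefficients")
  }
  if (method == "closed_form" || (method == "auto" && closed_ok)) {
    delta <- max(params$alpha1 - params$alpha3, 0)
    b1 <- params$beta1; b2 <- params$beta2; a2 <- params$alpha2
    A <- b1 * b2
    B <- b1 * b2 + b1 * a2 - delta * b2
    C <- -delta * b2
    x <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
    y <- a2 / (b2 * (1 + x))
    return(list(x = x, y = y, z = LIPID_ENERGY_COEF * x + y,
                method = "closed_form"))
  }
  state <- c(x = init[["x"]], y = init[["y"]])
  t_done <- 0
  chunk <- 50
  repeat {
    sol <- deSolve::ode(y = state, times = seq(0, chunk, by = 0.01),
                        func = fuel_derivs, parms = params, method = "rk4")
    state <- pmax(sol[nrow(sol), c("x", "y")], 0)
    t_done <- t_done + chunk
    dn <- sqrt(sum(unlist(fuel_derivs(0, state, params))^2))
    if (dn < tol) break
    if (t_done > max_time) {
      abort("steady state not reached within max_time",
            class = "convflight_convergence_error")
    }
  }
  list(x = unname(state["x"]), y = unname(state["y"]),
       z = LIPID_ENERGY_COEF * unname(state["x"]) + unname(state["y"]),
       method = "numeric")
}

#' ATP output and its fuel partition
#'
#' ATP output in carbohydrate-equivalent units: `z = 2.25 x + y`, lipids
#' contributing 2.25 energy units per concentration unit of acyl-CoA.
#'
#' @param x Acyl-CoA concentration (or a list with `x` and `y`, e.g. from
#'   [steady_state()]).
#' @param y Carbohydrate concentration.
#' @return Tibble: `z`, `lipid_energy`, `carb_energy`, `lipid_share`,
#'   `carb_share`.
#' @export
atp_output <- function(x, y = NULL) {
  if (is.list(x)) { y <- x$y; x <- x$x }
  if (any(x < 0) || any(y < 0)) abort("state must be non-negative",
                                      class = "convflight_domain_error")
  lip <- LIPID_ENERGY_COEF * x
  z <- lip + y
  tibble(z = z, lipid_energy = lip, carb_energy = y,
         lipid_share = ifelse(z > 0, lip / z, NA_real_),
         carb_share = ifelse(z > 0, y / z, NA_real_))
}

#' Sweep an enzymatic activity and locate the fuel-dominance switch
#'
#' Computes the steady state along a grid of `alpha1` (ATGL) or `alpha3`
#' (ACOT7) values, classifies the dominant fuel at each grid point, and
#' reports the grid value at which dominance first switches along the
#' traversal. By default dominance compares energy outputs
#' (`2.25 x*` vs `y*`); `criterion = "concentration"` compares `x*` vs `y*`
#' directly. Ties go to carbohydrate.
#'
#' @param params Baseline [kinetic_params()]; the swept entry is overwritten.
#' @param name `"alpha1"` or `"alpha3"`.
#' @param grid Monotone numeric grid, traversed in the given order.
#' @param criterion `"energy"` (default) or `"concentration"`.
#' @param method Steady-state method, see [steady_state()].
#' @return A tibble of class `fuel_sweep` with columns `param`, `value`,
#'   `x_star`, `y_star`, `lipid_energy`, `carb_energy`, `dominant`, and
#'   attributes `threshold` (grid value of the first dominance switch, `NA`
#'   if none) and `criterion`.
#' @export
sweep_activity <- function(params, name = c("alpha1", "alpha3"), grid,
                           criterion = c("energy", "concentration"),
                           method = "auto") {
  name <- match.arg(name)
  criterion <- match.arg(criterion)
  if (is.unsorted(grid) && is.unsorted(rev(grid))) {
    abort("grid must be monotone")
  }
  rows <- lapply(grid, function(v) {
    p <- params
    p[[name]] <- v
    ss <- steady_state(p, method = method)
    tibble(param = name, value = v, x_star = ss$x, y_star = ss$y,
           lipid_energy = LIPID_ENERGY_COEF * ss$x, carb_energy = ss$y)
  })
  out <- bind_rows(rows) |>
    mutate(dominant = ifelse(
      if (criterion == "energy") .data$lipid_energy > .data$carb_energy
      else .data$x_star > .data$y_star,
      "lipid", "carbohydrate"))
  switch_at <- which(out$dominant[-1] != out$dominant[-nrow(out)])
  threshold <- if (length(switch_at) > 0) out$value[switch_at[1] + 1] else NA_real_
  structure(out, threshold = threshold, criterion = criterion,
            class = c("fuel_sweep", class(out)))
}

#' @export
glance.fuel_sweep <- function(x, ...) {
  tibble(param = x$param[1], criterion = attr(x, "criterion"),
         threshold = attr(x, "threshold"),
         switched = !is.na(attr(x, "threshold")),
         n_grid = nrow(x))
}

#' Plot steady-state fuel energies along an activity sweep
#'
#' @param object A `fuel_sweep`.
#' @param ... Unused.
#' @return A ggplot of lipid and carbohydrate steady-state energies against
#'   the swept activity, with the dominance switch marked.
#' @export
autoplot.fuel_sweep <- function(object, ...) {
  thr <- attr(object, "threshold")
  p <- tidyr::pivot_longer(as_tibble(object),
                           c("lipid_energy", "carb_energy"),
                           names_to = "fuel", values_to = "energy") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$value, y = .data$energy,
                                 colour = .data$fuel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$param[1], y = "steady-state energy output")
  if (!is.na(thr)) p <- p + ggplot2::geom_vline(xintercept = thr, linetype = 2)
  p
}
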
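#' SIR model parameters
#'
#' Bundles the rate constants of the SIR model with logistic recruitment of
#' susceptibles. Rates are per month: `alpha` is the infection rate per
#' susceptible-infective contact pair (the chance that reading posts turns a
#' potential author into an active one), `beta` the recovery rate per
#' infective (posts losing their pull), `mu` the logistic growth rate of the
#' author pool, and `K` the carrying capacity — the largest author population
#' the topic can recruit.
#'
#' `alpha` and `beta` must lie in `[0, 1)`; `mu` is non-negative and may
#' exceed 1; `K` must be positive.
#'
#' @param alpha Infection rate per contact pair per month, in `[0, 1)`.
#' @param beta Recovery rate per month, in `[0, 1)`.
#' @param mu Recruitment (population growth) rate per month, `>= 0`.
#' @param K Carrying capacity in authors, `> 0`.
#' @return An object of class `sir_params` (a named list).
#' @examples
#' sir_params(alpha = 0.0045, beta = 0.6798, mu = 0.1226, K = 1384)
#' @export
sir_params <- function(alpha, beta, mu, K) {
  for (nm in c("alpha", "beta", "mu", "K")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1).")
  if (beta < 0 || beta >= 1) abort("`beta` must lie in [0, 1).")
  if (mu < 0) abort("`mu` must be non-negative.")
  if (K <= 0) abort("`K` must be positive.")
  structure(list(alpha = alpha, beta = beta, mu = mu, K = K),
            class = "sir_params")
}

#' @export
print.sir_params <- function(x, ...) {
  cat("<sir_params>  alpha =", x$alpha, " beta =", x$beta,
      " mu =", x$mu, " K =", x$K, "\n")
  invisible(x)
}

as_sir_params <- function(x) {
  if (inherits(x, "sir_params")) return(x)
  x <- as.list(x)
  sir_params(x$alpha, x$beta, x$mu, x$K)
}

#' Initial compartment sizes
#'
#' @param S0 Susceptible authors at time 0.
#' @param I0 Infective (actively posting) authors at time 0.
#' @param R0 Recovered (inactive past) authors at time 0.
#' @return An object of class `sir_init` (a named list).
#' @export
sir_init <- function(S0, I0 = 1, R0 = 0) {
  if (any(c(S0, I0, R0) < 0)) abort("initial compartments must be non-negative.")
  structure(list(S0 = S0, I0 = I0, R0 = R0), class = "sir_init")
}

as_sir_init <- function(x) {
  if (inherits(x, "sir_init")) return(x)
  x <- as.list(x)
  sir_init(x$S0, x$I0 %||% 1, x$R0 %||% 0)
}

#' Right-hand side of the SIR system with logistic recruitment
#'
#' Evaluates the instantaneous compartment derivatives
#' \deqn{dS/dt = \mu\,\frac{K - N}{K}\,N - \alpha S I,\quad
#'       dI/dt = \alpha S I - \beta I,\quad
#'       dR/dt = \beta I,}
#' with \eqn{N = S + I + R}. New users enter the susceptible pool at a
#' logistic rate that vanishes as the total population approaches the carrying
#' capacity `K`; with `mu = 0` the total population is conserved and the
#' system reduces to the classical closed SIR model.
#'
#' @param state Numeric vector `c(S, I, R)` (names optional).
#' @param params An [sir_params()] object or a list/vector with those fields.
#' @return Named numeric vector `c(dS, dI, dR)`.
#' @examples
#' sir_rhs(c(S = 100, I = 10, R = 0),
#'         sir_params(alpha = 0.01, beta = 0.5, mu = 0, K = 1000))
#' @export
sir_rhs <- function(state, params) {
  state <- as.numeric(state)
  if (length(state) != 3L || !all(is.finite(state))) {
    abort("`state` must be three finite numbers (S, I, R).")
  }
  p <- as_sir_params(params)
  S <- state[1]; I <- state[2]; R <- state[3]
  N <- S + I + R
  c(dS = p$mu * ((p$K - N) / p$K) * N - p$alpha * S * I,
    dI = p$alpha * S * I - p$beta * I,
    dR = p$beta * I)
}

#' Simulate the SIR trajectory on a monthly grid
#'
#' Integrates the model from `t = 0` to `t = horizon` with an adaptive
#' explicit Runge-Kutta scheme (deSolve's `ode45`, relative tolerance `1e-6`,
#' absolute `1e-9`) and reports compartment sizes at integer months. A
#' discrete Euler mode with a one-month step is available via
#' `method = "euler"` for comparison with discretised model variants; the
#' continuous integrator is the default.
#'
#' The exact solution never leaves the non-negative orthant, so tiny negative
#' excursions (above `-1e-6`) are integration noise and are clipped to zero;
#' larger ones signal integrator failure and abort with an error.
#'
#' @param params An [sir_params()] object.
#' @param init An [sir_init()] object (or list with `S0`, `I0`, `R0`).
#' @param horizon Number of months to simulate (`>= 1`).
#' @param method `"adaptive"` (default) or `"euler"`.
#' @return A tibble with columns `t`, `S`, `I`, `R`, `N`.
#' @examples
#' traj <- simulate_sir(sir_params(0.008, 0.7, 0.13, 1000),
#'                      sir_init(S0 = 100), horizon = 30)
#' head(traj)
#' @export
simulate_sir <- function(params, init, horizon,
                         method = c("adaptive", "euler")) {
  p <- as_sir_params(params)
  ini <- as_sir_init(init)
  method <- match.arg(method)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    abort("`horizon` must be a single number >= 1.")
  }
  times <- 0:horizon
  if (method == "euler") {
    m <- matrix(NA_real_, nrow = length(times), ncol = 3,
                dimnames = list(NULL, c("S", "I", "R")))
    y <- c(ini$S0, ini$I0, ini$R0)
    m[1, ] <- y
    for (i in seq_len(horizon)) {
      y <- y + sir_rhs(y, p)
      m[i + 1, ] <- y
    }
  } else {
    out <- tryCatch(
      deSolve::ode(
        y = c(S = ini$S0, I = ini$I0, R = ini$R0),
        times = times, func = "sir_derivs",
        parms = c(p$alpha, p$beta, p$mu, p$K),
        dllname = "sirtopics", initfunc = "sir_initmod",
        method = "ode45", rtol = 1e-6, atol = 1e-9
      ),
      warning = function(w) abort(paste0("integrator failure: ", conditionMessage(w)))
    )
    if (nrow(out) < length(times) || anyNA(out)) {
      abort(sprintf("integrator failure near t = %.3f (step-size collapse).",
                    max(out[stats::complete.cases(out), "time"], 0)))
    }
    m <- unclass(out)[, c("S", "I", "R"), drop = FALSE]
  }
  low <- min(m)
  if (low < -1e-6) {
    t_bad <- times[which(apply(m, 1, min) < -1e-6)[1]]
    abort(sprintf("integration produced a negative excursion (%.3g) at t = %s.",
                  low, t_bad))
  }
  m[m < 0] <- 0
  tibble::tibble(t = times, S = m[, "S"], I = m[, "I"], R = m[, "R"],
                 N = m[, "S"] + m[, "I"] + m[, "R"])
}

#' Effective reproduction ratio of a topic
#'
#' The average number of secondary "infections" (newly recruited authors) per
#' infective at the start of an outbreak: `alpha * S0 / beta`. By the
#' classical threshold principle a value above 1 predicts initial epidemic
#' growth of the author count, below 1 die-out.
#'
#' @param params An [sir_params()] object; `beta` must be positive.
#' @param S0 Initial susceptible pool.
#' @return A single number.
#' @examples
#' effective_reproduction_ratio(sir_params(0.0045, 0.6798, 0.1226, 1384), 163)
#' @export
effective_reproduction_ratio <- function(params, S0) {
  p <- as_sir_params(params)
  if (p$beta == 0) {
    abort("`beta` must be positive: the ratio is undefined at beta = 0.")
  }
  p$alpha * S0 / p$beta
}
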
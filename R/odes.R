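#' Mean-field plant right-hand side
#'
#' Deterministic approximation of the branching-plant model. New tips are
#' created in proportion to nodes, new nodes (each with a leaf) in
#' proportion to tips, and basal death is approximated as proportional to
#' tips (each tip marks a stem along which death can propagate):
#' `dT = lambda_B N`, `dN = dL = (lambda_G - lambda_D) T`.
#'
#' @param state Named numeric vector `c(T =, N =, L =)`: tips, live nodes,
#'   leaves.
#' @param params A [plant_params()] object.
#' @return Named numeric vector of derivatives, per day.
#' @examples
#' plant_rhs(c(T = 0, N = 10, L = 10), plant_params())
#' @export
plant_rhs <- function(state, params) {
  c(T = params$lambda_B * state[["N"]],
    N = (params$lambda_G - params$lambda_D) * state[["T"]],
    L = (params$lambda_G - params$lambda_D) * state[["T"]])
}

#' Mean-field beetle right-hand side
#'
#' Two-stage linear beetle model without food limitation:
#' `dJ = -r J + b A - mu_J J`, `dA = r J - mu_A A`.
#'
#' @param state Named numeric vector `c(J =, A =)`.
#' @param params A [beetle_params()] object.
#' @return Named numeric vector of derivatives, per day.
#' @export
beetle_rhs <- function(state, params) {
  J <- state[["J"]]; A <- state[["A"]]
  c(J = -params$r * J + params$b * A - params$mu_J * J,
    A = params$r * J - params$mu_A * A)
}

#' Asymptotic plant growth rate
#'
#' Dominant eigenvalue of the linear plant system
#' `d(T, N)/dt = [[0, lambda_B], [lambda_G - lambda_D, 0]] (T, N)`,
#' i.e. `sqrt(lambda_B (lambda_G - lambda_D))`. Computed from the system
#' matrix by a general eigenvalue routine.
#'
#' @param params A [plant_params()] object; requires `lambda_G > lambda_D`.
#' @return Growth rate, per day.
#' @examples
#' plant_growth_rate(plant_params()) # about 0.0159 per day
#' @export
plant_growth_rate <- function(params) {
  if (params$lambda_G <= params$lambda_D) {
    stop("no positive growth: lambda_G must exceed lambda_D", call. = FALSE)
  }
  m <- rbind(c(0, params$lambda_B),
             c(params$lambda_G - params$lambda_D, 0))
  max(Re(eigen(m, only.values = TRUE)$values))
}

#' Asymptotic beetle growth rate
#'
#' Dominant eigenvalue of the linear beetle system
#' `d(J, A)/dt = [[-r - mu_J, b], [r, -mu_A]] (J, A)`, the larger root of
#' `(lambda + r + mu_J)(lambda + mu_A) = r b`.
#'
#' @param params A [beetle_params()] object.
#' @return Growth (or decay) rate, per day.
#' @export
beetle_growth_rate <- function(params) {
  m <- rbind(c(-params$r - params$mu_J, params$b),
             c(params$r, -params$mu_A))
  max(Re(eigen(m, only.values = TRUE)$values))
}

holling <- function(x, alpha) x / (alpha + x)

# Tip growth coefficient G(L). The default ties tip growth to per-node
# leaf availability, G = lambda_G * L / N: with a full canopy (one leaf
# per live node, as in the beetle-free model where L == N) growth runs at
# lambda_G, and it falls in proportion as beetles strip leaves. Without
# beetles this reduces the coupled model exactly to the plant-only model.
# "constant" (G == lambda_G, no feedback) and "holling"
# (G = lambda_G * L/(alpha+L)) are alternative readings kept for
# comparison.
g_coefficient <- function(L, N, lambda_G, alpha, g_form) {
  switch(g_form,
    leaf_per_node = if (N > 0) lambda_G * max(L, 0) / N else 0,
    constant = lambda_G,
    holling = lambda_G * holling(max(L, 0), alpha),
    stop("unknown g_form: ", g_form, call. = FALSE)
  )
}

#' Coupled plant-beetle right-hand side
#'
#' The seven-variable interaction model. Plant: undamaged tips `T`, live
#' nodes `N`, undamaged leaves `L`, plus accumulated damaged leaves `LX`
#' and beetle-damaged tips `TX` (damaged tips no longer grow but still
#' propagate basal death, so node and leaf death is proportional to
#' `T + TX`). Beetles: juveniles `J` and adults `A`. Adults graze leaves at
#' `gamma_A`; juveniles graze tips, leaves or nodes at their species rate;
#' every grazing term saturates through the Holling type-II response
#' `x/(alpha + x)`. Node grazing destroys the node's leaf as well. The
#' juvenile-to-adult transition succeeds in proportion to leaf
#' availability, and adults suffer up to `mu_A2` extra mortality as leaves
#' vanish.
#'
#' @param state Named numeric vector with elements `T`, `N`, `L`, `LX`,
#'   `TX`, `J`, `A`.
#' @param plant A [plant_params()] object.
#' @param beetle A [beetle_params()] object.
#' @param inter An [interaction_params()] object.
#' @param g_form Tip-growth coefficient `G(L)`: `"leaf_per_node"` (default;
#'   `G = lambda_G L/N`, so growth runs at full rate with one leaf per node
#'   and falls as beetles strip the canopy), `"constant"`, or `"holling"`.
#' @param recruitment Denominator of the transition-success response:
#'   `"alpha"` (default, `L/(alpha+L)`, the shared Holling constant) or
#'   `"unit"` (`L/(1+L)`).
#' @param starvation Extra adult mortality form: `"saturating"` (default,
#'   `mu_A2 (1 - L/(alpha+L))`, vanishing when leaves are plentiful and
#'   approaching `mu_A2` as leaves run out) or `"offset"`
#'   (`mu_A2 (1 - 1/(alpha+L))`).
#' @param K Optional node carrying capacity: the tip-creation term becomes
#'   logistic, `lambda_B N (1 - N/K)`.
#' @return Named numeric vector of the seven derivatives, per day.
#' @examples
#' pr <- species_preset("leaf")
#' st <- c(T = 10, N = 100, L = 100, LX = 0, TX = 0, J = 0, A = 8)
#' coupled_rhs(st, pr$plant, pr$beetle, pr$inter)
#' @export
coupled_rhs <- function(state, plant, beetle, inter,
                        g_form = c("leaf_per_node", "constant", "holling"),
                        recruitment = c("alpha", "unit"),
                        starvation = c("saturating", "offset"),
                        K = NULL) {
  g_form <- match.arg(g_form)
  recruitment <- match.arg(recruitment)
  starvation <- match.arg(starvation)
  T <- state[["T"]]; N <- state[["N"]]; L <- state[["L"]]
  LX <- state[["LX"]]; TX <- state[["TX"]]
  J <- state[["J"]]; A <- state[["A"]]
  al <- inter$alpha

  HT <- holling(T, al); HN <- holling(N, al); HL <- holling(L, al)
  G <- g_coefficient(L, N, plant$lambda_G, al, g_form)
  branch <- plant$lambda_B * N * (if (is.null(K)) 1 else 1 - N / K)
  death <- plant$lambda_D * (T + TX)
  leaf_graze <- inter$gamma_A * A * HL + J * HL * (inter$gamma_JN + inter$gamma_JL)

  rec_frac <- if (recruitment == "alpha") HL else L / (1 + L)
  starve <- if (starvation == "saturating") {
    inter$mu_A2 * A * (1 - HL)
  } else {
    inter$mu_A2 * A * (1 - 1 / (al + L))
  }

  c(
    T = branch - inter$gamma_JT * J * HT,
    N = G * T - death - inter$gamma_JN * J * HN,
    L = G * T - death - leaf_graze,
    LX = death + leaf_graze,
    TX = inter$gamma_JT * J * HT,
    J = -beetle$r * J + beetle$b * A - beetle$mu_J * J,
    A = beetle$r * J * rec_frac - beetle$mu_A * A - starve
  )
}

# deSolve-compatible rhs closure for a model selector
rhs_function <- function(model, plant, beetle = NULL, inter = NULL,
                         g_form = "leaf_per_node", recruitment = "alpha",
                         starvation = "saturating", K = NULL) {
  switch(model,
    plant = function(t, y, p) list(unname(plant_rhs(y, plant))),
    beetle = function(t, y, p) list(unname(beetle_rhs(y, beetle))),
    coupled = function(t, y, p) {
      list(unname(coupled_rhs(y, plant, beetle, inter, g_form = g_form,
                              recruitment = recruitment,
                              starvation = starvation, K = K)))
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

default_init <- function(model) {
  switch(model,
    plant = c(T = 1, N = 2, L = 2),
    beetle = c(J = 0, A = 1),
    coupled = c(T = 10, N = 100, L = 100, LX = 0, TX = 0, J = 0, A = 0)
  )
}

#' Integrate a mean-field model
#'
#' Dense-output integration of the plant-only, beetle-only or coupled
#' model with `deSolve::lsoda`. States are clipped at zero only in the
#' returned table, never inside the right-hand side.
#'
#' @param model `"plant"`, `"beetle"` or `"coupled"`.
#' @param init Named initial state (`T, N, L` for plant; `J, A` for
#'   beetle; the seven coupled states otherwise).
#' @param t_end Horizon in days.
#' @param plant,beetle,inter Parameter objects as required by the model.
#' @param times Optional output time grid (defaults to steps of 1 day).
#' @param rtol,atol Solver tolerances.
#' @inheritParams coupled_rhs
#' @return A tibble with a `time` column and one column per state
#'   variable, with solver settings in attribute `"meta"`.
#' @examples
#' integrate_model("plant", c(T = 1, N = 2, L = 2), t_end = 10,
#'                 plant = plant_params())
#' @export
integrate_model <- function(model = c("coupled", "plant", "beetle"),
                            init = NULL, t_end, plant = plant_params(),
                            beetle = NULL, inter = NULL, times = NULL,
                            g_form = "leaf_per_node",
                            recruitment = "alpha",
                            starvation = "saturating",
                            K = NULL, rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  if (t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  if (is.null(init)) init <- default_init(model)
  if (is.null(times)) times <- seq(0, t_end, by = min(1, t_end))
  fn <- rhs_function(model, plant, beetle, inter, g_form = g_form,
                     recruitment = recruitment, starvation = starvation,
                     K = K)
  sol <- deSolve::ode(y = init, times = times, func = fn, parms = NULL,
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times)) {
    stop("integration failure at t = ", sol[nrow(sol), 1], call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  out[-1] <- lapply(out[-1], pmax, 0)
  attr(out, "meta") <- list(
    model = model, init = init, rtol = rtol, atol = atol,
    g_form = if (model == "coupled") g_form else NULL,
    recruitment = if (model == "coupled") recruitment else NULL,
    starvation = if (model == "coupled") starvation else NULL,
    K = K,
    params = list(plant = if (!is.null(plant)) unclass(plant),
                  beetle = if (!is.null(beetle)) unclass(beetle),
                  inter = if (!is.null(inter)) unclass(inter))
  )
  out
}
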
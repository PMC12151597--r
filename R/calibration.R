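#' Convert a lifespan to a Poisson rate
#'
#' A stage lasting `lifespan` weeks corresponds to an exponential exit
#' rate of `1 / (7 * lifespan)` per day. Used for the juvenile-to-adult
#' transition rate (juvenile lifespan) and adult mortality (adult
#' lifespan).
#'
#' @param lifespan Lifespan in weeks.
#' @return Rate, per day.
#' @examples
#' lifespan_to_rate(6)  # 0.0238: leaf-beetle juvenile stage
#' lifespan_to_rate(16) # 0.0089: adult mortality, all species
#' @export
lifespan_to_rate <- function(lifespan) {
  if (any(lifespan <= 0)) stop("`lifespan` must be > 0", call. = FALSE)
  1 / (7 * lifespan)
}

#' Convert lifetime fecundity to a daily birth rate
#'
#' @param eggs Eggs laid over the adult lifetime.
#' @param adult_lifespan Adult lifespan in weeks.
#' @return Birth rate, juveniles per adult per day.
#' @examples
#' fecundity_to_birth_rate(300, 16) # 2.6786
#' @export
fecundity_to_birth_rate <- function(eggs, adult_lifespan) {
  if (any(eggs < 0)) stop("`eggs` must be >= 0", call. = FALSE)
  if (any(adult_lifespan <= 0)) {
    stop("`adult_lifespan` must be > 0", call. = FALSE)
  }
  eggs / (7 * adult_lifespan)
}

#' Tip growth rate from an observed relative growth rate
#'
#' Inverts the plant-only dominant eigenvalue: given an observed
#' no-beetle relative growth rate `Lambda` (per day) and known branching
#' and basal death rates, returns the tip growth rate such that
#' `plant_growth_rate()` reproduces `Lambda`, i.e.
#' `lambda_G = Lambda^2 / lambda_B + lambda_D`.
#'
#' @param Lambda Observed relative (leaf-area) growth rate, per day.
#' @param lambda_B Branching rate, per day.
#' @param lambda_D Basal death rate, per day.
#' @return Tip growth rate `lambda_G`, per day.
#' @examples
#' fit_tip_growth_rate(0.016, 0.0027, 0.0014) # 0.0962
#' @export
fit_tip_growth_rate <- function(Lambda, lambda_B, lambda_D) {
  if (Lambda <= 0) stop("`Lambda` must be > 0", call. = FALSE)
  if (lambda_B <= 0) stop("`lambda_B` must be > 0", call. = FALSE)
  Lambda^2 / lambda_B + lambda_D
}

#' Juvenile mortality from a percentage population increase
#'
#' A glasshouse population with abundant food grows at the dominant
#' eigenvalue of the beetle-only model. Observing a total increase of
#' `pct_increase` percent over `horizon` weeks implies an eigenvalue
#' `lambda = log(1 + pct_increase/100) / (7 * horizon)`; this function
#' returns the unique juvenile mortality making `lambda` the dominant
#' eigenvalue given `r`, `b` and `mu_A`:
#' `mu_J = r b / (lambda + mu_A) - lambda - r`.
#'
#' @param pct_increase Population increase over the horizon, percent
#'   (e.g. 340 means the final population is 4.4 times the initial one).
#' @param horizon Observation horizon in weeks (default 24).
#' @param r,b,mu_A Remaining beetle rates, per day.
#' @return Juvenile mortality `mu_J`, per day.
#' @examples
#' fit_juvenile_mortality(340, 24, r = 1/42, b = 300/112, mu_A = 1/112)
#' @export
fit_juvenile_mortality <- function(pct_increase, horizon = 24, r, b, mu_A) {
  if (pct_increase <= -100) {
    stop("`pct_increase` must exceed -100", call. = FALSE)
  }
  lambda <- log(1 + pct_increase / 100) / (7 * horizon)
  mu_J <- r * b / (lambda + mu_A) - lambda - r
  if (mu_J <= 0) {
    stop("infeasible observation: implied juvenile mortality is not positive",
         call. = FALSE)
  }
  mu_J
}

#' Realised relative growth rate of leaves under grazing
#'
#' Integrates the coupled model and returns `log(L(w)/L(0)) / w` over a
#' window of `window` days (default eight weeks, the length of the
#' glasshouse trials the grazing rates are fitted to).
#'
#' @param plant,beetle,inter Parameter objects; `beetle` and `inter` may be
#'   `NULL` for a beetle-free run.
#' @param init Named 7-element initial state; defaults to the standard
#'   release scenario [release_init()] with `P0 = 100` nodes and `B0 = 10`
#'   adults.
#' @param window Fitting window in days (default 56).
#' @param ... Passed to [integrate_model()] (e.g. `g_form`).
#' @return Realised growth rate per day, or `-Inf` if the leaves are
#'   consumed within the window.
#' @export
realized_rgr <- function(plant, beetle = NULL, inter = NULL,
                         init = NULL, window = 56, ...) {
  if (is.null(beetle)) beetle <- beetle_params(0, 0, 0, 0)
  if (is.null(inter)) inter <- interaction_params(0, 0, 0, 0, alpha = 10, mu_A2 = 0)
  if (is.null(init)) init <- release_init(P0 = 100, B0 = 10)
  if (init[["L"]] <= 0) stop("initial leaf count must be > 0", call. = FALSE)
  sol <- integrate_model("coupled", init = init, t_end = window,
                         plant = plant, beetle = beetle, inter = inter,
                         times = c(0, window), ...)
  L_end <- sol$L[nrow(sol)]
  if (L_end <= 0) return(-Inf)
  log(L_end / init[["L"]]) / window
}

#' Fit grazing rates to an observed growth-rate reduction
#'
#' Recovers the species' grazing rate(s) by matching the model's realised
#' eight-week leaf growth rate to an observed target. For the leaf beetle
#' the juvenile and adult grazing rates are assumed equal and the common
#' value is fitted; for the tip and stem beetles the adult rate is held
#' fixed (it is shared across species) and the juvenile tip or node rate
#' is fitted. The root is found by Brent's method on a bracket
#' `[0, gamma_max]`; the realised growth rate is strictly decreasing in
#' the grazing rate over the bracket, so the root is unique.
#'
#' @param target_rgr Observed realised growth rate, per day; must lie at
#'   or below the beetle-free rate.
#' @param species `"leaf"`, `"tip"` or `"stem"`.
#' @param plant,beetle,inter Parameter objects holding all non-fitted
#'   rates (defaults: the species preset).
#' @param gamma_max Upper end of the search bracket, per day.
#' @param tol Absolute tolerance on the fitted rate.
#' @inheritParams realized_rgr
#' @return The fitted grazing rate, per day (for `"leaf"`, the common
#'   value assigned to both `gamma_A` and `gamma_JL`).
#' @export
fit_grazing_rate <- function(target_rgr, species, plant = NULL,
                             beetle = NULL, inter = NULL, init = NULL,
                             window = 56, gamma_max = 10, tol = 1e-8, ...) {
  preset <- species_preset(species)
  if (is.null(plant)) plant <- preset$plant
  if (is.null(beetle)) beetle <- preset$beetle
  if (is.null(inter)) inter <- preset$inter

  with_gamma <- function(gamma) {
    i <- inter
    if (species == "leaf") {
      i$gamma_A <- gamma; i$gamma_JL <- gamma
    } else if (species == "tip") {
      i$gamma_JT <- gamma
    } else {
      i$gamma_JN <- gamma
    }
    i
  }
  objective <- function(gamma) {
    r <- realized_rgr(plant, beetle, with_gamma(gamma), init = init,
                      window = window, ...)
    if (!is.finite(r)) r <- -1e6   # leaves consumed within the window
    r - target_rgr
  }
  f0 <- objective(0)
  if (f0 < -tol) {
    stop("unfittable target: exceeds the beetle-free growth rate",
         call. = FALSE)
  }
  if (f0 <= tol) return(0)
  if (objective(gamma_max) > 0) {
    stop("unfittable target: not reachable with gamma <= ", gamma_max,
         call. = FALSE)
  }
  stats::uniroot(objective, c(0, gamma_max), tol = tol)$root
}
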
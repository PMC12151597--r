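#' Initial state of a release scenario
#'
#' The standard experiment initial condition: a stand of `P0` live nodes
#' with one undamaged leaf per node, ten nodes per growing tip (so
#' `T0 = P0/10`, rounded to a whole tip and at least 1), no damaged
#' material, and a release of `B0` adult beetles with no juveniles.
#'
#' @param P0 Initial number of live nodes (= leaves).
#' @param B0 Adults released at time zero.
#' @return Named 7-element state vector `T, N, L, LX, TX, J, A`.
#' @export
release_init <- function(P0, B0 = 0) {
  if (P0 <= 0) stop("`P0` must be > 0", call. = FALSE)
  if (B0 < 0) stop("`B0` must be >= 0", call. = FALSE)
  c(T = max(1, round(P0 / 10)), N = P0, L = P0, LX = 0, TX = 0,
    J = 0, A = B0)
}

# integrate the coupled model with a terminal root at L = eps;
# returns the (possibly early) end time and final state
integrate_to_consumption <- function(init, horizon, plant, beetle, inter,
                                     eps = 1, g_form = "leaf_per_node",
                                     recruitment = "alpha",
                                     starvation = "saturating",
                                     K = NULL, rtol = 1e-8, atol = 1e-10) {
  fn <- rhs_function("coupled", plant, beetle, inter, g_form = g_form,
                     recruitment = recruitment, starvation = starvation,
                     K = K)
  sol <- deSolve::lsodar(y = init, times = c(0, horizon), func = fn,
                         parms = NULL, rtol = rtol, atol = atol,
                         rootfunc = function(t, y, p) y[["L"]] - eps)
  last <- sol[nrow(sol), ]
  t_end <- last[[1]]
  list(
    consumed = t_end < horizon || last[["L"]] <= eps + 1e-8,
    time = if (t_end < horizon || last[["L"]] <= eps + 1e-8) t_end else NA_real_,
    state = last[-1]
  )
}

#' Run a single release experiment
#'
#' Integrates the coupled model from [release_init()] over the horizon and
#' classifies the outcome. The release is classified `"consumed"` if the
#' undamaged leaf count falls below the extinction threshold `eps` at any
#' time before the horizon (leaf counts below one are biologically
#' extinct), in which case damage is 1 by convention. Otherwise the
#' outcome is `"coexist"` and damage is the relative leaf reduction at the
#' horizon against the same scenario without beetles,
#' `1 - L(horizon) / L_nobeetle(horizon)`.
#'
#' @param P0 Initial nodes (= leaves).
#' @param B0 Adults released.
#' @param species `"leaf"`, `"tip"` or `"stem"` (preset), or supply
#'   `plant`/`beetle`/`inter` directly.
#' @param horizon Days to run (default 1000).
#' @param eps Leaf-extinction threshold (default 1 leaf).
#' @param plant,beetle,inter Optional parameter overrides.
#' @param ... Passed to the integrator (`g_form`, `recruitment`,
#'   `starvation`, `K`, `rtol`, `atol`).
#' @return One-row tibble with columns `P0`, `B0`, `classification`,
#'   `damage`, `time_of_consumption`.
#' @examples
#' run_release(P0 = 100, B0 = 0, species = "leaf", horizon = 200)
#' @export
run_release <- function(P0, B0, species = "leaf", horizon = 1000, eps = 1,
                        plant = NULL, beetle = NULL, inter = NULL, ...) {
  preset <- species_preset(species)
  if (is.null(plant)) plant <- preset$plant
  if (is.null(beetle)) beetle <- preset$beetle
  if (is.null(inter)) inter <- preset$inter

  res <- integrate_to_consumption(release_init(P0, B0), horizon,
                                  plant, beetle, inter, eps = eps, ...)
  if (res$consumed) {
    damage <- 1
  } else {
    ref <- integrate_to_consumption(release_init(P0, 0), horizon,
                                    plant, beetle, inter, eps = eps, ...)
    damage <- 1 - res$state[["L"]] / ref$state[["L"]]
  }
  tibble::tibble(
    P0 = P0, B0 = B0,
    classification = if (res$consumed) "consumed" else "coexist",
    damage = damage,
    time_of_consumption = res$time
  )
}

#' Critical release size
#'
#' The smallest released adult population that consumes all leaves of a
#' stand of `P0` nodes within the horizon, found by exponential
#' bracketing followed by bisection. The consumed outcome is monotone in
#' `B0` (more beetles can only remove leaves faster), which the bisection
#' relies on; the returned bracket endpoints always satisfy
#' coexist-at-`B0*-1` / consumed-at-`B0*`.
#'
#' @inheritParams run_release
#' @param integer If `TRUE` (default) search whole beetles; otherwise
#'   refine the threshold to a real value with absolute tolerance `tol`.
#' @param cap Give up (with an error) if even `cap` beetles do not consume
#'   the stand.
#' @param tol Bisection tolerance for the continuous refinement.
#' @return The critical release size `B0*` (count of adults).
#' @examples
#' \donttest{
#' critical_release_size(P0 = 100, species = "stem")
#' }
#' @export
critical_release_size <- function(P0, species = "leaf", horizon = 1000,
                                  eps = 1, integer = TRUE, cap = 100 * P0,
                                  tol = 0.01, plant = NULL, beetle = NULL,
                                  inter = NULL, ...) {
  preset <- species_preset(species)
  if (is.null(plant)) plant <- preset$plant
  if (is.null(beetle)) beetle <- preset$beetle
  if (is.null(inter)) inter <- preset$inter

  consumed <- function(B0) {
    integrate_to_consumption(release_init(P0, B0), horizon, plant, beetle,
                             inter, eps = eps, ...)$consumed
  }
  hi <- 1
  while (!consumed(hi)) {
    hi <- hi * 2
    if (hi > cap) {
      stop("no threshold found: not consumed even at B0 = ", cap,
           call. = FALSE)
    }
  }
  lo <- if (hi == 1) 0 else hi / 2       # lo coexists (or is zero)
  if (integer) {
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (consumed(mid)) hi <- mid else lo <- mid
    }
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (consumed(mid)) hi <- mid else lo <- mid
    }
  }
  hi
}

#' Critical release size per 100 leaves
#'
#' The threshold release size scales close to linearly with stand size;
#' its slope is the field-relevant quantity "beetles per 100 plant
#' leaves". Evaluated by default on a large stand (`P0 = 10000`), where
#' the Holling constant is negligible against the counts and the
#' threshold-to-size ratio has converged.
#'
#' @inheritParams critical_release_size
#' @return Adults per 100 leaves needed to consume the stand.
#' @export
critical_release_per_100_leaves <- function(species, P0 = 10000, ...) {
  100 * critical_release_size(P0 = P0, species = species, ...) / P0
}

#' Leaf-damage map over release scenarios
#'
#' Damage (relative leaf reduction at the horizon) for every combination
#' of stand size and release size, as plotted in release-planning damage
#' maps. Optionally computes the critical release size for each stand
#' size (the threshold curve separating coexistence from consumption).
#'
#' @param P0_grid,B0_grid Numeric vectors of stand sizes and release
#'   sizes.
#' @inheritParams run_release
#' @param threshold Also compute the critical release size per `P0`
#'   column (stored in attribute `"threshold"`).
#' @return A long tibble with columns `P0`, `B0`, `damage`,
#'   `classification`.
#' @export
damage_map <- function(P0_grid, B0_grid, species = "leaf", horizon = 1000,
                       eps = 1, threshold = TRUE, ...) {
  if (!length(P0_grid) || !length(B0_grid)) {
    stop("grids must be nonempty", call. = FALSE)
  }
  out <- purrr::map_dfr(P0_grid, function(P0) {
    purrr::map_dfr(B0_grid, function(B0) {
      run_release(P0 = P0, B0 = B0, species = species, horizon = horizon,
                  eps = eps, ...)
    })
  })
  if (threshold) {
    attr(out, "threshold") <- tibble::tibble(
      P0 = P0_grid,
      B0_star = purrr::map_dbl(P0_grid, function(P0) {
        critical_release_size(P0 = P0, species = species, horizon = horizon,
                              eps = eps, ...)
      })
    )
  }
  attr(out, "species") <- species
  out
}

default_scaled_parameters <- function(species) {
  c("lambda_B", "lambda_G", "lambda_D", "r", "b", "mu_A", "mu_J",
    "gamma_A",
    switch(species, leaf = "gamma_JL", tip = "gamma_JT", stem = "gamma_JN"),
    "alpha", "mu_A2")
}

#' Monte Carlo parameter-sensitivity experiment
#'
#' Re-runs the critical-release-size computation `n_sims` times, each time
#' rescaling every listed parameter by an independent factor drawn from
#' U(0.5, 2), and records the minimum number of beetles per 100 leaves
#' needed to consume the stand. Simulations in which even `cap` beetles do
#' not consume the stand are recorded as censored (response `NA`).
#'
#' The scaling factors are drawn once from the master seed, row by row, so
#' row `i` is unchanged when `n_sims` grows.
#'
#' @param species `"leaf"`, `"tip"` or `"stem"`.
#' @param n_sims Number of simulations.
#' @param P0 Stand size (default 100).
#' @param seed Master seed for the scaling draws.
#' @param scaled Character vector of parameters to rescale; the default
#'   covers every demographic, grazing and food-limitation parameter of
#'   the species.
#' @param range Lower and upper bound of the uniform scaling distribution
#'   (default `c(0.5, 2)`; a degenerate `c(1, 1)` reproduces the unscaled
#'   threshold in every row).
#' @inheritParams critical_release_size
#' @return A tibble of class `"sensitivity_table"` with one column per
#'   scaling factor, plus `b0_per_100` and `censored`.
#' @export
sensitivity_mc <- function(species, n_sims = 5000, P0 = 100, seed = 1L,
                           scaled = default_scaled_parameters(species),
                           range = c(0.5, 2),
                           horizon = 1000, eps = 1, cap = 100 * P0, ...) {
  if (n_sims < 2 * length(scaled)) {
    stop("`n_sims` must be at least twice the number of scaled parameters",
         call. = FALSE)
  }
  preset <- species_preset(species)
  set.seed(seed)
  X <- matrix(stats::runif(n_sims * length(scaled), range[1], range[2]),
              nrow = n_sims, byrow = TRUE,
              dimnames = list(NULL, scaled))
  response <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    sc <- scale_preset(preset, X[i, ])
    b0 <- tryCatch(
      critical_release_size(P0 = P0, species = species, horizon = horizon,
                            eps = eps, cap = cap, plant = sc$plant,
                            beetle = sc$beetle, inter = sc$inter, ...),
      error = function(e) NA_real_
    )
    response[i] <- if (is.na(b0)) NA_real_ else 100 * b0 / P0
  }
  out <- tibble::as_tibble(as.data.frame(X))
  out$b0_per_100 <- response
  out$censored <- is.na(response)
  class(out) <- c("sensitivity_table", class(out))
  attr(out, "meta") <- list(species = species, P0 = P0, seed = seed,
                            horizon = horizon, eps = eps, cap = cap,
                            n_censored = sum(out$censored))
  out
}

#' Effect sizes of the sensitivity experiment
#'
#' Ordinary least squares of the per-100-leaves critical release size on
#' the parameter scaling factors (with intercept). Because every factor is
#' drawn from the same U(0.5, 2) range, the coefficients are directly
#' comparable effect sizes: a positive coefficient means increasing that
#' parameter raises the release size needed for control. Censored rows are
#' excluded (their count is reported by `glance()`).
#'
#' @param tbl A `"sensitivity_table"` from [sensitivity_mc()].
#' @return An object of class `"sensitivity_fit"`; use [tidy()] for the
#'   coefficient table and [glance()] for the fit summary.
#' @export
sensitivity_regression <- function(tbl) {
  stopifnot(inherits(tbl, "sensitivity_table") ||
              all(c("b0_per_100", "censored") %in% names(tbl)))
  predictors <- setdiff(names(tbl), c("b0_per_100", "censored"))
  usable <- tbl[!tbl$censored, , drop = FALSE]
  if (nrow(usable) == 0) {
    stop("degenerate design: all rows censored", call. = FALSE)
  }
  if (nrow(usable) < 2 * length(predictors)) {
    stop("too few usable rows (", nrow(usable), ") for ",
         length(predictors), " predictors", call. = FALSE)
  }
  dat <- as.data.frame(usable[, c(predictors, "b0_per_100")])
  fit <- stats::lm(b0_per_100 ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: aliased predictors ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(fit = fit, meta = attr(tbl, "meta"),
         n_censored = sum(tbl$censored), n_used = nrow(usable)),
    class = "sensitivity_fit"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sensitivity_fit <- function(x, ...) {
  sm <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @export
glance.sensitivity_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    nobs = x$n_used,
    n_censored = x$n_censored
  )
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat("<sensitivity_fit> critical release size ~ parameter scalings\n")
  if (!is.null(x$meta$species)) cat("species:", x$meta$species, "\n")
  cat("rows used:", x$n_used, " censored:", x$n_censored, "\n")
  print(tidy(x))
  invisible(x)
}
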
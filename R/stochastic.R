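#' Initial plant topology
#'
#' The seed plant: a dead basal node, two live unbranched nodes each
#' bearing a leaf, and a single growing tip at the distal end, connected in
#' a chain. All stochastic simulations start from this configuration.
#'
#' A plant topology is a list of parallel node vectors: `status` (0 =
#' live-unbranched, 1 = live-branched, 2 = dead), `leaf` (does the node
#' carry a leaf), `parent` (index of the node nearer the base, 0 for the
#' basal node), `dead_children` (running count of dead child nodes, used to
#' detect exposure to basal death), and `tip_at`, the attachment node of
#' each growing tip.
#'
#' @return A list of class `"plant_topology"`.
#' @examples
#' plant_counts(init_plant())
#' @export
init_plant <- function() {
  structure(
    list(
      status = c(2L, 0L, 0L),
      leaf = c(FALSE, TRUE, TRUE),
      parent = c(0L, 1L, 2L),
      dead_children = c(0L, 0L, 0L),
      tip_at = 3L
    ),
    class = "plant_topology"
  )
}

#' Count plant units
#'
#' @param plant A `"plant_topology"`.
#' @return A one-row tibble with columns `tips`, `live_nodes`, `leaves`,
#'   `dead_nodes`.
#' @export
plant_counts <- function(plant) {
  tibble::tibble(
    tips = length(plant$tip_at),
    live_nodes = sum(plant$status < 2L),
    leaves = sum(plant$leaf),
    dead_nodes = sum(plant$status == 2L)
  )
}

# Live nodes adjacent to at least one dead node (parent side or any dead
# child). The basal node is dead from the start, so exposure spreads
# outward from the base.
exposed_nodes <- function(plant) {
  live <- which(plant$status < 2L)
  if (!length(live)) return(integer(0))
  par <- plant$parent[live]
  par_dead <- par > 0L & plant$status[pmax(par, 1L)] == 2L
  live[par_dead | plant$dead_children[live] > 0L]
}

# One synchronous update. All Bernoulli draws are evaluated against the
# step-start state, then applied together; nodes created this step cannot
# act until the next step.
step_topology <- function(plant, p_branch, p_grow, p_die) {
  live <- which(plant$status < 2L)
  n_tip <- length(plant$tip_at)

  branching <- if (p_branch > 0 && length(live)) {
    live[stats::runif(length(live)) < p_branch]
  } else integer(0)
  growing <- if (p_grow > 0 && n_tip) {
    which(stats::runif(n_tip) < p_grow)
  } else integer(0)
  exposed <- if (p_die > 0) exposed_nodes(plant) else integer(0)
  dying <- if (length(exposed)) {
    exposed[stats::runif(length(exposed)) < p_die]
  } else integer(0)

  # branching: a new tip appears at the node; the node keeps its leaf and
  # is marked branched (nodes may branch more than once)
  if (length(branching)) {
    plant$tip_at <- c(plant$tip_at, branching)
    plant$status[branching] <- 1L
  }
  # tip growth: a new live leaf-bearing node is inserted at the tip's
  # position and the tip moves distally, so stems remain chains
  if (length(growing)) {
    n0 <- length(plant$status)
    new_idx <- n0 + seq_along(growing)
    plant$status <- c(plant$status, integer(length(growing)))
    plant$leaf <- c(plant$leaf, rep(TRUE, length(growing)))
    plant$parent <- c(plant$parent, plant$tip_at[growing])
    plant$dead_children <- c(plant$dead_children, integer(length(growing)))
    plant$tip_at[growing] <- new_idx
  }
  # basal death: the node dies and loses its leaf; its parent records a
  # dead child so that all neighbours of the dead node become exposed
  if (length(dying)) {
    plant$status[dying] <- 2L
    plant$leaf[dying] <- FALSE
    par <- plant$parent[dying]
    par <- par[par > 0L]
    if (length(par)) {
      plant$dead_children <- plant$dead_children +
        tabulate(par, nbins = length(plant$dead_children))
    }
  }
  plant
}

#' Advance a plant one time step
#'
#' Applies the three stochastic events over an interval `dt`: every live
#' node branches with probability `lambda_B * dt`, every tip grows with
#' probability `lambda_G * dt`, and every live node adjacent to a dead node
#' dies with probability `lambda_D * dt`. Draws are simultaneous against the
#' step-start state.
#'
#' @param plant A `"plant_topology"`.
#' @param params A [plant_params()] object.
#' @param dt Time step in days; each `lambda * dt` must lie in `[0, 1]`.
#' @return The updated `"plant_topology"`.
#' @export
plant_step <- function(plant, params, dt) {
  stopifnot(inherits(plant, "plant_topology"))
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  probs <- c(params$lambda_B, params$lambda_G, params$lambda_D) * dt
  if (any(probs > 1)) {
    stop("invalid step size: lambda * dt exceeds 1 (dt = ", dt, ")",
         call. = FALSE)
  }
  step_topology(plant, probs[1], probs[2], probs[3])
}

#' Simulate the stochastic plant model
#'
#' Repeated synchronous application of the three plant events from the
#' [init_plant()] configuration, with counts recorded at every step. The
#' simulation stops early (and the trajectory is padded with zeros) if no
#' live nodes and no tips remain.
#'
#' @param params A [plant_params()] object.
#' @param t_end Simulation horizon in days.
#' @param dt Time step in days (default 0.1).
#' @param seed Integer seed; fixed seed gives a bit-identical trajectory.
#' @return A tibble with columns `time`, `tips`, `live_nodes`, `leaves`,
#'   carrying the parameters, seed and time step as attribute `"meta"`.
#' @examples
#' traj <- simulate_plant(plant_params(), t_end = 50, seed = 1)
#' tail(traj)
#' @export
simulate_plant <- function(params, t_end, dt = 0.1, seed = NULL) {
  if (t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  probs <- c(params$lambda_B, params$lambda_G, params$lambda_D) * dt
  if (dt <= 0 || any(probs > 1)) {
    stop("invalid step size: lambda * dt exceeds 1 (dt = ", dt, ")",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  plant <- init_plant()
  n_step <- as.integer(round(t_end / dt))
  tips <- nodes <- leaves <- numeric(n_step + 1)
  tips[1] <- 1; nodes[1] <- 2; leaves[1] <- 2
  for (s in seq_len(n_step)) {
    plant <- step_topology(plant, probs[1], probs[2], probs[3])
    tips[s + 1] <- length(plant$tip_at)
    nodes[s + 1] <- sum(plant$status < 2L)
    leaves[s + 1] <- sum(plant$leaf)
    if (nodes[s + 1] == 0 && tips[s + 1] == 0) break
  }
  out <- tibble::tibble(
    time = seq(0, by = dt, length.out = n_step + 1),
    tips = tips, live_nodes = nodes, leaves = leaves
  )
  attr(out, "meta") <- list(params = unclass(params), dt = dt, seed = seed,
                            model = "stochastic_plant")
  out
}

#' Simulate an ensemble of stochastic plants
#'
#' @inheritParams simulate_plant
#' @param n_reps Number of independent replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it so that
#'   replicate `i` is reproducible and unchanged when `n_reps` grows.
#' @return A tibble with columns `rep`, `time`, `tips`, `live_nodes`,
#'   `leaves`.
#' @export
simulate_plant_ensemble <- function(params, n_reps, t_end, dt = 0.1,
                                    seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    traj <- simulate_plant(params, t_end = t_end, dt = dt, seed = seeds[i])
    dplyr::mutate(traj, rep = i, .before = 1)
  })
}

#' Summarise an ensemble over replicates
#'
#' @param ensemble Output of [simulate_plant_ensemble()].
#' @return A tibble with per-time mean and standard error of each count.
#' @export
summarise_ensemble <- function(ensemble) {
  ensemble |>
    tidyr::pivot_longer(c("tips", "live_nodes", "leaves"),
                        names_to = "variable", values_to = "count") |>
    dplyr::group_by(.data$time, .data$variable) |>
    dplyr::summarise(
      mean = mean(.data$count),
      se = stats::sd(.data$count) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Empirical exponential growth rate of a trajectory
#'
#' Least-squares slope of `log(count)` against time over a window; for a
#' population growing exponentially this estimates the asymptotic growth
#' rate (the dominant eigenvalue of the mean-field system).
#'
#' @param traj A trajectory tibble with a `time` column.
#' @param window Length-2 numeric, the closed time interval to fit over.
#' @param response Column to fit (default `"live_nodes"`).
#' @return Growth rate, per day.
#' @examples
#' tr <- tibble::tibble(time = 0:100, live_nodes = 5 * exp(0.016 * (0:100)))
#' estimate_growth_rate(tr, c(0, 100))
#' @export
estimate_growth_rate <- function(traj, window = range(traj$time),
                                 response = "live_nodes") {
  w <- traj$time >= window[1] & traj$time <= window[2]
  y <- traj[[response]][w]
  t <- traj$time[w]
  if (length(y) < 2) stop("window contains fewer than 2 points", call. = FALSE)
  if (any(y <= 0)) {
    stop("undefined growth rate: nonpositive counts in window", call. = FALSE)
  }
  ly <- log(y)
  sum((t - mean(t)) * (ly - mean(ly))) / sum((t - mean(t))^2)
}
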
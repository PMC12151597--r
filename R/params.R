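#' Plant demographic rates
#'
#' Rate constants of the branching-plant model. All rates are per-day
#' probabilities (interpreted as hazards in the mean-field limit): a node
#' branches to form a new tip at rate `lambda_B`, a tip grows a new
#' leaf-bearing node at rate `lambda_G`, and a live node adjacent to a dead
#' node dies at rate `lambda_D` (basal death, which propagates outward from
#' the dead basal node).
#'
#' @param lambda_B Branching rate, per node per day.
#' @param lambda_G Tip growth rate, per tip per day.
#' @param lambda_D Basal death rate, per exposed node per day.
#' @return A named list of class `"plant_params"`.
#' @examples
#' plant_params()
#' plant_growth_rate(plant_params())
#' @export
plant_params <- function(lambda_B = 0.0027, lambda_G = 0.0948,
                         lambda_D = 0.0014) {
  p <- list(lambda_B = lambda_B, lambda_G = lambda_G, lambda_D = lambda_D)
  check_rates(p)
  structure(p, class = "plant_params")
}

#' Beetle stage-structured rates
#'
#' Rates of the two-stage (juvenile/adult) beetle population model.
#' Juveniles become adults as a Poisson process with rate `r`; adults lay
#' eggs (new juveniles) at rate `b` throughout adult life; stage-specific
#' mortalities are `mu_J` and `mu_A`.
#'
#' @param r Juvenile-to-adult transition rate, per day.
#' @param b Birth rate, juveniles per adult per day.
#' @param mu_A Adult mortality rate, per day.
#' @param mu_J Juvenile mortality rate, per day.
#' @return A named list of class `"beetle_params"`.
#' @export
beetle_params <- function(r, b, mu_A, mu_J) {
  p <- list(r = r, b = b, mu_A = mu_A, mu_J = mu_J)
  check_rates(p)
  structure(p, class = "beetle_params")
}

#' Plant-beetle interaction rates
#'
#' Grazing and food-limitation parameters of the coupled model. Adults of
#' all species graze leaves at `gamma_A`; juveniles graze tips
#' (`gamma_JT`), leaves (`gamma_JL`) or nodes (`gamma_JN`) depending on the
#' species (exactly one is nonzero per species preset). All grazing
#' saturates through a Holling type-II response `x / (alpha + x)` in the
#' grazed resource. `mu_A2` is the extra adult mortality incurred as leaves
#' run out.
#'
#' @param gamma_A Adult leaf-grazing rate, leaves per adult per day.
#' @param gamma_JT,gamma_JL,gamma_JN Juvenile grazing rates on tips, leaves
#'   and nodes respectively, per juvenile per day.
#' @param alpha Holling type-II half-saturation constant (resource units).
#' @param mu_A2 Maximum additional (starvation) adult mortality, per day.
#' @return A named list of class `"interaction_params"`.
#' @export
interaction_params <- function(gamma_A = 0.0661, gamma_JT = 0,
                               gamma_JL = 0, gamma_JN = 0,
                               alpha = 10, mu_A2 = 0.0089) {
  p <- list(gamma_A = gamma_A, gamma_JT = gamma_JT, gamma_JL = gamma_JL,
            gamma_JN = gamma_JN, alpha = alpha, mu_A2 = mu_A2)
  check_rates(p)
  structure(p, class = "interaction_params")
}

check_rates <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("parameter `", nm, "` must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' Named parameter presets
#'
#' The fitted parameterisation of the three biocontrol beetle species and
#' the plant. `"neolema_ogloblini"` (leaf beetle: juveniles graze leaves),
#' `"neolema_abbreviata"` (tip beetle: juveniles graze growing tips) and
#' `"lema_basicostata"` (stem beetle: juveniles bore stems, destroying
#' nodes and their leaves). The `"plant"` preset carries the plant rates
#' only.
#'
#' @return A named list; each species entry has elements `plant`, `beetle`,
#'   `inter` and `species`.
#' @export
preset_registry <- function() {
  plant <- plant_params(0.0027, 0.0948, 0.0014)
  list(
    plant = list(plant = plant),
    neolema_ogloblini = list(
      species = "leaf", plant = plant,
      beetle = beetle_params(r = 0.0238, b = 2.6786, mu_A = 0.0089, mu_J = 3.561),
      inter = interaction_params(gamma_A = 0.0661, gamma_JL = 0.0661,
                                 alpha = 10, mu_A2 = 0.0089)
    ),
    neolema_abbreviata = list(
      species = "tip", plant = plant,
      beetle = beetle_params(r = 0.0143, b = 2.6786, mu_A = 0.0089, mu_J = 2.267),
      inter = interaction_params(gamma_A = 0.0661, gamma_JT = 0.0281,
                                 alpha = 10, mu_A2 = 0.0089)
    ),
    lema_basicostata = list(
      species = "stem", plant = plant,
      beetle = beetle_params(r = 0.0130, b = 1.3393, mu_A = 0.0089, mu_J = 0.991),
      inter = interaction_params(gamma_A = 0.0661, gamma_JN = 0.0112,
                                 alpha = 10, mu_A2 = 0.0089)
    )
  )
}

#' Look up a species preset
#'
#' @param species One of `"leaf"` (*Neolema ogloblini*), `"tip"`
#'   (*Neolema abbreviata*), `"stem"` (*Lema basicostata*), or a full
#'   preset name from [preset_registry()].
#' @return A preset list with elements `species`, `plant`, `beetle`, `inter`.
#' @examples
#' species_preset("stem")$beetle$b
#' @export
species_preset <- function(species) {
  reg <- preset_registry()
  key <- switch(species,
    leaf = "neolema_ogloblini",
    tip = "neolema_abbreviata",
    stem = "lema_basicostata",
    species
  )
  if (!key %in% names(reg) || key == "plant") {
    stop("unknown species preset: `", species, "`", call. = FALSE)
  }
  reg[[key]]
}

#' Rescale a preset by named multiplicative factors
#'
#' Used by the Monte Carlo sensitivity analysis: each factor multiplies the
#' matching rate wherever it occurs in the preset.
#'
#' @param preset A species preset (see [species_preset()]).
#' @param scaling Named numeric vector of multipliers, e.g.
#'   `c(lambda_G = 1.5, b = 0.7)`.
#' @return The rescaled preset.
#' @export
scale_preset <- function(preset, scaling) {
  stopifnot(is.numeric(scaling), !is.null(names(scaling)))
  for (part in c("plant", "beetle", "inter")) {
    hit <- intersect(names(scaling), names(preset[[part]]))
    for (nm in hit) {
      preset[[part]][[nm]] <- preset[[part]][[nm]] * unname(scaling[[nm]])
    }
  }
  unknown <- setdiff(names(scaling),
                     c(names(preset$plant), names(preset$beetle),
                       names(preset$inter)))
  if (length(unknown)) {
    stop("unknown parameter(s) in scaling: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  preset
}

#' @export
print.plant_params <- function(x, ...) {
  cat("<plant_params>\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.beetle_params <- function(x, ...) {
  cat("<beetle_params>\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("<interaction_params>\n")
  print(unlist(x)); invisible(x)
}
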
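#' Load a run configuration
#'
#' Reads a YAML configuration, validates every key against the model's
#' parameter names, merges species-preset defaults with any explicit
#' overrides, and reports each applied default. Recognised top-level keys:
#' `model`, `species`, `parameters` (named rate overrides), `scenario`
#' (`P0`, `B0`, `horizon`, `eps`), `solver` (`rtol`, `atol`, `g_form`,
#' `recruitment`, `starvation`, `K`), `seed`, `output`.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress the per-default messages.
#' @return A validated configuration list of class `"wb_config"` with
#'   resolved `plant`, `beetle` and `inter` parameter objects.
#' @examples
#' cfg <- load_config(system.file("extdata", "release-config.yaml",
#'                                package = "weedbeetle"), quiet = TRUE)
#' cfg$inter$alpha
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)

  known_top <- c("model", "species", "parameters", "scenario", "solver",
                 "seed", "output")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  species <- cfg$species %||% "leaf"
  preset <- species_preset(species)
  note <- function(...) if (!quiet) message(...)

  pars <- cfg$parameters %||% list()
  all_names <- c(names(preset$plant), names(preset$beetle),
                 names(preset$inter))
  bad <- setdiff(names(pars), all_names)
  if (length(bad)) {
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (part in c("plant", "beetle", "inter")) {
    for (nm in names(preset[[part]])) {
      if (nm %in% names(pars)) {
        v <- pars[[nm]]
        if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
          stop("invalid value for parameter `", nm, "`", call. = FALSE)
        }
        note("override: ", nm, " = ", v)
        preset[[part]][[nm]] <- v
      } else {
        note("default (", species, " preset): ", nm, " = ",
             preset[[part]][[nm]])
      }
    }
    check_rates(preset[[part]])
  }

  scen_defaults <- list(P0 = 100, B0 = 0, horizon = 1000, eps = 1)
  scen <- utils::modifyList(scen_defaults, cfg$scenario %||% list())
  bad <- setdiff(names(scen), names(scen_defaults))
  if (length(bad)) {
    stop("unknown scenario key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (scen$P0 <= 0) stop("scenario P0 must be > 0", call. = FALSE)
  if (scen$B0 < 0) stop("scenario B0 must be >= 0", call. = FALSE)

  solver_defaults <- list(rtol = 1e-8, atol = 1e-10,
                          g_form = "leaf_per_node", recruitment = "alpha",
                          starvation = "saturating", K = NULL, dt = 0.1)
  solver <- utils::modifyList(solver_defaults, cfg$solver %||% list())
  bad <- setdiff(names(solver), names(solver_defaults))
  if (length(bad)) {
    stop("unknown solver key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  structure(
    list(model = cfg$model %||% "coupled", species = species,
         plant = preset$plant, beetle = preset$beetle,
         inter = preset$inter, scenario = scen, solver = solver,
         seed = cfg$seed %||% 1L, output = cfg$output),
    class = "wb_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

result_metadata <- function(x, extra = list()) {
  meta <- attr(x, "meta") %||% list()
  c(list(package = "weedbeetle",
         version = as.character(utils::packageVersion("weedbeetle"))),
    meta, extra)
}

#' Write a result table with reproducibility metadata
#'
#' CSV output carries a commented header block (package version, seed,
#' resolved parameters, solver settings) so a run can be reproduced from
#' the file alone; JSON output stores the same metadata alongside the
#' data.
#'
#' @param x A trajectory or result tibble (attributes written as
#'   metadata).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  meta <- result_metadata(x)
  if (format == "csv") {
    hdr <- paste0("# ", names(flatten_meta(meta)), ": ",
                  unlist(flatten_meta(meta)))
    writeLines(hdr, path)
    readr::write_csv(tibble::as_tibble(x), path, append = TRUE,
                     col_names = TRUE)
  } else {
    jsonlite::write_json(
      list(metadata = meta, data = tibble::as_tibble(x)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  }
  invisible(path)
}

flatten_meta <- function(meta) {
  out <- list()
  rec <- function(x, prefix = "") {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(v)) rec(v, key)
      else if (!is.null(v)) out[[key]] <<- paste(format(v, digits = 15),
                                                 collapse = " ")
    }
  }
  rec(meta)
  out
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a CSV or JSON results file.
#' @return A tibble; for CSV the commented metadata lines are stored in
#'   attribute `"metadata_lines"`, for JSON in attribute `"metadata"`.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(obj$data)
    attr(out, "metadata") <- obj$metadata
    return(out)
  }
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  hdr <- grep("^#", readLines(path, n = 200), value = TRUE)
  attr(out, "metadata_lines") <- hdr
  out
}
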
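# Configuration parsing, result serialization, presets and the seeded
# random-scenario generator used by the property-test suite.

scenario_keys <- c("P", "q", "c_prime", "f_star", "K",
                   "alpha1", "alpha2", "b1", "b2",
                   "r_min", "r_max", "r_step",
                   "B_min", "B_max", "B_step")

#' Read a scenario configuration from a key = value file
#'
#' The format is a plain-text `key = value` file (one pair per line, `#`
#' comments allowed). Recognized keys: economics `P`, `q`, `c_prime`,
#' `f_star`, `K`; social `alpha1`, `alpha2`, `b1`, `b2` (population 2
#' defaults to population 1); grids `r_min`, `r_max`, `r_step`, `B_min`,
#' `B_max`, `B_step`. Missing keys fall back to the bundled case-study
#' defaults (`P = 23`, `q = 0.023`, `c_prime = 2e-5`, `f_star = 18`,
#' symmetric `alpha = 1`, `b = 0.3`, grids of step 0.01 over r in
#' \[0, 2\] and B' in \[0.01, 1\]). Unknown keys raise a warning; values
#' outside their domain raise an error naming the offending key.
#'
#' @param path Path to the config file. The bundled default is at
#'   `system.file("extdata", "laguna_default.conf", package = "fisherygame")`.
#' @return A [scenario_config()] object.
#' @seealso [write_scenario()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: %s", path),
                 class = "fisherygame_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      rlang::abort(sprintf("Cannot parse config line: '%s'", ln),
                   class = "fisherygame_io_error")
    }
    key <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(parts[2])))
    if (is.na(val)) {
      rlang::abort(sprintf("Value for `%s` is not numeric.", key),
                   class = "fisherygame_io_error")
    }
    kv[[key]] <- val
  }
  unknown <- setdiff(names(kv), scenario_keys)
  if (length(unknown) > 0) {
    rlang::warn(sprintf("Ignoring unknown config keys: %s",
                        paste(unknown, collapse = ", ")),
                class = "fisherygame_unknown_keys")
    kv <- kv[setdiff(names(kv), unknown)]
  }
  scenario_from_keys(kv)
}

scenario_from_keys <- function(kv) {
  pick <- function(key, default) kv[[key]] %||% default
  econ <- bioeconomic_params(
    P = pick("P", 23), q = pick("q", 0.023),
    c_prime = pick("c_prime", 2e-5), f_star = pick("f_star", 18),
    K = kv[["K"]])
  alpha1 <- pick("alpha1", 1)
  b1 <- pick("b1", 0.3)
  social <- social_params(
    alpha1 = alpha1, b1 = b1,
    alpha2 = pick("alpha2", alpha1), b2 = pick("b2", b1))
  scenario_config(
    social = social, econ = econ,
    r_grid = seq(pick("r_min", 0), pick("r_max", 2),
                 by = pick("r_step", 0.01)),
    B_grid = seq(pick("B_min", 0.01), pick("B_max", 1),
                 by = pick("B_step", 0.01)))
}

#' Write a scenario configuration to a key = value file
#'
#' Values are written at full precision so that
#' [load_scenario()] round-trips exactly. Grids are stored as
#' min/max/step; only configs with regular grids can be serialized.
#'
#' @param config A [scenario_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  grid_step <- function(g, name) {
    if (length(g) == 1L) return(0)
    steps <- diff(g)
    if (diff(range(steps)) > 1e-9 * max(steps)) {
      rlang::abort(sprintf("`%s` is not a regular grid; cannot serialize.", name),
                   class = "fisherygame_io_error")
    }
    steps[1]
  }
  num <- function(x) format(x, digits = 17, scientific = NA)
  kv <- c(
    P = config$econ$P, q = config$econ$q, c_prime = config$econ$c_prime,
    f_star = config$econ$f_star,
    if (!is.null(config$econ$K)) c(K = config$econ$K),
    alpha1 = config$social$alpha1, alpha2 = config$social$alpha2,
    b1 = config$social$b1, b2 = config$social$b2,
    r_min = min(config$r_grid), r_max = max(config$r_grid),
    r_step = grid_step(config$r_grid, "r_grid"),
    B_min = min(config$B_grid), B_max = max(config$B_grid),
    B_step = grid_step(config$B_grid, "B_grid"))
  writeLines(c("# fisherygame scenario configuration",
               paste(names(kv), "=", vapply(kv, num, character(1)))),
             path)
  invisible(path)
}

preset_social <- list(
  high_tolerance_high_control = c(alpha = 1, b = 0.3),
  high_tolerance_low_control = c(alpha = 0.8, b = 0.3),
  low_tolerance_high_control = c(alpha = 1, b = 0.7),
  low_tolerance_low_control = c(alpha = 0.8, b = 0.7))

#' Bundled sensitivity-analysis scenarios
#'
#' The four case-study scenarios crossing risk tolerance (high, `b = 0.3`;
#' low, `b = 0.7`) with control perception (high, `alpha = 1`; low,
#' `alpha = 0.8`), symmetric across the two populations, with default
#' economics and grids.
#'
#' @param name One of `"high_tolerance_high_control"`,
#'   `"high_tolerance_low_control"`, `"low_tolerance_high_control"`,
#'   `"low_tolerance_low_control"`.
#' @param ... Overrides passed to [scenario_config()] (e.g. coarser
#'   `r_grid`/`B_grid`, a different `econ`).
#' @return A [scenario_config()] object.
#' @examples
#' scenario_preset("low_tolerance_low_control")
#' @export
scenario_preset <- function(name = names(preset_social), ...) {
  name <- match.arg(name)
  s <- preset_social[[name]]
  scenario_config(social = social_params(alpha1 = s[["alpha"]],
                                         b1 = s[["b"]]), ...)
}

#' Seeded random scenario draws for property testing
#'
#' Draws `n` independent scenarios with control perceptions and risk
#' tolerances uniform on \[0, 1\], growth rate uniform on \[0, 2\] and
#' relative stock size uniform on (0, 1\], with default economics.
#' Reproducible: the same seed yields the same table, and the caller's RNG
#' state is left untouched.
#'
#' @param n Number of draws (positive).
#' @param seed Integer seed.
#' @return A tibble with columns `alpha1`, `alpha2`, `b1`, `b2`, `r`,
#'   `B_prime`, ready for [classify_games()].
#' @examples
#' random_scenarios(3, seed = 42)
#' @export
random_scenarios <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    rlang::abort("`n` must be a positive integer.",
                 class = "fisherygame_domain_error")
  }
  n <- as.integer(n)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  tibble::tibble(
    alpha1 = stats::runif(n), alpha2 = stats::runif(n),
    b1 = stats::runif(n), b2 = stats::runif(n),
    r = stats::runif(n, 0, 2),
    B_prime = 1 - stats::runif(n))  # uniform on (0, 1]
}

#' Write and re-read sweep results
#'
#' CSV serialization for sweep tables, frequency curves and any tibble of
#' results. Doubles are written in shortest round-trip form (readr) and
#' parsed back with the correctly rounded base reader, so a write/read
#' cycle recovers bit-identical values and the sweep-determinism property
#' survives serialization.
#'
#' @param x A data frame (e.g. from [sweep_scenario()]).
#' @param path Output CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_results <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- tibble::as_tibble(x)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.factor),
                                          as.character))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Single-game classification as a JSON-ready record
#'
#' @param game A [fishery_game()] object.
#' @return A named list with the generating parameters, penalty, label and
#'   interior equilibrium; serialize with
#'   `jsonlite::toJSON(..., auto_unbox = TRUE)`.
#' @export
outcome_record <- function(game) {
  stopifnot(inherits(game, "fishery_game"))
  g <- glance(game)
  list(r = game$stock$r, B_prime = game$stock$B_prime,
       alpha1 = game$social$alpha1, alpha2 = game$social$alpha2,
       b1 = game$social$b1, b2 = game$social$b2,
       delta = game$delta_C, delta_N = game$delta_N,
       label = g$label, x_bar = g$x_bar)
}

#' Write a run manifest
#'
#' Records the scenario, package version, timestamp and output paths of a
#' command-line run as JSON. Re-running with the same config reproduces
#' identical result files; only the timestamp differs.
#'
#' @param path Manifest output path.
#' @param config The [scenario_config()] used.
#' @param outputs Character vector of result-file paths.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, outputs, extra = list()) {
  stopifnot(inherits(config, "scenario_config"))
  manifest <- c(list(
    package = "fisherygame",
    version = as.character(utils::packageVersion("fisherygame")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      econ = config$econ[!vapply(config$econ, is.null, logical(1))],
      social = unclass(config$social),
      r_grid = list(min = min(config$r_grid), max = max(config$r_grid),
                    n = length(config$r_grid)),
      B_grid = list(min = min(config$B_grid), max = max(config$B_grid),
                    n = length(config$B_grid))),
    outputs = as.list(outputs)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
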
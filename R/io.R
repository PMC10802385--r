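trajectory_cols <- c("realization", "time_s", "time_h", "chrom_id",
                     "x_um", "y_um", "paired", "partner_id")

#' Write / read a trajectory as tidy CSV
#'
#' The canonical on-disk form of a trajectory: one row per realization x
#' sample time x chromosome, columns `realization, time_s, time_h, chrom_id,
#' x_um, y_um, paired, partner_id`. Coordinates round-trip to well below
#' 1e-9 um; discrete fields round-trip exactly.
#'
#' @param traj A `pairing_trajectory` tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `pairing_trajectory` tibble.
#' @export
write_trajectory <- function(traj, path) {
  missing <- setdiff(trajectory_cols, names(traj))
  if (length(missing))
    abort(paste0("trajectory is missing column(s): ",
                 paste(missing, collapse = ", ")))
  readr::write_csv(traj[, trajectory_cols], path)
  invisible(path)
}

#' @param chromosomes Optional [chromosome_set()] to attach to the result
#'   (otherwise analyses fall back on the paired-layout convention).
#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, chromosomes = NULL) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(trajectory_cols, hdr)
  if (length(missing))
    abort(paste0("not a trajectory file; missing column(s): ",
                 paste(missing, collapse = ", ")))
  out <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      realization = readr::col_integer(),
      time_s = readr::col_double(), time_h = readr::col_double(),
      chrom_id = readr::col_integer(),
      x_um = readr::col_double(), y_um = readr::col_double(),
      paired = readr::col_logical(),
      partner_id = readr::col_integer()))
  prob <- readr::problems(out)
  if (nrow(prob))
    abort(sprintf("malformed trajectory row %d: expected %s in column `%s`",
                  prob$row[1L], prob$expected[1L], hdr[prob$col[1L]]))
  if (!is.null(chromosomes)) attr(out, "chromosomes") <- chromosomes
  class(out) <- c("pairing_trajectory", class(out))
  out
}

#' Serialize a scenario to / from JSON
#'
#' Scenario files carry the preset name, any overrides and the fully
#' resolved parameters (force field keys use the standard symbols `C_a`,
#' `C_r`, `C_r1`, `ell_a`, `ell_r`, `ell_r1`, `C_b`, `ell_b`). Reading
#' rebuilds the scenario from the resolved parameters so the round trip is
#' lossless.
#'
#' @param scenario A `scenario` from [build_scenario()].
#' @param path File path (`.json`).
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a `scenario`.
#' @export
write_scenario <- function(scenario, path) {
  sp <- scenario$params
  payload <- list(
    scenario = scenario$name,
    realizations = scenario$realizations,
    params = sp[setdiff(names(sp), "force")],
    force = unclass(sp$force),
    chromosomes = as.data.frame(scenario$chromosomes))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- do.call(force_params, as.list(payload$force))
  sp <- do.call(sim_params, c(as.list(payload$params), list(force = fp)))
  ch <- tibble::as_tibble(payload$chromosomes)
  ch$chrom_id <- as.integer(ch$chrom_id)
  ch$pair_id <- as.integer(ch$pair_id)
  ch$homolog_id <- as.integer(ch$homolog_id)
  ch$name <- as.character(ch$name)
  class(ch) <- c("chromosome_set", class(ch))
  structure(list(name = payload$scenario, params = sp, chromosomes = ch,
                 realizations = as.integer(payload$realizations)),
            class = "scenario")
}

#' Run manifest
#'
#' Provenance record for an ensemble run: scenario name, resolved
#' parameters, base seed and per-realization seeds, package version and the
#' output files produced. Written as JSON next to the outputs so every
#' result file is reproducible from its manifest alone.
#'
#' @param scenario A `scenario`.
#' @param seed Base seed of the run.
#' @param realizations Realization count actually run.
#' @param outputs Character vector of output file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(scenario, seed, realizations, outputs) {
  structure(list(
    scenario = scenario$name,
    package_version = as.character(utils::packageVersion("meiopair")),
    seed = seed,
    seeds = seq(seed, seed + realizations - 1L),
    realizations = realizations,
    params = scenario$params[setdiff(names(scenario$params), "force")],
    force = unclass(scenario$params$force),
    outputs = outputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deterministic hand-crafted fixture trajectory
#'
#' A two-pair trajectory used by analysis tests and the `fixtures` CLI
#' subcommand: pair 1 is pinned at the held 0.05 um separation (always
#' paired), pair 2 at a constant 3 um (never paired), so the pairing
#' fraction is exactly 0.5 at every sample.
#'
#' @param times Sample times in seconds.
#' @return A `pairing_trajectory` tibble (single realization).
#' @export
fixture_trajectory <- function(times = seq(0, 21600, by = 3600)) {
  ch <- chromosome_set(2)
  ns <- length(times)
  pos <- rbind(c(-2, 0.025), c(-2, -0.025), c(1.5, 0), c(-1.5, 0))
  out <- tibble::tibble(
    realization = 1L,
    time_s = rep(times, each = 4L),
    time_h = display_hours(rep(times, each = 4L)),
    chrom_id = rep(1:4, ns),
    x_um = rep(pos[, 1L], ns),
    y_um = rep(pos[, 2L], ns),
    paired = rep(c(TRUE, TRUE, FALSE, FALSE), ns),
    partner_id = rep(c(2L, 1L, NA_integer_, NA_integer_), ns))
  attr(out, "chromosomes") <- ch
  class(out) <- c("pairing_trajectory", class(out))
  out
}
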
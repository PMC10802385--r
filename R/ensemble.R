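#' Budding yeast karyotype
#'
#' The 16 nuclear chromosomes of *Saccharomyces cerevisiae* with canonical
#' physical lengths in kilobase pairs (S288C assembly sizes rounded to the
#' nearest kbp). The three shortest (chrI, chrVI, chrIII; 230-317 kbp) are the
#' pairs the model predicts to be slowest to pair; all other chromosomes
#' exceed 400 kbp.
#'
#' @return A tibble with columns `chrom` (roman numeral) and `length_kbp`,
#'   ordered chrI..chrXVI.
#' @examples
#' mean(yeast_karyotype()$length_kbp)  # scaling denominator, ~754 kbp
#' @export
yeast_karyotype <- function() {
  tibble::tibble(
    chrom = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
              "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI"),
    length_kbp = c(230, 813, 317, 1532, 577, 270, 1091, 562,
                   440, 746, 667, 1078, 924, 784, 1091, 948)
  )
}

#' Build a chromosome set with homolog partnerships
#'
#' Lays out `2 * n_pairs` chromosomes as consecutive homolog pairs
#' (chromosomes `2k - 1` and `2k` are partners) and attaches size-scaled
#' interaction radii via [scale_radii()]. With `lengths_kbp = NULL` all
#' chromosomes take the mean yeast length, so scaled radii equal the base
#' radii (the uniform-size simplification).
#'
#' @param n_pairs Number of homolog pairs.
#' @param lengths_kbp Optional per-pair lengths (kbp), length `n_pairs`.
#'   `"yeast"` selects the 16-pair karyotype from [yeast_karyotype()].
#' @param base Base [force_params()] used for radius scaling.
#' @param scale_by_length If `FALSE`, radii stay at base values regardless of
#'   lengths (used by the uniform-size experiments).
#'
#' @return A tibble of class `chromosome_set` with one row per chromosome:
#'   `chrom_id`, `pair_id`, `homolog_id`, `name`, `length_kbp`, `ell_a`,
#'   `ell_r`.
#' @examples
#' chromosome_set(2)
#' chromosome_set(16, "yeast")
#' @export
chromosome_set <- function(n_pairs, lengths_kbp = NULL,
                           base = force_params(), scale_by_length = TRUE) {
  nm <- NULL
  if (identical(lengths_kbp, "yeast")) {
    ky <- yeast_karyotype()
    lengths_kbp <- ky$length_kbp
    nm <- ky$chrom
    n_pairs <- nrow(ky)
  }
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1)
    abort("`n_pairs` must be a positive count")
  n_pairs <- as.integer(n_pairs)
  if (is.null(lengths_kbp)) {
    lengths_kbp <- rep(mean(yeast_karyotype()$length_kbp), n_pairs)
  }
  if (length(lengths_kbp) != n_pairs)
    abort("`lengths_kbp` must have one entry per homolog pair")
  if (is.null(nm)) nm <- as.character(seq_len(n_pairs))
  sr <- scale_radii(lengths_kbp, base)
  out <- tibble::tibble(
    chrom_id = seq_len(2L * n_pairs),
    pair_id = rep(seq_len(n_pairs), each = 2L),
    homolog_id = as.integer(rep(seq_len(n_pairs) * 2L, each = 2L)) -
      rep(c(0L, 1L), n_pairs),
    name = rep(nm, each = 2L),
    length_kbp = rep(sr$length_kbp, each = 2L),
    ell_a = if (scale_by_length) rep(sr$ell_a, each = 2L) else base$ell_a,
    ell_r = if (scale_by_length) rep(sr$ell_r, each = 2L) else base$ell_r
  )
  class(out) <- c("chromosome_set", class(out))
  out
}

#' Random initial placement with pairwise exclusion
#'
#' Places every chromosome uniformly at random in the nuclear disc, redrawing
#' any chromosome whose center falls within the exclusion distance (default
#' 400 nm, the pairing threshold) of an already-placed one, so that no pair
#' starts paired. Orientations are independent uniform unit vectors.
#'
#' @param chromosomes A [chromosome_set()].
#' @param nucleus_radius Disc radius (um).
#' @param exclusion Minimum initial center-to-center distance (um).
#' @param max_tries Redraw budget per chromosome before giving up.
#'
#' @return An `abm_state` object (see [new_state()]) at time 0.
#' @examples
#' set.seed(1)
#' st <- place_chromosomes(chromosome_set(2))
#' min(dist(st$positions)) >= 0.4
#' @export
place_chromosomes <- function(chromosomes, nucleus_radius = 3.25,
                              exclusion = 0.4, max_tries = 1e5) {
  if (exclusion >= 2 * nucleus_radius)
    abort("`exclusion` must be smaller than the nucleus diameter")
  n <- nrow(chromosomes)
  pos <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        abort(sprintf(
          "placement failed for chromosome %d after %d draws (%.0f chromosomes in a %.2f um disc is too dense for a %.2f um exclusion)",
          i, max_tries, n, nucleus_radius, exclusion))
      r <- nucleus_radius * sqrt(runif(1L))
      th <- runif(1L, 0, 2 * pi)
      cand <- c(r * cos(th), r * sin(th))
      if (i == 1L) break
      d2 <- (pos[seq_len(i - 1L), 1L] - cand[1L])^2 +
            (pos[seq_len(i - 1L), 2L] - cand[2L])^2
      if (min(d2) >= exclusion^2) break
    }
    pos[i, ] <- cand
  }
  th <- runif(n, 0, 2 * pi)
  new_state(chromosomes, positions = pos,
            orientations = cbind(cos(th), sin(th)))
}

scenario_names <- c("base", "uniform_n_pairs", "size_adjusted",
                    "velocity_sweep", "attraction_only", "repulsion_only",
                    "dominant_attraction", "dumbbell",
                    "spo11_reduced_forces", "spo11_slow")

#' Named scenario presets for the model's experiments
#'
#' Returns a fully-populated scenario (parameters + chromosome set +
#' realization count) for each experiment family:
#' \describe{
#'   \item{base}{Wild-type parameters, 16 uniform-size pairs.}
#'   \item{uniform_n_pairs}{Like base with a configurable number of
#'     uniform-size pairs (chromosome-number experiment).}
#'   \item{size_adjusted}{16 yeast pairs with length-scaled radii.}
#'   \item{velocity_sweep}{List of size-adjusted scenarios over
#'     v0 = 150, 180, 210, 240, 270, 300, 600 nm/s.}
#'   \item{attraction_only}{Size-adjusted with `C_r = 0` (excluded volume
#'     kept), isolating homolog attraction.}
#'   \item{repulsion_only}{Size-adjusted with `C_a = 0`, isolating
#'     non-homolog repulsion.}
#'   \item{dominant_attraction}{`C_a` x 10, `C_r` / 10.}
#'   \item{dumbbell}{Size-adjusted active-dumbbell variant.}
#'   \item{spo11_reduced_forces}{3-fold reduced `C_a` and `C_r` (the
#'     conventional rounded value 0.0017), wild-type speed.}
#'   \item{spo11_slow}{v0 = 231 nm/s (77% of wild type), `C_a = 0.0017`,
#'     `C_r = 0.005`, `C_r1 = 0.015`.}
#' }
#'
#' @param name One of the preset names above.
#' @param n_pairs Pair count for `uniform_n_pairs` (default 2, the dilute
#'   case).
#' @param realizations Monte-Carlo realization count (default 200).
#' @param ... Overrides forwarded to [sim_params()] (e.g. `v0`, `dt`,
#'   `t_final`, `sample_every`).
#'
#' @return A `scenario` object: `list(name, params, chromosomes,
#'   realizations)`; for `velocity_sweep`, a named list of scenarios.
#' @examples
#' build_scenario("base")$params$v0
#' build_scenario("spo11_slow")$params$v0  # 0.231
#' @export
build_scenario <- function(name, n_pairs = 2, realizations = 200, ...) {
  if (!is.character(name) || length(name) != 1L || !name %in% scenario_names)
    abort(paste0("unknown scenario; valid names are: ",
                 paste(scenario_names, collapse = ", ")))
  if (name == "velocity_sweep") {
    v0s <- c(0.15, 0.18, 0.21, 0.24, 0.27, 0.3, 0.6)
    out <- lapply(v0s, function(v) {
      sc <- build_scenario("size_adjusted", realizations = realizations,
                           v0 = v, ...)
      sc$name <- sprintf("velocity_sweep_v0=%gnm/s", 1000 * v)
      sc
    })
    names(out) <- sprintf("v0_%g", 1000 * v0s)
    return(out)
  }
  fp <- switch(name,
    attraction_only = force_params(C_r = 0),
    repulsion_only = force_params(C_a = 0),
    dominant_attraction = force_params(C_a = 0.05, C_r = 0.0005),
    spo11_reduced_forces = force_params(C_a = 0.0017, C_r = 0.0017),
    spo11_slow = force_params(C_a = 0.0017, C_r = 0.005, C_r1 = 0.015),
    force_params()
  )
  chroms <- switch(name,
    base = chromosome_set(16, base = fp),
    uniform_n_pairs = chromosome_set(n_pairs, base = fp),
    chromosome_set(16, "yeast", base = fp)
  )
  extra <- list(...)
  defaults <- list(force = fp)
  if (name == "spo11_slow") defaults$v0 <- 0.231
  if (name == "dumbbell") defaults$dumbbell <- TRUE
  sp <- do.call(sim_params, modifyList(defaults, extra))
  structure(list(name = name, params = sp, chromosomes = chroms,
                 realizations = as.integer(realizations)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: %s>\n", x$name))
  cat(sprintf("  %d homolog pairs, %d realizations\n",
              nrow(x$chromosomes) / 2L, x$realizations))
  cat(sprintf("  v0 = %g um/s, D = %g um^2/s, dt = %g s, window %g..%g s (%.0f-%.0f h displayed)\n",
              x$params$v0, x$params$D, x$params$dt, 0, x$params$t_final,
              display_hours(0), display_hours(x$params$t_final)))
  if (x$params$dumbbell) cat("  active-dumbbell variant\n")
  invisible(x)
}
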
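#' Interaction force parameters
#'
#' Bundles the strengths and length scales of the pair potentials, the
#' excluded-volume core and the nuclear-envelope repulsion. Defaults are the
#' calibrated wild-type ("base") values; lengths are in micrometers, strengths
#' are nondimensional (numerically, micrometers/second of drift at contact
#' when divided by their length scale).
#'
#' @param C_a Attractive strength between homologs.
#' @param C_r Repulsive strength between non-homologs.
#' @param C_r1 Excluded-volume strength, all chromosome pairs.
#' @param ell_a Attractive length scale (um); the homology-search reach.
#' @param ell_r Non-homolog repulsive length scale (um).
#' @param ell_r1 Excluded-volume length scale (um); half the held separation
#'   scale of a paired homolog pair.
#' @param C_b Boundary (nuclear envelope) repulsion strength.
#' @param ell_b Boundary repulsion length scale (um).
#'
#' @return A list of class `force_params`.
#' @examples
#' force_params()
#' force_params(C_a = 0.0017, C_r = 0.0017)  # reduced-break mutant forces
#' @export
force_params <- function(C_a = 0.005, C_r = 0.005, C_r1 = 0.05,
                         ell_a = 0.4, ell_r = 0.4, ell_r1 = 0.05,
                         C_b = 0.15, ell_b = 0.05) {
  p <- list(C_a = C_a, C_r = C_r, C_r1 = C_r1,
            ell_a = ell_a, ell_r = ell_r, ell_r1 = ell_r1,
            C_b = C_b, ell_b = ell_b)
  for (nm in c("C_a", "C_r", "C_r1", "C_b")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      abort(sprintf("`%s` must be a single non-negative number", nm))
  }
  for (nm in c("ell_a", "ell_r", "ell_r1", "ell_b")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      abort(sprintf("`%s` must be a single positive number", nm))
  }
  structure(p, class = "force_params")
}

#' @export
print.force_params <- function(x, ...) {
  cat("<force_params>\n")
  cat(sprintf("  homolog:     C_a = %g, ell_a = %g um\n", x$C_a, x$ell_a))
  cat(sprintf("  non-homolog: C_r = %g, ell_r = %g um\n", x$C_r, x$ell_r))
  cat(sprintf("  excluded vol: C_r1 = %g, ell_r1 = %g um\n", x$C_r1, x$ell_r1))
  cat(sprintf("  boundary:    C_b = %g, ell_b = %g um\n", x$C_b, x$ell_b))
  invisible(x)
}

#' Pair potential between two chromosome centers
#'
#' Morse potential built from Yukawa (decaying-exponential) terms. Homolog
#' pairs combine the short-range excluded-volume repulsion with an attraction
#' on scale `ell_a`; non-homolog pairs combine it with a repulsion on scale
#' `ell_r`:
#' \deqn{U_{hom}(d) = C_{r1} e^{-d/\ell_{r1}} - C_a e^{-d/\ell_a}}
#' \deqn{U_{nonhom}(d) = C_{r1} e^{-d/\ell_{r1}} + C_r e^{-d/\ell_r}}
#'
#' @param d Center-to-center separation(s) in micrometers (vectorized).
#' @param params A [force_params()] object.
#' @param relation `"homolog"` or `"non_homolog"`.
#' @param ell_a,ell_r Optional per-pair length-scale overrides (um), used when
#'   interaction radii are chromosome-size scaled; default to `params`.
#'
#' @return Potential energy (nondimensional), same length as `d`.
#' @examples
#' pair_potential(0, force_params(), "homolog")  # C_r1 - C_a = 0.045
#' @export
pair_potential <- function(d, params = force_params(),
                           relation = c("homolog", "non_homolog"),
                           ell_a = params$ell_a, ell_r = params$ell_r) {
  relation <- match.arg(relation)
  if (any(!is.finite(d)) || any(d < 0))
    abort("`d` must be finite and non-negative")
  core <- params$C_r1 * exp(-d / params$ell_r1)
  if (relation == "homolog") core - params$C_a * exp(-d / ell_a)
  else core + params$C_r * exp(-d / ell_r)
}

#' Pair force between two chromosome centers
#'
#' Negative gradient of [pair_potential()], evaluated at the displacement
#' `delta = x_i - x_j`; the returned vector is the force on chromosome i.
#' The force is central: it acts along `delta` and swapping the two
#' chromosomes negates it. At exactly coincident centers the direction is
#' drawn uniformly from R's current RNG stream (deterministic under a seed)
#' with the `d -> 0` limiting magnitude.
#'
#' @param delta Displacement 2-vector (um), or an n x 2 matrix of
#'   displacements.
#' @inheritParams pair_potential
#'
#' @return Force 2-vector (or n x 2 matrix), units um/s of overdamped drift.
#' @export
pair_force <- function(delta, params = force_params(),
                       relation = c("homolog", "non_homolog"),
                       ell_a = params$ell_a, ell_r = params$ell_r) {
  relation <- match.arg(relation)
  if (is.matrix(delta)) {
    out <- t(apply(delta, 1L, pair_force, params = params,
                   relation = relation, ell_a = ell_a, ell_r = ell_r))
    dimnames(out) <- NULL
    return(out)
  }
  if (length(delta) != 2L || any(!is.finite(delta)))
    abort("`delta` must be a finite 2-vector")
  d <- sqrt(sum(delta^2))
  if (d == 0) {
    th <- runif(1L, 0, 2 * pi)
    u <- c(cos(th), sin(th))
    mag <- params$C_r1 / params$ell_r1 +
      if (relation == "homolog") -params$C_a / ell_a else params$C_r / ell_r
    return(mag * u)
  }
  # -dU/dd, so a positive magnitude pushes i away from j
  mag <- (params$C_r1 / params$ell_r1) * exp(-d / params$ell_r1)
  mag <- mag + if (relation == "homolog") {
    -(params$C_a / ell_a) * exp(-d / ell_a)
  } else {
    (params$C_r / ell_r) * exp(-d / ell_r)
  }
  mag * delta / d
}

#' Repulsive force of the nuclear envelope
#'
#' Purely repulsive Yukawa-type wall: magnitude
#' \eqn{(C_b/\ell_b)\,e^{-(L - \|x\|)/\ell_b}} directed radially inward,
#' where `L` is the nucleus radius. Negligible (< 1e-10) at the center for
#' base parameters; grows by a factor `e` per `ell_b` of approach to the
#' envelope.
#'
#' @param x Position 2-vector (um), or an n x 2 matrix.
#' @param nucleus_radius Nucleus (domain) radius L in um.
#' @param params A [force_params()] object (uses `C_b`, `ell_b`).
#'
#' @return Force 2-vector (or n x 2 matrix) pointing toward the origin.
#' @export
boundary_force <- function(x, nucleus_radius = 3.25, params = force_params()) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, boundary_force, nucleus_radius = nucleus_radius,
                   params = params))
    dimnames(out) <- NULL
    return(out)
  }
  if (length(x) != 2L || any(!is.finite(x)))
    abort("`x` must be a finite 2-vector")
  nr <- sqrt(sum(x^2))
  if (nr == 0) return(c(0, 0))
  mag <- (params$C_b / params$ell_b) * exp(-(nucleus_radius - nr) / params$ell_b)
  -mag * x / nr
}

#' Scale interaction radii by relative chromosome length
#'
#' The attractive and non-homolog repulsive radii of each chromosome are
#' scaled by its length relative to the mean length of the set, reflecting
#' the larger number of recombination intermediates engaged in the homology
#' search along a longer chromosome. The excluded-volume radius `ell_r1`
#' stays at its base value for all chromosomes, matching the uniform width of
#' the synaptonemal complex.
#'
#' @param lengths_kbp Positive numeric vector of physical chromosome lengths
#'   (kilobase pairs); one entry per chromosome or per homolog pair.
#' @param base A [force_params()] object supplying the base radii.
#'
#' @return A tibble with columns `length_kbp`, `rel_length`, `ell_a`, `ell_r`
#'   (um), carrying `ell_r1` as an attribute.
#' @examples
#' scale_radii(c(250, 500, 750))
#' @export
scale_radii <- function(lengths_kbp, base = force_params()) {
  if (length(lengths_kbp) < 1L || any(!is.finite(lengths_kbp)) ||
      any(lengths_kbp <= 0))
    abort("`lengths_kbp` must be positive and non-empty")
  rel <- lengths_kbp / mean(lengths_kbp)
  out <- tibble::tibble(
    length_kbp = lengths_kbp,
    rel_length = rel,
    ell_a = base$ell_a * rel,
    ell_r = base$ell_r * rel
  )
  attr(out, "ell_r1") <- base$ell_r1
  out
}
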
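#' Simulation parameters
#'
#' Physical and numerical controls for the overdamped equations of motion.
#' The simulated clock starts at 0 s and is displayed offset by +3 h (the
#' experimental time of minimum pairing); the default window of 21600 s spans
#' displayed t = 3 h to t = 9 h.
#'
#' @param v0 Translational (self-propulsion) speed, um/s.
#' @param D Diffusion constant of the thermal noise, um^2/s.
#' @param dt Integration step, s. Must satisfy `v0 * dt < ell_r1` so the
#'   shortest force scale is resolved.
#' @param t_final Simulated duration, s (displayed end = 3 h + t_final).
#' @param sample_every Output sampling interval, s.
#' @param nucleus_radius Nuclear disc radius L, um.
#' @param capture_distance Homolog pairing capture threshold, um.
#' @param paired_separation Held center separation of a captured pair, um.
#' @param dumbbell Use the active-dumbbell (two-bead) chromosome variant.
#' @param bond_stiffness Dimensionless bond-stiffness scale for the dumbbell;
#'   the per-chromosome Lagrange-multiplier surrogate is
#'   `bond_stiffness / ell^2` where `ell` is the chromosome's bond length.
#'   The default 1 is the closed-form value for which `<|r|^2> = ell^2`
#'   (see [calibrate_bond_stiffness()]).
#' @param interaction_cutoff Pair forces are skipped beyond this separation
#'   (um); at the default 5 um the neglected drift is < 2e-5 um/s.
#' @param force A [force_params()] object.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(v0 = 0.3, D = 1e-4, dt = 0.05,
                       t_final = 21600, sample_every = 60,
                       nucleus_radius = 3.25,
                       capture_distance = 0.4, paired_separation = 0.05,
                       dumbbell = FALSE, bond_stiffness = 1,
                       interaction_cutoff = 5,
                       force = force_params()) {
  if (!inherits(force, "force_params")) abort("`force` must be a force_params object")
  if (dt <= 0) abort("`dt` must be positive")
  if (v0 * dt >= force$ell_r1)
    abort(sprintf(
      "time step too coarse: v0 * dt = %g um must stay below ell_r1 = %g um",
      v0 * dt, force$ell_r1))
  if (t_final <= 0 || sample_every <= 0) abort("times must be positive")
  structure(list(
    v0 = v0, D = D, dt = dt, t_final = t_final, sample_every = sample_every,
    nucleus_radius = nucleus_radius, capture_distance = capture_distance,
    paired_separation = paired_separation, dumbbell = dumbbell,
    bond_stiffness = bond_stiffness, interaction_cutoff = interaction_cutoff,
    force = force), class = "sim_params")
}

#' Displayed time in hours
#'
#' The simulation clock runs in seconds from 0; results are displayed on the
#' experimental axis where the run starts at t = 3 h.
#'
#' @param time_s Simulated time(s) in seconds.
#' @return Displayed hours, `3 + time_s / 3600`.
#' @export
display_hours <- function(time_s) 3 + time_s / 3600

#' Ensemble state
#'
#' Positions, orientations and pairing status of every chromosome at one
#' instant of one realization. Captured pairs store a shared composite center
#' and a frozen member axis; member positions are rendered at +/- half the
#' held separation about the center.
#'
#' @param chromosomes A [chromosome_set()].
#' @param positions n x 2 matrix of chromosome centers (um).
#' @param orientations n x 2 matrix of unit heading vectors.
#' @param time Simulation clock (s).
#' @param paired_with Integer vector of partner `chrom_id` (NA if unpaired).
#' @param pair_time Capture times (s), NA if unpaired.
#' @param beads Optional 2n x 2 bead matrix for the dumbbell variant.
#'
#' @return A list of class `abm_state`.
#' @export
new_state <- function(chromosomes, positions, orientations,
                      time = 0, paired_with = rep(NA_integer_, nrow(positions)),
                      pair_time = rep(NA_real_, nrow(positions)),
                      beads = NULL) {
  n <- nrow(chromosomes)
  stopifnot(nrow(positions) == n, nrow(orientations) == n)
  structure(list(
    time = time,
    positions = positions,
    orientations = orientations,
    paired_with = as.integer(paired_with),
    pair_time = as.numeric(pair_time),
    comp_center = positions,
    pair_axis = matrix(0, n, 2L),
    last_disp = rep(0, n),
    beads = beads,
    chromosomes = chromosomes), class = "abm_state")
}

#' @export
print.abm_state <- function(x, ...) {
  cat(sprintf("<abm_state> %d chromosomes at t = %g s (%.2f h displayed), %d paired\n",
              nrow(x$positions), x$time, display_hours(x$time),
              sum(!is.na(x$paired_with))))
  invisible(x)
}

#' @export
as_tibble.abm_state <- function(x, ...) {
  tibble::tibble(
    chrom_id = x$chromosomes$chrom_id,
    time_s = x$time,
    time_h = display_hours(x$time),
    x_um = x$positions[, 1L],
    y_um = x$positions[, 2L],
    paired = !is.na(x$paired_with),
    partner_id = x$paired_with)
}

#' Validate ensemble-state invariants
#'
#' Checks unit orientations, symmetry and homolog-exclusivity of the pairing
#' map, the held separation of captured pairs, and (when `params` is given)
#' containment within the nuclear envelope. Errors name the violated
#' invariant.
#'
#' @param state An `abm_state`.
#' @param params Optional [sim_params()] enabling the containment and
#'   separation checks.
#' @param tol Numerical tolerance for unit norms.
#' @return `state`, invisibly.
#' @export
validate_state <- function(state, params = NULL, tol = 1e-6) {
  nrm <- sqrt(rowSums(state$orientations^2))
  if (any(abs(nrm - 1) > tol))
    abort("state invariant violated: orientations must be unit vectors")
  pw <- state$paired_with
  idx <- which(!is.na(pw))
  if (length(idx)) {
    back <- pw[pw[idx]]
    if (any(is.na(back)) || any(back != idx))
      abort("state invariant violated: paired_with must be symmetric")
    hom <- state$chromosomes$homolog_id
    if (any(pw[idx] != hom[idx]))
      abort("state invariant violated: paired_with may only link homologs")
    if (!is.null(params)) {
      sep <- sqrt(rowSums((state$positions[idx, , drop = FALSE] -
                           state$positions[pw[idx], , drop = FALSE])^2))
      if (any(abs(sep - params$paired_separation) > 1e-9))
        abort("state invariant violated: paired members must sit at the held separation")
    }
  }
  if (!is.null(params)) {
    r <- sqrt(rowSums(state$positions^2))
    if (any(r > params$nucleus_radius + params$force$ell_b + 1e-6))
      abort("state invariant violated: chromosome outside the nuclear envelope")
  }
  invisible(state)
}

# ---- internal bridge to the C++ core --------------------------------------

core_args <- function(state, params, chromosomes) {
  n <- nrow(chromosomes)
  hom0 <- chromosomes$homolog_id - 1L
  hom0[is.na(hom0)] <- -1L
  beads <- state$beads
  if (params$dumbbell) {
    if (is.null(beads)) {
      # initialize beads at +/- ell/2 about the center along a random axis
      th <- runif(n, 0, 2 * pi)
      half <- chromosomes$ell_a / 2
      beads <- matrix(NA_real_, 2L * n, 2L)
      beads[2L * seq_len(n) - 1L, ] <- state$positions -
        cbind(half * cos(th), half * sin(th))
      beads[2L * seq_len(n), ] <- state$positions +
        cbind(half * cos(th), half * sin(th))
    }
  } else {
    beads <- state$positions
  }
  pw0 <- state$paired_with - 1L
  pw0[is.na(pw0)] <- -1L
  list(beads = beads, hom0 = hom0, pw0 = pw0,
       lambda = params$bond_stiffness / chromosomes$ell_a^2)
}

run_core <- function(state, params, chromosomes, n_steps, sample_every_steps,
                     sample_initial = TRUE) {
  fp <- params$force
  ca <- core_args(state, params, chromosomes)
  .sim_core(ca$beads, state$orientations, ca$hom0,
            chromosomes$ell_a, chromosomes$ell_r,
            fp$C_a, fp$C_r, fp$C_r1, fp$ell_r1, fp$C_b, fp$ell_b,
            params$nucleus_radius, params$v0, params$D, params$dt,
            as.integer(n_steps), as.integer(sample_every_steps),
            params$capture_distance, params$paired_separation,
            params$interaction_cutoff,
            params$dumbbell, ca$lambda,
            ca$pw0, state$pair_time, state$comp_center, state$pair_axis,
            state$last_disp, state$time, sample_initial)
}

state_from_core <- function(core, state, chromosomes, params) {
  st <- core$state
  pw <- st$paired_with
  pw[pw < 0] <- NA_integer_
  pw <- pw + 1L
  n <- nrow(chromosomes)
  ns <- length(core$times)
  pos <- cbind(core$x[ns, ], core$y[ns, ])
  out <- state
  out$time <- st$time
  out$positions <- pos
  out$orientations <- st$orientations
  out$paired_with <- as.integer(pw)
  out$pair_time <- st$pair_time
  out$comp_center <- st$comp_center
  out$pair_axis <- st$pair_axis
  out$last_disp <- st$last_disp
  out$beads <- if (params$dumbbell) st$beads else NULL
  out
}

#' Advance the ensemble by one (or more) time steps
#'
#' One Euler-Maruyama update of every motion unit followed by the pairing
#' capture scan ([bind_pairs()] semantics). Free chromosomes move with
#' propulsion + pair forces + boundary force + noise and re-orient along
#' their realized displacement; captured pairs move rigidly as a single
#' composite agent with a single noise draw.
#'
#' @param state An `abm_state` (validated on entry).
#' @param params A [sim_params()].
#' @param n_steps Number of steps to take (default 1).
#' @return The advanced `abm_state`.
#' @export
pairing_step <- function(state, params, n_steps = 1L) {
  validate_state(state, params)
  chromosomes <- state$chromosomes
  core <- run_core(state, params, chromosomes, n_steps,
                   sample_every_steps = max(n_steps, 1L),
                   sample_initial = FALSE)
  state_from_core(core, state, chromosomes, params)
}

#' Apply the permanent pairing-capture rule
#'
#' Any unpaired homolog pair whose centers sit within the capture distance
#' becomes permanently paired: the pair is collapsed onto its midpoint, the
#' member axis is frozen along the pre-capture separation, members are held
#' at the paired separation, and the composite inherits the orientation of
#' the faster member. Non-homologs are never captured.
#'
#' @param state An `abm_state`.
#' @param params A [sim_params()].
#' @return The updated `abm_state`.
#' @export
bind_pairs <- function(state, params) {
  hom <- state$chromosomes$homolog_id
  n <- length(hom)
  for (i in seq_len(n)) {
    j <- hom[i]
    if (is.na(j) || j <= i) next
    if (!is.na(state$paired_with[i]) || !is.na(state$paired_with[j])) next
    delta <- state$positions[i, ] - state$positions[j, ]
    d <- sqrt(sum(delta^2))
    if (d > params$capture_distance) next
    ctr <- (state$positions[i, ] + state$positions[j, ]) / 2
    axis <- if (d > 0) delta / d else {
      th <- runif(1L, 0, 2 * pi); c(cos(th), sin(th))
    }
    state$paired_with[c(i, j)] <- c(j, i)
    state$pair_time[c(i, j)] <- state$time
    state$comp_center[i, ] <- ctr
    state$pair_axis[i, ] <- axis
    half <- params$paired_separation / 2
    state$positions[i, ] <- ctr + half * axis
    state$positions[j, ] <- ctr - half * axis
    if (state$last_disp[j] > state$last_disp[i])
      state$orientations[i, ] <- state$orientations[j, ]
  }
  state
}

#' Simulate one realization
#'
#' Integrates the ensemble from t = 0 to `params$t_final` with fixed step
#' `params$dt`, applying the capture rule after every step and sampling the
#' state every `params$sample_every` seconds. The trajectory is a
#' deterministic function of (parameters, chromosomes, initial state, seed).
#'
#' @param params A [sim_params()].
#' @param chromosomes A [chromosome_set()]; defaults to the set carried by
#'   `initial`.
#' @param initial Optional `abm_state`; by default a fresh
#'   [place_chromosomes()] draw.
#' @param seed Optional integer seed applied before placement and
#'   integration.
#' @return A tidy tibble of class `pairing_trajectory` with columns
#'   `realization`, `time_s`, `time_h`, `chrom_id`, `x_um`, `y_um`, `paired`,
#'   `partner_id`, plus `chromosomes`, `params`, `final_state` attributes.
#' @export
simulate_trajectory <- function(params, chromosomes = NULL, initial = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) {
    if (is.null(chromosomes)) abort("supply `chromosomes` or `initial`")
    initial <- place_chromosomes(chromosomes, params$nucleus_radius,
                                 exclusion = params$capture_distance)
  }
  if (is.null(chromosomes)) chromosomes <- initial$chromosomes
  n_steps <- round(params$t_final / params$dt)
  ses <- max(1L, round(params$sample_every / params$dt))
  core <- run_core(initial, params, chromosomes, n_steps, ses,
                   sample_initial = TRUE)
  n <- nrow(chromosomes)
  ns <- length(core$times)
  partner <- as.vector(t(core$partner))
  partner[partner < 0] <- NA_integer_
  out <- tibble::tibble(
    realization = 1L,
    time_s = rep(core$times, each = n),
    time_h = display_hours(rep(core$times, each = n)),
    chrom_id = rep(chromosomes$chrom_id, ns),
    x_um = as.vector(t(core$x)),
    y_um = as.vector(t(core$y)),
    paired = !is.na(partner),
    partner_id = partner + 1L)
  attr(out, "chromosomes") <- chromosomes
  attr(out, "params") <- params
  attr(out, "final_state") <- state_from_core(core, initial, chromosomes, params)
  if (params$dumbbell) attr(out, "bond_r2") <- core$bond_r2
  class(out) <- c("pairing_trajectory", class(out))
  out
}

#' Simulate a Monte-Carlo ensemble of realizations
#'
#' Runs `realizations` independent realizations of a scenario with seeds
#' `seed, seed + 1, ...` (embarrassingly parallel yet reproducible) and binds
#' the trajectories into one tidy table.
#'
#' @param scenario A `scenario` from [build_scenario()], or a [sim_params()]
#'   object (then `chromosomes` is required).
#' @param realizations Number of realizations; defaults to the scenario's.
#' @param seed Base integer seed; realization r uses `seed + r - 1`.
#' @param chromosomes Required when `scenario` is a bare `sim_params`.
#' @return A `pairing_trajectory` tibble pooling all realizations, with a
#'   `capture_times` attribute (tibble: realization, pair_id, capture_s).
#' @export
simulate_ensemble <- function(scenario, realizations = NULL, seed = 1,
                              chromosomes = NULL) {
  if (inherits(scenario, "scenario")) {
    params <- scenario$params
    chromosomes <- scenario$chromosomes
    if (is.null(realizations)) realizations <- scenario$realizations
  } else {
    params <- scenario
    if (is.null(chromosomes)) abort("supply `chromosomes` with bare sim_params")
    if (is.null(realizations)) realizations <- 1L
  }
  runs <- vector("list", realizations)
  caps <- vector("list", realizations)
  for (r in seq_len(realizations)) {
    tr <- simulate_trajectory(params, chromosomes, seed = seed + r - 1L)
    tr$realization <- r
    fs <- attr(tr, "final_state")
    reps <- which(!is.na(fs$paired_with) &
                    fs$paired_with > seq_along(fs$paired_with))
    caps[[r]] <- tibble::tibble(
      realization = r,
      pair_id = chromosomes$pair_id[reps],
      capture_s = fs$pair_time[reps])
    attr(tr, "final_state") <- NULL
    runs[[r]] <- tr
  }
  out <- dplyr::bind_rows(runs)
  attr(out, "chromosomes") <- chromosomes
  attr(out, "params") <- params
  attr(out, "capture_times") <- dplyr::bind_rows(caps)
  if (inherits(scenario, "scenario")) attr(out, "scenario") <- scenario$name
  class(out) <- c("pairing_trajectory", class(out))
  out
}

# ---- active dumbbell -------------------------------------------------------

#' Bond force of the active-dumbbell chromosome
#'
#' Equal and opposite forces on the two beads of a dumbbell, linear in the
#' bond vector (bead 2 minus bead 1): bead 1 feels \eqn{+2\lambda D r}, bead
#' 2 feels \eqn{-2\lambda D r}, where the stiffness surrogate lambda replaces the
#' Lagrange multiplier that constrains the mean-squared bond length to
#' `ell^2`.
#'
#' @param r Bond 2-vector `r2 - r1` (um).
#' @param params A [sim_params()] (supplies `D` and `bond_stiffness`).
#' @param bond_length Target root-mean-square bond length `ell` (um).
#' @return A 2 x 2 matrix; rows are the forces on bead 1 and bead 2.
#' @export
dumbbell_bond_force <- function(r, params = sim_params(dumbbell = TRUE),
                                bond_length = 0.4) {
  lambda <- params$bond_stiffness / bond_length^2
  f1 <- 2 * lambda * params$D * r
  rbind(f1, -f1, deparse.level = 0)
}

#' Calibrate the dumbbell bond stiffness
#'
#' Bisection on the stiffness scale `s` (where the per-chromosome multiplier
#' is `s / ell^2`) so that a long free-dumbbell run satisfies
#' `<|r|^2> = ell^2`. With propulsion acting on the dumbbell as a whole and
#' independent per-bead noise, the bond is an Ornstein-Uhlenbeck process and
#' the analytic answer is `s = 1`; this routine verifies it by simulation.
#'
#' @param bond_length Target `ell` (um).
#' @param params A [sim_params()]; `dumbbell` is forced on.
#' @param t_total,t_burn Run length and burn-in (s).
#' @param seed Seed for the calibration runs.
#' @param lower,upper Bisection bracket for the scale.
#' @param iter Bisection iterations.
#' @return The calibrated scale (numeric), with the measured
#'   `<|r|^2>/ell^2` per iterate as attribute `"trace"`.
#' @export
calibrate_bond_stiffness <- function(bond_length = 0.4,
                                     params = sim_params(dumbbell = TRUE),
                                     t_total = 40000, t_burn = 4000,
                                     seed = 1, lower = 0.25, upper = 4,
                                     iter = 8) {
  params$dumbbell <- TRUE
  measure <- function(scale, sd) {
    p <- params
    p$bond_stiffness <- scale
    p$t_final <- t_total
    p$sample_every <- 5
    p$nucleus_radius <- 1e4   # calibration runs on a free dumbbell
    # a single free dumbbell: bond length rides on ell_a
    chroms <- tibble::tibble(
      chrom_id = 1L, pair_id = 1L, homolog_id = NA_integer_, name = "cal",
      length_kbp = bond_length, ell_a = bond_length, ell_r = bond_length)
    set.seed(sd)
    st <- new_state(chroms, positions = matrix(0, 1, 2),
                    orientations = matrix(c(1, 0), 1, 2))
    tr <- simulate_trajectory(p, chroms, initial = st)
    b2 <- attr(tr, "bond_r2")
    keep <- which(seq_len(nrow(b2)) * p$sample_every > t_burn)
    mean(b2[keep, ], na.rm = TRUE) / bond_length^2
  }
  lo <- lower; hi <- upper
  trace <- numeric(0)
  for (k in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    ratio <- measure(mid, seed + k)
    trace <- c(trace, setNames(ratio, format(mid, digits = 4)))
    # <r^2> decreases with stiffness: ratio > 1 means too soft
    if (ratio > 1) lo <- mid else hi <- mid
  }
  structure(sqrt(lo * hi), trace = trace)
}
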
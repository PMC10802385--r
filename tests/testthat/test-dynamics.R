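test_that("a lone noiseless chromosome translates exactly v0 dt per step", {
  ch <- single_free_chromosome()
  p <- sim_params(D = 0, nucleus_radius = 50)
  st <- make_state(ch, positions = matrix(0, 1, 2),
                   orientations = matrix(c(0.6, 0.8), 1, 2))
  st1 <- pairing_step(st, p)
  expect_equal(st1$positions[1, ], p$dt * p$v0 * c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(st1$orientations[1, ], c(0.6, 0.8), tolerance = 1e-12)
  # n steps of pure propulsion accumulate linearly
  st50 <- pairing_step(st, p, n_steps = 50L)
  expect_equal(st50$positions[1, ], 50 * p$dt * p$v0 * c(0.6, 0.8),
               tolerance = 1e-10)
})

test_that("noise term has per-coordinate displacement variance 2 D dt", {
  ch <- single_free_chromosome()
  p <- sim_params(v0 = 0, D = 1e-4, dt = 0.05, t_final = 5000,
                  sample_every = 0.05, nucleus_radius = 1000)
  st <- make_state(ch, positions = matrix(0, 1, 2))
  set.seed(99)
  tr <- simulate_trajectory(p, ch, initial = st)
  incr <- diff(tr$x_um)
  expect_equal(var(incr), 2 * p$D * p$dt, tolerance = 0.05)
  expect_equal(mean(incr), 0, tolerance = 3 * sd(incr) / sqrt(length(incr)))
})

test_that("one step matches the R-side force evaluation (C++ vs R oracle)", {
  ch <- chromosome_set(2)  # chromosomes 1-2 homologs, 3-4 homologs
  p <- sim_params(D = 0)
  pos <- rbind(c(0, 0), c(0.6, 0), c(0.15, 0.1), c(-2, 1))
  ori <- matrix(rep(c(0, 1), each = 4), 4, 2)
  st <- make_state(ch, positions = pos, orientations = ori)
  st1 <- pairing_step(st, p)
  fp <- p$force
  rel <- function(i, j) if (ch$homolog_id[i] == j) "homolog" else "non_homolog"
  for (i in 1:4) {
    f <- c(0, 0)
    for (j in setdiff(1:4, i))
      f <- f + pair_force(pos[i, ] - pos[j, ], fp, rel(i, j))
    f <- f + boundary_force(pos[i, ], p$nucleus_radius, fp)
    expected <- pos[i, ] + p$dt * (p$v0 * ori[i, ] + f)
    expect_equal(st1$positions[i, ], expected, tolerance = 1e-12)
  }
})

test_that("non-homologs inside the repulsive core move apart", {
  ch <- two_nonhomologs()
  p <- sim_params(v0 = 0, D = 0)
  st <- make_state(ch, positions = rbind(c(-0.1, 0), c(0.1, 0)))
  st1 <- pairing_step(st, p)
  d0 <- 0.2
  d1 <- abs(st1$positions[2, 1] - st1$positions[1, 1])
  expect_gt(d1, d0)
})

test_that("capture rule: threshold, permanence, relation gate, held distance", {
  ch <- chromosome_set(2)
  p <- sim_params()
  # homologs at 0.39 um capture; the far pair does not
  st <- make_state(ch, positions = rbind(c(0, 0), c(0.39, 0),
                                         c(-2, 0), c(2, 0)))
  st2 <- bind_pairs(st, p)
  expect_equal(st2$paired_with[1:2], c(2L, 1L))
  expect_true(all(is.na(st2$paired_with[3:4])))
  expect_equal(sqrt(sum((st2$positions[1, ] - st2$positions[2, ])^2)),
               p$paired_separation, tolerance = 1e-12)
  # at 0.41 um nothing happens
  st <- make_state(ch, positions = rbind(c(0, 0), c(0.41, 0),
                                         c(-2, 0), c(2, 0)))
  expect_true(all(is.na(bind_pairs(st, p)$paired_with)))
  # non-homologs at 0.01 um are never captured (simulate through the core)
  nh <- two_nonhomologs()
  stn <- make_state(nh, positions = rbind(c(-0.005, 0), c(0.005, 0)))
  set.seed(1)
  trn <- simulate_trajectory(sim_params(t_final = 60, sample_every = 1),
                             nh, initial = stn)
  expect_true(all(!trn$paired))
})

test_that("captured pairs stay captured and are held at 50 nm forever", {
  sc <- build_scenario("uniform_n_pairs", n_pairs = 2, t_final = 1800,
                       sample_every = 5)
  tr <- simulate_ensemble(sc, realizations = 4, seed = 21)
  pd <- pair_distances(tr)
  by_pair <- split(pd, interaction(pd$realization, pd$pair_id))
  for (b in by_pair) {
    b <- b[order(b$time_s), ]
    # once paired, the paired flag is a suffix of the sample sequence
    expect_true(all(diff(as.integer(b$paired)) >= 0))
    if (any(b$paired))
      expect_equal(b$distance_um[b$paired],
                   rep(0.05, sum(b$paired)), tolerance = 1e-9)
  }
  # and the ensemble pairing fraction is non-decreasing
  pf <- pairing_fraction(tr)
  expect_true(all(diff(pf$fraction) >= 0))
})

test_that("trajectories are a pure function of the seed", {
  sc <- build_scenario("uniform_n_pairs", n_pairs = 2, t_final = 600,
                       sample_every = 30)
  a <- simulate_ensemble(sc, realizations = 2, seed = 13)
  b <- simulate_ensemble(sc, realizations = 2, seed = 13)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c1 <- simulate_ensemble(sc, realizations = 2, seed = 14)
  expect_false(identical(a$x_um, c1$x_um))
})

test_that("all chromosomes stay confined to the nuclear envelope", {
  sc <- build_scenario("uniform_n_pairs", n_pairs = 4, t_final = 3600,
                       sample_every = 10)
  tr <- simulate_ensemble(sc, realizations = 3, seed = 31)
  r <- sqrt(tr$x_um^2 + tr$y_um^2)
  expect_lte(max(r), sc$params$nucleus_radius + sc$params$force$ell_b + 1e-6)
})

test_that("state validation names the violated invariant", {
  ch <- chromosome_set(2)
  p <- sim_params()
  st <- make_state(ch, positions = matrix(rnorm(8), 4, 2))
  st$orientations[2, ] <- c(3, 0)
  expect_error(pairing_step(st, p), "unit vectors")
  st <- make_state(ch, positions = matrix(0.1 * matrix(rnorm(8)), 4, 2))
  st$paired_with <- c(3L, NA, NA, NA)
  expect_error(validate_state(st), "symmetric|homologs")
})

test_that("sampling grid starts at t = 0 and is strictly increasing", {
  ch <- chromosome_set(1)
  p <- sim_params(t_final = 100, sample_every = 7)  # not a divisor of t_final
  set.seed(3)
  tr <- simulate_trajectory(p, ch, seed = 3)
  tt <- unique(tr$time_s)
  expect_equal(tt[1], 0)
  expect_true(all(diff(tt) > 0))
  expect_lte(max(tt), p$t_final + 1e-9)
  expect_equal(max(tt), p$t_final)  # final state is always sampled
  expect_equal(unique(tr$time_h), display_hours(tt))
})

test_that("dumbbell bond forces are equal, opposite and linear", {
  p <- sim_params(dumbbell = TRUE)
  f <- dumbbell_bond_force(c(0.3, -0.1), p, bond_length = 0.4)
  expect_equal(f[1, ] + f[2, ], c(0, 0))
  expect_equal(f[1, ], 2 * (1 / 0.4^2) * p$D * c(0.3, -0.1))
  expect_equal(dumbbell_bond_force(c(0, 0), p), matrix(0, 2, 2))
  # bead 1 is pulled toward bead 2: force parallel to r
  expect_gt(sum(f[1, ] * c(0.3, -0.1)), 0)
})

test_that("free dumbbell equilibrates at <r^2> = ell^2 within 5%", {
  ch <- single_free_chromosome(ell = 0.4)
  p <- sim_params(v0 = 0, dumbbell = TRUE, t_final = 4e5, sample_every = 2,
                  nucleus_radius = 200)
  set.seed(8)
  st <- make_state(ch, positions = matrix(0, 1, 2))
  tr <- simulate_trajectory(p, ch, initial = st)
  b2 <- attr(tr, "bond_r2")
  keep <- seq_len(nrow(b2)) * p$sample_every > 4000  # burn-in ~10 OU times
  ratio <- mean(b2[keep, 1]) / 0.4^2
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
})

test_that("bisection calibration recovers the closed-form bond stiffness", {
  s <- calibrate_bond_stiffness(bond_length = 0.4, t_total = 30000,
                                t_burn = 3000, seed = 4, iter = 6)
  expect_gt(s, 0.85)
  expect_lt(s, 1.18)
})

test_that("dumbbell ensembles pair and their trajectories expose bond data", {
  sc <- build_scenario("dumbbell", t_final = 1800, sample_every = 30)
  tr <- simulate_trajectory(sc$params, sc$chromosomes, seed = 12)
  expect_false(is.null(attr(tr, "bond_r2")))
  # captured pairs report the held 50 nm distance like the single-bead model
  pd <- pair_distances(tr)
  if (any(pd$paired))
    expect_equal(unique(round(pd$distance_um[pd$paired], 9)), 0.05)
})
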
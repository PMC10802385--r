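test_that("pairing fraction handles saturated, empty and mixed fixtures", {
  fx <- fixture_trajectory()
  pf <- pairing_fraction(fx)
  expect_equal(pf$fraction, rep(0.5, nrow(pf)))
  expect_equal(pf$n_pairs, rep(2L, nrow(pf)))
  # all pairs pre-paired -> 1 everywhere; all far -> 0 everywhere
  both <- fx
  both$x_um[both$chrom_id == 3] <- 0.025
  both$x_um[both$chrom_id == 4] <- -0.025
  both$y_um[both$chrom_id %in% 3:4] <- 2
  expect_equal(pairing_fraction(both)$fraction, rep(1, nrow(pf)))
  none <- fx
  none$y_um[none$chrom_id == 2] <- 3  # break pair 1 apart
  expect_equal(pairing_fraction(none)$fraction, rep(0, nrow(pf)))
  # threshold is inclusive at exactly 400 nm
  at_thr <- fx
  at_thr$x_um[at_thr$chrom_id == 1] <- -2
  at_thr$x_um[at_thr$chrom_id == 2] <- -1.6
  at_thr$y_um[at_thr$chrom_id %in% 1:2] <- 0
  expect_equal(pairing_fraction(at_thr)$fraction, rep(0.5, nrow(pf)))
})

test_that("mismatched time grids across realizations are rejected", {
  a <- fixture_trajectory(times = c(0, 100, 200))
  b <- fixture_trajectory(times = c(0, 150, 300))
  b$realization <- 2L
  bad <- dplyr::bind_rows(a, b)
  attr(bad, "chromosomes") <- attr(a, "chromosomes")
  expect_error(pairing_fraction(bad), "time grid")
})

test_that("distance curves: degenerate single realization equals raw data", {
  fx <- fixture_trajectory(times = c(0, 7200, 14400, 21600))
  dc <- distance_curves(fx, at_hours = c(3, 5, 7, 9))
  expect_equal(unique(dc$sd_um), 0)
  expect_equal(dc$mean_um[dc$rank == 1], rep(0.05, 4))
  expect_equal(dc$mean_um[dc$rank == 2], rep(3, 4))
  # ranks follow ascending initial distance
  expect_lt(dc$index_value[dc$rank == 1][1], dc$index_value[dc$rank == 2][1])
})

test_that("size-indexed curves rank pairs by chromosome length", {
  sc <- build_scenario("size_adjusted", t_final = 600, sample_every = 300)
  tr <- simulate_ensemble(sc, realizations = 2, seed = 5)
  dc <- distance_curves(tr, index_by = "size", at_hours = c(3))
  ky <- sort(yeast_karyotype()$length_kbp)
  expect_equal(dc$index_value[order(dc$rank)], ky)
  expect_equal(nrow(dc), 16L)
})

test_that("matched control picks the best non-homolog and breaks ties low", {
  # geometry: pair 1 at distance 2; chromosome 3 sits exactly 2 from
  # chromosome 1 as well, so it is the optimal (equidistant) control
  ch <- chromosome_set(2)
  times <- c(0, 3600)
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(5, 5) / sqrt(2))
  tr <- tibble::tibble(
    realization = 1L,
    time_s = rep(times, each = 4),
    time_h = display_hours(rep(times, each = 4)),
    chrom_id = rep(1:4, 2),
    x_um = rep(pos[, 1], 2), y_um = rep(pos[, 2], 2),
    paired = FALSE, partner_id = NA_integer_)
  attr(tr, "chromosomes") <- ch
  cm <- matched_nonhomolog_control(tr, at_hours = c(3, 4))
  m1 <- cm$matches[cm$matches$chrom_id == 1, ]
  expect_equal(m1$control_id, 3L)
  expect_equal(m1$target_um, 2)
  expect_equal(m1$control_um, 2)
  # tie-break: put chromosomes 3 and 4 both at exactly 2 from chromosome 1
  pos2 <- rbind(c(0, 0), c(2, 0), c(0, 2), c(0, -2))
  tr2 <- tr
  tr2$x_um <- rep(pos2[, 1], 2); tr2$y_um <- rep(pos2[, 2], 2)
  attr(tr2, "chromosomes") <- ch
  m2 <- matched_nonhomolog_control(tr2)$matches
  expect_equal(m2$control_id[m2$chrom_id == 1], 3L)  # lowest id wins
  expect_error(matched_nonhomolog_control(
    tr[tr$chrom_id %in% 1:2, ], chromosomes = ch[1:2, ]), "two homolog")
})

test_that("residence times: empty when never close, exact on a step fixture", {
  fx <- fixture_trajectory()
  rt <- residence_times(fx, radius = 0.4)
  # only non-homolog pairings are scanned; all fixture non-homologs are far
  expect_equal(nrow(rt), 0L)
  # constructed visit: two non-homologs within radius for samples 3..5 of 8
  ch <- two_nonhomologs()
  times <- seq(0, 7, by = 1)
  dists <- c(1, 1, 0.2, 0.2, 0.2, 1, 1, 1)
  tr <- tibble::tibble(
    realization = 1L,
    time_s = rep(times, each = 2),
    time_h = display_hours(rep(times, each = 2)),
    chrom_id = rep(1:2, 8),
    x_um = as.vector(rbind(0, dists)),
    y_um = 0, paired = FALSE, partner_id = NA_integer_)
  attr(tr, "chromosomes") <- ch
  rt <- residence_times(tr, radius = 0.4)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$enter_s, 2)
  expect_equal(rt$duration_s, 3)  # leaves the radius at t = 5
})

test_that("head-on non-homolog crossing matches the quadrature oracle", {
  # relative coordinate driven only by the C_r Yukawa term: v0 = 0, D = 0,
  # excluded volume off; released at 50 nm, residence ends at 400 nm.
  # t = (ell^2 / (2 C_r)) (e^{b/ell} - e^{a/ell}) by separating variables.
  ch <- two_nonhomologs()
  run <- function(C_r) {
    fp <- force_params(C_a = 0, C_r = C_r, C_r1 = 0)
    p <- sim_params(v0 = 0, D = 0, dt = 0.01, t_final = 120,
                    sample_every = 0.1, force = fp, nucleus_radius = 50)
    st <- make_state(ch, positions = rbind(c(-0.025, 0), c(0.025, 0)))
    tr <- simulate_trajectory(p, ch, initial = st)
    residence_times(tr, radius = 0.4)$duration_s[1]
  }
  oracle <- function(C_r, a = 0.05, b = 0.4, ell = 0.4)
    (ell^2 / (2 * C_r)) * (exp(b / ell) - exp(a / ell))
  t1 <- run(0.005)
  expect_equal(t1, oracle(0.005), tolerance = 0.02)
  # doubling the repulsive strength halves the crossing time exactly here
  t2 <- run(0.010)
  expect_equal(t1 / t2, 2, tolerance = 0.02)
})

test_that("tidiers summarize trajectories and controls", {
  fx <- fixture_trajectory(times = c(0, 21600))
  td <- tidy(fx)
  expect_named(td, c("realization", "pair_id", "time_s", "time_h",
                     "distance_um", "paired"))
  g <- glance(fx)
  expect_equal(g$final_fraction, 0.5)
  expect_equal(g$n_pairs, 2L)
  expect_equal(g$t_final_h, 9)
})

test_that("plot helpers return ggplot objects", {
  fx <- fixture_trajectory(times = c(0, 10800, 21600))
  expect_s3_class(plot_pairing_fraction(pairing_fraction(fx)), "ggplot")
  expect_s3_class(autoplot(distance_curves(fx, at_hours = c(3, 9))), "ggplot")
  expect_s3_class(plot_nucleus(fx), "ggplot")
})
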
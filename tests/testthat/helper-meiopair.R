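# Shared fixtures for the test suite. Everything is generated in code; the
# heavier Monte-Carlo ensembles used by the acceptance criteria are cached in
# this environment so several criteria can share one run.

.accept_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .accept_cache)) {
    assign(key, force(expr), envir = .accept_cache)
  }
  get(key, envir = .accept_cache)
}

# a single chromosome with no homolog partner (free agent)
single_free_chromosome <- function(ell = 0.4) {
  tibble::tibble(chrom_id = 1L, pair_id = 1L, homolog_id = NA_integer_,
                 name = "solo", length_kbp = 750, ell_a = ell, ell_r = ell)
}

# two non-homologous chromosomes (no partner present in the simulation)
two_nonhomologs <- function(ell = 0.4) {
  tibble::tibble(chrom_id = 1:2, pair_id = 1:2,
                 homolog_id = NA_integer_, name = c("a", "b"),
                 length_kbp = 750, ell_a = ell, ell_r = ell)
}

make_state <- function(chromosomes, positions, orientations = NULL) {
  n <- nrow(positions)
  if (is.null(orientations)) {
    orientations <- matrix(rep(c(1, 0), each = n), n, 2L)
  }
  new_state(chromosomes, positions = positions, orientations = orientations)
}

# fraction paired at the displayed hour nearest `hour`
fraction_at <- function(traj, hour) {
  pf <- pairing_fraction(traj)
  pf$fraction[which.min(abs(pf$time_h - hour))]
}
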
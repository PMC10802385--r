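#' Tidy and summarize pairing results
#'
#' `tidy()` on a `pairing_trajectory` returns the per-pair distance table
#' (one row per realization x pair x time); `glance()` condenses the run to
#' one row. `tidy()` on a `control_match` returns its matched-control
#' curves.
#'
#' @param x A `pairing_trajectory` or `control_match`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pairing_trajectory <- function(x, ...) pair_distances(x)

#' @rdname tidy.pairing_trajectory
#' @export
glance.pairing_trajectory <- function(x, ...) {
  pf <- pairing_fraction(x)
  ch <- traj_chromosomes(x)
  tibble::tibble(
    realizations = dplyr::n_distinct(x$realization),
    n_pairs = dplyr::n_distinct(ch$pair_id),
    t_final_h = max(x$time_h),
    final_fraction = pf$fraction[nrow(pf)],
    mean_capture_h = {
      ct <- attr(x, "capture_times")
      if (is.null(ct) || nrow(ct) == 0L) NA_real_
      else mean(display_hours(ct$capture_s))
    })
}

#' @rdname tidy.pairing_trajectory
#' @export
tidy.control_match <- function(x, ...) x$curves

#' @rdname tidy.pairing_trajectory
#' @export
glance.control_match <- function(x, ...) {
  cv <- x$curves
  first <- cv[cv$time_h == min(cv$time_h), ]
  last <- cv[cv$time_h == max(cv$time_h), ]
  tibble::tibble(
    n_chromosomes = dplyr::n_distinct(x$matches$chrom_id),
    mean_um_start = mean(first$mean_um),
    mean_um_end = mean(last$mean_um))
}
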
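traj_chromosomes <- function(traj, chromosomes = NULL) {
  if (!is.null(chromosomes)) return(chromosomes)
  ch <- attr(traj, "chromosomes")
  if (!is.null(ch)) return(ch)
  # fall back on the layout convention: chromosomes 2k-1 and 2k are homologs
  ids <- sort(unique(traj$chrom_id))
  if (length(ids) %% 2L != 0L)
    abort("odd number of chromosomes and no `chromosomes` table supplied")
  n_pairs <- length(ids) / 2L
  chromosome_set(n_pairs)[, c("chrom_id", "pair_id", "homolog_id")] |>
    dplyr::mutate(chrom_id = ids[.data$chrom_id],
                  homolog_id = ids[.data$homolog_id])
}

#' Homolog pair distances over time
#'
#' Tidy per-pair center-to-center distances, one row per realization x pair x
#' sample time. Captured pairs sit at the held separation (50 nm by
#' default), which is what the distance reflects after capture.
#'
#' @param traj A `pairing_trajectory` tibble.
#' @param chromosomes Optional [chromosome_set()] if `traj` lacks the
#'   attribute (e.g. read from CSV).
#' @return Tibble: `realization`, `pair_id`, `time_s`, `time_h`,
#'   `distance_um`, `paired`.
#' @export
pair_distances <- function(traj, chromosomes = NULL) {
  ch <- traj_chromosomes(traj, chromosomes)
  reps <- ch[ch$chrom_id < ch$homolog_id, , drop = FALSE]
  a <- dplyr::inner_join(
    traj, tibble::tibble(chrom_id = reps$chrom_id, pair_id = reps$pair_id,
                         mate_id = reps$homolog_id),
    by = "chrom_id")
  b <- dplyr::select(traj, "realization", "time_s",
                     mate_id = "chrom_id", mx = "x_um", my = "y_um")
  dplyr::inner_join(a, b, by = c("realization", "time_s", "mate_id")) |>
    dplyr::transmute(
      realization = .data$realization,
      pair_id = .data$pair_id,
      time_s = .data$time_s,
      time_h = .data$time_h,
      distance_um = sqrt((.data$x_um - .data$mx)^2 + (.data$y_um - .data$my)^2),
      paired = .data$paired)
}

#' Ensemble pairing fraction over time
#'
#' Fraction of homolog pairs whose members are within the pairing threshold,
#' pooled over pairs and realizations (denominator `n_pairs x
#' realizations`). Inherits monotonicity from capture permanence when applied
#' to simulated trajectories.
#'
#' @param traj A `pairing_trajectory` (or any tibble with the trajectory
#'   schema; all realizations must share one time grid).
#' @param threshold Pairing distance threshold (um).
#' @param chromosomes Optional [chromosome_set()].
#' @return Tibble of class `pairing_fraction`: `time_s`, `time_h`,
#'   `n_pairs`, `fraction`.
#' @export
pairing_fraction <- function(traj, threshold = 0.4, chromosomes = NULL) {
  pd <- pair_distances(traj, chromosomes)
  grids <- pd |>
    dplyr::group_by(.data$realization) |>
    dplyr::summarise(key = paste(sort(unique(.data$time_s)), collapse = ","))
  if (dplyr::n_distinct(grids$key) > 1L)
    abort("realizations do not share a common time grid")
  out <- pd |>
    dplyr::group_by(.data$time_s, .data$time_h) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     fraction = mean(.data$distance_um <= threshold),
                     .groups = "drop")
  class(out) <- c("pairing_fraction", class(out))
  out
}

#' Ensemble distance curves indexed by initial distance or chromosome size
#'
#' Within each realization, homolog pairs are ranked either by their
#' center-to-center distance at the first sample (ascending initial
#' distance) or by physical chromosome length; distances are then averaged
#' across realizations at matched rank, reported at the requested displayed
#' times. Ties in the ranking key break by `pair_id`.
#'
#' @param traj A `pairing_trajectory`.
#' @param index_by `"initial_distance"` or `"size"`.
#' @param at_hours Displayed times to report (nearest sample is used).
#' @param chromosomes Optional [chromosome_set()].
#' @return Tibble of class `distance_curves`: `rank`, `index_value`,
#'   `time_h`, `mean_um`, `sd_um`, `n`.
#' @export
distance_curves <- function(traj, index_by = c("initial_distance", "size"),
                            at_hours = c(3, 5, 7, 9), chromosomes = NULL) {
  index_by <- match.arg(index_by)
  ch <- traj_chromosomes(traj, chromosomes)
  pd <- pair_distances(traj, ch)
  if (nrow(pd) == 0L) abort("empty trajectory")
  ranks <- if (index_by == "initial_distance") {
    pd |>
      dplyr::filter(.data$time_s == min(.data$time_s)) |>
      dplyr::group_by(.data$realization) |>
      dplyr::arrange(.data$distance_um, .data$pair_id, .by_group = TRUE) |>
      dplyr::mutate(rank = dplyr::row_number(),
                    index_value = .data$distance_um) |>
      dplyr::ungroup() |>
      dplyr::select("realization", "pair_id", "rank", "index_value")
  } else {
    len <- ch |>
      dplyr::distinct(.data$pair_id, .data$length_kbp) |>
      dplyr::arrange(.data$length_kbp, .data$pair_id) |>
      dplyr::mutate(rank = dplyr::row_number())
    tidyr::expand_grid(realization = unique(pd$realization),
                       len[, c("pair_id", "rank", "length_kbp")]) |>
      dplyr::rename(index_value = "length_kbp")
  }
  tt <- sort(unique(pd$time_h))
  pick <- vapply(at_hours, function(h) tt[which.min(abs(tt - h))], numeric(1))
  out <- pd |>
    dplyr::inner_join(ranks, by = c("realization", "pair_id")) |>
    dplyr::filter(.data$time_h %in% pick) |>
    dplyr::group_by(.data$rank, .data$time_h) |>
    dplyr::summarise(index_value = mean(.data$index_value),
                     mean_um = mean(.data$distance_um),
                     sd_um = sd(.data$distance_um),
                     n = dplyr::n(), .groups = "drop")
  out$sd_um[is.na(out$sd_um)] <- 0
  attr(out, "index_by") <- index_by
  class(out) <- c("distance_curves", class(out))
  out
}

#' Matched non-homolog control distances
#'
#' For every chromosome, selects the non-homologous chromosome whose
#' distance at the first sample best matches the chromosome's distance to
#' its own homolog (ties break toward the lowest chromosome id), then tracks
#' that control pair's distance over time. Non-homolog distances are
#' expected to stay statistically stationary while homolog distances shrink.
#'
#' @inheritParams distance_curves
#' @return A list of class `control_match` with elements `matches` (tibble:
#'   realization, chrom_id, control_id, target_um, control_um) and `curves`
#'   (tibble: rank, time_h, mean_um, sd_um, n — ranked by the homolog's
#'   initial distance, as for [distance_curves()]).
#' @export
matched_nonhomolog_control <- function(traj, at_hours = c(3, 5, 7, 9),
                                       chromosomes = NULL) {
  ch <- traj_chromosomes(traj, chromosomes)
  if (dplyr::n_distinct(ch$pair_id) < 2L)
    abort("need at least two homolog classes to build a non-homolog control")
  t0 <- min(traj$time_s)
  base <- traj |>
    dplyr::filter(.data$time_s == t0) |>
    dplyr::select("realization", "chrom_id", "x_um", "y_um")
  hom_map <- tibble::tibble(chrom_id = ch$chrom_id, mate_id = ch$homolog_id,
                            pair_id = ch$pair_id)
  # all ordered chromosome pairs at t0, flagged homolog / non-homolog
  cand <- base |>
    dplyr::inner_join(hom_map, by = "chrom_id") |>
    dplyr::inner_join(base |> dplyr::rename(other_id = "chrom_id",
                                            ox = "x_um", oy = "y_um"),
                      by = "realization", relationship = "many-to-many") |>
    dplyr::filter(.data$other_id != .data$chrom_id) |>
    dplyr::mutate(d0 = sqrt((.data$x_um - .data$ox)^2 +
                            (.data$y_um - .data$oy)^2))
  target <- cand |>
    dplyr::filter(.data$other_id == .data$mate_id) |>
    dplyr::select("realization", "chrom_id", target_um = "d0")
  matches <- cand |>
    dplyr::filter(.data$other_id != .data$mate_id) |>
    dplyr::inner_join(target, by = c("realization", "chrom_id")) |>
    dplyr::group_by(.data$realization, .data$chrom_id) |>
    dplyr::arrange(abs(.data$d0 - .data$target_um), .data$other_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("realization", "chrom_id", control_id = "other_id",
                  target_um = "target_um", control_um = "d0")
  # control distance curves over time, ranked by the homolog initial distance
  ranked <- matches |>
    dplyr::group_by(.data$realization) |>
    dplyr::arrange(.data$target_um, .data$chrom_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  a <- traj |> dplyr::select("realization", "time_s", "time_h",
                             "chrom_id", "x_um", "y_um")
  b <- traj |> dplyr::select("realization", "time_s",
                             control_id = "chrom_id", cx = "x_um", cy = "y_um")
  tt <- sort(unique(traj$time_h))
  pick <- vapply(at_hours, function(h) tt[which.min(abs(tt - h))], numeric(1))
  curves <- ranked |>
    dplyr::inner_join(a, by = c("realization", "chrom_id"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(b, by = c("realization", "time_s", "control_id")) |>
    dplyr::filter(.data$time_h %in% pick) |>
    dplyr::mutate(distance_um = sqrt((.data$x_um - .data$cx)^2 +
                                     (.data$y_um - .data$cy)^2)) |>
    dplyr::group_by(.data$rank, .data$time_h) |>
    dplyr::summarise(mean_um = mean(.data$distance_um),
                     sd_um = sd(.data$distance_um),
                     n = dplyr::n(), .groups = "drop")
  curves$sd_um[is.na(curves$sd_um)] <- 0
  structure(list(matches = matches, curves = curves), class = "control_match")
}

#' @export
print.control_match <- function(x, ...) {
  cat(sprintf("<control_match> %d matched chromosomes, %d realizations\n",
              dplyr::n_distinct(x$matches$chrom_id),
              dplyr::n_distinct(x$matches$realization)))
  invisible(x)
}

#' Non-homolog residence times
#'
#' Durations of maximal contiguous intervals during which a non-homologous
#' chromosome pair stays within the given radius, pooled over pairs and
#' realizations. Doubling the non-homolog repulsion strength is expected to
#' halve the mean residence time in the force-dominated regime. Sample the
#' trajectory densely (`sample_every` at or below 1 s) for this analysis;
#' durations are resolved to the sampling interval.
#'
#' @param traj A `pairing_trajectory`.
#' @param radius Proximity radius (um).
#' @param chromosomes Optional [chromosome_set()].
#' @return Tibble: `realization`, `chrom_i`, `chrom_j`, `enter_s`,
#'   `duration_s` (one row per contiguous visit; empty if no pair ever comes
#'   within `radius`).
#' @export
residence_times <- function(traj, radius = 0.4, chromosomes = NULL) {
  ch <- traj_chromosomes(traj, chromosomes)
  ids <- ch$chrom_id
  hom <- setNames(ch$homolog_id, ch$chrom_id)
  prs <- utils::combn(ids, 2L)
  keep <- vapply(seq_len(ncol(prs)), function(k) {
    h <- hom[as.character(prs[1L, k])]
    is.na(h) || h != prs[2L, k]
  }, logical(1))
  prs <- prs[, keep, drop = FALSE]
  a <- traj |> dplyr::select("realization", "time_s", "chrom_id",
                             "x_um", "y_um")
  out <- list()
  dt_grid <- NULL
  for (r in unique(traj$realization)) {
    ar <- a[a$realization == r, , drop = FALSE]
    tt <- sort(unique(ar$time_s))
    if (length(tt) > 1L) dt_grid <- min(diff(tt))
    wide_x <- matrix(NA_real_, length(tt), length(ids),
                     dimnames = list(NULL, ids))
    wide_y <- wide_x
    for (id in ids) {
      sub <- ar[ar$chrom_id == id, , drop = FALSE]
      sub <- sub[order(sub$time_s), , drop = FALSE]
      wide_x[, as.character(id)] <- sub$x_um
      wide_y[, as.character(id)] <- sub$y_um
    }
    for (k in seq_len(ncol(prs))) {
      i <- as.character(prs[1L, k]); j <- as.character(prs[2L, k])
      close <- sqrt((wide_x[, i] - wide_x[, j])^2 +
                    (wide_y[, i] - wide_y[, j])^2) < radius
      rl <- rle(close)
      if (!any(rl$values)) next
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      vis <- which(rl$values)
      out[[length(out) + 1L]] <- tibble::tibble(
        realization = r,
        chrom_i = prs[1L, k], chrom_j = prs[2L, k],
        enter_s = tt[starts[vis]],
        duration_s = (tt[pmin(ends[vis] + 1L, length(tt))] - tt[starts[vis]]))
    }
  }
  if (!length(out))
    return(tibble::tibble(realization = integer(), chrom_i = integer(),
                          chrom_j = integer(), enter_s = numeric(),
                          duration_s = numeric()))
  dplyr::bind_rows(out)
}
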
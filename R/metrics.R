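# Quantifications computed on simulation snapshots and track tables.
#
# All functions are pure: the same snapshot/track input (and seed, where
# pair sampling is involved) gives the same output. Track tables are plain
# tibbles with columns (replicate,) cell_id/id, kind, minute, x_um, y_um, so
# any conforming table - not only simulator output - can be analyzed.

CELL_DIAMETER_UM <- 20  # cell diameter at the end of epiboly

norm_tracks <- function(tracks) {
  if ("cell_id" %in% names(tracks) && !"id" %in% names(tracks))
    tracks <- dplyr::rename(tracks, id = "cell_id")
  if (!"replicate" %in% names(tracks)) tracks$replicate <- 1L
  stopifnot(all(c("id", "minute", "x_um", "y_um") %in% names(tracks)))
  tracks
}

#' Tissue thickness in cell-diameter units
#'
#' At `n_positions` evenly spaced columns within the anchor span, measures
#' the vertical extent of the contiguous block of cell-occupied sites
#' (SC + DC, separator included) containing the separator row, and divides
#' by the 20-um reference cell diameter. Columns without cells are excluded.
#'
#' @param state a `cpm_state`.
#' @param n_positions number of measurement columns (10 in the standard
#'   protocol).
#' @param x_range optional `c(min, max)` site columns restricting the
#'   measured region (e.g. the active region of a localized source);
#'   defaults to the anchor span.
#' @return tibble with `position`, `x_um` and `thickness` (cell diameters);
#'   excluded columns are dropped.
#' @export
tissue_thickness <- function(state, n_positions = 10, x_range = NULL) {
  g <- state$geom
  if (g$sep_row < 0) stop("thickness is defined for the tissue section only")
  if (is.null(x_range)) x_range <- c(g$anchor_lx + 2, g$anchor_rx - 2)
  cols <- round(seq(x_range[1], x_range[2], length.out = n_positions))
  purrr::map_dfr(seq_along(cols), function(i) {
    x <- cols[i]
    col <- state$labels[x, ]
    tissue <- col >= LAB_CELL0 | col == LAB_SEP
    if (!any(col >= LAB_CELL0)) return(NULL)    # no cells: excluded
    # contiguous run containing the separator row
    y <- g$sep_row
    lo <- y; while (lo > 1 && tissue[lo - 1]) lo <- lo - 1
    hi <- y; while (hi < length(col) && tissue[hi + 1]) hi <- hi + 1
    if (!any(col[lo:hi] >= LAB_CELL0)) return(NULL)
    tibble::tibble(position = i, x_um = (x - 0.5) * g$spacing,
                   thickness = (hi - lo + 1) * g$spacing / CELL_DIAMETER_UM)
  })
}

#' Cell-layer count
#'
#' Counts, per measurement column, the number of distinct deep cells stacked
#' vertically within the tissue block, plus one for the superficial layer.
#'
#' @inheritParams tissue_thickness
#' @return tibble with `position`, `x_um` and `layers`.
#' @export
count_layers <- function(state, n_positions = 10) {
  g <- state$geom
  if (g$sep_row < 0) stop("layer counts are defined for the tissue section only")
  kind_by_id <- stats::setNames(state$cells$kind, state$cells$id)
  cols <- round(seq(g$anchor_lx + 2, g$anchor_rx - 2,
                    length.out = n_positions))
  purrr::map_dfr(seq_along(cols), function(i) {
    x <- cols[i]
    col <- state$labels[x, ]
    tissue <- col >= LAB_CELL0 | col == LAB_SEP
    if (!any(col >= LAB_CELL0)) return(NULL)
    y <- g$sep_row
    lo <- y; while (lo > 1 && tissue[lo - 1]) lo <- lo - 1
    hi <- y; while (hi < length(col) && tissue[hi + 1]) hi <- hi + 1
    ids <- unique(col[lo:hi][col[lo:hi] >= LAB_CELL0])
    n_dc <- sum(kind_by_id[as.character(ids)] == "DC", na.rm = TRUE)
    tibble::tibble(position = i, x_um = (x - 0.5) * g$spacing,
                   layers = n_dc + 1)
  })
}

#' Pairwise tissue expansion E
#'
#' For sampled same-kind cell pairs present at both `t_i` and `t_f`,
#' computes `E = (d_f - d_i) / d_i` where `d_i`, `d_f` are the initial and
#' final pair distances, the standard cell-pair expansion measure. Pair
#' sampling is seeded and therefore reproducible; expansion is
#' scale-invariant in the coordinate units.
#'
#' @param tracks a track tibble.
#' @param t_i,t_f initial and final minutes (nearest recorded minute is
#'   used).
#' @param kinds cell kinds to include.
#' @param n_pairs pairs sampled per replicate.
#' @param seed sampling seed.
#' @return tibble with one row per sampled pair: `replicate`, `id1`, `id2`,
#'   `d_i`, `d_f`, `E`.
#' @export
expansion <- function(tracks, t_i, t_f, kinds = "DC", n_pairs = 50,
                      seed = 1) {
  tracks <- norm_tracks(tracks)
  if ("kind" %in% names(tracks)) tracks <- tracks[tracks$kind %in% kinds, ]
  purrr::map_dfr(unique(tracks$replicate), function(r) {
    tr <- tracks[tracks$replicate == r, ]
    ti <- tr$minute[which.min(abs(tr$minute - t_i))]
    tf <- tr$minute[which.min(abs(tr$minute - t_f))]
    p0 <- tr[tr$minute == ti, c("id", "x_um", "y_um")]
    p1 <- tr[tr$minute == tf, c("id", "x_um", "y_um")]
    ids <- intersect(p0$id, p1$id)
    if (length(ids) < 2) stop("fewer than 2 cells present at both times")
    pairs <- t(utils::combn(sort(ids), 2))
    withr::with_seed(seed + r, {
      if (nrow(pairs) > n_pairs)
        pairs <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
    })
    i0 <- match(pairs[, 1], p0$id); j0 <- match(pairs[, 2], p0$id)
    i1 <- match(pairs[, 1], p1$id); j1 <- match(pairs[, 2], p1$id)
    d_i <- sqrt((p0$x_um[i0] - p0$x_um[j0])^2 + (p0$y_um[i0] - p0$y_um[j0])^2)
    d_f <- sqrt((p1$x_um[i1] - p1$x_um[j1])^2 + (p1$y_um[i1] - p1$y_um[j1])^2)
    tibble::tibble(replicate = r, id1 = pairs[, 1], id2 = pairs[, 2],
                   d_i = d_i, d_f = d_f, E = (d_f - d_i) / d_i)
  })
}

#' Deep-cell intercalation events by band crossing
#'
#' Detects crossings of the lower boundary of the sub-separator band (the
#' DC stratum within `band_depth_um` of the basal separator). A deep cell
#' whose centroid rises into the band is an `Out` event (movement toward the
#' SL); one dropping out of the band is an `In` event. A hysteresis margin
#' suppresses double-counting of rapid fluctuations around the boundary.
#'
#' @param tracks a track tibble (deep cells only are used).
#' @param sep_y_um y position of the separator row, um (for simulator
#'   output, `state$geom$sep_row * state$geom$spacing`).
#' @param band_depth_um band depth below the separator (one 20-um cell
#'   diameter by default).
#' @param hysteresis_um hysteresis margin (0.25 cell diameters by default).
#' @return tibble of events: `replicate`, `id`, `minute`, `direction`
#'   (`"Out"`/`"In"`).
#' @export
intercalation_events <- function(tracks, sep_y_um, band_depth_um = 20,
                                 hysteresis_um = 5) {
  tracks <- norm_tracks(tracks)
  if ("kind" %in% names(tracks)) tracks <- tracks[tracks$kind == "DC", ]
  b <- sep_y_um - band_depth_um
  hi <- b + hysteresis_um; lo <- b - hysteresis_um
  tracks |>
    dplyr::arrange(.data$replicate, .data$id, .data$minute) |>
    dplyr::group_by(.data$replicate, .data$id) |>
    dplyr::group_modify(function(df, key) {
      y <- df$y_um
      state <- y[1] > b
      out <- integer(); dir <- character()
      for (i in seq_along(y)[-1]) {
        if (!state && y[i] > hi) {
          state <- TRUE; out <- c(out, i); dir <- c(dir, "Out")
        } else if (state && y[i] < lo) {
          state <- FALSE; out <- c(out, i); dir <- c(dir, "In")
        }
      }
      tibble::tibble(minute = df$minute[out], direction = dir)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(id = "id")
}

#' Intercalation percentages and event-direction fractions
#'
#' @inheritParams intercalation_events
#' @return one-row tibble: `n_events`, `out_frac`, `in_frac` (fractions of
#'   events directed toward / away from the SL; they sum to 1),
#'   `intercalation_pct` (cells with at least one event over cells observed
#'   in the band), `n_observed`.
#' @export
intercalation_summary <- function(tracks, sep_y_um, band_depth_um = 20,
                                  hysteresis_um = 5) {
  tracks <- norm_tracks(tracks)
  ev <- intercalation_events(tracks, sep_y_um, band_depth_um, hysteresis_um)
  b <- sep_y_um - band_depth_um
  dc <- if ("kind" %in% names(tracks)) tracks[tracks$kind == "DC", ] else tracks
  observed <- unique(dc$id[dc$y_um > b])
  n_out <- sum(ev$direction == "Out"); n_in <- sum(ev$direction == "In")
  n_ev <- n_out + n_in
  tibble::tibble(
    n_events = n_ev,
    out_frac = if (n_ev > 0) n_out / n_ev else NA_real_,
    in_frac = if (n_ev > 0) n_in / n_ev else NA_real_,
    intercalation_pct = if (length(observed) > 0)
      length(unique(ev$id)) / length(observed) else NA_real_,
    n_observed = length(observed))
}

#' Chemotaxis index of an explant
#'
#' The chemotaxis index is the net displacement of the deep-cell cluster
#' centroid toward the target, divided by the total path length of the
#' centroid: 1 for a straight approach, about 0 for an unbiased walk, -1
#' for a straight retreat.
#'
#' @param tracks a track tibble (DC rows are used when a `kind` column is
#'   present).
#' @param target `c(x_um, y_um)` of the attractant source.
#' @return one-row tibble: `ci`, `net_toward`, `path_length`, `flag`
#'   (`"zero_path"` when the centroid never moved, in which case `ci` is 0).
#' @export
chemotaxis_index <- function(tracks, target) {
  tracks <- norm_tracks(tracks)
  if ("kind" %in% names(tracks)) tracks <- tracks[tracks$kind == "DC", ]
  cen <- tracks |>
    dplyr::group_by(.data$minute) |>
    dplyr::summarise(x = mean(.data$x_um), y = mean(.data$y_um),
                     .groups = "drop") |>
    dplyr::arrange(.data$minute)
  if (nrow(cen) < 2) stop("need at least two time points")
  steps <- sqrt(diff(cen$x)^2 + diff(cen$y)^2)
  path <- sum(steps)
  v0 <- c(target[1] - cen$x[1], target[2] - cen$y[1])
  u <- v0 / sqrt(sum(v0^2))
  net <- (cen$x[nrow(cen)] - cen$x[1]) * u[1] +
    (cen$y[nrow(cen)] - cen$y[1]) * u[2]
  if (path == 0)
    return(tibble::tibble(ci = 0, net_toward = 0, path_length = 0,
                          flag = "zero_path"))
  tibble::tibble(ci = net / path, net_toward = net, path_length = path,
                 flag = "")
}

#' Displacement-direction histogram
#'
#' Bins per-step deep-cell displacement angles relative to the outward SL
#' normal: 0 degrees points toward the SL, 180 degrees away from it. The
#' in-silico counterpart of protrusion-angle measurements.
#'
#' @param tracks a track tibble.
#' @param binwidth bin width in degrees.
#' @return tibble with `bin_lo`, `bin_hi`, `bin_mid`, `count`; mean step
#'   angle in `attr(, "mean_angle")`.
#' @export
displacement_direction_histogram <- function(tracks, binwidth = 10) {
  tracks <- norm_tracks(tracks)
  if ("kind" %in% names(tracks)) tracks <- tracks[tracks$kind == "DC", ]
  ang <- tracks |>
    dplyr::arrange(.data$replicate, .data$id, .data$minute) |>
    dplyr::group_by(.data$replicate, .data$id) |>
    dplyr::reframe(dx = diff(.data$x_um), dy = diff(.data$y_um)) |>
    dplyr::filter(.data$dx != 0 | .data$dy != 0) |>
    dplyr::mutate(angle = acos(.data$dy / sqrt(.data$dx^2 + .data$dy^2)) *
                    180 / pi)
  breaks <- seq(0, 180, by = binwidth)
  cut_idx <- findInterval(ang$angle, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  out <- tibble::tibble(bin_lo = breaks[-length(breaks)],
                        bin_hi = breaks[-1],
                        bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
                        count = tabulate(cut_idx, nbins = length(breaks) - 1))
  attr(out, "mean_angle") <- mean(ang$angle)
  out
}
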
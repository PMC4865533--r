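# R-side driver for the compiled Metropolis engine.

cells_cpp <- function(cells) {
  list(id = as.integer(cells$id),
       kind = ifelse(cells$kind == "DC", 0L, 1L),
       target_volume = as.numeric(cells$target_volume),
       frozen = cells$frozen,
       c0 = as.numeric(cells$c0))
}

bonds_cpp <- function(bonds) {
  list(a = as.integer(bonds$a), b = as.integer(bonds$b),
       active = bonds$active, d0 = as.numeric(bonds$d0))
}

links_cpp <- function(links) {
  list(dc = as.integer(links$dc), sc = as.integer(links$sc),
       rest = as.numeric(links$rest), age = as.integer(links$age))
}

geom_cpp <- function(geom) {
  list(spacing = geom$spacing, sep_row = as.integer(geom$sep_row),
       anchor_lx = as.integer(geom$anchor_lx),
       anchor_rx = as.integer(geom$anchor_rx))
}

state_params <- function(state, energy, chemo, links, mcs_min = 0.015) {
  params_cpp(energy, chemo, links,
             boundary = !state$geom$explant,
             replenish = !state$geom$explant,
             dc_c0 = if (chemo$pattern == "ubiquitous") chemo$c0 else 0,
             mcs_min = mcs_min,
             clamp = state$geom$clamp)
}

#' Advance a simulation state by whole sweeps
#'
#' Runs `n_sweeps` Monte Carlo sweeps (one sweep = one copy attempt per
#' mutable site, 0.1 simulated minutes), interleaving the chemoattractant
#' diffusion-decay substeps, elastic-link updates, SL cohesion enforcement
#' and the lateral boundary rules after every sweep.
#'
#' @param state a `cpm_state`.
#' @param n_sweeps number of sweeps to run.
#' @param energy,chemo,links parameter objects; see [energy_params()],
#'   [chemo_params()], [link_params()].
#' @param seed integer seed for the engine's generator; drawn from the R
#'   session RNG when `NULL`.
#' @param mcs_min simulated minutes per sweep (time resolution of the
#'   Metropolis dynamics; chemoattractant stepping, link/bond updates and
#'   boundary rules run on a fixed 0.1-minute tick).
#' @return the advanced `cpm_state`; per-minute centroid records accumulate
#'   in `attr(, "tracks")` as a tibble (minute, id, kind, x_um, y_um,
#'   volume).
#' @export
advance <- function(state, n_sweeps, energy = energy_params(),
                    chemo = chemo_params(), links = link_params(),
                    seed = NULL, mcs_min = 0.015) {
  if (n_sweeps <= 0) return(state)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  p <- state_params(state, energy, chemo, links, mcs_min = mcs_min)
  res <- cpm_advance_cpp(state$labels, state$conc,
                         cells_cpp(state$cells), bonds_cpp(state$bonds),
                         links_cpp(state$links), p, geom_cpp(state$geom),
                         as.integer(n_sweeps), seed, state$time_min)
  old <- state$cells
  cc <- res$cells
  cells <- tibble::tibble(id = cc$id,
                          kind = ifelse(cc$kind == 0L, "DC", "SC"),
                          volume = cc$volume, target_volume = cc$target_volume,
                          frozen = cc$frozen, c0 = cc$c0,
                          division_time = NA_real_, divided = TRUE,
                          cx = cc$cx, cy = cc$cy)
  m <- match(cells$id, old$id)
  known <- !is.na(m)
  cells$division_time[known] <- old$division_time[m[known]]
  cells$divided[known] <- old$divided[m[known]]

  state$labels <- res$labels
  state$conc <- res$conc
  state$cells <- cells
  state$bonds <- tibble::as_tibble(res$bonds)
  state$links <- tibble::as_tibble(res$links)
  state$time_min <- res$time_min
  state$counters$inserted <- state$counters$inserted + length(res$inserted)
  state$counters$removed <- state$counters$removed + length(res$removed)
  state$counters$frozen <- state$counters$frozen + length(res$frozen_events)
  ev <- state$events
  add_ev <- function(ev, ids, type) {
    if (length(ids) == 0) return(ev)
    dplyr::bind_rows(ev, tibble::tibble(minute = res$time_min, type = type,
                                        id = as.integer(ids), detail = ""))
  }
  ev <- add_ev(ev, res$inserted, "replenish")
  ev <- add_ev(ev, res$frozen_events, "freeze")
  ev <- add_ev(ev, res$removed, "remove")
  state$events <- ev

  trk <- res$tracks
  if (nrow(trk) > 0) {
    sp <- state$geom$spacing
    tr <- tibble::tibble(minute = trk[, 1], id = as.integer(trk[, 2]),
                         kind = ifelse(trk[, 3] == 0, "DC", "SC"),
                         x_um = (trk[, 4] - 0.5) * sp,
                         y_um = (trk[, 5] - 0.5) * sp,
                         volume = trk[, 6])
    attr(state, "tracks") <- dplyr::bind_rows(attr(state, "tracks"), tr)
  }
  state
}

#' One Metropolis sweep
#'
#' Convenience wrapper around [advance()] for a single sweep; returns the
#' number of accepted copy attempts in `attr(, "accepted")`.
#'
#' @inheritParams advance
#' @return the advanced `cpm_state`.
#' @export
metropolis_sweep <- function(state, energy = energy_params(),
                             chemo = chemo_params(), links = link_params(),
                             seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  p <- state_params(state, energy, chemo, links)
  res <- cpm_advance_cpp(state$labels, state$conc, cells_cpp(state$cells),
                         bonds_cpp(state$bonds), links_cpp(state$links), p,
                         geom_cpp(state$geom), 1L, seed, state$time_min)
  out <- advance_merge_single(state, res)
  attr(out, "accepted") <- res$accepted
  out
}

advance_merge_single <- function(state, res) {
  # shared merge used by metropolis_sweep (no track handling needed)
  old <- state$cells
  cc <- res$cells
  cells <- tibble::tibble(id = cc$id,
                          kind = ifelse(cc$kind == 0L, "DC", "SC"),
                          volume = cc$volume, target_volume = cc$target_volume,
                          frozen = cc$frozen, c0 = cc$c0,
                          division_time = NA_real_, divided = TRUE,
                          cx = cc$cx, cy = cc$cy)
  m <- match(cells$id, old$id)
  known <- !is.na(m)
  cells$division_time[known] <- old$division_time[m[known]]
  cells$divided[known] <- old$divided[m[known]]
  state$labels <- res$labels
  state$conc <- res$conc
  state$cells <- cells
  state$bonds <- tibble::as_tibble(res$bonds)
  state$links <- tibble::as_tibble(res$links)
  state$time_min <- res$time_min
  state
}

#' Contact-energy change of a proposed copy
#'
#' Sums, over the 4th-order (20-site) neighborhood of `site`, the adhesion
#' energies with the proposed label minus those with the current label.
#' Deterministic; same-label contacts contribute nothing.
#'
#' @param state a `cpm_state`.
#' @param site integer `c(x, y)`, 1-based lattice coordinates.
#' @param new_label proposed label for the site.
#' @param energy an [energy_params()].
#' @return the contact energy difference (scalar).
#' @export
contact_energy_delta <- function(state, site, new_label,
                                 energy = energy_params()) {
  d <- delta_components(state, site, new_label, energy = energy)
  d$contact
}

#' Volume-constraint energy change of a proposed copy
#'
#' @inheritParams contact_energy_delta
#' @return the volume energy difference; special regions (cavity, external)
#'   and frozen cells contribute nothing.
#' @export
volume_energy_delta <- function(state, site, new_label,
                                energy = energy_params()) {
  d <- delta_components(state, site, new_label, energy = energy)
  d$volume
}

#' Chemotaxis energy change of a proposed extension
#'
#' Returns `-lambda_chem * (conc[target] - conc[source])` when the extending
#' cell is an unfrozen deep cell, 0 otherwise, so that up-gradient
#' extensions are favored.
#'
#' @param state a `cpm_state`.
#' @param source_site,target_site 1-based `c(x, y)` coordinates; the copy
#'   extends the cell occupying `source_site` into `target_site`.
#' @param chemo a [chemo_params()].
#' @return the chemotaxis energy difference.
#' @export
chemotaxis_energy_delta <- function(state, source_site, target_site,
                                    chemo = chemo_params()) {
  lab <- state$labels[source_site[1], source_site[2]]
  d <- delta_components(state, target_site, lab, source_site = source_site,
                        chemo = chemo)
  d$chemo
}

delta_components <- function(state, site, new_label,
                             source_site = site,
                             energy = energy_params(),
                             chemo = chemo_params(),
                             links = link_params()) {
  known <- c(LAB_EXT, LAB_CAV, LAB_SEP, LAB_ANC, state$cells$id)
  if (!(new_label %in% known)) stop("unknown label ", new_label)
  p <- state_params(state, energy, chemo, links)
  cpm_delta_cpp(state$labels, state$conc, cells_cpp(state$cells),
                bonds_cpp(state$bonds), links_cpp(state$links), p,
                geom_cpp(state$geom),
                site[1], site[2], as.integer(new_label),
                source_site[1], source_site[2])
}

#' Local connectivity guard
#'
#' Tests whether removing `site` from its current cell keeps the cell's
#' sites 8-connected within the site's 3x3 neighborhood (a local
#' simple-point test). Moves failing the test are rejected by the engine so
#' that cells remain connected domains.
#'
#' @param state a `cpm_state` (or a bare label matrix).
#' @param site 1-based `c(x, y)`.
#' @return `TRUE` (safe to remove) or `FALSE` (would disconnect).
#' @export
local_connectivity_guard <- function(state, site) {
  lab <- if (is.matrix(state)) state else state$labels
  connectivity_guard_cpp(lab, site[1], site[2])
}

#' Total lattice Hamiltonian
#'
#' Recomputes from scratch the contact, volume, elastic-link and cohesion
#' energies of a state. Used as the brute-force oracle against which the
#' engine's incremental energy differences are verified.
#'
#' @param state a `cpm_state`.
#' @inheritParams advance
#' @return named list with components `contact`, `volume`, `link`,
#'   `cohesion`, `total`.
#' @export
cpm_hamiltonian <- function(state, energy = energy_params(),
                            chemo = chemo_params(), links = link_params()) {
  p <- state_params(state, energy, chemo, links)
  cpm_hamiltonian_cpp(state$labels, cells_cpp(state$cells),
                      bonds_cpp(state$bonds), links_cpp(state$links), p,
                      geom_cpp(state$geom))
}

#' @export
print.cpm_state <- function(x, ...) {
  n_dc <- sum(x$cells$kind == "DC")
  n_sc <- sum(x$cells$kind == "SC")
  cat("<cpm_state> ", nrow(x$labels), "x", ncol(x$labels),
      " lattice, t = ", x$time_min, " min\n", sep = "")
  cat("  cells: ", n_dc, " DC, ", n_sc, " SC (",
      sum(x$cells$frozen), " frozen); links: ", nrow(x$links),
      "; bonds: ", nrow(x$bonds), "\n", sep = "")
  invisible(x)
}

#' Census check: registry volumes against the label grid
#'
#' @param state a `cpm_state`.
#' @return `TRUE` invisibly if every registered cell's volume equals its
#'   site count on the grid (errors otherwise).
#' @export
check_census <- function(state) {
  lab <- state$labels
  tab <- table(lab[lab >= LAB_CELL0])
  ids <- as.integer(names(tab))
  if (!setequal(ids, state$cells$id))
    stop("labels on grid and registry ids differ")
  m <- match(state$cells$id, ids)
  if (!all(state$cells$volume == as.integer(tab)[m]))
    stop("volume bookkeeping mismatch")
  invisible(TRUE)
}
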
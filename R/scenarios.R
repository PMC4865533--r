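# Scenario definitions and the replicate runner.

#' Scenario configuration
#'
#' Bundles everything needed to reproduce one in-silico experiment: the
#' geometry, all energy/chemoattractant/link parameters, the schedule and
#' the replicate protocol. A run is reproducible from the config alone.
#'
#' @param name scenario name.
#' @param geometry a [geometry_config()].
#' @param energy an [energy_params()].
#' @param chemo a [chemo_params()].
#' @param links a [link_params()].
#' @param duration_min simulated duration (240 min = the 4-hour epiboly
#'   window).
#' @param mcs_min simulated minutes per Monte Carlo sweep; 0.015 gives the
#'   16000 sweeps per run that keep mechanical relaxation fast relative to
#'   the division and secretion timescales.
#' @param divisions run the one-division-per-cell schedule.
#' @param replicates number of seeded replicates.
#' @param base_seed base RNG seed; replicate `i` uses `base_seed + i`.
#' @param explant_purified_source use the clamped-disc source in the explant
#'   assay.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(name = "control",
                            geometry = geometry_config(),
                            energy = energy_params(),
                            chemo = chemo_params(),
                            links = link_params(),
                            duration_min = 240, mcs_min = 0.015,
                            divisions = TRUE,
                            replicates = 30, base_seed = 1,
                            explant_purified_source = FALSE) {
  structure(list(name = name, geometry = geometry, energy = energy,
                 chemo = chemo, links = links,
                 duration_min = duration_min, mcs_min = mcs_min,
                 divisions = divisions,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 explant_purified_source = explant_purified_source),
            class = "scenario_config")
}

#' Run one seeded replicate of a scenario
#'
#' Builds the initial state, draws the division schedule, and advances the
#' lattice in chunks between division events up to the configured duration.
#' All randomness (initialization, division axes, engine seeds) derives from
#' `base_seed + replicate`.
#'
#' @param config a [scenario_config()].
#' @param replicate replicate index (1-based).
#' @return list with `state` (final `cpm_state`), `tracks` (per-minute
#'   centroid tibble) and `events`.
#' @export
run_replicate <- function(config, replicate = 1) {
  seed <- config$base_seed + replicate
  withr::with_seed(seed, {
    if (config$geometry$explant_mode == "two-cluster") {
      st <- build_explant_assay(config$geometry, config$chemo,
                                purified_source = config$explant_purified_source)
    } else {
      st <- build_bcr(config$geometry, config$chemo)
    }
    if (config$divisions) st <- schedule_divisions(st)

    sp <- st$geom$spacing
    tr0 <- tibble::tibble(minute = 0, id = st$cells$id, kind = st$cells$kind,
                          x_um = (st$cells$cx - 0.5) * sp,
                          y_um = (st$cells$cy - 0.5) * sp,
                          volume = as.numeric(st$cells$volume))
    attr(st, "tracks") <- tr0

    adv <- function(st, minutes) {
      # ceiling so the sweep clock always reaches (or just passes) the next
      # event, whatever mcs_min divides
      n <- ceiling(minutes / config$mcs_min - 1e-9)
      if (n <= 0) return(st)
      advance(st, n, config$energy, config$chemo, config$links,
              mcs_min = config$mcs_min)
    }
    repeat {
      pend <- st$cells$division_time
      pend <- pend[!is.na(pend) & pend > st$time_min + 1e-9]
      t_next <- if (length(pend) > 0) min(pend) else Inf
      if (t_next >= config$duration_min) {
        st <- adv(st, config$duration_min - st$time_min)
        break
      }
      st <- adv(st, t_next - st$time_min)
      due <- st$cells$id[!is.na(st$cells$division_time) &
                           st$cells$division_time <= st$time_min + 1e-9]
      for (id in due) st <- divide_cell(st, id)
      if (st$time_min >= config$duration_min - 1e-9) break
    }
    list(state = st, tracks = attr(st, "tracks"), events = st$events,
         replicate = replicate, seed = seed)
  })
}

#' Run all replicates of a scenario
#'
#' @param config a [scenario_config()].
#' @param replicates optional override of `config$replicates`.
#' @param out_dir if given, per-replicate track CSVs and a metrics summary
#'   CSV are written there.
#' @param progress print one line per replicate.
#' @return a `cpm_run` object: list with `config`, `tracks` (tibble with a
#'   `replicate` column), `states` (final states) and `summary` (one row per
#'   replicate; see [tidy.cpm_run()]).
#' @export
run_scenario <- function(config, replicates = NULL, out_dir = NULL,
                         progress = FALSE) {
  reps <- if (is.null(replicates)) config$replicates else as.integer(replicates)
  runs <- purrr::map(seq_len(reps), function(r) {
    if (progress) message(config$name, " replicate ", r, "/", reps)
    run_replicate(config, r)
  })
  tracks <- purrr::map2_dfr(runs, seq_len(reps), function(run, r) {
    dplyr::mutate(run$tracks, replicate = r, .before = 1)
  })
  states <- purrr::map(runs, "state")
  summary <- purrr::map2_dfr(states, seq_len(reps), function(st, r) {
    replicate_summary(st, tracks[tracks$replicate == r, ], config)
  })
  out <- structure(list(config = config, tracks = tracks, states = states,
                        summary = summary),
                   class = "cpm_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

replicate_summary <- function(state, tracks, config) {
  r <- tracks$replicate[1]
  if (!state$geom$explant) {
    th <- tissue_thickness(state)
    ly <- count_layers(state)
    ic <- intercalation_summary(tracks, sep_y_um = sep_y_um(state))
    ex <- expansion(tracks, t_i = 0, t_f = config$duration_min,
                    kinds = "DC", seed = config$base_seed + r)
    tibble::tibble(replicate = r,
                   thickness = mean(th$thickness),
                   layers = mean(ly$layers),
                   expansion = mean(ex$E),
                   out_frac = ic$out_frac, in_frac = ic$in_frac,
                   intercalation_pct = ic$intercalation_pct,
                   n_events = ic$n_events,
                   n_cells = nrow(state$cells))
  } else {
    idx <- chemotaxis_index(tracks, target = state$geom$target)
    tibble::tibble(replicate = r, ci = idx$ci,
                   net_toward = idx$net_toward, path_length = idx$path_length,
                   n_cells = nrow(state$cells))
  }
}

# y (um) of the top edge of the separator row; band definitions hang off it
sep_y_um <- function(state) {
  if (state$geom$sep_row < 0) stop("state has no separator row")
  state$geom$sep_row * state$geom$spacing
}

#' The shipped scenario suite
#'
#' Named configurations for every in-silico experiment: control, chemotaxis
#' off, mosaic secretion, cohesion sweep, explant assays, the secretion-level
#' sweep, inhibition / ubiquitous / localized sources, multilayer tissues and
#' DC depletion.
#'
#' @param base_seed base seed shared by all configs.
#' @param replicates replicate count per config (30 in the standard
#'   protocol).
#' @return named list of [scenario_config()]s; sweep entries are themselves
#'   named lists of configs.
#' @export
scenario_suite <- function(base_seed = 1, replicates = 30) {
  cfg <- function(name, ...) {
    scenario_config(name = name, base_seed = base_seed,
                    replicates = replicates, ...)
  }
  level_grid <- c(0.1, 0.25, 0.5, 1, 1.3, 1.5, 2, 3)
  suite <- list(
    control = cfg("control"),
    chem_off = cfg("chem_off", chemo = chemo_params(lambda_chem = 0)),
    mosaic_sl = cfg("mosaic_sl", chemo = chemo_params(pattern = "mosaic-SL")),
    inhibition = cfg("inhibition", chemo = chemo_params(pattern = "none")),
    ubiquitous = cfg("ubiquitous", chemo = chemo_params(pattern = "ubiquitous")),
    ubiquitous_1p3 = cfg("ubiquitous_1p3",
                         chemo = chemo_params(pattern = "ubiquitous",
                                              level_multiplier = 1.3)),
    localized = cfg("localized", chemo = chemo_params(pattern = "localized-SL")),
    # explant assays run in dish conditions: slower chemoattractant
    # clearance than in the embryo, so the gradient spans the gap
    explant_assay = cfg("explant_assay",
                        geometry = geometry_config(width = 200, height = 100,
                                                   explant_mode = "two-cluster"),
                        chemo = chemo_params(k_decay = 0.1),
                        divisions = FALSE),
    explant_no_chemo = cfg("explant_no_chemo",
                           geometry = geometry_config(width = 200, height = 100,
                                                      explant_mode = "two-cluster"),
                           chemo = chemo_params(lambda_chem = 0, k_decay = 0.1),
                           divisions = FALSE),
    explant_purified = cfg("explant_purified",
                           geometry = geometry_config(width = 200, height = 100,
                                                      explant_mode = "two-cluster"),
                           chemo = chemo_params(k_decay = 0.1),
                           divisions = FALSE,
                           explant_purified_source = TRUE),
    secretion_sweep = purrr::map(
      stats::setNames(level_grid, paste0("level_", level_grid)),
      function(m) cfg(paste0("secretion_", m),
                      chemo = chemo_params(level_multiplier = m))),
    cohesion_sweep = purrr::map(
      stats::setNames(c(0, 0.05, 0.2, 0.5, 1), paste0("p_form_", c(0, 0.05, 0.2, 0.5, 1))),
      function(p) cfg(paste0("cohesion_", p), links = link_params(p_form = p))),
    multilayer = purrr::map(
      stats::setNames(3:5, paste0("layers_", 3:5)),
      function(k) cfg(paste0("multilayer_", k),
                      geometry = geometry_config(dc_layers = k))),
    dc_depletion = purrr::map(
      stats::setNames(c(0.25, 0.5), paste0("fraction_", c(0.25, 0.5))),
      function(f) cfg(paste0("depletion_", f),
                      geometry = geometry_config(dc_depletion_fraction = f)))
  )
  suite
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-replicate summary of a scenario run
#'
#' @param x a `cpm_run`.
#' @param ... unused.
#' @return tibble with one row per replicate (thickness in cell diameters,
#'   mean layer count, expansion, Out/In event fractions, intercalation
#'   percentage for tissue runs; chemotaxis index for explant runs).
#' @export
tidy.cpm_run <- function(x, ...) x$summary

#' One-row summary of a scenario run
#'
#' @param x a `cpm_run`.
#' @param ... unused.
#' @return tibble with the scenario name, replicate count, and mean +/- SD
#'   of each replicate-level metric.
#' @export
glance.cpm_run <- function(x, ...) {
  s <- x$summary
  num <- names(s)[vapply(s, is.numeric, logical(1))]
  num <- setdiff(num, "replicate")
  out <- tibble::tibble(scenario = x$config$name, replicates = nrow(s))
  for (v in num) {
    out[[paste0(v, "_mean")]] <- mean(s[[v]], na.rm = TRUE)
    out[[paste0(v, "_sd")]] <- stats::sd(s[[v]], na.rm = TRUE)
  }
  out
}

#' @export
print.cpm_run <- function(x, ...) {
  cat("<cpm_run> scenario '", x$config$name, "', ",
      nrow(x$summary), " replicates\n", sep = "")
  print(glance(x))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Write a full state snapshot as plain-text tables
#'
#' Writes the label grid, concentration grid, cell registry and link table
#' of a state to CSV files under `dir` (one file per table, minute stamp in
#' the name).
#'
#' @param state a `cpm_state`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_snapshot <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("t%04d", round(state$time_min))
  utils::write.csv(state$labels, file.path(dir, paste0(stamp, "_labels.csv")),
                   row.names = FALSE)
  utils::write.csv(state$conc, file.path(dir, paste0(stamp, "_conc.csv")),
                   row.names = FALSE)
  utils::write.csv(state$cells, file.path(dir, paste0(stamp, "_cells.csv")),
                   row.names = FALSE)
  lk <- state$links
  if (nrow(lk) > 0) {
    lk$rest_length_um <- lk$rest * state$geom$spacing
    lk$length_um <- lk$length * state$geom$spacing
    lk$age_min <- lk$age * 0.1
  }
  utils::write.csv(lk, file.path(dir, paste0(stamp, "_links.csv")),
                   row.names = FALSE)
  invisible(dir)
}
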
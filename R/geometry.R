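#' Geometry of a simulated blastocoel-roof section
#'
#' Describes the lattice and the initial tissue: a single superficial layer
#' (SL) of cuboidal cells resting on a one-site immutable basal separator,
#' `dc_layers` tiers of deep cells (DCs) beneath it, the blastocoel cavity
#' below, and external medium above. Immutable anchor columns sit
#' `anchor_inset` sites from the lateral grid borders at SL height.
#'
#' @param width,height lattice dimensions in sites (2.5 um per site).
#' @param n_sc number of superficial cells.
#' @param dc_layers number of initial deep-cell tiers (0 allowed).
#' @param dc_depletion_fraction fraction of DC slots left empty (as cavity),
#'   chosen at random with the replicate seed.
#' @param cavity_depth minimum depth of the cavity below the deep layer,
#'   sites.
#' @param anchor_inset distance of the anchor columns from the lateral grid
#'   borders, sites.
#' @param spacing um per lattice site.
#' @param explant_mode `"off"` for the tissue section, `"two-cluster"` for
#'   the explant chemotaxis assay.
#' @param explant_gap gap between the two explants, um.
#' @param localized_region integer range (SL cell indices, 1-based) of
#'   secreting SCs for the localized pattern, or `NULL` for the default
#'   central third.
#' @return a list of class `geometry_config`.
#' @export
geometry_config <- function(width = 240, height = 120, n_sc = 24,
                            dc_layers = 2, dc_depletion_fraction = 0,
                            cavity_depth = 40, anchor_inset = 30,
                            spacing = 2.5,
                            explant_mode = c("off", "two-cluster"),
                            explant_gap = 75, localized_region = NULL) {
  explant_mode <- match.arg(explant_mode)
  stopifnot(dc_layers >= 0, dc_depletion_fraction >= 0,
            dc_depletion_fraction <= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_sc = as.integer(n_sc), dc_layers = as.integer(dc_layers),
                 dc_depletion_fraction = dc_depletion_fraction,
                 cavity_depth = as.integer(cavity_depth),
                 anchor_inset = as.integer(anchor_inset), spacing = spacing,
                 explant_mode = explant_mode, explant_gap = explant_gap,
                 localized_region = localized_region),
            class = "geometry_config")
}

# lattice label constants
LAB_EXT <- 0L; LAB_CAV <- 1L; LAB_SEP <- 2L; LAB_ANC <- 3L; LAB_CELL0 <- 10L
DC_SIDE <- 8L          # initial DC square side (64 sites ~ 20 um diameter)
SC_TARGET <- 100L      # SC target volume, sites
DC_TARGET <- 64L       # DC target volume, sites

new_cpm_state <- function(labels, conc, cells, bonds, links, geom, time_min = 0) {
  structure(list(labels = labels, conc = conc, cells = cells, bonds = bonds,
                 links = links, geom = geom, time_min = time_min,
                 counters = list(inserted = 0L, removed = 0L, frozen = 0L,
                                 divisions = 0L, division_skips = 0L),
                 events = tibble::tibble(minute = numeric(), type = character(),
                                         id = integer(), detail = character())),
            class = "cpm_state")
}

empty_cells <- function() {
  tibble::tibble(id = integer(), kind = character(), volume = integer(),
                 target_volume = numeric(), frozen = logical(), c0 = numeric(),
                 division_time = numeric(), divided = logical(),
                 cx = numeric(), cy = numeric())
}

empty_bonds <- function() {
  tibble::tibble(a = integer(), b = integer(), active = logical(), d0 = numeric())
}

empty_links <- function() {
  tibble::tibble(dc = integer(), sc = integer(), rest = numeric(),
                 age = integer(), length = numeric())
}

# secretion level per cell under a given pattern
secretion_levels <- function(kind, sc_index, pattern, c0, localized_region) {
  lev <- rep(0, length(kind))
  if (pattern == "uniform-SL") {
    lev[kind == "SC"] <- c0
  } else if (pattern == "mosaic-SL") {
    lev[kind == "SC" & sc_index %% 2L == 1L] <- c0
  } else if (pattern == "ubiquitous") {
    lev[] <- c0
  } else if (pattern == "localized-SL") {
    lev[kind == "SC" & sc_index %in% localized_region] <- c0
  }
  lev
}

#' Build the initial blastocoel-roof configuration
#'
#' Lays out, from the top of the grid: external medium, one row of SCs (each
#' at its 100-site target volume), the one-site immutable separator spanning
#' anchor to anchor, `dc_layers` tiers of 8x8 DCs, and cavity filling the
#' rest. Anchor columns (4 sites tall) sit on the separator ends. Initial
#' cell volumes equal target volumes exactly.
#'
#' @param geom a [geometry_config()].
#' @param chemo a [chemo_params()]; sets the secretion pattern.
#' @return a `cpm_state`.
#' @export
build_bcr <- function(geom, chemo = chemo_params()) {
  w <- geom$width; h <- geom$height
  sep_row <- geom$cavity_depth + geom$dc_layers * DC_SIDE + 1L
  anc_lx <- geom$anchor_inset + 1L
  anc_rx <- w - geom$anchor_inset
  if (anc_rx - anc_lx < 20L) stop("grid too narrow for the anchor inset")

  # The tissue spans the full grid width; the anchors stand inside it, so
  # the outer strips act as buffer tissue that the release rules absorb.
  # SCs fill the three segments delimited by the two anchor columns.
  segs <- list(c(1L, anc_lx - 1L), c(anc_lx + 1L, anc_rx - 1L),
               c(anc_rx + 1L, w))
  cellw <- max(4L, min(10L, round(w / geom$n_sc)))
  seg_widths <- purrr::map(segs, function(s) {
    segw <- s[2] - s[1] + 1L
    n <- max(1L, round(segw / cellw))
    base <- segw %/% n
    if (base < 4L) { n <- max(1L, segw %/% 4L); base <- segw %/% n }
    if (base > 10L) { n <- ceiling(segw / 10L); base <- segw %/% n }
    wd <- rep(base, n)
    extra <- segw - sum(wd)
    if (extra > 0) wd[seq_len(extra)] <- wd[seq_len(extra)] + 1L
    wd
  })
  sc_h_max <- max(ceiling(SC_TARGET / unlist(seg_widths)))
  if (sep_row + 4L + sc_h_max + 2L > h)
    stop("grid too short: need height >= ", sep_row + sc_h_max + 6L,
         " for ", geom$dc_layers, " DC tiers and the SL")

  labels <- matrix(LAB_EXT, nrow = w, ncol = h)
  labels[, seq_len(sep_row)] <- LAB_CAV             # everything below SL plane
  labels[, sep_row] <- LAB_SEP                      # basal layer, full width
  labels[anc_lx, sep_row + 1:4] <- LAB_ANC
  labels[anc_rx, sep_row + 1:4] <- LAB_ANC

  ids <- integer(); kinds <- character(); tvols <- numeric(); sc_index <- integer()
  seg_of <- integer()
  next_id <- LAB_CELL0
  sc_counter <- 0L

  # SL: rectangles of exactly SC_TARGET sites, ragged top row when width
  # does not divide 100
  for (si in seq_along(segs)) {
    x0 <- segs[[si]][1]
    for (wi in seg_widths[[si]]) {
      full_rows <- SC_TARGET %/% wi
      rem <- SC_TARGET - full_rows * wi
      labels[x0:(x0 + wi - 1L), sep_row + 1L + seq_len(full_rows) - 1L] <- next_id
      if (rem > 0)
        labels[x0:(x0 + rem - 1L), sep_row + 1L + full_rows] <- next_id
      sc_counter <- sc_counter + 1L
      ids <- c(ids, next_id); kinds <- c(kinds, "SC")
      tvols <- c(tvols, SC_TARGET); sc_index <- c(sc_index, sc_counter)
      seg_of <- c(seg_of, si)
      next_id <- next_id + 1L
      x0 <- x0 + wi
    }
  }
  n_sc_actual <- sc_counter

  # DC tiers across the full width
  n_dc_tier <- w %/% DC_SIDE
  pad <- (w - n_dc_tier * DC_SIDE) %/% 2L
  dc_slots <- list()
  for (tier in seq_len(geom$dc_layers)) {
    ytop <- sep_row - 1L - (tier - 1L) * DC_SIDE
    for (j in seq_len(n_dc_tier)) {
      xs <- pad + (j - 1L) * DC_SIDE + 1L
      dc_slots[[length(dc_slots) + 1L]] <-
        list(x = xs:(xs + DC_SIDE - 1L), y = (ytop - DC_SIDE + 1L):ytop)
    }
  }
  keep <- seq_along(dc_slots)
  if (geom$dc_depletion_fraction > 0) {
    n_drop <- floor(geom$dc_depletion_fraction * length(dc_slots))
    keep <- sort(sample(seq_along(dc_slots), length(dc_slots) - n_drop))
  }
  for (s in keep) {
    slot <- dc_slots[[s]]
    labels[slot$x, slot$y] <- next_id
    ids <- c(ids, next_id); kinds <- c(kinds, "DC")
    tvols <- c(tvols, DC_TARGET); sc_index <- c(sc_index, NA_integer_)
    seg_of <- c(seg_of, NA_integer_)
    next_id <- next_id + 1L
  }

  loc <- geom$localized_region
  if (is.null(loc)) {
    # central third of the SCs between the anchors
    mid <- which(seg_of == 2L & kinds == "SC")
    third <- max(1L, length(mid) %/% 3L)
    start <- (length(mid) - third) %/% 2L + 1L
    loc <- sc_index[mid[start:(start + third - 1L)]]
  }
  c0 <- secretion_levels(kinds, ifelse(is.na(sc_index), -1L, sc_index),
                         chemo$pattern, chemo$c0, loc)
  cells <- tibble::tibble(id = ids, kind = kinds, volume = NA_integer_,
                          target_volume = tvols, frozen = FALSE, c0 = c0,
                          division_time = NA_real_, divided = FALSE,
                          cx = NA_real_, cy = NA_real_)
  vols <- tabulate(labels[labels >= LAB_CELL0] - LAB_CELL0 + 1L)
  cells$volume <- vols[cells$id - LAB_CELL0 + 1L]
  stopifnot(all(cells$volume == cells$target_volume))

  # SC neighbor chain: consecutive within each segment; the SCs flanking an
  # anchor column bond to that anchor
  bonds <- empty_bonds()
  for (si in seq_along(segs)) {
    sc_ids <- cells$id[cells$kind == "SC"][seg_of[kinds == "SC"] == si]
    if (length(sc_ids) > 1)
      bonds <- dplyr::bind_rows(bonds, tibble::tibble(
        a = sc_ids[-length(sc_ids)], b = sc_ids[-1], active = FALSE, d0 = 0))
    if (si == 1) bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      a = sc_ids[length(sc_ids)], b = -1L, active = FALSE, d0 = 0))
    if (si == 2) bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      a = c(sc_ids[1], sc_ids[length(sc_ids)]), b = c(-1L, -2L),
      active = FALSE, d0 = 0))
    if (si == 3) bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      a = sc_ids[1], b = -2L, active = FALSE, d0 = 0))
  }

  gm <- list(width = w, height = h, spacing = geom$spacing,
             sep_row = sep_row, anchor_lx = anc_lx, anchor_rx = anc_rx,
             explant = FALSE, target = NULL)
  st <- new_cpm_state(labels, matrix(0, w, h), cells, bonds, empty_links(), gm)
  st <- refresh_centroids(st)
  st
}

#' Build the two-explant chemotaxis assay
#'
#' A roughly round cluster of deep cells and a round cluster of secreting
#' superficial cells separated by a cell-free gap on a uniform substrate (no
#' separator, no anchors, no divisions). With `purified_source = TRUE` the SC
#' cluster is replaced by a fixed chemoattractant clamp disc, emulating a
#' bead soaked in purified attractant.
#'
#' @param geom a [geometry_config()] with `explant_mode = "two-cluster"`.
#' @param chemo a [chemo_params()].
#' @param purified_source replace the SC explant with a clamped source disc.
#' @return a `cpm_state`; the attractant target position is stored in
#'   `state$geom$target` (um).
#' @export
build_explant_assay <- function(geom, chemo = chemo_params(),
                                purified_source = FALSE) {
  if (geom$explant_mode != "two-cluster")
    stop("geom$explant_mode must be 'two-cluster'")
  w <- geom$width; h <- geom$height
  gap_sites <- round(geom$explant_gap / geom$spacing)
  dc_block <- 3L   # 3x3 blocks of 8x8 DCs
  sc_block <- 3L   # 3x3 blocks of 10x10 SCs
  dc_w <- dc_block * DC_SIDE
  sc_w <- sc_block * 10L
  need_w <- 10L + dc_w + gap_sites + sc_w + 10L
  if (need_w > w) stop("grid too narrow for the requested explant gap: need ",
                       need_w, " sites")
  margin <- (w - dc_w - gap_sites - sc_w) %/% 2L
  yc <- h %/% 2L

  labels <- matrix(LAB_EXT, nrow = w, ncol = h)
  ids <- integer(); kinds <- character(); tvols <- numeric()
  next_id <- LAB_CELL0

  dc_x0 <- margin + 1L
  dc_y0 <- yc - dc_w %/% 2L
  corner <- function(i, j, n) (i %in% c(1L, n)) && (j %in% c(1L, n))
  for (i in seq_len(dc_block)) for (j in seq_len(dc_block)) {
    if (dc_block >= 3L && corner(i, j, dc_block) && dc_block %% 2L == 1L &&
        dc_block > 3L) next   # knock corners off larger clusters only
    xs <- dc_x0 + (i - 1L) * DC_SIDE
    ys <- dc_y0 + (j - 1L) * DC_SIDE
    labels[xs:(xs + DC_SIDE - 1L), ys:(ys + DC_SIDE - 1L)] <- next_id
    ids <- c(ids, next_id); kinds <- c(kinds, "DC"); tvols <- c(tvols, DC_TARGET)
    next_id <- next_id + 1L
  }

  sc_x0 <- margin + dc_w + gap_sites + 1L
  sc_y0 <- yc - sc_w %/% 2L
  clamp <- NULL
  if (purified_source) {
    cxs <- sc_x0 + sc_w / 2; cys <- yc
    r <- 12
    sites <- integer()
    for (x in seq_len(w)) for (y in seq_len(h)) {
      if ((x - cxs)^2 + (y - cys)^2 <= r^2)
        sites <- c(sites, (x - 1L) + w * (y - 1L))
    }
    clamp <- list(sites = sites, value = chemo$c0)
    target <- c(cxs, cys)
  } else {
    for (i in seq_len(sc_block)) for (j in seq_len(sc_block)) {
      xs <- sc_x0 + (i - 1L) * 10L
      ys <- sc_y0 + (j - 1L) * 10L
      labels[xs:(xs + 9L), ys:(ys + 9L)] <- next_id
      ids <- c(ids, next_id); kinds <- c(kinds, "SC"); tvols <- c(tvols, SC_TARGET)
      next_id <- next_id + 1L
    }
    target <- c(sc_x0 + sc_w / 2, yc)
  }

  c0 <- ifelse(kinds == "SC" & chemo$pattern != "none", chemo$c0, 0)
  cells <- tibble::tibble(id = ids, kind = kinds, volume = NA_integer_,
                          target_volume = tvols, frozen = FALSE, c0 = c0,
                          division_time = NA_real_, divided = FALSE,
                          cx = NA_real_, cy = NA_real_)
  vols <- tabulate(labels[labels >= LAB_CELL0] - LAB_CELL0 + 1L)
  cells$volume <- vols[cells$id - LAB_CELL0 + 1L]

  gm <- list(width = w, height = h, spacing = geom$spacing,
             sep_row = -1L, anchor_lx = -1L, anchor_rx = -1L,
             explant = TRUE, target = (target - 0.5) * geom$spacing,
             clamp = clamp)
  st <- new_cpm_state(labels, matrix(0, w, h), cells, empty_bonds(),
                      empty_links(), gm)
  refresh_centroids(st)
}

# recompute cell centroids (site coordinates, 1-based) from the label grid
refresh_centroids <- function(state) {
  lab <- state$labels
  idx <- which(lab >= LAB_CELL0)
  if (length(idx) == 0) return(state)
  w <- nrow(lab)
  xs <- ((idx - 1L) %% w) + 1L
  ys <- ((idx - 1L) %/% w) + 1L
  l <- lab[idx]
  cx <- tapply(xs, l, mean); cy <- tapply(ys, l, mean)
  vol <- tapply(xs, l, length)
  m <- match(state$cells$id, as.integer(names(cx)))
  state$cells$cx <- as.numeric(cx)[m]
  state$cells$cy <- as.numeric(cy)[m]
  state$cells$volume <- as.integer(vol)[m]
  state
}
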
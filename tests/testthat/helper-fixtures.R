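# Shared fixtures and independent R-side oracles.

# small blastocoel-roof section that runs in well under a second per sweep
small_geom <- function(...) {
  args <- list(width = 100, height = 72, n_sc = 10, dc_layers = 2,
               cavity_depth = 20, anchor_inset = 10)
  override <- list(...)
  args[names(override)] <- override
  do.call(geometry_config, args)
}

fast_chemo <- function(...) chemo_params(...)

# hand-built open state: a few rectangular cells in medium, no separator
toy_state <- function(blocks, w = 30, h = 24, kinds = NULL, c0 = 0) {
  labels <- matrix(epiboly:::LAB_EXT, w, h)
  n <- length(blocks)
  if (is.null(kinds)) kinds <- rep("DC", n)
  ids <- seq(10L, by = 1L, length.out = n)
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    labels[b$x, b$y] <- ids[i]
  }
  vols <- vapply(blocks, function(b) length(b$x) * length(b$y), numeric(1))
  cells <- tibble::tibble(id = ids, kind = kinds, volume = as.integer(vols),
                          target_volume = vols, frozen = FALSE,
                          c0 = rep_len(c0, n),
                          division_time = NA_real_, divided = TRUE,
                          cx = NA_real_, cy = NA_real_)
  gm <- list(width = w, height = h, spacing = 2.5, sep_row = -1L,
             anchor_lx = -1L, anchor_rx = -1L, explant = TRUE, target = NULL,
             clamp = NULL)
  st <- epiboly:::new_cpm_state(labels, matrix(0, w, h), cells,
                                epiboly:::empty_bonds(),
                                epiboly:::empty_links(), gm)
  epiboly:::refresh_centroids(st)
}

# independent contact Hamiltonian: brute force over every unordered pair in
# the 4th-order neighborhood
NB10_R <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1), c(2, 0), c(0, 2),
                c(1, 2), c(2, 1), c(1, -2), c(2, -1))

kind_code_of <- function(label, cells) {
  if (label == 0) return("external")
  if (label == 1) return("cavity")
  if (label == 2) return("separator")
  if (label == 3) return("anchor")
  cells$kind[match(label, cells$id)]
}

contact_H_bruteforce <- function(state, energy) {
  lab <- state$labels
  w <- nrow(lab); h <- ncol(lab)
  J <- energy$J
  total <- 0
  for (x in seq_len(w)) for (y in seq_len(h)) {
    la <- lab[x, y]
    for (k in seq_len(nrow(NB10_R))) {
      nx <- x + NB10_R[k, 1]; ny <- y + NB10_R[k, 2]
      if (nx < 1 || nx > w || ny < 1 || ny > h) next
      lb <- lab[nx, ny]
      if (lb != la)
        total <- total + J[kind_code_of(la, state$cells),
                           kind_code_of(lb, state$cells)]
    }
  }
  total
}

volume_H_bruteforce <- function(state, energy) {
  v <- state$cells$volume
  t <- ifelse(state$cells$frozen, 0, state$cells$target_volume)
  sum(energy$lambda_volume * (v - t)^2)
}

# flood fill (8-connectivity) over a set of sites given as a 2-column matrix
flood_components <- function(sites) {
  n <- nrow(sites)
  if (n == 0) return(0L)
  comp <- rep(0L, n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      adj <- which(comp == 0 &
                     abs(sites[, 1] - sites[i, 1]) <= 1 &
                     abs(sites[, 2] - sites[i, 2]) <= 1)
      comp[adj] <- ncomp
      queue <- c(queue, adj)
    }
  }
  ncomp
}

# synthetic track table builder
make_tracks <- function(df) {
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  tibble::as_tibble(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
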
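# Chemoattractant field operations outside the main sweep loop.

#' Advance the chemoattractant field alone
#'
#' Forward-time explicit diffusion-decay update
#' (dc/dt = D * laplacian(c) - k * c) with the secretion clamp applied each
#' substep and zero-flux borders. The lattice of cells is held fixed.
#'
#' @param state a `cpm_state`.
#' @param minutes duration; must be an integer multiple of `dt_chem`.
#' @param chemo a [chemo_params()].
#' @return the state with an updated `conc` grid.
#' @export
step_field <- function(state, minutes, chemo = chemo_params()) {
  if (chemo$D * chemo$dt_chem > 0.25 + 1e-12)
    stop("unstable diffusion scheme: D * dt_chem must be <= 0.25")
  n <- minutes / chemo$dt_chem
  if (abs(n - round(n)) > 1e-9)
    stop("minutes must be an integer multiple of dt_chem")
  clamp <- state$geom$clamp
  state$conc <- chemo_step_cpp(state$conc, state$labels,
                               as.integer(state$cells$id),
                               as.numeric(state$cells$c0),
                               chemo$D, chemo$k_decay, chemo$dt_chem,
                               as.integer(round(n)), chemo$level_multiplier,
                               if (is.null(clamp)) integer() else as.integer(clamp$sites),
                               if (is.null(clamp)) 0 else clamp$value)
  state
}

#' Radial concentration profile through the tissue
#'
#' Mean chemoattractant concentration per lattice row, restricted to the
#' columns spanned by the tissue (the anchor span when anchors are present,
#' else the columns containing cells). Depth is measured downward from the
#' separator row (or the topmost cell row), so increasing depth runs from
#' the SL toward the blastocoel cavity.
#'
#' @param state a `cpm_state`.
#' @return tibble with `depth_um` and `mean_conc`, ordered by depth.
#' @export
radial_profile <- function(state) {
  lab <- state$labels
  g <- state$geom
  if (g$anchor_lx > 0) {
    cols <- (g$anchor_lx + 1):(g$anchor_rx - 1)
    ref_row <- g$sep_row
  } else {
    cell_cols <- which(apply(lab >= LAB_CELL0, 1, any))
    if (length(cell_cols) == 0) stop("no tissue span: state contains no cells")
    cols <- min(cell_cols):max(cell_cols)
    ref_row <- max(which(apply(lab[cols, , drop = FALSE] >= LAB_CELL0, 2, any)))
  }
  sub <- state$conc[cols, , drop = FALSE]
  tibble::tibble(depth_um = (ref_row - seq_len(ncol(sub))) * g$spacing,
                 mean_conc = colMeans(sub)) |>
    dplyr::arrange(.data$depth_um)
}

#' Steady-state of the diffusion-decay problem by dense linear solve
#'
#' Independent reference solution of the discrete Helmholtz problem
#' `D * laplacian(c) - k * c + S = 0` with per-site source rates `S`,
#' optional Dirichlet sites, and zero-flux borders, assembled as a dense
#' linear system. Intended for verifying the time-stepped solver on small
#' grids.
#'
#' @param width,height grid size in sites.
#' @param source_idx 1-based linear indices (column-major, x fastest) of
#'   secreting sites.
#' @param source_rate secretion rate(s), recycled over `source_idx`.
#' @param clamp_idx,clamp_val optional Dirichlet sites and values.
#' @param D,k_decay diffusion and decay parameters.
#' @return matrix of steady concentrations, `width` x `height`.
#' @export
chemo_steady_dense <- function(width, height, source_idx = integer(),
                               source_rate = numeric(),
                               clamp_idx = integer(), clamp_val = numeric(),
                               D = 25, k_decay = 0.5) {
  n <- width * height
  source_rate <- rep_len(source_rate, length(source_idx))
  clamp_val <- rep_len(clamp_val, length(clamp_idx))
  A <- matrix(0, n, n)
  b <- numeric(n)
  b[source_idx] <- -source_rate
  for (i in seq_len(n)) {
    if (i %in% clamp_idx) {
      A[i, ] <- 0
      A[i, i] <- 1
      b[i] <- clamp_val[match(i, clamp_idx)]
      next
    }
    x <- (i - 1) %% width + 1
    y <- (i - 1) %/% width + 1
    nb <- c(if (x > 1) i - 1, if (x < width) i + 1,
            if (y > 1) i - width, if (y < height) i + width)
    A[i, i] <- -D * length(nb) - k_decay
    A[i, nb] <- D
  }
  matrix(solve(A, b), nrow = width)
}
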
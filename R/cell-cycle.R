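# One asynchronous midline division per cell, without growth.

#' Draw the division schedule
#'
#' Every initial cell receives one cell-autonomous division time, i.i.d.
#' uniform on (`window[1]`, `window[2]`) minutes, so divisions are
#' asynchronous and avoid the equilibration windows at the start and end of
#' the 240-minute run. Daughters never divide.
#'
#' @param state a `cpm_state` (freshly built).
#' @param window division-time window in minutes.
#' @return the state with `division_time` filled for all undivided cells.
#' @export
schedule_divisions <- function(state, window = c(20, 220)) {
  n <- nrow(state$cells)
  t <- stats::runif(n, window[1], window[2])
  state$cells$division_time <- ifelse(state$cells$divided, NA_real_,
                                      round(t, 1))
  state
}

# flood fill over 8-connectivity; returns TRUE if `sites` (matrix x,y) is
# one connected component
sites_connected <- function(sites) {
  n <- nrow(sites)
  if (n <= 1) return(n == 1)
  key <- sites[, 1] * 1e5 + sites[, 2]
  seen <- logical(n)
  stack <- 1L; seen[1] <- TRUE; cnt <- 1L
  while (length(stack) > 0) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    dx <- abs(sites[, 1] - sites[i, 1])
    dy <- abs(sites[, 2] - sites[i, 2])
    nb <- which(!seen & dx <= 1 & dy <= 1)
    if (length(nb) > 0) {
      seen[nb] <- TRUE
      cnt <- cnt + length(nb)
      stack <- c(stack, nb)
    }
  }
  cnt == n
}

#' Divide a cell through its midline
#'
#' Splits the cell's sites by a straight line through its centroid: a random
#' orientation for deep cells, always vertical (perpendicular to the SL
#' plane) for superficial cells, so both SC daughters keep basal contact.
#' Daughter target volumes are half the mother's (no growth). The SC
#' neighbor chain is repaired (daughters bond each other and inherit the
#' mother's left/right partners); a DC mother's elastic link is dropped and
#' re-forms through the regular per-sweep rule; links to an SC mother are
#' reassigned to the nearer daughter. One daughter keeps the mother's id so
#' cell tracks remain continuous through division.
#'
#' @param state a `cpm_state`.
#' @param id id of the dividing cell.
#' @param max_retry random-axis retries for deep cells before the fallback
#'   median split along the best axis.
#' @return the updated state; the new daughter's id is in
#'   `attr(, "daughter")` (NA if the division was skipped).
#' @export
divide_cell <- function(state, id, max_retry = 8) {
  ci <- match(id, state$cells$id)
  if (is.na(ci)) stop("no cell with id ", id)
  cell <- state$cells[ci, ]
  if (cell$frozen) {
    # released cells are outside the simulation area and do not divide
    state$cells$division_time[ci] <- NA_real_
    attr(state, "daughter") <- NA_integer_
    return(state)
  }
  idx <- which(state$labels == id)
  w <- nrow(state$labels)
  sites <- cbind(((idx - 1L) %% w) + 1L, ((idx - 1L) %/% w) + 1L)
  if (nrow(sites) < 2) {
    state$counters$division_skips <- state$counters$division_skips + 1L
    state$events <- dplyr::bind_rows(state$events, tibble::tibble(
      minute = state$time_min, type = "division_skip", id = id,
      detail = "unsplittable 1-site cell"))
    attr(state, "daughter") <- NA_integer_
    return(state)
  }
  cx <- mean(sites[, 1]); cy <- mean(sites[, 2])

  split_by <- function(theta) {
    nx <- cos(theta); ny <- sin(theta)
    proj <- (sites[, 1] - cx) * nx + (sites[, 2] - cy) * ny
    side_b <- proj >= 0
    if (all(side_b) || !any(side_b)) return(NULL)
    if (!sites_connected(sites[!side_b, , drop = FALSE])) return(NULL)
    if (!sites_connected(sites[side_b, , drop = FALSE])) return(NULL)
    side_b
  }

  if (cell$kind == "SC") {
    theta <- 0                       # vertical plane: split left/right
    side_b <- split_by(theta)
    if (is.null(side_b)) {
      proj <- sites[, 1] - cx
      side_b <- rank(proj, ties.method = "first") > nrow(sites) / 2
    }
  } else {
    side_b <- NULL
    theta <- stats::runif(1, 0, pi)
    for (k in seq_len(max_retry)) {
      side_b <- split_by(theta)
      if (!is.null(side_b)) break
      theta <- stats::runif(1, 0, pi)
    }
    if (is.null(side_b)) {           # median split along the last axis
      proj <- (sites[, 1] - cx) * cos(theta) + (sites[, 2] - cy) * sin(theta)
      side_b <- rank(proj, ties.method = "first") > nrow(sites) / 2
    }
  }

  new_id <- max(state$cells$id) + 1L
  idx_b <- idx[side_b]
  state$labels[idx_b] <- new_id

  tv <- cell$target_volume
  half_a <- round(tv / 2); half_b <- tv - half_a
  state$cells$target_volume[ci] <- half_a
  state$cells$volume[ci] <- sum(!side_b)
  state$cells$divided[ci] <- TRUE
  state$cells$division_time[ci] <- NA_real_
  daughter <- cell
  daughter$id <- new_id
  daughter$target_volume <- half_b
  daughter$volume <- sum(side_b)
  daughter$divided <- TRUE
  daughter$division_time <- NA_real_
  state$cells <- dplyr::bind_rows(state$cells, daughter)
  state <- refresh_centroids(state)

  if (cell$kind == "SC") {
    # chain repair: mother's partners split by side, daughters bond each other
    pos_x <- function(pid) {
      if (pid == -1L) return(state$geom$anchor_lx)
      if (pid == -2L) return(state$geom$anchor_rx)
      state$cells$cx[match(pid, state$cells$id)]
    }
    mine <- state$bonds$a == id | state$bonds$b == id
    partners <- ifelse(state$bonds$a[mine] == id,
                       state$bonds$b[mine], state$bonds$a[mine])
    state$bonds <- state$bonds[!mine, ]
    ca <- state$cells$cx[ci]; cb <- state$cells$cx[match(new_id, state$cells$id)]
    left_id <- if (ca <= cb) id else new_id
    right_id <- if (ca <= cb) new_id else id
    nb <- tibble::tibble(a = left_id, b = right_id, active = FALSE, d0 = 0)
    for (p in partners) {
      px <- pos_x(p)
      owner <- if (!is.na(px) && px < cx) left_id else right_id
      nb <- dplyr::bind_rows(nb, tibble::tibble(a = owner, b = p,
                                                active = FALSE, d0 = 0))
    }
    state$bonds <- dplyr::bind_rows(state$bonds, nb)
    # reassign links that pointed at the SC mother to the nearer daughter
    if (nrow(state$links) > 0) {
      for (li in which(state$links$sc == id)) {
        dcx <- state$cells$cx[match(state$links$dc[li], state$cells$id)]
        state$links$sc[li] <- if (abs(dcx - ca) <= abs(dcx - cb)) id else new_id
      }
    }
  } else {
    # DC mother: drop its link; daughters re-link via the per-sweep rule
    state$links <- state$links[state$links$dc != id, ]
  }

  state$counters$divisions <- state$counters$divisions + 1L
  state$events <- dplyr::bind_rows(state$events, tibble::tibble(
    minute = state$time_min, type = "division", id = id,
    detail = sprintf("daughter=%d theta=%.3f", new_id, theta)))
  attr(state, "daughter") <- new_id
  state
}
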
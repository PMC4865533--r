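# Quantifications on snapshots and track tables.

test_that("thickness arithmetic is exact on constructed stacks", {
  set.seed(41)
  st <- build_bcr(small_geom())
  # constructed initial state: 2 DC tiers (8 sites each) + separator + SL
  # height per SC column; compute the expectation per measured column
  th <- tissue_thickness(st)
  g <- st$geom
  cols <- round(seq(g$anchor_lx + 2, g$anchor_rx - 2, length.out = 10))
  expected <- vapply(cols, function(x) {
    col <- st$labels[x, ]
    run <- which(col >= 10 | col == 2L)
    (max(run) - min(run) + 1) * 2.5 / 20
  }, numeric(1))
  expect_equal(th$thickness, expected)
  # a 3-tier stack of 20-um cells plus a 20-um SL reads 4.05 (stack + the
  # one-site basal layer)
  w <- 30; h <- 60; sep <- 25
  labels <- matrix(1L, w, h)
  labels[, 26:60] <- 0L
  labels[, sep] <- 2L
  labels[11:18, 17:24] <- 10L; labels[11:18, 9:16] <- 11L
  labels[11:18, 1:8] <- 12L
  labels[11:18, 26:33] <- 13L
  cells <- tibble::tibble(id = 10:13, kind = c("DC", "DC", "DC", "SC"),
                          volume = 64L, target_volume = 64, frozen = FALSE,
                          c0 = 0, division_time = NA_real_, divided = TRUE,
                          cx = NA_real_, cy = NA_real_)
  gm <- list(width = w, height = h, spacing = 2.5, sep_row = sep,
             anchor_lx = 2L, anchor_rx = 29L, explant = FALSE, target = NULL,
             clamp = NULL)
  stk <- epiboly:::new_cpm_state(labels, matrix(0, w, h), cells,
                                 epiboly:::empty_bonds(),
                                 epiboly:::empty_links(), gm)
  stk <- epiboly:::refresh_centroids(stk)
  th2 <- tissue_thickness(stk, n_positions = 3, x_range = c(12, 17))
  expect_equal(unique(th2$thickness), (8 * 4 + 1) * 2.5 / 20)  # 4.125
})

test_that("layer counts see the stacked deep cells plus the SL", {
  set.seed(42)
  st <- build_bcr(small_geom())
  expect_equal(unique(count_layers(st)$layers), 3)
  st4 <- build_bcr(small_geom(dc_layers = 4, height = 110, cavity_depth = 30))
  expect_equal(unique(count_layers(st4)$layers), 5)
})

test_that("expansion follows its definition and is scale invariant", {
  tr <- make_tracks(tibble::tibble(
    id = rep(1:4, each = 2),
    kind = "DC",
    minute = rep(c(0, 100), 4),
    x_um = c(0, 0, 10, 20, 20, 40, 30, 60),
    y_um = 0))
  # static tracks
  tr0 <- tr; tr0$x_um <- rep(c(0, 10, 20, 30), each = 2)
  e0 <- expansion(tr0, 0, 100, n_pairs = 6, seed = 1)
  expect_true(all(e0$E == 0))
  # all x doubled between t_i and t_f: E = 1 for every horizontal pair
  e1 <- expansion(tr, 0, 100, n_pairs = 6, seed = 1)
  expect_true(all(abs(e1$E - 1) < 1e-12))
  # exact scale invariance in the coordinate units
  tr_sites <- tr; tr_sites$x_um <- tr_sites$x_um / 2.5
  e2 <- expansion(tr_sites, 0, 100, n_pairs = 6, seed = 1)
  expect_identical(e1$E, e2$E)
  # seeded pair sampling is reproducible
  expect_identical(expansion(tr, 0, 100, n_pairs = 3, seed = 7),
                   expansion(tr, 0, 100, n_pairs = 3, seed = 7))
  expect_error(expansion(tr[tr$id == 1, ], 0, 100), "fewer than 2")
})

test_that("intercalation events detect crossings with hysteresis", {
  sep <- 100  # um; band lower boundary at 80, margins at 75 / 85
  mono <- make_tracks(tibble::tibble(
    id = 1L, kind = "DC", minute = 0:10,
    x_um = 0, y_um = seq(60, 95, length.out = 11)))
  ev <- intercalation_events(mono, sep_y_um = sep)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$direction, "Out")
  # zigzag within the hysteresis margin: no double counting
  zig <- make_tracks(tibble::tibble(
    id = 1L, kind = "DC", minute = 0:8,
    x_um = 0,
    y_um = c(60, 70, 86, 79, 83, 78, 84, 70, 60)))
  ev2 <- intercalation_events(zig, sep_y_um = sep)
  # one entry (86) and one exit (70): oscillations between 78-84 stay
  # inside the +/-5 margin
  expect_identical(ev2$direction, c("Out", "In"))
  # fractions sum to one by construction
  s <- intercalation_summary(dplyr::bind_rows(mono, zig |> dplyr::mutate(id = 2L)),
                             sep_y_um = sep)
  expect_equal(s$out_frac + s$in_frac, 1)
  expect_equal(s$n_events, 3L)
  expect_equal(s$intercalation_pct, 1)    # both observed cells crossed
})

test_that("chemotaxis index has the right limits and null behavior", {
  straight <- make_tracks(tibble::tibble(
    id = 1L, kind = "DC", minute = 0:10, x_um = seq(0, 50, 5), y_um = 0))
  expect_equal(chemotaxis_index(straight, target = c(1000, 0))$ci, 1)
  expect_equal(chemotaxis_index(straight, target = c(-1000, 0))$ci, -1)
  # zero path flagged
  frozen <- make_tracks(tibble::tibble(
    id = 1L, kind = "DC", minute = 0:5, x_um = 3, y_um = 4))
  z <- chemotaxis_index(frozen, target = c(10, 0))
  expect_equal(z$ci, 0)
  expect_identical(z$flag, "zero_path")
  # unbiased random walks: mean CI within 3 SE of zero over 30 seeds
  cis <- vapply(1:30, function(s) {
    withr::with_seed(s, {
      steps <- matrix(stats::rnorm(2 * 200), ncol = 2)
      pos <- apply(steps, 2, cumsum)
      tr <- make_tracks(tibble::tibble(id = 1L, kind = "DC", minute = 1:200,
                                       x_um = pos[, 1], y_um = pos[, 2]))
      chemotaxis_index(tr, target = c(500, 0))$ci
    })
  }, numeric(1))
  expect_lt(abs(mean(cis)), 3 * stats::sd(cis) / sqrt(length(cis)))
})

test_that("displacement-direction histogram resolves the SL bias", {
  up <- make_tracks(tibble::tibble(
    id = 1L, kind = "DC", minute = 0:20, x_um = 0, y_um = seq(0, 100, 5)))
  h <- displacement_direction_histogram(up)
  expect_identical(which(h$count > 0), 1L)        # all mass at 0 degrees
  expect_equal(attr(h, "mean_angle"), 0)
  # isotropic steps: uniform over bins (chi-squared, p > 0.01)
  withr::with_seed(99, {
    ang <- stats::runif(4000, 0, 2 * pi)
    tr <- make_tracks(tibble::tibble(
      id = rep(1:20, each = 200), kind = "DC",
      minute = rep(1:200, 20),
      x_um = as.vector(apply(matrix(cos(ang), 200), 2, cumsum)),
      y_um = as.vector(apply(matrix(sin(ang), 200), 2, cumsum))))
  })
  h2 <- displacement_direction_histogram(tr)
  # projected isotropic angles are NOT uniform in angle; compare against
  # the sin-weighted expectation... in 2D, angle to an axis IS uniform
  p <- stats::chisq.test(h2$count)$p.value
  expect_gt(p, 0.01)
})

test_that("metrics are pure functions of their inputs", {
  set.seed(44)
  cfg <- scenario_config("fix", geometry = small_geom(), replicates = 1,
                         base_seed = 3, duration_min = 60, mcs_min = 0.05)
  r <- run_replicate(cfg, 1)
  a <- intercalation_summary(r$tracks, sep_y_um = epiboly:::sep_y_um(r$state))
  b <- intercalation_summary(r$tracks, sep_y_um = epiboly:::sep_y_um(r$state))
  expect_identical(a, b)
  expect_identical(tissue_thickness(r$state), tissue_thickness(r$state))
})
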
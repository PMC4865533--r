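# Chemoattractant secretion, diffusion, decay, and the chemotaxis term.

test_that("without secretion the total concentration decays monotonically", {
  st <- toy_state(list(list(x = 5:12, y = 5:12)), w = 25, h = 25, c0 = 0)
  st$conc[10:15, 10:15] <- 2
  ch <- chemo_params(lambda_chem = 0)
  totals <- numeric(12)
  for (k in 1:12) {
    st <- step_field(st, 0.5, ch)
    totals[k] <- sum(st$conc)
  }
  expect_true(all(diff(totals) < 0))
  expect_true(all(st$conc >= 0))
})

test_that("1-D source-sink steady state follows c0 * exp(-x / sqrt(D/k))", {
  # clamped reservoir column at the left edge of a quasi-1D strip
  w <- 80; h <- 7
  labels <- matrix(0L, w, h)
  cells <- epiboly:::empty_cells()
  gm <- list(width = w, height = h, spacing = 2.5, sep_row = -1L,
             anchor_lx = -1L, anchor_rx = -1L, explant = TRUE, target = NULL,
             clamp = list(sites = 0L + w * (0:(h - 1L)), value = 1))
  st <- epiboly:::new_cpm_state(labels, matrix(0, w, h), cells,
                                epiboly:::empty_bonds(),
                                epiboly:::empty_links(), gm)
  ch <- chemo_params(lambda_chem = 0, D = 25, k_decay = 0.5)
  st <- step_field(st, 60, ch)      # ample time to reach steady state
  lambda <- sqrt(ch$D / ch$k_decay)
  x <- 4:40                          # beyond 3 sites from the clamp
  measured <- st$conc[x + 1, 4]
  expected <- exp(-x / lambda)
  expect_lt(max(abs(measured / expected - 1)), 0.02)
})

test_that("uniform production reaches the maintained level c0", {
  # one producing cell filling the whole grid: zero-flux borders, secretion
  # balances decay at conc = c0 everywhere
  w <- 20; h <- 20
  labels <- matrix(10L, w, h)
  cells <- tibble::tibble(id = 10L, kind = "DC", volume = w * h,
                          target_volume = w * h, frozen = FALSE, c0 = 1,
                          division_time = NA_real_, divided = TRUE,
                          cx = NA_real_, cy = NA_real_)
  gm <- list(width = w, height = h, spacing = 2.5, sep_row = -1L,
             anchor_lx = -1L, anchor_rx = -1L, explant = TRUE, target = NULL,
             clamp = NULL)
  st <- epiboly:::new_cpm_state(labels, matrix(0, w, h), cells,
                                epiboly:::empty_bonds(),
                                epiboly:::empty_links(), gm)
  st <- epiboly:::refresh_centroids(st)
  st <- step_field(st, 30, chemo_params(lambda_chem = 0))
  expect_lt(max(abs(st$conc - 1)), 1e-3)
})

test_that("time-stepped steady state matches the dense Helmholtz solve", {
  w <- 16; h <- 12
  st <- toy_state(list(list(x = 5:10, y = 7:10)), w = w, h = h, c0 = 1)
  ch <- chemo_params(lambda_chem = 0, D = 10, k_decay = 0.8)
  st <- step_field(st, 80, ch)
  idx <- which(st$labels == 10L)
  ref <- chemo_steady_dense(w, h, source_idx = idx,
                            source_rate = ch$k_decay * 1,
                            D = ch$D, k_decay = ch$k_decay)
  expect_lt(max(abs(st$conc - ref)) / max(ref), 1e-4)
})

test_that("chemotaxis energy follows the concentration difference", {
  st <- toy_state(list(list(x = 5:12, y = 5:12),
                       list(x = 13:20, y = 5:12)),
                  kinds = c("DC", "SC"))
  st$conc[, ] <- 0.5
  ch <- chemo_params(lambda_chem = 50)
  # flat field: zero
  expect_equal(chemotaxis_energy_delta(st, c(12, 8), c(13, 8), ch), 0)
  # known difference: -lambda * dc for a DC extension
  st$conc[13, 8] <- 2.5   # +2.0 over the source site
  d <- chemotaxis_energy_delta(st, c(12, 8), c(13, 8), ch)
  expect_equal(d, -50 * 2.0)
  # an SC extending in the same gradient contributes nothing
  d_sc <- chemotaxis_energy_delta(st, c(13, 8), c(12, 8), ch)
  st2 <- st
  st2$conc[12, 8] <- 5
  d_sc2 <- chemotaxis_energy_delta(st2, c(13, 8), c(12, 8), ch)
  expect_equal(d_sc, 0)
  expect_equal(d_sc2, 0)
  # frozen DCs contribute nothing
  st$cells$frozen[1] <- TRUE
  expect_equal(chemotaxis_energy_delta(st, c(12, 8), c(13, 8), ch), 0)
})

test_that("radial profile decreases from the SL toward the cavity", {
  set.seed(3)
  st <- build_bcr(small_geom(), chemo_params())
  st <- step_field(st, 30, chemo_params())
  pr <- radial_profile(st)
  below <- pr[pr$depth_um >= 0 & pr$depth_um <= 40, ]
  below <- below[order(below$depth_um), ]
  expect_true(all(diff(below$mean_conc) < 0))
  # no secretion: all-zero profile
  st0 <- build_bcr(small_geom(), chemo_params(pattern = "none"))
  st0 <- step_field(st0, 5, chemo_params(pattern = "none"))
  expect_true(all(radial_profile(st0)$mean_conc == 0))
})

test_that("ubiquitous production forms a gradient toward the cavity", {
  set.seed(4)
  ch <- chemo_params(pattern = "ubiquitous")
  st <- build_bcr(small_geom(), ch)
  st <- step_field(st, 30, ch)
  pr <- radial_profile(st)
  # concentration at the DL bottom edge drops toward the cavity interior
  deep <- pr[pr$depth_um >= 30 & pr$depth_um <= 60, ]
  deep <- deep[order(deep$depth_um), ]
  expect_true(all(diff(deep$mean_conc) < 0))
})

test_that("mosaic and uniform secretion give similar gradients at depth", {
  set.seed(5)
  # equal total secretion: the mosaic (alternating SCs) at double rate
  ch_u <- chemo_params(pattern = "uniform-SL", c0 = 1, lambda_chem = 0)
  ch_m <- chemo_params(pattern = "mosaic-SL", c0 = 2, lambda_chem = 0)
  st_u <- step_field(build_bcr(small_geom(), ch_u), 40, ch_u)
  st_m <- step_field(build_bcr(small_geom(), ch_m), 40, ch_m)
  pr_u <- radial_profile(st_u)
  pr_m <- radial_profile(st_m)
  sel <- pr_u$depth_um >= 20 & pr_u$depth_um <= 45   # >= 1 cell diameter deep
  rel <- abs(pr_m$mean_conc[sel] / pr_u$mean_conc[sel] - 1)
  expect_lt(max(rel), 0.10)
})

test_that("unstable diffusion settings error at load", {
  expect_error(chemo_params(D = 100, dt_chem = 0.005), "unstable")
  expect_error(step_field(toy_state(list(list(x = 1:2, y = 1:2))), 0.3012,
                          chemo_params()), "multiple")
})
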
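# SL integrity (neighbor bonds, basal contact) and elastic DC-SC links.

test_that("SCs never drop below the minimal basal contact", {
  set.seed(31)
  st <- build_bcr(small_geom())
  for (k in 1:8) {
    st <- advance(st, 25, seed = 100 + k)
    sc <- st$cells[st$cells$kind == "SC" & !st$cells$frozen, ]
    sep <- st$geom$sep_row
    for (id in sc$id) {
      sites <- which(st$labels == id, arr.ind = TRUE)
      contact <- sum(sites[, 2] == sep + 1L)
      expect_gte(contact, 2)
    }
  }
})

test_that("deep cells never invade the superficial compartment", {
  set.seed(32)
  cfg <- scenario_config("fix", geometry = small_geom(), replicates = 1,
                         base_seed = 7, duration_min = 120, mcs_min = 0.05)
  r <- run_replicate(cfg, 1)
  st <- r$state
  sep <- st$geom$sep_row
  dc_ids <- st$cells$id[st$cells$kind == "DC"]
  above <- st$labels[, (sep + 1):ncol(st$labels)]
  expect_false(any(above %in% dc_ids))
})

test_that("links form on basal contact with the SC above and break by rule", {
  set.seed(33)
  st <- build_bcr(small_geom())
  # with p_form = 1 every separator-touching DC links within one tick
  st1 <- advance(st, 10, links = link_params(p_form = 1), seed = 5)
  dc_touch <- st1$cells$id[st1$cells$kind == "DC" & !st1$cells$frozen]
  sep <- st1$geom$sep_row
  touching <- vapply(dc_touch, function(id) {
    s <- which(st1$labels == id, arr.ind = TRUE)
    any(s[, 2] == sep - 1L)
  }, logical(1))
  linked <- dc_touch[touching] %in% st1$links$dc
  expect_true(all(linked))
  # rest length equals the centroid distance at formation (within the
  # movement of a single tick)
  lk <- st1$links[1, ]
  dc <- st1$cells[match(lk$dc, st1$cells$id), ]
  sc <- st1$cells[match(lk$sc, st1$cells$id), ]
  expect_lt(abs(lk$length - sqrt((dc$cx - sc$cx)^2 + (dc$cy - sc$cy)^2)), 1e-6)
  expect_equal(sc$kind, "SC")
  # p_break = 1 clears all links at the next tick
  st2 <- advance(st1, 10, links = link_params(p_form = 0, p_break = 1), seed = 6)
  expect_identical(nrow(st2$links), 0L)
  # at most one link per DC
  st3 <- advance(st, 20, links = link_params(p_form = 1, p_break = 0), seed = 7)
  expect_false(any(duplicated(st3$links$dc)))
})

test_that("overstretched links are removed", {
  # one DC linked to one SC across a separator; the DC is then displaced
  # along the separator to twice the rest length
  w <- 60; h <- 30; sep <- 12
  make <- function(dc_x0) {
    labels <- matrix(0L, w, h)
    labels[, seq_len(sep - 1)] <- 1L
    labels[, sep] <- 2L
    labels[10:19, (sep + 1):(sep + 10)] <- 11L                 # SC above
    labels[dc_x0:(dc_x0 + 7L), (sep - 8L):(sep - 1L)] <- 10L   # DC below
    cells <- tibble::tibble(id = c(10L, 11L), kind = c("DC", "SC"),
                            volume = c(64L, 100L), target_volume = c(64, 100),
                            frozen = FALSE, c0 = 0,
                            division_time = NA_real_, divided = TRUE,
                            cx = NA_real_, cy = NA_real_)
    gm <- list(width = w, height = h, spacing = 2.5, sep_row = sep,
               anchor_lx = -1L, anchor_rx = -1L, explant = FALSE,
               target = NULL, clamp = NULL)
    st <- epiboly:::new_cpm_state(labels, matrix(0, w, h), cells,
                                  epiboly:::empty_bonds(),
                                  epiboly:::empty_links(), gm)
    epiboly:::refresh_centroids(st)
  }
  st <- make(11L)
  st$links <- tibble::tibble(dc = 10L, sc = 11L, rest = 9, age = 0L,
                             length = 9)
  lk_par <- link_params(p_form = 0, p_break = 0)
  # near rest length: the link survives a tick
  st1 <- advance(st, 10, links = lk_par, seed = 9)
  expect_true(10L %in% st1$links$dc)
  # displaced to > 2 x rest (still touching the separator): removed
  st2 <- make(45L)
  st2$links <- st$links
  st2 <- advance(st2, 10, links = lk_par, seed = 10)
  expect_false(10L %in% st2$links$dc)
})

test_that("link energy matches a from-scratch recount", {
  set.seed(35)
  st <- build_bcr(small_geom())
  st <- advance(st, 10, links = link_params(p_form = 0.8), seed = 10)
  expect_gt(nrow(st$links), 2)
  en <- energy_params()
  lk_par <- link_params(k_spring = 0.7)
  H <- cpm_hamiltonian(st, en, chemo_params(), lk_par)
  by_hand <- sum(lk_par$k_spring * (st$links$length - st$links$rest)^2)
  expect_equal(H$link, by_hand, tolerance = 1e-9)
  # moving a linked cell by one site changes the link energy consistently
  lk <- st$links[1, ]
  sites <- which(st$labels == lk$dc, arr.ind = TRUE)
  bottom <- sites[which.min(sites[, 2]), ]
  d <- epiboly:::delta_components(st, c(bottom[1], bottom[2] - 1L), lk$dc,
                                  energy = en, links = lk_par)
  st2 <- st
  st2$labels[bottom[1], bottom[2] - 1L] <- lk$dc
  st2 <- epiboly:::refresh_centroids(st2)
  H2 <- cpm_hamiltonian(st2, en, chemo_params(), lk_par)
  expect_equal(d$mech, H2$link - H$link, tolerance = 1e-9)
})

test_that("separated neighbor SCs are pulled back into contact", {
  # two SCs on a separator with a gap hammered in between them
  w <- 40; h <- 26; sep <- 8
  labels <- matrix(0L, w, h)
  labels[, seq_len(sep - 1)] <- 1L
  labels[, sep] <- 2L
  labels[6:15, (sep + 1):(sep + 10)] <- 10L
  labels[24:33, (sep + 1):(sep + 10)] <- 11L
  cells <- tibble::tibble(id = c(10L, 11L), kind = "SC", volume = 100L,
                          target_volume = 100, frozen = FALSE, c0 = 0,
                          division_time = NA_real_, divided = TRUE,
                          cx = NA_real_, cy = NA_real_)
  bonds <- tibble::tibble(a = 10L, b = 11L, active = FALSE, d0 = 0)
  gm <- list(width = w, height = h, spacing = 2.5, sep_row = sep,
             anchor_lx = -1L, anchor_rx = -1L, explant = FALSE, target = NULL,
             clamp = NULL)
  st <- epiboly:::new_cpm_state(labels, matrix(0, w, h), cells, bonds,
                                epiboly:::empty_links(), gm)
  st <- epiboly:::refresh_centroids(st)
  en <- energy_params(temperature = 4)
  lk <- link_params(k_coh = 5)
  restored <- 0
  for (trial in 1:6) {
    s <- st
    for (k in 1:40) {
      s <- advance(s, 25, en, chemo_params(lambda_chem = 0), lk,
                   seed = 1000 * trial + k)
      area <- contact_area_cpp(s$labels, 10L, 11L)
      if (area >= lk$contact_threshold) break
    }
    if (contact_area_cpp(s$labels, 10L, 11L) >= lk$contact_threshold)
      restored <- restored + 1
  }
  expect_gte(restored, 5)
})
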
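#' Contact-energy and Metropolis parameters
#'
#' Defines the adhesion energies `J` between the six site classes of the
#' lattice (deep cell \code{DC}, superficial cell \code{SC}, blastocoel
#' \code{cavity}, \code{external} medium, immutable \code{separator} and
#' \code{anchor}), the volume-constraint stiffness and the Metropolis
#' temperature. Boundary sites of two different labels pay `J(kindA, kindB)`
#' per neighboring site pair over the 4th-order (20-site) neighborhood;
#' same-label contacts cost nothing. Defaults are the package's calibrated
#' values for the standard blastocoel-roof scenario.
#'
#' @param J named 6x6 symmetric matrix of contact energies. Row/column order
#'   \code{DC, SC, cavity, external, separator, anchor}. If `NULL`, the
#'   calibrated defaults are used.
#' @param lambda_volume energy per squared site of deviation from target
#'   volume.
#' @param temperature energy scale of the Metropolis acceptance; must be > 0.
#' @return a list of class `energy_params`.
#' @export
energy_params <- function(J = NULL, lambda_volume = 1, temperature = 10) {
  kinds <- c("DC", "SC", "cavity", "external", "separator", "anchor")
  if (is.null(J)) {
    # Calibrated values. Per-pair energies are summed over the 20-site
    # contact neighborhood, so the J scale is ~5x smaller than
    # 1st-order-neighborhood intuition. Cells adhere strongly to the basal
    # separator (low J) and the bare separator is costly (high J against
    # cell-free space), so both layers wet the basal membrane.
    J <- matrix(0, 6, 6, dimnames = list(kinds, kinds))
    J["DC", "DC"] <- 0.8
    J["SC", "SC"] <- 0.8
    J["DC", "SC"] <- J["SC", "DC"] <- 1.0
    J["DC", "cavity"] <- J["cavity", "DC"] <- 2.0
    J["SC", "cavity"] <- J["cavity", "SC"] <- 2.0
    J["DC", "external"] <- J["external", "DC"] <- 2.8
    J["SC", "external"] <- J["external", "SC"] <- 2.8
    J["SC", "separator"] <- J["separator", "SC"] <- 0.1
    J["DC", "separator"] <- J["separator", "DC"] <- 0.1
    J["separator", "cavity"] <- J["cavity", "separator"] <- 2.0
    J["separator", "external"] <- J["external", "separator"] <- 2.0
    J["SC", "anchor"] <- J["anchor", "SC"] <- 0.4
    J["DC", "anchor"] <- J["anchor", "DC"] <- 1.2
    J["anchor", "cavity"] <- J["cavity", "anchor"] <- 0.5
    J["anchor", "external"] <- J["external", "anchor"] <- 0.5
  }
  stopifnot(is.matrix(J), all(dim(J) == c(6, 6)))
  if (max(abs(J - t(J))) > 1e-12) stop("contact matrix J must be symmetric")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(J = J, lambda_volume = lambda_volume,
                 temperature = temperature),
            class = "energy_params")
}

#' Chemoattractant field parameters
#'
#' Producing cells secrete at rate `k_decay * c0` per site, so the field is
#' maintained at a constant level `c0` inside a wide producing region; it
#' diffuses with constant `D` and decays at rate `k_decay`, giving a
#' short-range gradient of decay length `sqrt(D / k_decay)` (about 7 sites,
#' i.e. 18 um, at the defaults) wherever producing tissue meets cell-free
#' space. Deep cells bias their membrane extensions up-gradient with
#' strength `lambda_chem`.
#'
#' @param lambda_chem energy per unit concentration difference, applied to
#'   extensions of unfrozen deep cells only.
#' @param D diffusion constant, site^2 per minute.
#' @param k_decay decay rate, 1/minute.
#' @param c0 maintained concentration level at producing cells (arbitrary
#'   units); the secretion rate is `k_decay * c0`.
#' @param dt_chem diffusion substep, minutes. The explicit scheme requires
#'   `D * dt_chem <= 0.25` (site spacing of 1); violations error at load.
#' @param pattern secretion pattern: `"uniform-SL"` (all SCs secrete),
#'   `"mosaic-SL"` (alternating SCs), `"ubiquitous"` (all cells),
#'   `"localized-SL"` (central third of the SL), or `"none"`.
#' @param level_multiplier dimensionless rescaling of the clamp level (the
#'   0.1x--3x secretion axis).
#' @return a list of class `chemo_params`.
#' @export
chemo_params <- function(lambda_chem = 400, D = 25, k_decay = 0.5, c0 = 1,
                         dt_chem = 0.005,
                         pattern = c("uniform-SL", "mosaic-SL", "ubiquitous",
                                     "localized-SL", "none"),
                         level_multiplier = 1) {
  pattern <- match.arg(pattern)
  if (lambda_chem < 0) stop("lambda_chem must be >= 0")
  if (D * dt_chem > 0.25 + 1e-12)
    stop("unstable diffusion scheme: D * dt_chem must be <= 0.25")
  structure(list(lambda_chem = lambda_chem, D = D, k_decay = k_decay,
                 c0 = c0, dt_chem = dt_chem, pattern = pattern,
                 level_multiplier = level_multiplier),
            class = "chemo_params")
}

#' Elastic DC-SC link and SL cohesion parameters
#'
#' Once a deep cell touches the immutable basal layer it may form an elastic
#' connection to the superficial cell immediately above it (probability
#' `p_form` per sweep). A link breaks when the DC loses basal contact, when
#' it stretches to twice its rest length, or spontaneously with probability
#' `p_break` per sweep. Assigned SC neighbor pairs whose contact area falls
#' below `contact_threshold` boundary sites are pulled back together by a
#' quadratic centroid-separation bias of strength `k_coh` until contact is
#' restored.
#'
#' @param p_form per-sweep link formation probability.
#' @param p_break per-sweep spontaneous link breaking probability.
#' @param k_spring spring constant, energy per squared site of extension.
#' @param contact_threshold minimum SC-SC contact area (boundary site pairs).
#' @param k_coh strength of the cohesion-restoring bias.
#' @param sc_min_contact minimal number of separator-adjacent sites each SC
#'   must keep (moves violating it are rejected).
#' @return a list of class `link_params`.
#' @export
link_params <- function(p_form = 0.2, p_break = 0.02, k_spring = 1.5,
                        contact_threshold = 3, k_coh = 2,
                        sc_min_contact = 2) {
  stopifnot(p_form >= 0, p_form <= 1, p_break >= 0, p_break <= 1,
            k_spring >= 0, k_coh >= 0)
  structure(list(p_form = p_form, p_break = p_break, k_spring = k_spring,
                 contact_threshold = as.integer(contact_threshold),
                 k_coh = k_coh, sc_min_contact = as.integer(sc_min_contact)),
            class = "link_params")
}

# Assemble the flat parameter list consumed by the compiled engine.
#   `clamp` optionally carries list(sites = 0-based site indices, value = c0)
#   for a fixed chemoattractant source that is not a cell (purified-source
#   explant assay).
params_cpp <- function(energy, chemo, links, boundary = TRUE,
                       replenish = TRUE, replenish_w = 12L, dc_c0 = 0,
                       mcs_min = 0.02, tick_min = 0.1,
                       record_every_min = 1L, clamp = NULL) {
  p <- list(J = unname(energy$J),
            lambda_v = energy$lambda_volume,
            temperature = energy$temperature,
            lambda_chem = chemo$lambda_chem,
            D = chemo$D, k_decay = chemo$k_decay, dt_chem = chemo$dt_chem,
            level_multiplier = chemo$level_multiplier,
            p_form = links$p_form, p_break = links$p_break,
            k_spring = links$k_spring, k_coh = links$k_coh,
            contact_threshold = links$contact_threshold,
            sc_min_contact = links$sc_min_contact,
            boundary = boundary, replenish = replenish,
            replenish_w = as.integer(replenish_w), dc_c0 = dc_c0,
            mcs_min = mcs_min, tick_min = tick_min,
            record_every_min = as.integer(record_every_min))
  if (!is.null(clamp)) {
    p$clamp_sites <- as.integer(clamp$sites)
    p$clamp_value <- clamp$value
  }
  p
}
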
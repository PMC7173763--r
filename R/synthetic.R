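# Synthetic test-data generators.
#
# A toy tetrameric channel replaces undeposited MD trajectories: a global
# two-state Markov latent variable (open/closed) drives all three gating
# observables per frame, producing the bimodal distributions and strong
# latent-state-induced cross-correlations the analysis modules must recover.
# A companion generator produces microstate energy tables with known
# ground-truth titration behaviour.

#' Toy channel generator specification
#'
#' Defaults mirror the published observations: kink dihedral modes at 130
#' (bent S6, open) and 245 degrees (straight S6, closed), inter-subunit
#' distances 6.0 vs 14.7 Angstrom, and cavity water counts of 25 (wet) vs
#' 3 (dewet).
#'
#' @param n_frames frames per trajectory.
#' @param p_switch per-frame Markov switch probability (both directions
#'   unless overridden).
#' @param p_open_to_closed,p_closed_to_open directional overrides.
#' @param start_state `"open"`, `"closed"`, or `"random"` (stationary draw).
#' @param dihedral_mean,dihedral_sd degrees; named open/closed means.
#' @param distance_mean,distance_sd Angstrom; named open/closed means.
#' @param water_rate expected cavity water counts (Poisson), open/closed.
#' @param cavity_radius,cavity_height cavity cylinder, Angstrom.
#' @param jitter_sd isotropic Gaussian positional jitter, Angstrom.
#' @param seed RNG seed.
#' @return list of class `toy_channel_spec`.
#' @export
toy_channel_spec <- function(n_frames = 2000L, p_switch = 0.05,
                             p_open_to_closed = p_switch,
                             p_closed_to_open = p_switch,
                             start_state = "open",
                             dihedral_mean = c(open = 130, closed = 245),
                             dihedral_sd = 10,
                             distance_mean = c(open = 6.0, closed = 14.7),
                             distance_sd = 1.0,
                             water_rate = c(open = 25, closed = 3),
                             cavity_radius = 5, cavity_height = 16,
                             jitter_sd = 0.02, seed = 1L) {
  spec <- list(n_frames = as.integer(n_frames),
               p_open_to_closed = p_open_to_closed,
               p_closed_to_open = p_closed_to_open,
               start_state = start_state,
               dihedral_mean = dihedral_mean, dihedral_sd = dihedral_sd,
               distance_mean = distance_mean, distance_sd = distance_sd,
               water_rate = water_rate,
               cavity_radius = cavity_radius, cavity_height = cavity_height,
               jitter_sd = jitter_sd, seed = as.integer(seed))
  if (spec$n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (any(c(p_open_to_closed, p_closed_to_open) < 0) ||
      any(c(p_open_to_closed, p_closed_to_open) >= 1))
    stop("switch probabilities must lie in [0, 1)", call. = FALSE)
  if (dihedral_sd <= 0 || distance_sd <= 0)
    stop("dihedral_sd and distance_sd must be positive", call. = FALSE)
  if (any(water_rate < 0)) stop("water rates must be >= 0", call. = FALSE)
  if (any(distance_mean <= 0))
    stop("infeasible geometry: distance means must be positive", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (!start_state %in% c("open", "closed", "random"))
    stop("start_state must be open, closed or random", call. = FALSE)
  class(spec) <- c("toy_channel_spec", "list")
  spec
}

# helix scaffold constants (Angstrom): Calpha spacing and planar angle used
# to realise an exact target torsion via the standard internal-coordinate
# construction
TOY_L <- 6
TOY_ALPHA <- 70 * pi / 180

# 4 points whose 1-2-3-4 torsion equals phi (degrees), before rigid motion
#' @noRd
helix_points <- function(phi_deg) {
  phi <- phi_deg * pi / 180
  sa <- sin(TOY_ALPHA); ca <- cos(TOY_ALPHA)
  rbind(c(-TOY_L * ca, TOY_L * sa, 0),
        c(0, 0, 0),
        c(TOY_L, 0, 0),
        c(TOY_L, 0, 0) + TOY_L * c(ca, sa * cos(phi), sa * sin(phi)))
}

#' @noRd
rot_z <- function(ang) {
  c <- cos(ang); s <- sin(ang)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

#' Generate a toy channel trajectory
#'
#' Per frame: the latent gating state follows a two-state Markov chain; each
#' of the four chains carries a 4-point pseudo-helix whose torsion is drawn
#' from the state's wrapped-normal dihedral distribution, single-atom
#' R326/H418 proxy residues are placed on a chord so each adjacent-pair
#' minimum distance equals a draw from the state's distance distribution,
#' and water oxygens are placed uniformly in the cavity cylinder with a
#' state-dependent Poisson count. Axis and bound marker residues (401, 402,
#' 417) encode the cavity geometry. Isotropic Gaussian jitter is added to
#' all coordinates; output is deterministic under the spec's seed.
#'
#' @param spec a [toy_channel_spec()].
#' @param variant_label ensemble label attached to the trajectory.
#' @return list of class `toy_trajectory`: `frames` (a `pore_trajectory`),
#'   `states` (latent ground truth per frame), `spec`.
#' @export
generate_toy_trajectory <- function(spec, variant_label = "toy") {
  stopifnot(inherits(spec, "toy_channel_spec"))
  with_seed(spec$seed, {
    n <- spec$n_frames
    states <- character(n)
    states[1L] <- if (spec$start_state == "random") {
      q <- spec$p_closed_to_open / (spec$p_open_to_closed + spec$p_closed_to_open)
      if (stats::runif(1) < q) "open" else "closed"
    } else spec$start_state
    u <- stats::runif(n)
    for (k in seq_len(n)[-1L]) {
      p <- if (states[k - 1L] == "open") spec$p_open_to_closed else spec$p_closed_to_open
      states[k] <- if (u[k] < p) setdiff(c("open", "closed"), states[k - 1L]) else states[k - 1L]
    }
    ring <- c("A", "B", "C", "D")
    ang <- (seq_along(ring) - 1L) * pi / 2
    h2 <- spec$cavity_height / 2

    # fixed solute template (identity columns); coordinates filled per frame
    per_chain <- data.frame(
      residue_number = c(326L, 393L, 400L, 408L, 415L, 401L, 402L, 417L, 418L),
      residue_name = c("ARG", "LEU", "LEU", "VAL", "TYR", "VAL", "GLY", "PRO", "HIS"),
      atom_name = c("CZ", "CA", "CA", "CA", "CA", "CA", "CA", "CA", "NE2"),
      element = c("C", "C", "C", "C", "C", "C", "C", "C", "N"),
      stringsAsFactors = FALSE)
    solute <- do.call(rbind, lapply(ring, function(ch) cbind(chain_id = ch, per_chain)))

    frames <- vector("list", n)
    for (k in seq_len(n)) {
      st <- states[k]
      phi <- (stats::rnorm(4L, spec$dihedral_mean[[st]], spec$dihedral_sd)) %% 360
      d <- stats::rnorm(4L, spec$distance_mean[[st]], spec$distance_sd)
      d[d < 0.1] <- 0.1
      coords <- matrix(NA_real_, nrow(solute), 3L)
      h418 <- matrix(NA_real_, 4L, 3L)
      for (j in 1:4) {
        anchor <- c(10 * cos(ang[j]), 10 * sin(ang[j]), 0)
        jj <- ((j %% 4L) + 1L)           # chain receiving this pair's H418
        h418[jj, ] <- anchor + d[j] * c(cos(ang[j]), sin(ang[j]), 0)
        base <- (j - 1L) * nrow(per_chain)
        hp <- helix_points(phi[j]) %*% t(rot_z(ang[j]))
        hp <- sweep(hp, 2L, c(9 * cos(ang[j]), 9 * sin(ang[j]), -2), "+")
        coords[base + 1L, ] <- anchor                                   # R326 proxy
        coords[base + 2:5, ] <- hp                                      # helix
        coords[base + 6L, ] <- c(3 * cos(ang[j]), 3 * sin(ang[j]), 0)   # axis marker
        coords[base + 7L, ] <- c(6 * cos(ang[j]), 6 * sin(ang[j]), h2)  # upper bound
        coords[base + 8L, ] <- c(6 * cos(ang[j]), 6 * sin(ang[j]), -h2) # lower bound
      }
      for (j in 1:4) coords[(j - 1L) * nrow(per_chain) + 9L, ] <- h418[j, ]

      nw <- stats::rpois(1L, spec$water_rate[[st]])
      if (nw > 0L) {
        r <- spec$cavity_radius * sqrt(stats::runif(nw))
        th <- stats::runif(nw, 0, 2 * pi)
        wz <- stats::runif(nw, -h2, h2)
        wat <- cbind(r * cos(th), r * sin(th), wz)
      } else wat <- matrix(numeric(0L), 0L, 3L)

      all_xyz <- rbind(coords, wat)
      if (spec$jitter_sd > 0)
        all_xyz <- all_xyz + stats::rnorm(length(all_xyz), 0, spec$jitter_sd)
      all_xyz <- round(all_xyz, 3L)  # PDB fixed-column precision

      frames[[k]] <- structure_frame(
        chain_id = c(solute$chain_id, rep("W", nw)),
        residue_number = c(solute$residue_number, seq_len(nw)),
        residue_name = c(solute$residue_name, rep("HOH", nw)),
        atom_name = c(solute$atom_name, rep("O", nw)),
        x = all_xyz[, 1L], y = all_xyz[, 2L], z = all_xyz[, 3L],
        element = c(solute$element, rep("O", nw)),
        frame_index = k - 1L, time_ns = (k - 1L) * 0.01)
    }
    attr(frames, "variant") <- variant_label
    class(frames) <- "pore_trajectory"
    structure(list(frames = frames, states = states, spec = spec,
                   variant = variant_label),
              class = "toy_trajectory")
  })
}

#' Analytic latent-state-induced correlations of a toy spec
#'
#' Closed-form Pearson correlations implied by the two-state mixture at its
#' stationary occupancy: for observables `X`, `Y` with state-conditional
#' means differing by `dX`, `dY` and within-state variances `vX`, `vY`,
#' `r = u dX dY / sqrt((u dX^2 + vX)(u dY^2 + vY))` with `u = p(1-p)`.
#' Water counts contribute their Poisson variance. Used as the reference
#' value for end-to-end recovery checks.
#'
#' @param spec a [toy_channel_spec()].
#' @return list with `p_open`, `r_dist_dihedral`, `r_waters_dihedral`.
#' @export
toy_expected_correlations <- function(spec) {
  p <- spec$p_closed_to_open / (spec$p_open_to_closed + spec$p_closed_to_open)
  u <- p * (1 - p)
  d_th <- spec$dihedral_mean[["closed"]] - spec$dihedral_mean[["open"]]
  d_d <- spec$distance_mean[["closed"]] - spec$distance_mean[["open"]]
  d_w <- spec$water_rate[["closed"]] - spec$water_rate[["open"]]
  v_th <- spec$dihedral_sd^2
  v_d <- spec$distance_sd^2
  v_w <- p * spec$water_rate[["open"]] + (1 - p) * spec$water_rate[["closed"]]
  r_dd <- u * d_d * d_th / sqrt((u * d_d^2 + v_d) * (u * d_th^2 + v_th))
  r_wd <- u * d_w * d_th / sqrt((u * d_w^2 + v_w) * (u * d_th^2 + v_th))
  list(p_open = p, r_dist_dihedral = r_dd, r_waters_dihedral = r_wd)
}

#' Toy energy-table generator specification
#'
#' @param sites data.frame with `site_id`, `model_pka`, and `shift`
#'   (conformational energy shift per bound proton, kcal/mol).
#' @param couplings symmetric pairwise interaction matrix (kcal/mol), zero
#'   diagonal; scalar 0 expands to no coupling.
#' @param n_structures ensemble structures to emulate.
#' @param noise_sd per-(state, structure) Gaussian energy noise, kcal/mol.
#' @param temperature kelvin (for the ground-truth curves).
#' @param seed RNG seed.
#' @return list of class `toy_energy_spec`.
#' @export
toy_energy_spec <- function(sites, couplings = 0, n_structures = 10L,
                            noise_sd = 0, temperature = 310, seed = 1L) {
  stopifnot(is.data.frame(sites), all(c("site_id", "model_pka", "shift") %in% names(sites)))
  s <- nrow(sites)
  if (s > 20L) stop("at most 20 sites (exact enumeration)", call. = FALSE)
  if (identical(couplings, 0)) couplings <- matrix(0, s, s)
  couplings <- as.matrix(couplings)
  if (!isTRUE(all.equal(couplings, t(couplings))) || any(diag(couplings) != 0))
    stop("couplings must be symmetric with zero diagonal", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(sites = sites, couplings = couplings,
                 n_structures = as.integer(n_structures),
                 noise_sd = noise_sd, temperature = temperature,
                 seed = as.integer(seed)),
            class = c("toy_energy_spec", "list"))
}

# independent direct-sum titration on noiseless microstate energies
# (deliberately plain-arithmetic, separate from the model's log-domain path)
#' @noRd
direct_sum_theta <- function(ms, e0, model_pka, ph, temperature) {
  rt <- rt_kcal(temperature)
  th <- matrix(NA_real_, length(ph), ncol(ms))
  for (i in seq_along(ph)) {
    g <- e0 + log(10) * rt * (rowSums(ms) * ph[i] - as.vector(ms %*% model_pka))
    w <- exp(-(g - min(g)) / rt)
    th[i, ] <- colSums(ms * w) / sum(w)
  }
  colnames(th) <- colnames(ms)
  th
}

#' Generate a microstate energy table with known ground truth
#'
#' `E(x, m) = sum_i x_i shift_i + sum_{i<j} W_ij x_i x_j + noise(x, m)`;
#' the ground-truth protonation curves and pKa values come from full
#' enumeration on the noiseless means, so `shift = ln(10) RT` lowers a
#' site's true pKa by exactly one unit.
#'
#' @param spec a [toy_energy_spec()].
#' @param ph pH grid for the ground-truth curves.
#' @return list of class `toy_energy`: `table` (an [energy_table()]),
#'   `sites` (site table for [titration_fit()]), `truth` (list: `ph`,
#'   `theta`, `pka`).
#' @export
generate_energy_table <- function(spec, ph = seq(3, 8, by = 0.01)) {
  stopifnot(inherits(spec, "toy_energy_spec"))
  with_seed(spec$seed, {
    ms <- enumerate_microstates(spec$sites$site_id)
    e0 <- as.vector(ms %*% spec$sites$shift) +
      0.5 * rowSums((ms %*% spec$couplings) * ms)
    e0 <- round(e0, 6L)  # decimal-exact so tables round-trip through CSV text
    e <- matrix(e0, nrow(ms), spec$n_structures)
    if (spec$noise_sd > 0)
      e <- round(e + matrix(stats::rnorm(length(e), 0, spec$noise_sd), nrow(e)), 6L)
    tab <- energy_table(ms, paste0("S", seq_len(spec$n_structures)), e)
    th <- direct_sum_theta(ms, e0, spec$sites$model_pka, ph, spec$temperature)
    pka <- vapply(seq_len(ncol(th)), function(j)
      pka_from_curve(th[, j], ph)$pka, numeric(1L))
    names(pka) <- spec$sites$site_id
    sites <- data.frame(site_id = spec$sites$site_id,
                        model_pka = spec$sites$model_pka,
                        site_class = spec$sites$site_class %||% "acid",
                        stringsAsFactors = FALSE)
    structure(list(table = tab, sites = sites,
                   truth = list(ph = ph, theta = th, pka = pka), spec = spec),
              class = "toy_energy")
  })
}

# default variant labels: the unprotonated wild type stays open; the
# protonated/mutated forms transition open -> closed
DEFAULT_VARIANTS <- c("WildUnP", "Hp418", "Ep327_Hp418", "Ep420",
                      "Ep327_Hp418_Ep420", "H418R", "E327A_H418R",
                      "E420A", "E327A_H418R_E420A")

#' Generate a labelled suite of toy trajectories
#'
#' Five seeded trajectories per variant. The wild-type-like first variant
#' stays open (open-to-closed rate 0); every other variant starts open and
#' transitions toward closed, emulating ensembles where at least one of the
#' five trajectories closes.
#'
#' @param variants character vector of unique labels (default: nine
#'   protonation/mutation states of the pore-domain residues) or a named list of
#'   [toy_channel_spec()] overrides per label.
#' @param n_trajectories trajectories per variant.
#' @param base_spec spec whose fields the per-variant overrides modify.
#' @param master_seed seed from which all per-trajectory seeds derive.
#' @return named list (variant -> list of `toy_trajectory`).
#' @export
make_variant_suite <- function(variants = DEFAULT_VARIANTS, n_trajectories = 5L,
                               base_spec = toy_channel_spec(), master_seed = 1L) {
  if (!is.list(variants)) {
    labels <- variants
    overrides <- stats::setNames(vector("list", length(labels)), labels)
    for (i in seq_along(labels)) {
      overrides[[i]] <- if (i == 1L)
        list(p_open_to_closed = 0, p_closed_to_open = 0, start_state = "open")
      else
        list(p_open_to_closed = 0.003, p_closed_to_open = 0.001,
             start_state = "open")
    }
  } else overrides <- variants
  labels <- names(overrides)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("variant labels must be unique and non-empty", call. = FALSE)
  seeds <- with_seed(master_seed,
                     matrix(sample.int(.Machine$integer.max %/% 2L,
                                       length(labels) * n_trajectories),
                            nrow = length(labels)))
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) {
    sp <- base_spec
    for (nm in names(overrides[[i]])) sp[[nm]] <- overrides[[i]][[nm]]
    out[[i]] <- lapply(seq_len(n_trajectories), function(j) {
      sp$seed <- seeds[i, j]
      generate_toy_trajectory(do.call(toy_channel_spec, sp[setdiff(names(sp), character(0))]),
                              variant_label = labels[i])
    })
  }
  out
}
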
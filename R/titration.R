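# Ensemble-based multi-site titration.
#
# The pH-dependent free energy of a protonation microstate x over sites i is
#
#   G(x; pH) = <E>(x) + ln(10) R T sum_i x_i (pH - pKa_model,i)   [kcal/mol]
#
# where <E>(x) is the microstate energy averaged over the ensemble
# structures and pKa_model,i is the reference-compound pKa of site i
# (proton-binding convention of constant-pH statistical mechanics). The
# partition function over microstates gives per-site protonation fractions
#
#   theta_i(pH) = sum_x x_i exp(-G(x;pH)/RT) / sum_x exp(-G(x;pH)/RT)
#
# evaluated in the log domain so arbitrary energy offsets are harmless.
# The pKa is the pH where theta crosses 1/2; structural-fluctuation
# uncertainty comes from re-estimating with all microstate energies shifted
# to <E> +/- k sigma(x), k = 0.1 ... 1.0.

# reference-compound pKa values by residue type, used when the sites table
# omits model_pka (inherited convention of continuum-electrostatics tools)
MODEL_PKA_DEFAULTS <- c(E = 4.25, GLU = 4.25, D = 3.71, ASP = 3.71,
                        H = 6.54, HIS = 6.54, K = 10.40, LYS = 10.40,
                        R = 12.10, ARG = 12.10, CTR = 3.80, NTR = 8.00)
ACID_TYPES <- c("E", "GLU", "D", "ASP", "CTR")

#' Default site table for a set of site ids
#'
#' Site ids of the form `E327.A` / `GLU327.A` are mapped to residue-type
#' reference pKa values (Glu 4.25, Asp 3.71, His 6.54, Lys 10.40, Arg 12.10,
#' C-term 3.80, N-term 8.00) and an acid/base class.
#'
#' @param site_ids character vector.
#' @return data.frame with `site_id`, `model_pka`, `site_class`.
#' @export
default_sites <- function(site_ids) {
  type <- toupper(gsub("[^A-Za-z].*$", "", site_ids))
  pka <- MODEL_PKA_DEFAULTS[type]
  if (anyNA(pka))
    stop("cannot infer model pKa for site(s): ",
         paste(site_ids[is.na(pka)], collapse = ", "), call. = FALSE)
  data.frame(site_id = site_ids, model_pka = unname(pka),
             site_class = ifelse(type %in% ACID_TYPES, "acid", "base"),
             stringsAsFactors = FALSE)
}

#' Read a sites CSV (site_id, model_pka, site_class)
#'
#' @param path CSV path.
#' @return data.frame suitable for [titration_fit()].
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "model_pka") %in% names(df)))
    stop("sites CSV needs columns site_id, model_pka", call. = FALSE)
  if (is.null(df$site_class)) df$site_class <- "acid"
  if (any(!is.finite(df$model_pka)))
    stop("non-finite model_pka", call. = FALSE)
  df
}

#' Build a titration model from an energy table
#'
#' Reduces E(microstate, structure) to the per-microstate ensemble mean and
#' standard deviation at a given temperature. With a single structure the
#' sd is zero and uncertainty bands collapse.
#'
#' @param energy an [energy_table()].
#' @param sites data.frame (`site_id`, `model_pka`, `site_class`), or `NULL`
#'   to infer from the table's site ids via [default_sites()].
#' @param temperature kelvin.
#' @return list of class `titration_model`.
#' @export
titration_model <- function(energy, sites = NULL, temperature = 310) {
  stopifnot(inherits(energy, "energy_table"))
  if (length(energy$sites) > 20L)
    stop("more than 20 sites: exact enumeration infeasible; Monte-Carlo ",
         "titration sampling is out of scope", call. = FALSE)
  if (is.null(sites)) sites <- default_sites(energy$sites)
  if (!setequal(sites$site_id, energy$sites))
    stop("sites table does not match energy table site columns", call. = FALSE)
  sites <- sites[match(energy$sites, sites$site_id), , drop = FALSE]
  e <- energy$energy
  sd1 <- if (ncol(e) >= 2L) apply(e, 1L, stats::sd) else rep(0, nrow(e))
  if (ncol(e) < 2L)
    warning("single-structure energy table: sd = 0, uncertainty bands collapse",
            call. = FALSE)
  structure(list(sites = sites,
                 microstates = energy$microstates,
                 energy_mean = rowMeans(e),
                 energy_sd = sd1,
                 n_structures = ncol(e),
                 temperature = temperature),
            class = "titration_model")
}

#' Free energy of a protonation microstate at a pH
#'
#' @param model a [titration_model()].
#' @param protonation 0/1 vector over the model's sites.
#' @param ph pH value(s).
#' @param energy optional replacement for the model's mean energies
#'   (e.g. `<E> + k sigma`).
#' @return kcal/mol, one value per `ph`.
#' @export
microstate_free_energy <- function(model, protonation, ph,
                                   energy = model$energy_mean) {
  stopifnot(length(protonation) == length(model$sites$site_id))
  key <- paste(as.integer(protonation), collapse = "")
  i <- match(key, rownames(model$microstates))
  if (is.na(i)) stop("microstate not present in model", call. = FALSE)
  rt <- rt_kcal(model$temperature)
  np <- sum(protonation)
  pk <- sum(protonation * model$sites$model_pka)
  unname(energy[i] + log(10) * rt * (np * ph - pk))
}

# -G/RT for every microstate (rows) at every pH (columns)
#' @noRd
neg_g_over_rt <- function(model, ph, energy = model$energy_mean, subset = NULL) {
  ms <- model$microstates
  if (!is.null(subset)) {
    ms <- ms[subset, , drop = FALSE]
    energy <- energy[subset]
  }
  rt <- rt_kcal(model$temperature)
  np <- as.vector(ms %*% rep(1, ncol(ms)))
  pk <- as.vector(ms %*% model$sites$model_pka)
  # -G/RT = -E/RT - ln10 * n_prot * pH + ln10 * sum x_i pKa_i
  base <- -energy / rt + log(10) * pk
  outer(base, rep(1, length(ph))) - log(10) * outer(np, ph)
}

#' Protonation fraction of a site across a pH grid
#'
#' Boltzmann average of the site's proton occupancy over microstates,
#' evaluated with overflow-safe log-domain accumulation.
#'
#' @param model a [titration_model()].
#' @param site site id, or `NULL` for all sites.
#' @param ph pH grid (ascending).
#' @param subset integer indices of microstates to use (default all).
#' @param energy optional replacement energies (see
#'   [microstate_free_energy()]).
#' @return For one site a numeric vector over `ph`; otherwise a
#'   `length(ph)` x n_sites matrix.
#' @export
protonation_fraction <- function(model, site = NULL, ph, subset = NULL,
                                 energy = model$energy_mean) {
  lw <- neg_g_over_rt(model, ph, energy = energy, subset = subset)
  ms <- model$microstates
  if (!is.null(subset)) ms <- ms[subset, , drop = FALSE]
  log_z <- col_logsumexp(lw)
  site_ids <- model$sites$site_id
  want <- if (is.null(site)) site_ids else site
  theta <- vapply(want, function(s) {
    j <- ms[, match(s, site_ids)] == 1L
    if (!any(j)) return(rep(0, length(ph)))
    if (all(j)) return(rep(1, length(ph)))
    exp(col_logsumexp(lw[j, , drop = FALSE]) - log_z)
  }, numeric(length(ph)))
  theta <- matrix(theta, nrow = length(ph), dimnames = list(NULL, want))
  if (!is.null(site) && length(site) == 1L) as.vector(theta) else theta
}

#' Select the dominant microstates over a pH grid
#'
#' Union, over grid points, of microstates whose normalised Boltzmann
#' weight reaches `weight_threshold` at that pH; the top-weight state of
#' every grid point is always included. This is the desk-scale analogue of
#' pre-selecting the predominant titration states of a pH range.
#'
#' @param model a [titration_model()].
#' @param ph_grid pH grid.
#' @param weight_threshold in `[0, 1)`.
#' @return sorted integer indices into the model's microstates.
#' @export
select_dominant_states <- function(model, ph_grid, weight_threshold = 1e-6) {
  stopifnot(weight_threshold >= 0, weight_threshold < 1)
  lw <- neg_g_over_rt(model, ph_grid)
  log_z <- col_logsumexp(lw)
  lw_norm <- sweep(lw, 2L, log_z)
  keep <- rowSums(lw_norm >= log(max(weight_threshold, .Machine$double.xmin))) > 0L
  if (weight_threshold == 0) keep <- rep(TRUE, nrow(lw))
  top <- apply(lw_norm, 2L, which.max)
  sort(unique(c(which(keep), top)))
}

# theta -> pKa: smallest pH where theta crosses 1/2, linear interpolation
#' @noRd
pka_from_curve <- function(theta, ph) {
  d <- theta - 0.5
  hit <- which(abs(d) < 1e-12)
  crossings <- which(d[-length(d)] * d[-1L] < 0)
  locs <- c(ph[hit], vapply(crossings, function(i) {
    ph[i] + (ph[i + 1L] - ph[i]) * d[i] / (d[i] - d[i + 1L])
  }, numeric(1L)))
  locs <- sort(unique(locs))
  if (length(locs) == 0L) return(list(pka = NA_real_, multi = FALSE))
  list(pka = locs[1L], multi = length(locs) > 1L)
}

#' Locate the pKa on a titration curve
#'
#' Smallest pH where the protonation fraction crosses 0.5, by linear
#' interpolation between bracketing grid points; `NA` when the curve never
#' crosses. A `multi_crossing` attribute flags curves crossing more than
#' once.
#'
#' @param fraction protonation fractions in `[0, 1]`.
#' @param ph_grid ascending pH grid of the same length.
#' @return numeric pKa (or `NA`), with attribute `multi_crossing`.
#' @export
estimate_pka <- function(fraction, ph_grid) {
  stopifnot(length(fraction) == length(ph_grid), !is.unsorted(ph_grid))
  res <- pka_from_curve(fraction, ph_grid)
  structure(res$pka, multi_crossing = res$multi)
}

#' pKa uncertainty bands from structural energy fluctuation
#'
#' For each k, the pKa is recomputed with every microstate's energy shifted
#' to `<E> + k sigma(x)` and to `<E> - k sigma(x)` (a common sign across
#' microstates, both signs evaluated); the band is the (min, max) of the two
#' results. Bands are nested in k by construction.
#'
#' @param model a [titration_model()].
#' @param site site id.
#' @param ph_grid pH grid.
#' @param subset microstate indices (default all).
#' @param ks shift multipliers, default `0.1 ... 1.0`.
#' @return data.frame with columns `k`, `low`, `high`.
#' @export
pka_uncertainty <- function(model, site, ph_grid, subset = NULL,
                            ks = seq(0.1, 1.0, by = 0.1)) {
  if (all(model$energy_sd == 0) && model$n_structures < 2L)
    warning("single-structure table: uncertainty band collapses to the point",
            call. = FALSE)
  one <- function(energy) {
    th <- protonation_fraction(model, site, ph_grid, subset = subset,
                               energy = energy)
    pka_from_curve(th, ph_grid)$pka
  }
  bounds <- t(vapply(ks, function(k) {
    p <- c(one(model$energy_mean + k * model$energy_sd),
           one(model$energy_mean - k * model$energy_sd))
    if (all(is.na(p))) c(NA_real_, NA_real_) else range(p, na.rm = TRUE)
  }, numeric(2L)))
  data.frame(k = ks, low = bounds[, 1L], high = bounds[, 2L])
}

#' Fit the ensemble titration model
#'
#' The package's central estimator: reduces an energy table to per-microstate
#' ensemble means and standard deviations, selects the microstates dominant
#' anywhere on the pH grid, reconstructs the partition function, and returns
#' per-site protonation curves, pKa point estimates and `<E> +/- k sigma`
#' uncertainty bands as a fitted-model object.
#'
#' @param energy an [energy_table()] (or path to its CSV).
#' @param sites sites data.frame or CSV path; `NULL` infers reference pKa
#'   values from the site ids.
#' @param ph pH grid, default `seq(3, 8, 0.01)`.
#' @param temperature kelvin, default 310.
#' @param weight_threshold dominant-state Boltzmann weight cut.
#' @param ks uncertainty shift multipliers.
#' @return Object of class `titration_fit` with components `sites`, `model`,
#'   `subset`, `ph`, `theta` (grid x sites), `pka` (per-site point estimates
#'   and multi-crossing flags) and `bands` (per site and k).
#' @seealso [coef.titration_fit()], [predict.titration_fit()],
#'   [confint.titration_fit()], [plot.titration_fit()]
#' @export
titration_fit <- function(energy, sites = NULL, ph = seq(3, 8, by = 0.01),
                          temperature = 310, weight_threshold = 1e-6,
                          ks = seq(0.1, 1.0, by = 0.1)) {
  if (is.character(energy)) energy <- read_energy_table(energy)
  if (is.character(sites)) sites <- read_sites_csv(sites)
  model <- titration_model(energy, sites, temperature)
  subset <- select_dominant_states(model, ph, weight_threshold)
  theta <- protonation_fraction(model, site = NULL, ph = ph, subset = subset)
  pk <- lapply(model$sites$site_id, function(s) pka_from_curve(theta[, s], ph))
  pka <- data.frame(site_id = model$sites$site_id,
                    pka = vapply(pk, `[[`, numeric(1L), "pka"),
                    multi_crossing = vapply(pk, `[[`, logical(1L), "multi"),
                    stringsAsFactors = FALSE)
  bands <- do.call(rbind, lapply(model$sites$site_id, function(s) {
    b <- pka_uncertainty(model, s, ph, subset = subset, ks = ks)
    cbind(site_id = s, b)
  }))
  structure(list(sites = model$sites, model = model,
                 subset = subset, n_microstates = nrow(model$microstates),
                 weight_threshold = weight_threshold,
                 uncertainty_scheme = "global common-sign +/- k sigma shift",
                 ph = ph, theta = theta, pka = pka, bands = bands,
                 call = match.call()),
            class = "titration_fit")
}
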
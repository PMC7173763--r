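# Analysis configuration.
#
# A flat YAML-compatible key-value file controls residue selections, the
# cavity geometry, pooling window, pH grid and thresholds. Defaults follow
# the Kv1.2 pore-domain setup: ring order A->B->C->D, kink dihedral over the
# Calpha atoms of L393/L400/V408/Y415, inter-subunit R326->H418 nearest
# heavy-atom distance, pH 3-8 at 310 K.

#' Default analysis configuration
#'
#' @return A named list of class `analysis_config` with all defaults filled.
#' @export
default_config <- function() {
  cfg <- list(
    ring_order = c("A", "B", "C", "D"),
    dihedral_residues = c(393L, 400L, 408L, 415L),
    distance_from = 326L,
    distance_to = 418L,
    distance_atoms = "heavy",      # heavy | all | ca
    cavity_axis_residue = 401L,
    cavity_upper_residue = 402L,   # filter-base bound
    cavity_lower_residue = 417L,   # gate bound
    cavity_radius = 5.0,           # Angstrom
    cavity_axis = "auto",          # frame-derived axis, or a fixed 3-vector
    wet_threshold = "auto",        # waters; auto = inter-mode midpoint
    window_fraction = 0.25,        # last 500 ns of a 2 us run
    stride = 1L,
    ph_min = 3, ph_max = 8, ph_step = 0.01,
    temperature = 310,             # K
    weight_threshold = 1e-6,       # dominant-state Boltzmann weight cut
    energy_unit = "kcal/mol",
    bin_dihedral = 2,              # deg
    bin_distance = 0.25,           # Angstrom
    bin_water = 1,
    smooth_window = 5L,            # bins, moving-average for mode finding
    prominence = 0.1,              # fraction of global max
    correlation = "pearson",       # or spearman
    per_trajectory = FALSE
  )
  class(cfg) <- c("analysis_config", "list")
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!(cfg$window_fraction > 0 && cfg$window_fraction <= 1))
    stop("config field 'window_fraction' must be in (0, 1]", call. = FALSE)
  if (!(cfg$ph_min < cfg$ph_max))
    stop("config field 'ph_min' must be below 'ph_max'", call. = FALSE)
  if (!(cfg$ph_step > 0))
    stop("config field 'ph_step' must be positive", call. = FALSE)
  if (!(cfg$cavity_radius > 0))
    stop("config field 'cavity_radius' must be positive", call. = FALSE)
  if (!(cfg$temperature > 0))
    stop("config field 'temperature' must be positive", call. = FALSE)
  if (length(cfg$dihedral_residues) != 4L)
    stop("config field 'dihedral_residues' must name 4 residues", call. = FALSE)
  if (!identical(cfg$cavity_axis, "auto") &&
      !(is.numeric(cfg$cavity_axis) && length(cfg$cavity_axis) == 3L))
    stop("config field 'cavity_axis' must be \"auto\" or a 3-vector", call. = FALSE)
  if (!cfg$correlation %in% c("pearson", "spearman"))
    stop("config field 'correlation' must be pearson or spearman", call. = FALSE)
  if (!identical(cfg$wet_threshold, "auto") &&
      !(is.numeric(cfg$wet_threshold) && cfg$wet_threshold >= 0))
    stop("config field 'wet_threshold' must be \"auto\" or >= 0", call. = FALSE)
  if (!cfg$energy_unit %in% c("kcal/mol", "kJ/mol"))
    stop("config field 'energy_unit' must be kcal/mol or kJ/mol", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis configuration file
#'
#' Flat YAML key-value file; omitted keys take the defaults of
#' [default_config()], unknown keys are an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `analysis_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    v <- user[[k]]
    if (is.list(v)) v <- unlist(v)
    if (k %in% c("dihedral_residues", "distance_from", "distance_to",
                 "cavity_axis_residue", "cavity_upper_residue",
                 "cavity_lower_residue", "stride", "smooth_window"))
      v <- as.integer(v)
    cfg[[k]] <- v
  }
  validate_config(cfg)
  cfg
}

#' @noRd
ph_grid_of <- function(cfg) seq(cfg$ph_min, cfg$ph_max, by = cfg$ph_step)

#' Write an analysis configuration as YAML
#'
#' @param cfg an `analysis_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
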
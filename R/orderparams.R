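# Per-frame gating order parameters.
#
# Three observables distinguish the open (wet, bent-S6) and closed (dewet,
# straight-S6) pore: the number of water molecules inside a cylindrical
# cavity region, the S6 kink dihedral spanned by four Calpha atoms per
# chain, and the inter-subunit nearest-atom distance between a basic
# residue and the protonatable histidine of the adjacent subunit.

#' Construct a cavity region
#'
#' A finite cylinder: a point on the axis, a unit axis direction, axial
#' bounds relative to that point, and a radius.
#'
#' @param axis_point numeric 3-vector, Angstrom.
#' @param axis_direction numeric 3-vector; normalised internally, must be
#'   unit-norm to within 1e-9 after normalisation of a non-degenerate vector.
#' @param z_low,z_high axial bounds (Angstrom along the axis), `z_low < z_high`.
#' @param radius cylinder radius, Angstrom, > 0.
#' @return An object of class `cavity_region`.
#' @export
cavity_region <- function(axis_point, axis_direction, z_low, z_high, radius) {
  stopifnot(length(axis_point) == 3L, length(axis_direction) == 3L)
  nrm <- vnorm(axis_direction)
  if (nrm < 1e-9) stop("degenerate axis direction", call. = FALSE)
  axis_direction <- axis_direction / nrm
  if (abs(vnorm(axis_direction) - 1) > 1e-9)
    stop("axis direction not unit norm", call. = FALSE)
  if (!(z_low < z_high)) stop("z_low must be below z_high", call. = FALSE)
  if (!(radius > 0)) stop("radius must be positive", call. = FALSE)
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = as.numeric(axis_direction),
                 z_low = as.numeric(z_low), z_high = as.numeric(z_high),
                 radius = as.numeric(radius)),
            class = "cavity_region")
}

#' @noRd
resolve_residue <- function(frame, chain, resno, atoms = "all") {
  rows <- frame$chain_id == chain & frame$residue_number == resno
  if (atoms == "ca") {
    rows <- rows & frame$atom_name == "CA"
  } else if (atoms == "heavy") {
    rows <- rows & frame$element != "H" & !startsWith(frame$atom_name, "H")
  }
  idx <- which(rows)
  if (length(idx) == 0L)
    stop("residue ", resno, " (chain ", chain, ", atoms=", atoms,
         ") resolves to no atom in frame ",
         attr(frame, "frame_index") %||% "?", call. = FALSE)
  idx
}

#' @noRd
ca_centroid <- function(frame, resno, chains) {
  pts <- t(vapply(chains, function(ch) {
    i <- resolve_residue(frame, ch, resno, atoms = "ca")
    colMeans(frame_coords(frame)[i, , drop = FALSE])
  }, numeric(3L)))
  colMeans(pts)
}

#' Derive the cavity cylinder from a frame and config
#'
#' The axis point is the centroid of the axis residue's Calpha over the four
#' chains; the axial bounds are the projections of the upper (filter-base)
#' and lower (gate) residue Calpha centroids. By default the axis direction
#' is taken from the frame itself (unit vector from the lower to the upper
#' centroid) so the region co-rotates with the structure; a fixed lab-frame
#' vector may be forced through `config$cavity_axis`.
#'
#' @param frame a `structure_frame`.
#' @param config an `analysis_config`.
#' @return A [cavity_region()].
#' @export
define_cavity_region <- function(frame, config = default_config()) {
  chains <- config$ring_order
  axis_point <- ca_centroid(frame, config$cavity_axis_residue, chains)
  upper <- ca_centroid(frame, config$cavity_upper_residue, chains)
  lower <- ca_centroid(frame, config$cavity_lower_residue, chains)
  if (identical(config$cavity_axis, "auto")) {
    dir <- upper - lower
    if (vnorm(dir) < 1e-9)
      stop("cannot derive cavity axis: bound centroids coincide", call. = FALSE)
    dir <- dir / vnorm(dir)
  } else {
    dir <- as.numeric(config$cavity_axis)
    dir <- dir / vnorm(dir)
  }
  z_hi <- sum((upper - axis_point) * dir)
  z_lo <- sum((lower - axis_point) * dir)
  cavity_region(axis_point, dir, min(z_lo, z_hi), max(z_lo, z_hi),
                config$cavity_radius)
}

#' Count water molecules inside a cavity region
#'
#' Counts water oxygen atoms whose axial coordinate lies in
#' `[z_low, z_high]` and whose radial distance to the axis is at most the
#' radius; both boundaries inclusive. Water residues are recognised by name
#' (HOH, TIP3, SOL, WAT).
#'
#' @param frame a `structure_frame`.
#' @param region a [cavity_region()].
#' @return Integer count (0 with a warning when the frame has no waters).
#' @export
count_cavity_waters <- function(frame, region) {
  stopifnot(inherits(region, "cavity_region"))
  w <- is_water_row(frame) & (frame$element == "O" | startsWith(frame$atom_name, "O"))
  if (!any(w)) {
    warning("frame contains no water oxygen atoms", call. = FALSE)
    return(0L)
  }
  rel <- sweep(frame_coords(frame)[w, , drop = FALSE], 2L, region$axis_point)
  a <- as.vector(rel %*% region$axis_direction)
  rad2 <- rowSums(rel * rel) - a * a
  rad2[rad2 < 0] <- 0
  sum(a >= region$z_low & a <= region$z_high & sqrt(rad2) <= region$radius)
}

#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate dihedral geometry (collinear bond vectors)", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  deg <- atan2(y, x) * 180 / pi
  if (deg < 0) deg <- deg + 360
  deg %% 360
}

#' S6 kink dihedral of one chain
#'
#' The signed torsion of the four Calpha positions of the configured kink
#' residues (defaults L393, L400, V408, Y415), mapped into `[0, 360)` so
#' the straight-helix population around 245 degrees is not split by the
#' conventional (-180, 180] wrap.
#'
#' @param frame a `structure_frame`.
#' @param residues integer vector of 4 residue numbers, in order.
#' @param chain chain id.
#' @return Dihedral in degrees, `[0, 360)`.
#' @export
compute_kink_dihedral <- function(frame, residues, chain) {
  stopifnot(length(residues) == 4L)
  xyz <- frame_coords(frame)
  p <- lapply(residues, function(r) {
    i <- resolve_residue(frame, chain, r, atoms = "ca")
    if (length(i) != 1L)
      stop("residue ", r, " chain ", chain, " has ", length(i),
           " Calpha atoms", call. = FALSE)
    xyz[i, ]
  })
  torsion_angle(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
}

#' Nearest-atom distance between two residues
#'
#' Minimum Euclidean distance over all atom pairs of the two residues under
#' the configured atom subset (default heavy atoms, robust to
#' protonation-state hydrogen differences).
#'
#' @param frame a `structure_frame`.
#' @param res_a,res_b residue numbers.
#' @param chain_a,chain_b chain ids.
#' @param atoms `"heavy"`, `"all"` or `"ca"`.
#' @return Distance in Angstrom.
#' @export
compute_pair_min_distance <- function(frame, res_a, chain_a, res_b, chain_b,
                                      atoms = "heavy") {
  ia <- resolve_residue(frame, chain_a, res_a, atoms = atoms)
  ib <- resolve_residue(frame, chain_b, res_b, atoms = atoms)
  xyz <- frame_coords(frame)
  a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Extract the order-parameter series of a trajectory
#'
#' One record per frame: cavity water count, the kink dihedral of every
#' chain, and the nearest-atom distance of every adjacent ordered chain
#' pair in the ring (chain i's basic residue to the next chain's histidine).
#' The cavity region is re-derived per frame so the series is invariant
#' under rigid motions of the whole structure.
#'
#' @param frames a `pore_trajectory` or list of `structure_frame`s.
#' @param config an `analysis_config`.
#' @param variant_label ensemble label attached to every record.
#' @return A data.frame of class `order_param_series` with columns `frame`,
#'   `time_ns`, `variant`, `n_waters`, `dih_<chain>` and `dist_<ci>_<cj>`.
#' @export
extract_series <- function(frames, config = default_config(),
                           variant_label = NULL) {
  if (inherits(frames, "toy_trajectory")) frames <- frames$frames
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  variant_label <- variant_label %||% attr(frames, "variant") %||% "unlabelled"
  if (config$stride > 1L)
    frames <- frames[seq(1L, length(frames), by = config$stride)]
  chains <- config$ring_order
  nxt <- c(chains[-1L], chains[1L])
  n <- length(frames)
  nw <- integer(n)
  dih <- matrix(NA_real_, n, length(chains),
                dimnames = list(NULL, paste0("dih_", chains)))
  dst <- matrix(NA_real_, n, length(chains),
                dimnames = list(NULL, paste0("dist_", chains, "_", nxt)))
  for (k in seq_len(n)) {
    fr <- frames[[k]]
    region <- define_cavity_region(fr, config)
    nw[k] <- count_cavity_waters(fr, region)
    for (j in seq_along(chains)) {
      dih[k, j] <- compute_kink_dihedral(fr, config$dihedral_residues, chains[j])
      dst[k, j] <- compute_pair_min_distance(fr, config$distance_from, chains[j],
                                             config$distance_to, nxt[j],
                                             atoms = config$distance_atoms)
    }
  }
  out <- data.frame(
    frame = vapply(frames, function(f) attr(f, "frame_index") %||% NA_integer_,
                   integer(1L)),
    time_ns = vapply(frames, function(f) as.numeric(attr(f, "time_ns") %||% NA_real_),
                     numeric(1L)),
    variant = variant_label,
    n_waters = nw, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(dih), as.data.frame(dst))
  attr(out, "chains") <- chains
  attr(out, "pairs") <- colnames(dst)
  class(out) <- c("order_param_series", "data.frame")
  out
}

#' Convert a series to tidy long format
#'
#' @param series an `order_param_series`.
#' @return data.frame with columns frame, time_ns, variant, parameter, value.
#' @export
series_to_tidy <- function(series) {
  vcols <- setdiff(names(series), c("frame", "time_ns", "variant"))
  do.call(rbind, lapply(vcols, function(cn) {
    data.frame(frame = series$frame, time_ns = series$time_ns,
               variant = series$variant, parameter = cn,
               value = series[[cn]], stringsAsFactors = FALSE)
  }))
}

#' Write / read an order-parameter series CSV
#'
#' Wide per-frame format; `read_series_csv` restores the
#' `order_param_series` class and chain attributes.
#'
#' @param series an `order_param_series`.
#' @param path CSV path.
#' @return `path` (write) or the series (read).
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time_ns <- as.numeric(df$time_ns)
  dihc <- grep("^dih_", names(df), value = TRUE)
  attr(df, "chains") <- sub("^dih_", "", dihc)
  attr(df, "pairs") <- grep("^dist_", names(df), value = TRUE)
  class(df) <- c("order_param_series", "data.frame")
  df
}
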
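# Independent oracles and fixture builders. Each oracle is deliberately a
# different construction from the implementation it checks.

# torsion via perpendicular projections onto the central bond (the
# implementation uses plane normals instead)
oracle_torsion <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  bh <- b2 / sqrt(sum(b2^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * bh) * bh
  v2 <- (p4 - p3) - sum((p4 - p3) * bh) * bh
  cosphi <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  cosphi <- max(-1, min(1, cosphi))
  phi <- acos(cosphi) * 180 / pi
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sum(cr * b2) < 0) phi <- -phi
  phi <- phi %% 360
  phi
}

# all-pairs double loop
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  best
}

# per-point cylinder membership
oracle_cylinder_count <- function(pts, axis_point, axis_dir, z_low, z_high, radius) {
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  n <- 0L
  for (i in seq_len(nrow(pts))) {
    rel <- pts[i, ] - axis_point
    a <- sum(rel * axis_dir)
    rad <- sqrt(max(0, sum(rel^2) - a^2))
    if (a >= z_low && a <= z_high && rad <= radius) n <- n + 1L
  }
  n
}

# direct-sum multi-site titration over an explicit microstate list
# (plain arithmetic with an energy offset; no per-site log-domain machinery)
oracle_theta <- function(microstates, energies, model_pka, ph, temperature) {
  rt <- 0.0019872 * temperature
  th <- matrix(NA_real_, length(ph), ncol(microstates))
  for (i in seq_along(ph)) {
    g <- energies + log(10) * rt *
      (rowSums(microstates) * ph[i] - as.vector(microstates %*% model_pka))
    w <- exp(-(g - min(g)) / rt)
    th[i, ] <- colSums(microstates * w) / sum(w)
  }
  colnames(th) <- colnames(microstates)
  th
}

# random proper rotation + translation
random_rigid <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 20))
}

apply_rigid <- function(frame, rigid) {
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(rigid$R)
  xyz <- sweep(xyz, 2, rigid$t, "+")
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

mirror_frame <- function(frame) {
  frame$z <- -frame$z
  frame
}

# frame of bare points (all treated as water oxygens for counting tests)
water_frame <- function(pts) {
  structure_frame(chain_id = rep("W", nrow(pts)),
                  residue_number = seq_len(nrow(pts)),
                  residue_name = "HOH", atom_name = "O",
                  x = pts[, 1], y = pts[, 2], z = pts[, 3], element = "O")
}

# random 8-site model as an energy_table + site table
random_energy_model <- function(n_sites = 8, n_structures = 3, seed = 1) {
  withr::with_seed(seed, {
    ids <- paste0("E", 300 + seq_len(n_sites), ".A")
    ms <- enumerate_microstates(ids)
    e <- matrix(rnorm(nrow(ms) * n_structures, 0, 2), nrow(ms))
    sites <- data.frame(site_id = ids,
                        model_pka = runif(n_sites, 3.5, 7.5),
                        site_class = "acid", stringsAsFactors = FALSE)
    list(table = energy_table(ms, paste0("S", seq_len(n_structures)), e),
         sites = sites)
  })
}
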
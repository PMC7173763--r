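# Geometry of the three gating observables.

test_that("cavity region derives from axis and bound residue centroids", {
  # 4 axis CA at (+-1, +-1, 0) -> axis point at the origin
  fr <- structure_frame(
    chain_id = rep(c("A", "B", "C", "D"), times = 3),
    residue_number = rep(c(401L, 402L, 417L), each = 4),
    residue_name = "GLY", atom_name = "CA",
    x = c(1, -1, -1, 1, 2, -2, -2, 2, 2, -2, -2, 2),
    y = c(1, 1, -1, -1, 2, 2, -2, -2, 2, 2, -2, -2),
    z = c(rep(0, 4), rep(10, 4), rep(-5, 4)))
  reg <- define_cavity_region(fr)
  expect_equal(reg$axis_point, c(0, 0, 0))
  expect_equal(reg$axis_direction, c(0, 0, 1))
  expect_equal(reg$z_high, 10)
  expect_equal(reg$z_low, -5)
  expect_equal(reg$radius, 5)
})

test_that("toy frames reproduce the generator's cavity geometry", {
  sp <- toy_channel_spec(n_frames = 1, jitter_sd = 1e-9, seed = 2)
  tr <- generate_toy_trajectory(sp)
  reg <- define_cavity_region(tr$frames[[1]])
  expect_equal(reg$axis_point, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(reg$z_high, sp$cavity_height / 2, tolerance = 1e-6)
  expect_equal(reg$z_low, -sp$cavity_height / 2, tolerance = 1e-6)
})

test_that("water counting is boundary-inclusive and matches per-point membership", {
  reg <- cavity_region(c(0, 0, 0), c(0, 0, 1), -5, 5, 3)
  fr <- water_frame(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, -4),   # inside
                          c(0, 0, 6), c(5, 0, 0)))               # outside
  expect_identical(count_cavity_waters(fr, reg), 3L)
  # exactly on the radius and exactly at an axial bound both count
  fr2 <- water_frame(rbind(c(3, 0, 0), c(0, 0, 5), c(0, 3, -5)))
  expect_identical(count_cavity_waters(fr2, reg), 3L)

  withr::with_seed(42, {
    pts <- matrix(runif(500 * 3, -8, 8), ncol = 3)
    ap <- c(0.5, -0.3, 1); ad <- c(0.2, 0.3, 0.9)
    expect_identical(
      count_cavity_waters(water_frame(pts), cavity_region(ap, ad, -4, 4, 3.5)),
      oracle_cylinder_count(pts, ap, ad, -4, 4, 3.5))
  })
})

test_that("a frame with no waters counts zero with a warning", {
  fr <- structure_frame("A", 1L, "ALA", "CA", 0, 0, 0)
  reg <- cavity_region(c(0, 0, 0), c(0, 0, 1), -5, 5, 3)
  expect_warning(n <- count_cavity_waters(fr, reg), "no water")
  expect_identical(n, 0L)
})

test_that("water count is monotone in radius and in cylinder height", {
  withr::with_seed(1, {
    pts <- matrix(runif(300 * 3, -6, 6), ncol = 3)
    fr <- water_frame(pts)
    radii <- c(0.5, 1, 2, 3, 4, 6)
    by_r <- vapply(radii, function(r)
      count_cavity_waters(fr, cavity_region(c(0, 0, 0), c(0, 0, 1), -3, 3, r)),
      integer(1))
    expect_true(all(diff(by_r) >= 0))
    tops <- c(0.5, 1, 2, 4, 6)
    by_h <- vapply(tops, function(h)
      count_cavity_waters(fr, cavity_region(c(0, 0, 0), c(0, 0, 1), -h, h, 3)),
      integer(1))
    expect_true(all(diff(by_h) >= 0))
  })
})

kink_frame <- function(p) {
  structure_frame(chain_id = "A", residue_number = c(393L, 400L, 408L, 415L),
                  residue_name = "LEU", atom_name = "CA",
                  x = p[, 1], y = p[, 2], z = p[, 3])
}

test_that("planar cis and trans arrangements give 0 and 180 degrees", {
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(compute_kink_dihedral(kink_frame(cis), c(393, 400, 408, 415), "A"), 0)
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(compute_kink_dihedral(kink_frame(trans), c(393, 400, 408, 415), "A"), 180)
})

test_that("dihedral matches an independent projection oracle on random points", {
  withr::with_seed(7, {
    for (i in 1:200) {
      p <- matrix(rnorm(12, 0, 5), 4, 3)
      got <- compute_kink_dihedral(kink_frame(p), c(393, 400, 408, 415), "A")
      want <- oracle_torsion(p[1, ], p[2, ], p[3, ], p[4, ])
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("dihedral agrees with a reference structural-biology implementation", {
  skip_if_not_installed("bio3d")
  withr::with_seed(8, {
    for (i in 1:25) {
      p <- matrix(rnorm(12, 0, 5), 4, 3)
      got <- compute_kink_dihedral(kink_frame(p), c(393, 400, 408, 415), "A")
      ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4) %% 360
      expect_equal(got, as.numeric(ref), tolerance = 1e-6)
    }
  })
})

test_that("collinear bond vectors raise a degenerate-geometry error", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(compute_kink_dihedral(kink_frame(p), c(393, 400, 408, 415), "A"),
               "degenerate")
})

two_res_frame <- function(a, b) {
  structure_frame(chain_id = c(rep("A", nrow(a)), rep("B", nrow(b))),
                  residue_number = c(rep(326L, nrow(a)), rep(418L, nrow(b))),
                  residue_name = rep(c("ARG", "HIS"), c(nrow(a), nrow(b))),
                  atom_name = paste0("C", seq_len(nrow(a) + nrow(b))),
                  x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]),
                  z = c(a[, 3], b[, 3]))
}

test_that("minimum distance: 3-4-5 singleton case and nearest-pair selection", {
  fr <- two_res_frame(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
  expect_equal(compute_pair_min_distance(fr, 326, "A", 418, "B"), 5)
  fr2 <- two_res_frame(rbind(c(0, 0, 0), c(50, 0, 0)),
                       rbind(c(0, 0, 2), c(80, 0, 0)))
  expect_equal(compute_pair_min_distance(fr2, 326, "A", 418, "B"), 2)
})

test_that("minimum distance matches brute force and is symmetric", {
  withr::with_seed(9, {
    for (i in 1:50) {
      a <- matrix(rnorm(30, 0, 4), 10, 3)
      b <- matrix(rnorm(36, 2, 4), 12, 3)
      fr <- two_res_frame(a, b)
      got <- compute_pair_min_distance(fr, 326, "A", 418, "B")
      expect_equal(got, oracle_min_dist(a, b), tolerance = 1e-12)
      expect_equal(got, compute_pair_min_distance(fr, 418, "B", 326, "A"))
    }
  })
})

test_that("unresolvable residues produce a resolution error", {
  fr <- two_res_frame(rbind(c(0, 0, 0)), rbind(c(1, 0, 0)))
  expect_error(compute_pair_min_distance(fr, 999, "A", 418, "B"), "resolves to no atom")
})

test_that("observables are rigid-motion invariant; mirrors negate the dihedral", {
  sp <- toy_channel_spec(n_frames = 1, seed = 21)
  fr <- generate_toy_trajectory(sp)$frames[[1]]
  cfg <- default_config()
  base_dih <- compute_kink_dihedral(fr, cfg$dihedral_residues, "B")
  base_dst <- compute_pair_min_distance(fr, 326, "A", 418, "B")
  base_cnt <- count_cavity_waters(fr, define_cavity_region(fr, cfg))
  withr::with_seed(10, {
    for (i in 1:20) {
      tfr <- apply_rigid(fr, random_rigid())
      expect_equal(compute_kink_dihedral(tfr, cfg$dihedral_residues, "B"),
                   base_dih, tolerance = 1e-9)
      expect_equal(compute_pair_min_distance(tfr, 326, "A", 418, "B"),
                   base_dst, tolerance = 1e-9)
      expect_identical(count_cavity_waters(tfr, define_cavity_region(tfr, cfg)),
                       base_cnt)
    }
  })
  mfr <- mirror_frame(fr)
  expect_equal(compute_kink_dihedral(mfr, cfg$dihedral_residues, "B"),
               (360 - base_dih) %% 360, tolerance = 1e-9)
  expect_equal(compute_pair_min_distance(mfr, 326, "A", 418, "B"), base_dst)
  expect_identical(count_cavity_waters(mfr, define_cavity_region(mfr, cfg)),
                   base_cnt)
})

test_that("extract_series composes the three single-frame operations", {
  sp <- toy_channel_spec(n_frames = 6, seed = 13)
  tr <- generate_toy_trajectory(sp)
  cfg <- default_config()
  ser <- extract_series(tr$frames, cfg)
  expect_equal(nrow(ser), 6)
  for (k in c(1, 4)) {
    fr <- tr$frames[[k]]
    expect_identical(ser$n_waters[k],
                     count_cavity_waters(fr, define_cavity_region(fr, cfg)))
    expect_equal(ser$dih_C[k],
                 compute_kink_dihedral(fr, cfg$dihedral_residues, "C"))
    expect_equal(ser$dist_B_C[k],
                 compute_pair_min_distance(fr, 326, "B", 418, "C"))
  }
  expect_error(extract_series(list(), cfg), "empty")
})

test_that("tidy export is long-format with one row per (frame, parameter)", {
  tr <- generate_toy_trajectory(toy_channel_spec(n_frames = 3, seed = 1))
  ser <- extract_series(tr$frames)
  tidy <- series_to_tidy(ser)
  expect_setequal(unique(tidy$parameter),
                  c("n_waters", paste0("dih_", c("A", "B", "C", "D")),
                    paste0("dist_", c("A_B", "B_C", "C_D", "D_A"))))
  expect_equal(nrow(tidy), 3 * 9)
})
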
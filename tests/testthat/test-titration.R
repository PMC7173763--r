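# Partition-function titration: free energies, protonation fractions,
# dominant-state selection, pKa location, uncertainty bands, S3 surface.

single_site_model <- function(model_pka = 6.0, e_prot = 0, e_deprot = 0,
                              n_structures = 1, temperature = 310) {
  ms <- enumerate_microstates("H1.A")
  e <- matrix(rep(c(e_deprot, e_prot), n_structures), 2, n_structures)
  titration_model(
    suppressWarnings(energy_table(ms, paste0("S", seq_len(n_structures)), e)),
    data.frame(site_id = "H1.A", model_pka = model_pka, site_class = "base"),
    temperature = temperature) |> suppressWarnings()
}

test_that("free energy reduces to <E> when fully deprotonated and cancels at pKa", {
  m <- single_site_model(model_pka = 6.2, e_prot = 1.3, e_deprot = -0.4)
  expect_equal(microstate_free_energy(m, 0L, ph = 7.77), -0.4)
  m2 <- single_site_model(model_pka = 6.2, e_prot = 0.9, e_deprot = 0.9)
  expect_equal(microstate_free_energy(m2, 1L, ph = 6.2),
               microstate_free_energy(m2, 0L, ph = 6.2), tolerance = 1e-12)
})

test_that("free energy equals the hand-summed per-term expression", {
  withr::with_seed(12, {
    ids <- c("E1.A", "H2.A", "D3.A")
    ms <- enumerate_microstates(ids)
    e <- matrix(rnorm(8), 8, 1)
    sites <- data.frame(site_id = ids, model_pka = c(4.25, 6.54, 3.71),
                        site_class = c("acid", "base", "acid"))
    m <- suppressWarnings(titration_model(energy_table(ms, "S1", e), sites, 310))
    rt <- 0.0019872 * 310
    for (i in 1:8) {
      x <- ms[i, ]
      hand <- e[i, 1] + log(10) * rt * 7 * sum(x) -
        log(10) * rt * sum(x * sites$model_pka)
      expect_equal(microstate_free_energy(m, x, ph = 7), hand, tolerance = 1e-12)
    }
  })
})

test_that("an isolated site follows the Henderson-Hasselbalch closed form", {
  m <- single_site_model(model_pka = 6.0)
  expect_equal(protonation_fraction(m, "H1.A", ph = 6.0), 0.5, tolerance = 1e-14)
  expect_equal(protonation_fraction(m, "H1.A", ph = 5.0), 10 / 11, tolerance = 1e-12)
  expect_equal(protonation_fraction(m, "H1.A", ph = 7.0), 1 / 11, tolerance = 1e-12)
  ph <- seq(3, 8, 0.05)
  th <- protonation_fraction(m, "H1.A", ph = ph)
  expect_true(all(diff(th) < 0))  # strictly decreasing in pH
})

test_that("coupled multi-site fractions match the direct-sum oracle", {
  withr::with_seed(13, {
    rm8 <- random_energy_model(n_sites = 8, n_structures = 1, seed = 77)
    m <- suppressWarnings(titration_model(rm8$table, rm8$sites, 310))
    ph <- seq(3, 8, 0.25)
    got <- protonation_fraction(m, ph = ph)
    want <- oracle_theta(rm8$table$microstates, m$energy_mean,
                         rm8$sites$model_pka, ph, 310)
    expect_lt(max(abs(got - want)), 1e-10)
  })
})

test_that("total bound protons are non-increasing in pH (linked-function consistency)", {
  for (s in 1:3) {
    rm <- random_energy_model(n_sites = 6, n_structures = 2, seed = 100 + s)
    m <- titration_model(rm$table, rm$sites, 310)
    th <- protonation_fraction(m, ph = seq(3, 8, 0.1))
    expect_true(all(diff(rowSums(th)) <= 1e-12))
  }
})

test_that("adding a constant to all energies changes nothing (gauge invariance)", {
  rm <- random_energy_model(n_sites = 5, n_structures = 2, seed = 55)
  m <- titration_model(rm$table, rm$sites, 310)
  ph <- seq(3, 8, 0.1)
  base <- protonation_fraction(m, ph = ph)
  for (shift in c(-500, 123.456, 500)) {
    sh <- protonation_fraction(m, ph = ph, energy = m$energy_mean + shift)
    expect_lt(max(abs(sh - base)), 1e-10)
  }
})

test_that("dominant-state selection is lossless at tiny thresholds", {
  rm <- random_energy_model(n_sites = 6, n_structures = 2, seed = 8)
  m <- titration_model(rm$table, rm$sites, 310)
  ph <- seq(3, 8, 0.05)
  expect_identical(select_dominant_states(m, ph, 0), seq_len(64L))
  sub <- select_dominant_states(m, ph, 1e-4)
  expect_true(length(sub) < 64L)
  th_sub <- protonation_fraction(m, ph = ph, subset = sub)
  th_all <- protonation_fraction(m, ph = ph)
  expect_lt(max(abs(th_sub - th_all)), 1e-3)

  m1 <- single_site_model(model_pka = 5.5)
  expect_identical(select_dominant_states(m1, seq(3, 8, 0.5), 0.4), c(1L, 2L))
})

test_that("pKa location: exact grid hit, interpolation, closed-form recovery", {
  expect_equal(as.numeric(estimate_pka(c(0.8, 0.5, 0.2), c(5, 6, 7))), 6.0)
  expect_equal(as.numeric(estimate_pka(c(0.7, 0.3), c(5, 6))), 5.5)
  expect_true(is.na(estimate_pka(c(0.9, 0.8), c(5, 6))))
  m <- single_site_model(model_pka = 6.2)
  ph <- seq(3, 8, 0.01)
  pka <- estimate_pka(protonation_fraction(m, "H1.A", ph = ph), ph)
  expect_lt(abs(as.numeric(pka) - 6.2), 0.005)
  expect_false(attr(pka, "multi_crossing"))
})

test_that("uncertainty bands: sigma = 0 collapses, closed form at k = 1, nesting", {
  m0 <- single_site_model(model_pka = 6.0, n_structures = 3)
  ph <- seq(3, 8, 0.01)
  b0 <- pka_uncertainty(m0, "H1.A", ph)
  expect_true(all(abs(b0$low - 6.0) < 0.005 & abs(b0$high - 6.0) < 0.005))

  # only the protonated state fluctuates: energies (-1, 0, 1) -> sd exactly 1
  ms <- enumerate_microstates("H1.A")
  e <- rbind(c(0, 0, 0), c(-1, 0, 1))
  m1 <- titration_model(energy_table(ms, c("S1", "S2", "S3"), e),
                        data.frame(site_id = "H1.A", model_pka = 5.5,
                                   site_class = "base"), 310)
  expect_equal(unname(m1$energy_sd), c(0, 1), tolerance = 1e-12)
  b1 <- pka_uncertainty(m1, "H1.A", ph)
  halfw <- (b1$high - b1$low) / 2
  rtln10 <- 0.0019872 * 310 * log(10)
  expect_equal(halfw[b1$k == 1], 1 / rtln10, tolerance = 1e-4)
  # nested, monotone widths across k
  expect_true(all(diff(b1$high - b1$low) >= -1e-12))
  expect_true(all(diff(b1$low) <= 1e-12) && all(diff(b1$high) >= -1e-12))
})

test_that("the fitted model recovers ground truth and exposes the usual methods", {
  esp <- toy_energy_spec(
    data.frame(site_id = c("E327.A", "H418.A", "E420.A"),
               model_pka = c(4.25, 6.54, 4.25),
               shift = c(1.0, -0.5, 0)),
    n_structures = 4, noise_sd = 0, seed = 2)
  te <- generate_energy_table(esp)
  fit <- titration_fit(te$table, te$sites)
  expect_s3_class(fit, "titration_fit")
  expect_equal(coef(fit), te$truth$pka, tolerance = 0.006)
  # module output equals the generator's independent full-enumeration truth
  expect_lt(max(abs(fit$theta - te$truth$theta)), 1e-10)
  # 10 uncertainty bands per site
  expect_equal(nrow(fit$bands), 3 * 10)
  expect_equal(sort(unique(fit$bands$k)), seq(0.1, 1, 0.1))
  # methods
  expect_output(print(fit), "pKa estimates")
  s <- summary(fit)
  expect_s3_class(s, "summary.titration_fit")
  expect_output(print(s), "band_low")
  pr <- predict(fit, ph = c(4, 6))
  expect_equal(dim(pr), c(2L, 3L))
  ci <- confint(fit, k = 1.0)
  expect_equal(rownames(ci), te$sites$site_id)
  expect_true(all(ci[, "low"] <= coef(fit) + 1e-9))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("with pairwise couplings the fit matches brute-force enumeration", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 1.5  # repulsive
  esp <- toy_energy_spec(
    data.frame(site_id = c("E1.A", "E2.A"), model_pka = c(4.5, 4.5),
               shift = c(0, 0)),
    couplings = W, n_structures = 3, noise_sd = 0, seed = 4)
  te <- generate_energy_table(esp)
  fit <- titration_fit(te$table, te$sites, weight_threshold = 0)
  expect_lt(max(abs(fit$theta - te$truth$theta)), 1e-10)
  # repulsion spreads the two titrations apart relative to independent sites
  expect_true(all(is.finite(coef(fit))))
})

test_that("a single-structure table still fits, with degenerate bands", {
  ms <- enumerate_microstates(c("E1.A", "E2.A"))
  e <- matrix(c(0, 0.5, 0.2, 0.9), 4, 1)
  tab <- suppressWarnings(energy_table(ms, "S1", e))
  sites1 <- data.frame(site_id = c("E1.A", "E2.A"), model_pka = c(4.2, 5.1),
                       site_class = "acid")
  expect_warning(titration_model(tab, sites1), "single-structure")
  fit <- suppressWarnings(titration_fit(tab, sites1))
  expect_equal(fit$bands$low, fit$bands$high, tolerance = 1e-12)
  expect_true(all(is.finite(coef(fit))))
})

test_that("default-config run shape: 501-point grid and 10 bands per site", {
  esp <- toy_energy_spec(
    data.frame(site_id = c("E327.A", "H418.A"), model_pka = c(4.25, 6.54),
               shift = c(0, 0)),
    n_structures = 3, noise_sd = 0.1, seed = 6)
  te <- generate_energy_table(esp)
  cfg <- default_config()
  fit <- titration_fit(te$table, te$sites,
                       ph = seq(cfg$ph_min, cfg$ph_max, by = cfg$ph_step),
                       temperature = cfg$temperature)
  expect_equal(nrow(fit$theta), 501L)
  expect_equal(nrow(fit$bands[fit$bands$site_id == "E327.A", ]), 10L)
})
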
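test_that("adhesion extraction recovers a synthetic dip under noise", {
  # zero trace
  zero <- data.frame(distance = seq(0, 1, length.out = 2000), force = 0)
  expect_equal(extract_adhesion(zero, bin_size = 100)$adhesion_force, 0)

  # -1.50 nN Gaussian dip + sigma = 0.1 nN white noise, 1e4 points
  tr <- synth_force_trace(n = 1e4, depth = -1.5, noise_sd = 0.1, seed = 5)
  res <- extract_adhesion(tr, bin_size = 500)
  expect_equal(res$adhesion_force, 1.5, tolerance = 0.05 / 1.5)
  expect_equal(nrow(res$bins), 20)
  expect_lt(abs(res$plateau_force), 0.02)

  # invariant under a constant force offset
  tr_off <- tr; tr_off$force <- tr_off$force + 0.7
  res_off <- extract_adhesion(tr_off, bin_size = 500)
  expect_equal(res_off$adhesion_force, res$adhesion_force, tolerance = 1e-12)

  # noiseless trace: bin_size 1 vs 500 agree closely
  clean <- synth_force_trace(n = 1e4, depth = -1.5, noise_sd = 0)
  a1 <- extract_adhesion(clean, bin_size = 1)$adhesion_force
  a500 <- extract_adhesion(clean, bin_size = 500)$adhesion_force
  expect_lt(abs(a1 - a500), 0.05)

  expect_error(extract_adhesion(tr[1:600, ], bin_size = 500), "too short")
})

test_that("tip averaging filters ions by the footprint square", {
  mk <- function(a) structure(list(adhesion_force = a), class = "adhesion_result")
  pos <- tibble::tibble(x = c(0.0, 0.5, -0.5, 3.0), y = c(0, 0.5, -0.5, 3))
  res <- list(mk(1), mk(2), mk(3), mk(100))

  # single ion
  one <- tip_average(res[1], pos[1, ], footprint = 2.4, center = c(0, 0))
  expect_equal(one$mean_adhesion, 1)
  expect_equal(one$std_adhesion, 0)

  # three in, outlier excluded by the footprint; hand-computed mean/std
  t3 <- tip_average(res, pos, footprint = 2.4, center = c(0, 0))
  expect_equal(t3$n_ions, 3)
  expect_equal(t3$mean_adhesion, 2)
  expect_equal(t3$std_adhesion, 1)

  # brute-force filter oracle
  inside <- abs(pos$x) <= 1.2 & abs(pos$y) <= 1.2
  expect_equal(t3$mean_adhesion,
               mean(vapply(res[inside], function(r) r$adhesion_force, 0)))

  expect_error(tip_average(res, pos, footprint = 0.1, center = c(10, 10)),
               "no ions inside")
})

test_that("WHAM reproduces a flat landscape and Boltzmann inversion", {
  kT <- md_constants$kB * 300

  # windows drawn from a flat landscape (pure bias sampling)
  w <- analytic_umbrella_windows(seq(0, 1, by = 0.1), k_umb = 300, a = 0,
                                 z0 = 0, n_per_window = 3000, seed = 2)
  pmf <- wham_pmf(w, bin_width = 0.02, n_bootstrap = 50, seed = 3)
  mid <- !is.na(pmf$pmf) & pmf$z > 0 & pmf$z < 1
  # flat within the combined shot-noise/bootstrap scale about its own level
  dev <- pmf$pmf[mid] - mean(pmf$pmf[mid])
  expect_lt(max(abs(dev)), max(4 * pmf$std[mid], 0.5))

  # a single unbiased window equals direct Boltzmann inversion of the
  # histogram up to a constant
  set.seed(9)
  s <- rnorm(50000, 0.5, 0.08)
  w1 <- tibble::tibble(window = 1L, center = 0.5, k_umb = 0,
                       n_samples = length(s), samples = list(s))
  pmf1 <- wham_pmf(w1, bin_width = 0.02, n_bootstrap = 0)
  br <- seq(min(s) - 1e-9, max(s) + 0.02, by = 0.02)
  hist_inv <- -kT * log(tabulate(findInterval(s, br, left.open = TRUE),
                                 nbins = length(br) - 1))
  ok <- is.finite(hist_inv) & !is.na(pmf1$pmf)
  diffs <- pmf1$pmf[ok] - hist_inv[ok]
  expect_lt(max(diffs) - min(diffs), 1e-8)
})

test_that("WHAM recovers a quadratic potential from analytic windows", {
  a <- 50; z0 <- 0.5
  w <- analytic_umbrella_windows(seq(0, 1, by = 0.05), k_umb = 1000,
                                 a = a, z0 = z0, n_per_window = 4000,
                                 seed = 4)
  pmf <- wham_pmf(w, bin_width = 0.01, n_bootstrap = 50, seed = 5)
  sel <- !is.na(pmf$pmf) & pmf$z >= 0 & pmf$z <= 1
  z <- pmf$z[sel]; y <- pmf$pmf[sel]
  fit <- lm(y ~ z + I(z^2))
  curv <- 2 * coef(fit)[["I(z^2)"]]
  expect_rel_equal(curv, a, 0.05)

  # pointwise agreement after aligning the free constant
  target <- 0.5 * a * (z - z0)^2
  offset <- mean(y - target)
  expect_lt(max(abs(y - target - offset)), 0.5)

  # bootstrap errors are positive and modest where sampled
  expect_true(all(pmf$std[sel] >= 0))
  expect_lt(stats::median(pmf$std[sel]), 0.5)
})

test_that("WHAM rejects non-overlapping windows naming the gap", {
  w <- tibble::tibble(window = 1:2, center = c(0.2, 2.0), k_umb = 5000,
                      n_samples = 100,
                      samples = list(rnorm(100, 0.2, 0.02),
                                     rnorm(100, 2.0, 0.02)))
  expect_error(wham_pmf(w, n_bootstrap = 0), "do not overlap.*0\\.2.*2\\.0")
})

test_that("PMF binding free energy reads the minimum-to-plateau depth", {
  z <- seq(0.2, 2, by = 0.02)
  well <- -50 * exp(-(z - 0.6)^2 / (2 * 0.05^2))
  pmf <- tibble::tibble(z = z, pmf = well, std = 0)
  dg <- pmf_binding_dg(pmf)
  expect_true(dg$bound)
  expect_equal(dg$dG, 50, tolerance = 1e-3)
  expect_equal(dg$z_min, 0.6, tolerance = 0.02)

  # per-ligand division by the mean ligands-per-ion count
  dg44 <- pmf_binding_dg(pmf, per_ligand_divisor = 4.4)
  expect_equal(dg44$dG_per_ligand, dg44$dG / 4.4)

  # monotone profile decaying to its plateau: unbound verdict
  flat <- tibble::tibble(z = z, pmf = 5 * exp(-3 * z), std = 0)
  dg0 <- pmf_binding_dg(flat)
  expect_false(dg0$bound)
  expect_equal(dg0$dG, 0)
})

test_that("Langmuir inputs follow the hand arithmetic of the bound counts", {
  # 90 of 100 ions always bound, 10 unbound, volume 1.5e-22 L
  asg <- purrr::map_dfr(0:9, function(f) {
    tibble::tibble(frame = f, id = 1:100, species = "Ca2+",
                   n_b = 0L, n_m = as.integer(seq_len(100) <= 90),
                   n_i = 0L, n_direct = as.integer(seq_len(100) <= 90),
                   n_total = as.integer(seq_len(100) <= 90),
                   category = ifelse(seq_len(100) <= 90, "M", "unbound"),
                   bound = seq_len(100) <= 90)
  })
  li <- estimate_langmuir_inputs(asg, window = 0.5, volume_L = 1.5e-22)
  expect_equal(li$q_e, 90)
  expect_equal(li$q_m, 100)
  expect_equal(li$C_e, 10 / (md_constants$NA_mol * 1.5e-22))
  expect_false(li$all_bound)

  # all bound: infinite-K flag propagates to a rejection
  asg_all <- dplyr::mutate(asg, bound = TRUE)
  li_all <- estimate_langmuir_inputs(asg_all, volume_L = 1.5e-22)
  expect_true(li_all$all_bound)
  expect_error(langmuir_dg(li_all), "infinite K_0")
})

test_that("Langmuir free energy evaluates the isotherm exactly", {
  # symmetry point: half occupancy at the standard concentration
  half <- langmuir_dg(q_e = 50, q_m = 100, C_e = 1)
  expect_equal(half$K_0, 1)
  expect_equal(half$dG0, 0)

  # direct formula oracle
  r <- langmuir_dg(q_e = 90, q_m = 100, C_e = 0.065, temperature = 300)
  expect_equal(r$K_0, 9 / 0.065, tolerance = 1e-12)
  expect_equal(r$dG0, -md_constants$kB * 300 * log(9 / 0.065),
               tolerance = 1e-12)

  # doubling C_0 shifts dG0 by exactly -RT ln 2
  r2 <- langmuir_dg(q_e = 90, q_m = 100, C_e = 0.065, C_0 = 2)
  expect_equal(r2$dG0 - r$dG0, -md_constants$kB * 300 * log(2),
               tolerance = 1e-12)

  # antisymmetry: swapping occupancy and concentration roles inverts K_0
  set.seed(12)
  for (i in 1:25) {
    qm <- runif(1, 10, 200)
    qe <- runif(1, 0.05, 0.95) * qm
    ce <- runif(1, 1e-3, 2); c0 <- runif(1, 0.5, 2)
    fwd <- langmuir_dg(qe, qm, ce, c0)
    rev <- langmuir_dg(qm - qe, qm, c0, ce)
    expect_equal(rev$K_0, 1 / fwd$K_0, tolerance = 1e-10)
    expect_equal(rev$dG0, -fwd$dG0, tolerance = 1e-10)
  }

  expect_error(langmuir_dg(100, 100, 0.1), "q_e < q_m")
  expect_error(langmuir_dg(50, 100, 0), "C_e must be > 0")
})

test_that("Langmuir estimator recovers the generator bound fraction", {
  cs <- cutoff_scheme(0.30, 0.42, 0.59)
  lt <- generate_labeled_trajectory(
    10, 3000, c(M = 0.4, I = 0.2, unbound = 0.4),
    exchange_rate = 0.2, cutoffs = cs, box = sim_box(8, 8, 7), seed = 41)
  li <- estimate_langmuir_inputs(lt, window = 0.5)
  expect_lt(abs(li$q_e - 0.6 * 10), 0.02 * 10)
  r <- langmuir_dg(li)
  expect_equal(r$dG0,
               -md_constants$kB * 300 *
                 log(li$q_e / (li$q_m - li$q_e) / li$C_e),
               tolerance = 1e-12)
})

test_that("mg-per-g reporting view converts ion counts", {
  # 1e15 Ca ions on a 1 microgram absorbent
  v <- ions_to_mg_per_g(1e15, "Ca2+", 1e-6)
  expect_equal(v, 1e15 / md_constants$NA_mol * 40.078 * 1e3 / 1e-6)
  expect_error(ions_to_mg_per_g(1, "Xx", 1), "no molar mass")
})

test_that("AFM force conversions reproduce the printed worked examples", {
  # work picture: 78.4 pN over 3.32 Angstrom -> 15.7 kJ/mol
  w <- afm_force_to_dg(78.4, 0.332)
  expect_equal(w$dG_bind, 15.7, tolerance = 0.002)
  expect_equal(afm_force_to_dg(0, 0.22)$dG_bind, 0)

  # unit-conversion oracle at 100 pN, 0.22 nm
  u <- afm_force_to_dg(100, 0.22)
  expect_equal(u$dG_bind,
               md_constants$NA_mol * 100e-12 * 0.22e-9 / 1e3,
               tolerance = 1e-12)

  # per-carboxylate-group view for a 12-27 group tip coverage
  pg <- afm_force_to_dg(78.4, 0.22, coverage = c(12, 27))
  expect_equal(pg$dG_per_group_min, pg$dG_bind / 27)
  expect_equal(pg$dG_per_group_max, pg$dG_bind / 12)

  # Friddle equilibrium estimator: 78.4 pN, 0.09 N/m -> 20.6 kJ/mol
  expect_equal(friddle_dg(78.4, 0.09), 20.6, tolerance = 0.002)
  expect_equal(friddle_dg(0, 0.09), 0)
  expect_equal(friddle_dg(100, 0.10),
               md_constants$NA_mol * (100e-12)^2 / 0.2 / 1e3,
               tolerance = 1e-12)

  # algebraic identity: the two agree when L = F_eq / (2k)
  f <- 78.4; k <- 0.09
  L_nm <- f * 1e-12 / (2 * k) * 1e9
  expect_equal(afm_force_to_dg(f, L_nm)$dG_bind, friddle_dg(f, k),
               tolerance = 1e-12)
})
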
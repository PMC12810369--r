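ideal_gas_traj <- function(n_b = 600, n_frames = 20, seed = 1) {
  # one reference particle mid-slab + uniform B particles everywhere
  box <- sim_box(6, 6, 6)
  set.seed(seed)
  frames <- purrr::map_dfr(seq_len(n_frames) - 1L, function(f) {
    dplyr::bind_rows(
      tibble::tibble(frame = f, time = f, id = 1L, species = "A",
                     x = 3, y = 3, z = 3),
      tibble::tibble(frame = f, time = f, id = 1L + seq_len(n_b),
                     species = "B", x = runif(n_b, 0, 6),
                     y = runif(n_b, 0, 6), z = runif(n_b, 0, 6)))
  })
  ion_trajectory(frames, box)
}

test_that("ideal-gas g(r) is unity within shot noise", {
  rdf <- compute_rdf(ideal_gas_traj(), "A", "B", r_max = 2.0, dr = 0.1)
  # expected counts per bin ~ rho * shell; 3-sigma Poisson band on each bin
  box_v <- 6^3
  rho <- 600 / box_v
  shell <- 4 * pi * rdf$r^2 * 0.1 * rho * 20
  expect_true(all(abs(rdf$g - 1) < 3 / sqrt(shell)))
  # grand mean over bins with appreciable expected counts is much tighter
  expect_lt(abs(mean(rdf$g[rdf$r > 0.3]) - 1), 0.02)
})

test_that("a fixed pair produces a single peak at its separation", {
  frames <- purrr::map_dfr(0:9, function(f) {
    tibble::tibble(frame = f, time = f, id = 1:2, species = c("A", "B"),
                   x = c(2, 2.35), y = 2, z = 2)
  })
  traj <- ion_trajectory(frames, sim_box(6, 6, 6))
  rdf <- compute_rdf(traj, "A", "B", r_max = 1, dr = 0.01)
  expect_equal(sum(rdf$g > 0), 1)
  expect_equal(rdf$r[which.max(rdf$g)], 0.355, tolerance = 0.006)
  expect_equal(max(rdf$coordination), 1)
})

test_that("g(r) and n(r) match the brute-force O(N^2) oracle", {
  set.seed(4)
  box <- sim_box(5, 5, 5)
  fr <- tibble::tibble(frame = 0L, time = 0, id = 1:50,
                       species = rep(c("A", "B"), 25),
                       x = runif(50, 0, 5), y = runif(50, 0, 5),
                       z = runif(50, 0, 5))
  traj <- ion_trajectory(fr, box)
  breaks <- seq(0, 2, by = 0.05)
  rdf <- compute_rdf(traj, "A", "B", r_max = 2, dr = 0.05)
  oracle <- brute_force_g(fr[fr$species == "A", ], fr[fr$species == "B", ],
                          box, breaks, same_group = FALSE)
  expect_equal(rdf$g, oracle$g, tolerance = 1e-10)
  expect_equal(rdf$coordination, cumsum(oracle$counts) / 25,
               tolerance = 1e-10)

  # same-group case excludes self pairs
  rdf_aa <- compute_rdf(traj, "A", "A", r_max = 2, dr = 0.05)
  oracle_aa <- brute_force_g(fr[fr$species == "A", ],
                             fr[fr$species == "A", ], box, breaks,
                             same_group = TRUE)
  expect_equal(rdf_aa$g, oracle_aa$g, tolerance = 1e-10)
})

test_that("RDF input validation rejects bad groups and ranges", {
  traj <- ideal_gas_traj(n_b = 10, n_frames = 2)
  expect_error(compute_rdf(traj, "nope", "B"), "empty particle group")
  expect_error(compute_rdf(traj, "A", "B", r_max = 4), "min\\(lx, ly\\)/2")
})

# trimodal synthetic g(r): Gaussian peaks like the carbon-ion RDF
trimodal_g <- function(r, mu = c(0.28, 0.40, 0.50), amp = c(8, 4, 2),
                       sd = 0.02, baseline = 0.02) {
  baseline + amp[1] * exp(-(r - mu[1])^2 / (2 * sd^2)) +
    amp[2] * exp(-(r - mu[2])^2 / (2 * sd^2)) +
    amp[3] * exp(-(r - mu[3])^2 / (2 * sd^2))
}

test_that("derived cutoffs sit at the minima of a trimodal g(r)", {
  r <- seq(0.005, 0.7, by = 0.005)
  rdf <- tibble::tibble(r = r, g = trimodal_g(r))
  cs <- derive_cutoffs(rdf, smoothing = 3)
  expect_s3_class(cs, "cutoff_scheme")
  expect_equal(cs$source, "derived")

  # dense grid search on the generating mixture locates the true minima
  dense <- seq(0.28, 0.40, by = 1e-5)
  m1 <- dense[which.min(trimodal_g(dense))]
  dense <- seq(0.40, 0.50, by = 1e-5)
  m2 <- dense[which.min(trimodal_g(dense))]
  expect_equal(cs$bidentate_max, m1, tolerance = 0.012)
  expect_equal(cs$direct_max, m2, tolerance = 0.012)
  expect_gt(cs$total_max, 0.52)
  expect_null(cs$indirect_split)
})

test_that("an Mg-style four-peak g(r) yields an indirect split near the dip", {
  four_g <- function(r) {
    0.02 + 8 * exp(-(r - 0.26)^2 / (2 * 0.018^2)) +
      4 * exp(-(r - 0.34)^2 / (2 * 0.018^2)) +
      2.5 * exp(-(r - 0.41)^2 / (2 * 0.02^2)) +
      1.5 * exp(-(r - 0.52)^2 / (2 * 0.025^2))
  }
  r <- seq(0.005, 0.75, by = 0.005)
  cs <- derive_cutoffs(tibble::tibble(r = r, g = four_g(r)), smoothing = 3)
  expect_false(is.null(cs$indirect_split))
  # grid-search oracle: the true dip of the generating mixture between the
  # two indirect sub-peaks, mirroring the 0.45 nm dip inside 0.38-0.59 nm
  dense <- seq(0.41, 0.52, by = 1e-5)
  true_dip <- dense[which.min(four_g(dense))]
  expect_equal(cs$indirect_split, true_dip, tolerance = 0.03)
  expect_gt(cs$indirect_split, 0.42)
  expect_lt(cs$indirect_split, 0.50)
  expect_gt(cs$total_max, 0.55)
})

test_that("degenerate RDFs are rejected with advice", {
  r <- seq(0.01, 0.6, by = 0.005)
  expect_error(derive_cutoffs(tibble::tibble(r = r, g = exp(-5 * r))),
               "manual cutoffs")
  two_peak <- 0.02 + 8 * exp(-(r - 0.28)^2 / 8e-4) +
    4 * exp(-(r - 0.40)^2 / 8e-4)
  expect_error(derive_cutoffs(tibble::tibble(r = r, g = two_peak)),
               "manual cutoffs")
})

test_that("cutoff_scheme validates its ordering invariants", {
  expect_error(cutoff_scheme(0.4, 0.3, 0.6), "bidentate_max < direct_max")
  expect_error(cutoff_scheme(0.3, 0.42, 0.59, indirect_split = 0.4),
               "indirect_split")
  cs <- cutoff_scheme(0.3, 0.42, 0.59, indirect_split = 0.45)
  expect_equal(cs$indirect_split, 0.45)
})

test_that("hand-built frames classify to the expected motifs", {
  box <- sim_box(20, 20, 20)
  cs <- cutoff_scheme(0.30, 0.42, 0.59)
  carbons <- hand_carbons(c(5.0, 5.5), ys = 5, zs = 5)

  # ion 0.27 nm from ligand 1 C, 0.45 nm from ligand 2 C -> "B+I"
  frame <- tibble::tibble(frame = 0L, time = 0, id = 1L, species = "Ca2+",
                          x = 5.0 + 0.27, y = 5, z = 5)
  d2 <- sqrt((5.5 - 5.27)^2)  # 0.23 -- adjust ligand 2 to land at 0.45
  carbons$x[2] <- 5.27 + 0.45
  asg <- classify_frame(frame, carbons, cs, box)
  expect_equal(asg$category, "B+I")
  expect_equal(asg$n_b, 1)
  expect_equal(asg$n_direct, 1)
  expect_equal(asg$n_total, 2)

  # far ion is unbound
  far <- tibble::tibble(frame = 0L, time = 0, id = 1L, species = "Ca2+",
                        x = 15, y = 15, z = 15)
  expect_equal(classify_frame(far, carbons, cs, box)$category, "unbound")
  expect_false(classify_frame(far, carbons, cs, box)$bound)
})

test_that("classification is invariant under translation and periodic shifts", {
  cs <- cutoff_scheme(0.30, 0.42, 0.59)
  box <- sim_box(6, 6, 10)
  lt <- generate_labeled_trajectory(6, 40, c(B = 0.3, M = 0.3, unbound = 0.4),
                                    cutoffs = cs, box = box, seed = 9)
  base <- classify_trajectory(lt)

  shift_xy <- function(tbl, dx, dy) {
    tbl$x <- (tbl$x + dx) %% box$lx
    tbl$y <- (tbl$y + dy) %% box$ly
    tbl
  }
  # rigid in-plane translation of ions and ligands together (wrapped)
  fr2 <- shift_xy(lt$trajectory$frames, 2.7, 4.1)
  hg2 <- shift_xy(lt$headgroups, 2.7, 4.1)
  moved <- classify_trajectory(ion_trajectory(fr2, box), hg2, cs)
  expect_equal(moved$category, base$category)

  # whole-box image shift of only the ions
  fr3 <- lt$trajectory$frames
  fr3$x <- fr3$x + box$lx
  moved3 <- classify_trajectory(ion_trajectory(fr3, box), lt$headgroups, cs)
  expect_equal(moved3$category, base$category)
})

test_that("per-ion counts always satisfy bidentate <= direct <= total", {
  cs <- cutoff_scheme(0.30, 0.42, 0.59)
  lt <- generate_labeled_trajectory(
    8, 100, c(B = 0.25, M = 0.25, I = 0.25, unbound = 0.25),
    cutoffs = cs, box = sim_box(8, 8, 7), seed = 17)
  asg <- classify_trajectory(lt)
  expect_true(all(asg$n_b <= asg$n_direct))
  expect_true(all(asg$n_direct <= asg$n_total))
})

test_that("classifier recovers generator truth labels", {
  cs <- cutoff_scheme(0.30, 0.42, 0.59)
  lt <- generate_labeled_trajectory(
    10, 2000, c(B = 0.2, M = 0.2, I = 0.3, unbound = 0.3),
    exchange_rate = 0.1, cutoffs = cs, box = sim_box(8, 8, 7), seed = 23)
  asg <- classify_trajectory(lt)
  m <- dplyr::inner_join(asg, lt$truth, by = c("frame", "id"))
  expect_gte(mean(m$category == m$state), 0.99)
})

test_that("binding statistics follow the ligand-count column semantics", {
  # one frame, one ion: 1 bidentate + 2 monodentate ligands
  asg <- tibble::tibble(frame = 0L, id = 1L, species = "Ca2+",
                        n_b = 1L, n_m = 2L, n_i = 0L,
                        n_direct = 3L, n_total = 3L,
                        category = "B+M", bound = TRUE)
  st <- binding_statistics(asg)
  expect_equal(unname(st$ligands_per_ion), c(1, 3, 3))
  expect_equal(st$mean_bound, 1)

  # all-unbound trajectory
  asg0 <- tibble::tibble(frame = rep(0:4, each = 2), id = rep(1:2, 5),
                         species = "Ca2+", n_b = 0L, n_m = 0L, n_i = 0L,
                         n_direct = 0L, n_total = 0L,
                         category = "unbound", bound = FALSE)
  st0 <- binding_statistics(asg0)
  expect_equal(st0$mean_bound, 0)
  expect_equal(st0$std_bound, 0)
  expect_equal(st0$motif_histogram$category, "unbound")
  expect_equal(st0$motif_histogram$mean_ions, 2)
})

test_that("motif histogram recovers the generating mixture", {
  target <- c(B = 0.25, M = 0.2, I = 0.3, unbound = 0.25)
  n_ions <- 10
  lt <- generate_labeled_trajectory(n_ions, 4000, target,
                                    exchange_rate = 0.2,
                                    cutoffs = cutoff_scheme(0.3, 0.42, 0.59),
                                    box = sim_box(8, 8, 7), seed = 31)
  st <- binding_statistics(classify_trajectory(lt))
  h <- st$motif_histogram
  for (cat in names(target)) {
    got <- h$mean_ions[h$category == cat]
    expect_lt(abs(got - unname(target[cat]) * n_ions), 0.02 * n_ions)
  }
  expect_lt(abs(st$mean_bound - (1 - target[["unbound"]]) * n_ions),
            0.02 * n_ions)
})

test_that("bound-count series flags convergence correctly", {
  const <- tibble::tibble(frame = rep(0:99, each = 2), id = rep(1:2, 100),
                          species = "X", n_b = 1L, n_m = 0L, n_i = 0L,
                          n_direct = 1L, n_total = 1L, category = "B",
                          bound = TRUE)
  s <- bound_count_series(const, window = 50)
  expect_true(attr(s, "converged"))
  expect_equal(sd(s$n_bound), 0)

  # linearly increasing bound count: not converged
  ramp <- purrr::map_dfr(0:99, function(f) {
    tibble::tibble(frame = f, id = 1:100, species = "X",
                   n_b = 0L, n_m = 0L, n_i = 0L, n_direct = 0L,
                   n_total = 0L, category = "unbound",
                   bound = seq_len(100) <= f)
  })
  s2 <- bound_count_series(ramp, window = 60)
  expect_false(attr(s2, "converged"))

  # burn-in ramp followed by a stationary tail: converged once the window
  # sits past the generator's switch frame
  settled <- dplyr::bind_rows(
    ramp,
    purrr::map_dfr(100:299, function(f) {
      tibble::tibble(frame = f, id = 1:100, species = "X",
                     n_b = 0L, n_m = 0L, n_i = 0L, n_direct = 0L,
                     n_total = 0L, category = "unbound",
                     bound = seq_len(100) <= 99)
    }))
  expect_true(attr(bound_count_series(settled, window = 100), "converged"))
  expect_false(attr(bound_count_series(settled, window = 280), "converged"))

  expect_error(bound_count_series(const, window = 100), "shorter")
})
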
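# Independent oracles used across the test files. These deliberately avoid
# the package's own vectorized code paths: plain double loops and direct
# formula evaluation.

# O(N^2) pair-distance histogram + clipped-shell g(r), written from the
# definition with explicit loops.
brute_force_rdf <- function(frame_a, frame_b, box, breaks, same_group) {
  counts <- numeric(length(breaks) - 1)
  for (i in seq_len(nrow(frame_a))) {
    for (j in seq_len(nrow(frame_b))) {
      if (same_group && i == j) next
      dx <- frame_a$x[i] - frame_b$x[j]
      dx <- dx - box$lx * round(dx / box$lx)
      dy <- frame_a$y[i] - frame_b$y[j]
      dy <- dy - box$ly * round(dy / box$ly)
      dz <- frame_a$z[i] - frame_b$z[j]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      for (k in seq_along(counts)) {
        if (d > breaks[k] && d <= breaks[k + 1]) {
          counts[k] <- counts[k] + 1
          break
        }
      }
    }
  }
  counts
}

brute_force_g <- function(frame_a, frame_b, box, breaks, same_group) {
  counts <- brute_force_rdf(frame_a, frame_b, box, breaks, same_group)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dr <- diff(breaks)[1]
  shell <- numeric(length(centers))
  for (k in seq_along(centers)) {
    s <- 0
    for (i in seq_len(nrow(frame_a))) {
      # Simpson integration of the clipped zone area over the bin
      rr <- breaks[k] + dr * c(0, 0.25, 0.5, 0.75, 1)
      w <- c(1, 4, 2, 4, 1) / 12 * dr
      for (m in seq_along(rr)) {
        h <- min(box$lz, frame_a$z[i] + rr[m]) - max(0, frame_a$z[i] - rr[m])
        s <- s + w[m] * 2 * pi * rr[m] * min(h, 2 * rr[m])
      }
    }
    shell[k] <- s
  }
  rho_b <- (nrow(frame_b) - as.integer(same_group)) /
    (box$lx * box$ly * box$lz)
  list(counts = counts, g = counts / (shell * rho_b))
}

# A synthetic constant-pull force trace (nN) with a single Gaussian
# adhesion dip plus optional white noise, as a plain data frame. The dip
# width is kept wide relative to the 500-point bin width (0.05 of the
# distance range) so bin averaging flattens the extremum by < 2% for any
# bin alignment.
synth_force_trace <- function(n = 1e4, depth = -1.5, center = 0.3,
                              width = 0.15, noise_sd = 0.1, baseline = 0,
                              seed = 1) {
  set.seed(seed)
  d <- seq(0, 1, length.out = n)
  data.frame(distance = d,
             force = baseline + depth * exp(-(d - center)^2 / (2 * width^2)) +
               if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
}

# Analytic umbrella-window samples for a quadratic landscape
# U(z) = 0.5*a*(z - z0)^2 under a harmonic bias 0.5*k*(z - c)^2: the biased
# density is Gaussian with the closed-form mean and variance below.
analytic_umbrella_windows <- function(centers, k_umb, a, z0,
                                      n_per_window = 4000,
                                      temperature = 300, seed = 1) {
  kT <- ionlayer::md_constants$kB * temperature
  set.seed(seed)
  samples <- lapply(centers, function(cc) {
    mu <- (k_umb * cc + a * z0) / (k_umb + a)
    rnorm(n_per_window, mu, sqrt(kT / (k_umb + a)))
  })
  structure(tibble::tibble(window = seq_along(centers), center = centers,
                           k_umb = k_umb, n_samples = n_per_window,
                           samples = samples),
            temperature = temperature)
}

# Small rigid test geometry: a few carboxylate carbons in a big box so the
# minimum image never kicks in unless requested.
hand_carbons <- function(xs, ys = 0, zs = 0) {
  tibble::tibble(ligand_id = seq_along(xs), atom = "C",
                 x = xs, y = rep_len(ys, length(xs)),
                 z = rep_len(zs, length(xs)), charge = -1)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}

# one mid-slab reference particle plus a uniform ideal gas of B particles
ideal_gas_acceptance_traj <- function(n_b = 600, n_frames = 20, seed = 1) {
  box <- ionlayer::sim_box(6, 6, 6)
  set.seed(seed)
  frames <- purrr::map_dfr(seq_len(n_frames) - 1L, function(f) {
    dplyr::bind_rows(
      tibble::tibble(frame = f, time = f, id = 1L, species = "A",
                     x = 3, y = 3, z = 3),
      tibble::tibble(frame = f, time = f, id = 1L + seq_len(n_b),
                     species = "B", x = runif(n_b, 0, 6),
                     y = runif(n_b, 0, 6), z = runif(n_b, 0, 6)))
  })
  ionlayer::ion_trajectory(frames, box)
}
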
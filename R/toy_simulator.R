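#' Reduced Brownian-dynamics engine for ions above a charged monolayer
#'
#' Overdamped (inertialess) Langevin dynamics with the Euler-Maruyama scheme:
#'
#'   x(t+dt) = x(t) + F dt / (m gamma) + sqrt(2 kB T dt / (m gamma)) xi
#'
#' in GROMACS-consistent units (nm, ps, kJ/mol, u), where 1 u nm^2/ps^2 =
#' 1 kJ/mol so the diffusion constant D = kB T/(m gamma) comes out in nm^2/ps
#' directly. Solvent is implicit: a relative dielectric divides the Coulomb
#' constant; there is no explicit water, no inertia, and no Ewald summation —
#' nonbonded interactions use a plain cutoff with minimum image in x,y.
#' The z direction is bounded by reflecting walls at 0 and lz.
#'
#' @name toy_simulator
NULL

# Default atomic masses (u) for the shipped species.
.species_mass <- function(species) {
  m <- c("Mg2+" = 24.305, "Ca2+" = 40.078, "Sr2+" = 87.62, "Ba2+" = 137.327,
         "Na+" = 22.98977, "Cl-" = 35.453)
  out <- unname(m[species])
  out[is.na(out)] <- 40
  out
}

# Default LJ parameters for the carboxylate headgroup atoms (CHARMM-like
# generic carbonyl C / carboxylate O).
.default_headgroup_lj <- function() {
  list(C = c(epsilon = 0.29288, rmin_half = 0.2000),
       O = c(epsilon = 0.50208, rmin_half = 0.1700))
}

# Forces exerted on every row of `pos_a` by all rows of `pos_b` through the
# 12-6 LJ + screened Coulomb pair potential. eps/rmin/qq are n_a x n_b
# matrices of combined parameters; pairs beyond `cutoff` contribute nothing.
.group_forces <- function(pos_a, pos_b, eps, rmin, qq, box, cutoff, kC_eff,
                          exclude_self = FALSE) {
  dx <- min_image(outer(pos_a[, 1], pos_b[, 1], "-"), box$lx)
  dy <- min_image(outer(pos_a[, 2], pos_b[, 2], "-"), box$ly)
  dz <- outer(pos_a[, 3], pos_b[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  if (exclude_self) diag(r2) <- Inf
  r2[r2 > cutoff^2] <- Inf
  r <- sqrt(r2)
  sr6 <- (rmin / r)^6
  # radial force magnitude / r, so multiplying by the displacement
  # components gives Cartesian forces on a
  fr <- (12 * eps * (sr6^2 - sr6) / r + kC_eff * qq / r2) / r
  fr[!is.finite(fr)] <- 0
  cbind(rowSums(fr * dx), rowSums(fr * dy), rowSums(fr * dz))
}

# Combined-parameter matrices for species vectors sa (rows) vs sb (cols).
.pair_tables <- function(sa, qa, ea, ra, sb, qb, eb, rb) {
  list(eps = sqrt(outer(ea, eb)),
       rmin = outer(ra, rb, "+"),
       qq = outer(qa, qb))
}

# Look up q/epsilon/rmin_half for ion species from a forcefield_set,
# applying ECC scaling to the charges.
.ion_ff <- function(species, ff) {
  idx <- match(species, ff$params$species)
  if (anyNA(idx)) {
    stop("species without force-field parameters: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  list(q = apply_ecc(ff$params$q[idx], ff$ecc_factor),
       eps = ff$params$epsilon[idx],
       rmin_half = ff$params$rmin_half[idx])
}

.headgroup_ff <- function(headgroups, headgroup_lj, ecc_f = 1) {
  kind <- ifelse(headgroups$atom == "C", "C", "O")
  list(q = ecc_f * headgroups$charge,
       eps = vapply(kind, function(k) headgroup_lj[[k]]["epsilon"], 0),
       rmin_half = vapply(kind, function(k) headgroup_lj[[k]]["rmin_half"], 0))
}

# Shared integrator behind simulate_langevin / run_constant_pull /
# run_umbrella_windows. `bias` is NULL or
# list(kind = "harmonic", k, center0, rate, target) acting on the z reaction
# coordinate (target ion z minus monolayer plane z).
.langevin_engine <- function(ions, box, forcefield = NULL, headgroups = NULL,
                             n_steps, dt, temperature = 300, friction = 1,
                             mass = NULL, seed = 1L, output_every = 10L,
                             cutoff = 1.2, eps_r = 78.5,
                             ecc_headgroups = FALSE,
                             external_force = NULL, bias = NULL,
                             headgroup_lj = .default_headgroup_lj()) {
  stopifnot(inherits(box, "sim_box"), n_steps >= 1, dt > 0, friction > 0,
            temperature > 0)
  pos <- as.matrix(ions[, c("x", "y", "z")])
  n <- nrow(pos)
  species <- ions$species
  if (is.null(mass)) mass <- .species_mass(species)
  mass <- rep_len(mass, n)

  use_pairs <- !is.null(forcefield)
  kC_eff <- .kC / eps_r
  if (use_pairs) {
    ifp <- .ion_ff(species, forcefield)
    ii <- .pair_tables(species, ifp$q, ifp$eps, ifp$rmin_half,
                       species, ifp$q, ifp$eps, ifp$rmin_half)
    if (!is.null(headgroups)) {
      hfp <- .headgroup_ff(headgroups, headgroup_lj,
                           if (ecc_headgroups) forcefield$ecc_factor else 1)
      hg_pos <- as.matrix(headgroups[, c("x", "y", "z")])
      ih <- .pair_tables(species, ifp$q, ifp$eps, ifp$rmin_half,
                         headgroups$atom, hfp$q, hfp$eps, hfp$rmin_half)
    }
  }

  z_ref <- if (!is.null(headgroups)) mean(headgroups$z) else 0
  if (!is.null(bias)) {
    k_stiff <- bias$k
    dt_max <- 0.1 * min(mass) * friction / k_stiff
    if (dt > dt_max) {
      warning(sprintf(paste0("dt = %g ps exceeds the stability heuristic ",
                             "0.1 m*gamma/k = %g ps for the bias spring"),
                      dt, dt_max))
    }
  }

  mob <- dt / (mass * friction)                  # nm per (kJ/mol/nm)
  sig <- sqrt(2 * .kB * temperature * dt / (mass * friction))

  old_seed <- .Random.seed_exists()
  set.seed(seed)

  n_out <- floor(n_steps / output_every) + 1L
  out_pos <- array(NA_real_, c(n_out, n, 3))
  out_time <- numeric(n_out)
  bias_log <- if (!is.null(bias)) {
    list(time = numeric(n_out), center = numeric(n_out),
         rc = numeric(n_out), force = numeric(n_out))
  }
  iout <- 1L
  record <- function(step) {
    t <- step * dt
    out_pos[iout, , ] <<- pos
    out_time[iout] <<- t
    if (!is.null(bias)) {
      center <- bias$center0 + bias$rate * t
      rc <- pos[bias$target, 3] - z_ref
      bias_log$time[iout] <<- t
      bias_log$center[iout] <<- center
      bias_log$rc[iout] <<- rc
      # force exerted by the ion on the moving restraint: negative (a dip)
      # while the ion lags behind the retracting spring center
      bias_log$force[iout] <<- bias$k * (rc - center)
    }
    iout <<- iout + 1L
  }
  record(0L)

  lim <- 10 * max(box$lx, box$ly, box$lz)
  for (step in seq_len(n_steps)) {
    F <- matrix(0, n, 3)
    if (use_pairs) {
      if (n > 1) {
        F <- F + .group_forces(pos, pos, ii$eps, ii$rmin, ii$qq,
                               box, cutoff, kC_eff, exclude_self = TRUE)
      }
      if (!is.null(headgroups)) {
        F <- F + .group_forces(pos, hg_pos, ih$eps, ih$rmin, ih$qq,
                               box, cutoff, kC_eff)
      }
    }
    if (!is.null(external_force)) {
      F <- F + external_force(pos, (step - 1) * dt)
    }
    if (!is.null(bias)) {
      center <- bias$center0 + bias$rate * (step - 1) * dt
      rc <- pos[bias$target, 3] - z_ref
      F[bias$target, 3] <- F[bias$target, 3] - bias$k * (rc - center)
    }
    pos <- pos + F * mob + sig * matrix(stats::rnorm(3L * n), n, 3)
    if (any(!is.finite(pos)) || any(abs(pos) > lim)) {
      stop(sprintf(paste0("trajectory diverged at step %d ",
                          "(|coordinate| > 10 box lengths); ",
                          "reduce dt or soften the potential"), step))
    }
    # periodic wrap in x,y; reflecting walls in z
    pos[, 1] <- pos[, 1] %% box$lx
    pos[, 2] <- pos[, 2] %% box$ly
    z <- abs(pos[, 3])
    over <- z > box$lz
    z[over] <- 2 * box$lz - z[over]
    pos[, 3] <- pmin(pmax(z, 0), box$lz)
    if (step %% output_every == 0L) record(step)
  }
  .restore_seed(old_seed)

  ids <- if ("id" %in% names(ions)) ions$id else seq_len(n)
  frames <- tibble::tibble(
    frame = rep(seq_len(n_out) - 1L, each = n),
    time = rep(out_time, each = n),
    id = rep(ids, n_out),
    species = rep(species, n_out),
    x = as.vector(t(out_pos[, , 1])),
    y = as.vector(t(out_pos[, , 2])),
    z = as.vector(t(out_pos[, , 3])))
  list(frames = frames, z_ref = z_ref,
       bias_log = if (!is.null(bias)) tibble::as_tibble(bias_log))
}

#' Simulate overdamped Langevin dynamics of ions above the monolayer
#'
#' Integrates Brownian dynamics of the mobile ions in the implicit-solvent
#' nonbonded field of the (static) carboxylate headgroups and of each other.
#' Reproducible: the same seed yields a bit-identical trajectory.
#'
#' @param ions Tibble with columns `species`, `x`, `y`, `z` (nm); optional
#'   `id`.
#' @param box A [sim_box()].
#' @param forcefield A [forcefield_set()], or `NULL` to disable all pair
#'   interactions (free diffusion / external-force-only runs).
#' @param headgroups Tibble from [build_headgroups()], or `NULL`. Headgroups
#'   are held static (the rigid-tether limit of the restrained monolayer).
#' @param n_steps Number of integration steps.
#' @param dt Time step, ps. Must satisfy `dt << m*friction/k` for the
#'   stiffest harmonic restraint `k` in play (a warning fires at
#'   `dt > 0.1 m*friction/k` for bias springs).
#' @param temperature Temperature, K.
#' @param friction Langevin friction gamma, 1/ps; the diffusion constant is
#'   `kB*T/(mass*friction)`.
#' @param mass Particle mass(es), u; defaults per species.
#' @param seed Integer RNG seed (single generator per run, recorded in
#'   provenance).
#' @param output_every Record every this-many steps (frame 0 is the input).
#' @param cutoff Nonbonded cutoff, nm (default 1.2, mirroring a 12 Angstrom
#'   cutoff).
#' @param eps_r Relative dielectric of the implicit solvent dividing the
#'   Coulomb constant; default 78.5. Distinct from ECC charge scaling, which
#'   models electronic polarizability — the two are not double counted.
#' @param ecc_headgroups Also apply the force field's ECC factor to headgroup
#'   charges? Default `FALSE` (ions only).
#' @param external_force Optional `function(pos, t)` returning an n x 3
#'   force matrix (kJ/mol/nm) — used for test potentials.
#' @param record_headgroups Include the static headgroup atoms in every
#'   output frame (needed for downstream RDF/classification)? Default `TRUE`
#'   when `headgroups` is supplied.
#' @return An [ion_trajectory()].
#' @examples
#' ions <- tibble::tibble(species = "Ca2+", x = 1, y = 1, z = 2)
#' tr <- simulate_langevin(ions, sim_box(4, 4, 6), forcefield = NULL,
#'                         n_steps = 100, dt = 0.01, seed = 7)
#' @export
simulate_langevin <- function(ions, box, forcefield = NULL, headgroups = NULL,
                              n_steps = 1000L, dt = 0.001, temperature = 300,
                              friction = 1, mass = NULL, seed = 1L,
                              output_every = 10L, cutoff = 1.2, eps_r = 78.5,
                              ecc_headgroups = FALSE, external_force = NULL,
                              record_headgroups = !is.null(headgroups)) {
  res <- .langevin_engine(ions, box, forcefield, headgroups, n_steps, dt,
                          temperature, friction, mass, seed, output_every,
                          cutoff, eps_r, ecc_headgroups, external_force,
                          bias = NULL)
  frames <- res$frames
  if (record_headgroups && !is.null(headgroups)) {
    frames <- .append_headgroup_frames(frames, headgroups)
  }
  ion_trajectory(frames, box, dt_out = dt * output_every,
                 provenance = list(engine = "overdamped-langevin", seed = seed,
                                   dt = dt, n_steps = n_steps,
                                   temperature = temperature,
                                   friction = friction,
                                   forcefield = if (!is.null(forcefield))
                                     forcefield$name,
                                   eps_r = eps_r))
}

# Replicate the static headgroup atoms into every frame, after the ions.
.append_headgroup_frames <- function(frames, headgroups) {
  n_ion <- sum(frames$frame == frames$frame[1])
  fr <- unique(frames$frame)
  times <- frames$time[match(fr, frames$frame)]
  hg <- tibble::tibble(
    frame = rep(fr, each = nrow(headgroups)),
    time = rep(times, each = nrow(headgroups)),
    id = rep(n_ion + seq_len(nrow(headgroups)), length(fr)),
    species = rep(paste0(headgroups$atom, "_carb"), length(fr)),
    x = rep(headgroups$x, length(fr)),
    y = rep(headgroups$y, length(fr)),
    z = rep(headgroups$z, length(fr)))
  dplyr::arrange(dplyr::bind_rows(frames, hg), .data$frame, .data$id)
}

#' Constant-rate pull protocol
#'
#' Defaults echo the reference steered protocol: a harmonic restraint of
#' 5000 kJ/mol nm^2 retracted at 0.00002 nm/ps along the z component of the
#' monolayer-to-ion vector.
#'
#' @param k_pull Spring constant, kJ/mol nm^2 (> 0).
#' @param rate Retraction rate, nm/ps (>= 0).
#' @param target_ion Row index of the pulled ion in the `ions` table.
#' @return A `pull_protocol` list.
#' @export
pull_protocol <- function(k_pull = 5000, rate = 2e-5, target_ion = 1L) {
  stopifnot(k_pull > 0, rate >= 0)
  structure(list(k_pull = k_pull, rate = rate,
                 target_ion = as.integer(target_ion)),
            class = "pull_protocol")
}

#' Run a constant-rate pull of one bound ion
#'
#' Attaches a harmonic spring to the z reaction coordinate (target-ion z
#' minus the mean headgroup z) and retracts its center at a constant rate,
#' recording the spring force at every output interval. The recorded force is
#' the force the ion exerts on the moving restraint, so a bound ion produces
#' a negative (attractive) dip that returns to ~0 after detachment.
#'
#' @inheritParams simulate_langevin
#' @param protocol A [pull_protocol()].
#' @param start_center Initial restraint-center position along the reaction
#'   coordinate; default the target ion's starting coordinate.
#' @return A `pull_record` tibble with columns `time` (ps), `center` (nm),
#'   `z` (reaction coordinate, nm), `force` (kJ/mol/nm), carrying the
#'   protocol and start positions as attributes.
#' @export
run_constant_pull <- function(ions, box, forcefield = NULL, headgroups = NULL,
                              protocol = pull_protocol(), n_steps = 1000L,
                              dt = 0.001, temperature = 300, friction = 1,
                              mass = NULL, seed = 1L, output_every = 10L,
                              cutoff = 1.2, eps_r = 78.5,
                              ecc_headgroups = FALSE, external_force = NULL,
                              start_center = NULL) {
  stopifnot(inherits(protocol, "pull_protocol"),
            protocol$target_ion >= 1, protocol$target_ion <= nrow(ions))
  z_ref <- if (!is.null(headgroups)) mean(headgroups$z) else 0
  if (is.null(start_center)) {
    start_center <- ions$z[protocol$target_ion] - z_ref
  }
  res <- .langevin_engine(ions, box, forcefield, headgroups, n_steps, dt,
                          temperature, friction, mass, seed, output_every,
                          cutoff, eps_r, ecc_headgroups, external_force,
                          bias = list(kind = "harmonic", k = protocol$k_pull,
                                      center0 = start_center,
                                      rate = protocol$rate,
                                      target = protocol$target_ion))
  rec <- dplyr::select(res$bias_log, "time", "center", rc = "rc",
                       force = "force")
  rec <- dplyr::rename(rec, z = "rc")
  structure(tibble::new_tibble(rec, class = "pull_record"),
            protocol = protocol, ion = protocol$target_ion,
            start_xy = c(x = ions$x[protocol$target_ion],
                         y = ions$y[protocol$target_ion]),
            seed = seed)
}

#' Run a series of umbrella-sampling windows along z
#'
#' One biased run per window center: a harmonic umbrella on the z reaction
#' coordinate, with samples of the coordinate recorded after a burn-in.
#' Windows whose sample histograms fail to overlap their neighbors trigger a
#' warning (WHAM needs overlap).
#'
#' @inheritParams simulate_langevin
#' @param centers Strictly increasing window centers along z, nm.
#' @param k_umb Umbrella spring constant, kJ/mol nm^2; default 5000.
#' @param target_ion Pulled ion row index.
#' @param n_steps Steps per window.
#' @param burn_in Steps discarded from the start of each window.
#' @return An `umbrella_windows` tibble with columns `window`, `center`,
#'   `k_umb`, `n_samples` and a list-column `samples` of reaction-coordinate
#'   draws.
#' @export
run_umbrella_windows <- function(ions, box, centers, k_umb = 5000,
                                 forcefield = NULL, headgroups = NULL,
                                 target_ion = 1L, n_steps = 2000L,
                                 burn_in = 200L, dt = 0.001,
                                 temperature = 300, friction = 1, mass = NULL,
                                 seed = 1L, output_every = 5L, cutoff = 1.2,
                                 eps_r = 78.5, ecc_headgroups = FALSE,
                                 external_force = NULL) {
  if (length(centers) < 1 || any(diff(centers) <= 0)) {
    stop("window centers must be strictly increasing")
  }
  if (burn_in >= n_steps) stop("burn_in must leave at least one sample")
  z_ref <- if (!is.null(headgroups)) mean(headgroups$z) else 0
  runs <- purrr::imap(centers, function(c0, i) {
    start <- ions
    start$z[target_ion] <- c0 + z_ref   # start each window at its center
    res <- .langevin_engine(start, box, forcefield, headgroups, n_steps, dt,
                            temperature, friction, mass,
                            seed = seed + i - 1L, output_every,
                            cutoff, eps_r, ecc_headgroups, external_force,
                            bias = list(kind = "harmonic", k = k_umb,
                                        center0 = c0, rate = 0,
                                        target = target_ion))
    keep <- res$bias_log$time > burn_in * dt
    res$bias_log$rc[keep]
  })
  if (any(lengths(runs) == 0)) stop("a window produced no post-burn-in samples")
  out <- tibble::tibble(window = seq_along(centers), center = centers,
                        k_umb = k_umb, n_samples = lengths(runs),
                        samples = runs)
  .check_window_overlap(out)
  structure(tibble::new_tibble(out, class = "umbrella_windows"),
            temperature = temperature, seed = seed)
}

# Warn when adjacent windows share no sampled range.
.check_window_overlap <- function(windows) {
  if (nrow(windows) < 2) return(invisible(NULL))
  rng <- t(vapply(windows$samples, range, numeric(2)))
  for (i in seq_len(nrow(windows) - 1)) {
    if (rng[i, 2] < rng[i + 1, 1]) {
      warning(sprintf("umbrella windows %d and %d do not overlap (%.3f < %.3f)",
                      i, i + 1, rng[i, 2], rng[i + 1, 1]))
    }
  }
  invisible(NULL)
}

#' Generate a labeled trajectory with known binding-motif ground truth
#'
#' A purely statistical generator for parameter-recovery tests: each ion
#' performs an independent Markov switch among motif states (resampling from
#' `target_fractions` at `exchange_rate`), and its coordinates are placed in
#' the distance band of the assigned state around a private, well-separated
#' anchor ligand — so classification with the generating cutoffs recovers the
#' labels. Long-run empirical state fractions converge to
#' `target_fractions`.
#'
#' States: `"B"` (bidentate-direct band), `"M"` (monodentate-direct band),
#' `"I"` (indirect band), `"unbound"` (bulk, beyond `total_max`).
#'
#' @param n_ions Number of ions.
#' @param n_frames Number of frames.
#' @param target_fractions Named numeric over a subset of
#'   `c("B","M","I","unbound")`, summing to 1.
#' @param exchange_rate Per-ps probability rate of resampling the state;
#'   stationary distribution equals `target_fractions`.
#' @param cutoffs A [cutoff_scheme()] defining the distance bands.
#' @param box A [sim_box()]; must be large enough to hold `n_ions` anchors
#'   at >= 2.2 * `total_max` spacing, else the geometry is rejected.
#' @param seed Integer RNG seed.
#' @param dt_out Frame interval, ps.
#' @param species Ion species label.
#' @param jitter_sd Gaussian jitter (nm) on the placement distance; the
#'   source of the rare band-edge misclassifications.
#' @return A `labeled_trajectory` list: `trajectory` ([ion_trajectory()]),
#'   `headgroups` (anchor carboxylate carbons), `truth` (tibble `frame`,
#'   `id`, `state`, `bound`), `target_fractions`, `exchange_rate`,
#'   `cutoffs`.
#' @export
generate_labeled_trajectory <- function(n_ions, n_frames, target_fractions,
                                        exchange_rate = 0.1, cutoffs,
                                        box = sim_box(), seed = 1L,
                                        dt_out = 1, species = "Ca2+",
                                        jitter_sd = 0.002) {
  states <- names(target_fractions)
  stopifnot(!is.null(states),
            all(states %in% c("B", "M", "I", "unbound")))
  if (abs(sum(target_fractions) - 1) > 1e-8) {
    stop("target_fractions must sum to 1")
  }
  stopifnot(inherits(cutoffs, "cutoff_scheme"))
  bands <- list(
    B = c(0.6 * cutoffs$bidentate_max, cutoffs$bidentate_max),
    M = c(cutoffs$bidentate_max, cutoffs$direct_max),
    I = c(cutoffs$direct_max, cutoffs$total_max))
  if (any(vapply(bands, function(b) diff(b) <= 0, TRUE))) {
    stop("cutoff bands are geometrically infeasible (non-positive width)")
  }

  spacing <- 2.2 * cutoffs$total_max
  nx <- floor(box$lx / spacing)
  ny <- floor(box$ly / spacing)
  if (nx * ny < n_ions) {
    stop(sprintf(paste0("box too small for %d well-separated anchors at ",
                        "spacing %.2f nm (fits %d); enlarge the box"),
                 n_ions, spacing, nx * ny))
  }
  z_plane <- 0.5
  anchors <- tidyr::expand_grid(iy = seq_len(ny) - 1, ix = seq_len(nx) - 1)
  anchors <- anchors[seq_len(n_ions), ]
  hx <- (anchors$ix + 0.5) * spacing
  hy <- (anchors$iy + 0.5) * spacing
  headgroups <- tibble::tibble(ligand_id = seq_len(n_ions), atom = "C",
                               x = hx, y = hy, z = z_plane, charge = -1)

  old_seed <- .Random.seed_exists()
  set.seed(seed)
  p_switch <- 1 - exp(-exchange_rate * dt_out)
  state <- sample(states, n_ions, replace = TRUE, prob = target_fractions)
  z_top <- box$lz - 0.1
  z_bulk_lo <- min(z_plane + cutoffs$total_max + 0.3, z_top - 0.1)
  band_lo <- vapply(bands, `[`, 0, 1)
  band_hi <- vapply(bands, `[`, 0, 2)

  # vectorized placement of all ions of one frame given their states
  place_all <- function(state) {
    n <- length(state)
    x <- numeric(n); y <- numeric(n); z <- numeric(n)
    ub <- state == "unbound"
    if (any(ub)) {
      x[ub] <- stats::runif(sum(ub), 0, box$lx)
      y[ub] <- stats::runif(sum(ub), 0, box$ly)
      z[ub] <- stats::runif(sum(ub), z_bulk_lo, z_top)
    }
    bd <- which(!ub)
    if (length(bd)) {
      lo <- band_lo[state[bd]]; hi <- band_hi[state[bd]]
      pad <- 0.02 * (hi - lo)
      d <- stats::runif(length(bd), lo + pad, hi - pad) +
        stats::rnorm(length(bd), 0, jitter_sd)
      d <- pmax(d, 1e-3)
      theta <- stats::runif(length(bd), 0, pi / 4)  # stay near own anchor
      phi <- stats::runif(length(bd), 0, 2 * pi)
      x[bd] <- hx[bd] + d * sin(theta) * cos(phi)
      y[bd] <- hy[bd] + d * sin(theta) * sin(phi)
      z[bd] <- z_plane + d * cos(theta)
    }
    cbind(x, y, z)
  }

  pos_all <- array(NA_real_, c(n_frames, n_ions, 3))
  state_all <- matrix(NA_character_, n_frames, n_ions)
  for (f in seq_len(n_frames)) {
    if (f > 1) {
      switch_now <- stats::runif(n_ions) < p_switch
      if (any(switch_now)) {
        state[switch_now] <- sample(states, sum(switch_now), replace = TRUE,
                                    prob = target_fractions)
      }
    }
    pos_all[f, , ] <- place_all(state)
    state_all[f, ] <- state
  }
  .restore_seed(old_seed)

  frame_col <- rep(seq_len(n_frames) - 1L, each = n_ions)
  frames <- tibble::tibble(
    frame = frame_col, time = frame_col * dt_out,
    id = rep(seq_len(n_ions), n_frames), species = species,
    x = as.vector(t(pos_all[, , 1])),
    y = as.vector(t(pos_all[, , 2])),
    z = as.vector(t(pos_all[, , 3])))
  truth <- tibble::tibble(frame = frame_col,
                          id = rep(seq_len(n_ions), n_frames),
                          state = as.vector(t(state_all)),
                          bound = as.vector(t(state_all)) != "unbound")
  traj <- ion_trajectory(frames, box, dt_out = dt_out,
                         provenance = list(engine = "labeled-generator",
                                           seed = seed,
                                           target_fractions =
                                             as.list(target_fractions),
                                           exchange_rate = exchange_rate))
  structure(list(trajectory = traj, headgroups = headgroups,
                 truth = truth,
                 target_fractions = target_fractions,
                 exchange_rate = exchange_rate, cutoffs = cutoffs),
            class = "labeled_trajectory")
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  cat("<labeled_trajectory>", n_particles(x$trajectory), "ions x",
      n_frames(x$trajectory), "frames; target fractions:",
      paste(sprintf("%s=%.2f", names(x$target_fractions),
                    x$target_fractions), collapse = ", "), "\n")
  invisible(x)
}
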
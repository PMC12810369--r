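#' Binding-strength estimators
#'
#' Three routes to a binding strength for ions at the carboxylate monolayer:
#' adhesion forces extracted from constant-rate pull records, potential-of-
#' mean-force (PMF) free energies from umbrella sampling combined with the
#' weighted histogram analysis method (WHAM), and standard binding free
#' energies from the Langmuir adsorption isotherm. AFM adhesion forces
#' convert to free energies either as work over the binding-group length
#' (Delta G = N_A F L) or through the Friddle equilibrium estimator
#' (Delta G = N_A F^2 / 2k).
#'
#' @name free_energy
NULL

# kJ/mol/nm -> nN per molecule: 1e3 / (N_A * 1e-9) / 1e-9
.KJNM_TO_NN <- 1.66053906717e-3

#' Extract an adhesion force from a constant-rate pull record
#'
#' Bin-averages the force trace into non-overlapping bins of `bin_size`
#' points, takes the plateau as the mean of the final `plateau_fraction` of
#' bins (the large-distance baseline, approximately zero), and reports
#' `adhesion_force = |most-attractive bin mean - plateau|` as a positive nN
#' value. The default bin size of 500 points mirrors the reference analysis
#' (500 points at 10 ps per point).
#'
#' @param pull A `pull_record` (force in kJ/mol/nm, converted to nN) or any
#'   data frame with a `force` column already in nN plus a distance column
#'   (`center` or `z` or `x`).
#' @param bin_size Points per bin (>= 1); the record must contain at least
#'   `2 * bin_size` points.
#' @param plateau_fraction Final fraction of bins averaged for the baseline.
#' @param force_in Unit of the input force column: `"auto"` (pull_record ->
#'   kJ/mol/nm, else nN), `"kJ/mol/nm"` or `"nN"`.
#' @return An `adhesion_result` list: `bins` (tibble `distance`,
#'   `mean_force` in nN), `plateau_force`, `adhesion_force` (>= 0, nN),
#'   `bin_size`.
#' @export
extract_adhesion <- function(pull, bin_size = 500, plateau_fraction = 0.2,
                             force_in = c("auto", "kJ/mol/nm", "nN")) {
  force_in <- match.arg(force_in)
  if (force_in == "auto") {
    force_in <- if (inherits(pull, "pull_record")) "kJ/mol/nm" else "nN"
  }
  stopifnot(bin_size >= 1)
  if (nrow(pull) < 2 * bin_size) {
    stop("pull record too short: need at least 2 * bin_size = ",
         2 * bin_size, " points, got ", nrow(pull))
  }
  dist_col <- intersect(c("center", "z", "x", "distance"), names(pull))[1]
  if (is.na(dist_col)) stop("no distance column (center/z/x/distance) found")
  f <- pull$force * if (force_in == "kJ/mol/nm") .KJNM_TO_NN else 1
  d <- pull[[dist_col]]
  n_bins <- floor(length(f) / bin_size)
  idx <- rep(seq_len(n_bins), each = bin_size)
  keep <- seq_len(n_bins * bin_size)
  bins <- tibble::tibble(
    distance = as.numeric(tapply(d[keep], idx, mean)),
    mean_force = as.numeric(tapply(f[keep], idx, mean)))
  n_pl <- max(1L, round(plateau_fraction * n_bins))
  plateau <- mean(bins$mean_force[(n_bins - n_pl + 1):n_bins])
  extremal <- min(bins$mean_force)
  structure(list(bins = bins, plateau_force = plateau,
                 adhesion_force = abs(extremal - plateau),
                 bin_size = bin_size),
            class = "adhesion_result")
}

#' @export
print.adhesion_result <- function(x, ...) {
  cat(sprintf(
    "<adhesion_result> adhesion %.3f nN (plateau %.4f nN, %d bins of %d)\n",
    x$adhesion_force, x$plateau_force, nrow(x$bins), x$bin_size))
  invisible(x)
}

#' Tidy an adhesion result: the binned force curve
#' @param x An `adhesion_result`.
#' @param ... Unused.
#' @return Tibble `distance`, `mean_force`.
#' @export
tidy.adhesion_result <- function(x, ...) x$bins

#' @export
glance.adhesion_result <- function(x, ...) {
  tibble::tibble(adhesion_force = x$adhesion_force,
                 plateau_force = x$plateau_force,
                 n_bins = nrow(x$bins), bin_size = x$bin_size)
}

#' Average adhesion force over the ions under a model AFM tip footprint
#'
#' Mimics the tip-averaged observable: the mean adhesion force over all
#' bound ions whose starting x,y lie inside a square footprint (default
#' 2.4 nm x 2.4 nm, roughly the 3-6 nm^2 tip contact area) centered on the
#' monolayer.
#'
#' @param results List of `adhesion_result` objects, one per pulled ion.
#' @param ion_positions Tibble with `x`, `y` (nm) of each pulled ion at pull
#'   start, same order as `results`.
#' @param footprint Side length of the square footprint, nm.
#' @param center Length-2 xy center of the footprint, nm; default the
#'   centroid of `ion_positions`.
#' @return One-row tibble: `mean_adhesion`, `std_adhesion` (nN), `n_ions`.
#' @export
tip_average <- function(results, ion_positions, footprint = 2.4,
                        center = NULL) {
  stopifnot(length(results) == nrow(ion_positions))
  if (is.null(center)) {
    center <- c(mean(ion_positions$x), mean(ion_positions$y))
  }
  half <- footprint / 2
  inside <- abs(ion_positions$x - center[1]) <= half &
            abs(ion_positions$y - center[2]) <= half
  if (!any(inside)) stop("no ions inside the tip footprint")
  forces <- vapply(results[inside], function(r) r$adhesion_force, numeric(1))
  tibble::tibble(mean_adhesion = mean(forces),
                 std_adhesion = if (length(forces) > 1) stats::sd(forces)
                 else 0,
                 n_ions = length(forces))
}

# Error if sorted windows leave a gap in sampled z; names the gap.
.require_window_overlap <- function(windows) {
  if (nrow(windows) < 2) return(invisible(NULL))
  o <- order(windows$center)
  rng <- t(vapply(windows$samples[o], range, numeric(2)))
  for (i in seq_len(nrow(windows) - 1)) {
    if (rng[i, 2] < rng[i + 1, 1]) {
      stop(sprintf(
        "umbrella windows do not overlap between centers %.3f and %.3f nm (gap %.3f-%.3f)",
        windows$center[o][i], windows$center[o][i + 1],
        rng[i, 2], rng[i + 1, 1]))
    }
  }
  invisible(NULL)
}

# One self-consistent WHAM solve. n_kw: nbins x nwin histogram matrix,
# N_w: effective sample counts, bias_kw: bias energies (kJ/mol) at bin
# centers. Returns unnormalized -kT log density over bins (NA where empty).
.wham_solve <- function(n_kw, N_w, bias_kw, kT, tol, max_iter) {
  M_k <- rowSums(n_kw)
  c_kw <- exp(-bias_kw / kT)
  f_w <- rep(0, length(N_w))
  for (it in seq_len(max_iter)) {
    efw <- exp(f_w / kT)
    denom <- c_kw %*% (N_w * efw)
    P_k <- M_k / denom
    z_w <- crossprod(c_kw, P_k)        # per-window partition sums
    f_new <- -kT * log(as.numeric(z_w))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f_w))
    f_w <- f_new
    if (delta < tol) break
  }
  F_k <- -kT * log(as.numeric(P_k))
  F_k[M_k == 0] <- NA_real_
  F_k
}

#' Potential of mean force via WHAM with Bayesian bootstrap errors
#'
#' Combines umbrella-window samples into one free-energy profile by the
#' self-consistent weighted histogram analysis method, anchors the profile
#' so the plateau (the final `plateau_fraction` of the grid) averages zero,
#' and estimates per-bin uncertainties by the Bayesian bootstrap: windows
#' are reweighted with flat Dirichlet weights and WHAM is re-solved
#' `n_bootstrap` times (default 200).
#'
#' @param windows An `umbrella_windows` tibble (from
#'   [run_umbrella_windows()]) or any tibble with numeric `center`, `k_umb`
#'   and a list-column `samples`.
#' @param bin_width Histogram bin width along z, nm.
#' @param tol Self-consistency tolerance on the window free energies,
#'   kJ/mol.
#' @param max_iter Iteration cap.
#' @param n_bootstrap Bayesian bootstrap replicates (0 disables).
#' @param seed RNG seed for the bootstrap weights.
#' @param temperature K; default the windows' recorded temperature, else
#'   300.
#' @param plateau_fraction Final fraction of the grid used as the zero
#'   anchor.
#' @param min_count Bins with fewer pooled samples than this are reported
#'   as `NA` (under-sampled tails carry no usable free energy).
#' @return A `pmf_curve` tibble: `z` (bin centers, nm), `pmf` (kJ/mol,
#'   plateau-anchored), `std` (bootstrap standard deviation; 0 when
#'   bootstrap is disabled); attributes `temperature`, `n_bootstrap`,
#'   `windows` (center/k metadata), `plateau_fraction`.
#' @export
wham_pmf <- function(windows, bin_width = 0.02, tol = 1e-8, max_iter = 50000,
                     n_bootstrap = 200, seed = 1L, temperature = NULL,
                     plateau_fraction = 0.1, min_count = 5) {
  stopifnot(is.data.frame(windows),
            all(c("center", "k_umb", "samples") %in% names(windows)),
            nrow(windows) >= 1)
  temperature <- temperature %||% attr(windows, "temperature") %||% 300
  kT <- .kB * temperature
  .require_window_overlap(windows)

  all_s <- unlist(windows$samples)
  breaks <- seq(min(all_s) - 1e-9, max(all_s) + bin_width, by = bin_width)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nbins <- length(centers)
  nwin <- nrow(windows)
  n_kw <- vapply(windows$samples, function(s) {
    tabulate(findInterval(s, breaks, left.open = TRUE), nbins = nbins)
  }, numeric(nbins))
  n_kw <- matrix(n_kw, nrow = nbins)
  N_w <- colSums(n_kw)
  bias_kw <- vapply(seq_len(nwin), function(w) {
    0.5 * windows$k_umb[w] * (centers - windows$center[w])^2
  }, numeric(nbins))
  bias_kw <- matrix(bias_kw, nrow = nbins)

  sparse <- rowSums(n_kw) < min_count
  anchor <- function(F_k) {
    F_k[sparse] <- NA_real_
    ok <- which(!is.na(F_k))
    n_pl <- max(1L, round(plateau_fraction * length(ok)))
    F_k - mean(F_k[ok[(length(ok) - n_pl + 1):length(ok)]])
  }
  pmf <- anchor(.wham_solve(n_kw, N_w, bias_kw, kT, tol, max_iter))

  std <- rep(0, nbins)
  if (n_bootstrap > 0) {
    old_seed <- .Random.seed_exists()
    set.seed(seed)
    boots <- matrix(NA_real_, nbins, n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      g <- stats::rexp(nwin)
      g <- g / sum(g) * nwin          # flat Dirichlet weights, mean 1
      boots[, b] <- anchor(.wham_solve(
        sweep(n_kw, 2, g, `*`), N_w * g, bias_kw, kT, tol, max_iter))
    }
    std <- apply(boots, 1, stats::sd, na.rm = TRUE)
    .restore_seed(old_seed)
  }
  structure(tibble::new_tibble(list(z = centers, pmf = pmf, std = std),
                               class = "pmf_curve"),
            temperature = temperature, n_bootstrap = n_bootstrap,
            windows = windows[, c("center", "k_umb")],
            plateau_fraction = plateau_fraction)
}

#' Binding free energy from a PMF curve
#'
#' Delta G is the depth of the PMF minimum below the large-distance plateau
#' (which [wham_pmf()] anchors to zero). When the profile has no interior
#' minimum below the plateau the ion is reported unbound with Delta G = 0.
#' The per-ligand value divides by the mean number of ligands bound per ion
#' (e.g. 4.7 for Mg2+ and 4.4 for Ca2+/Sr2+/Ba2+ in the reference system).
#'
#' @param pmf A `pmf_curve` from [wham_pmf()].
#' @param per_ligand_divisor Mean ligands per bound ion; default 1 (report
#'   the total only).
#' @param min_depth Minimum depth (kJ/mol) below the plateau for a bound
#'   verdict; default 0.
#' @return A `pmf_dg` list: `dG` (kJ/mol, >= 0), `dG_per_ligand`, `z_min`
#'   (nm), `plateau`, `bound` flag.
#' @export
pmf_binding_dg <- function(pmf, per_ligand_divisor = 1, min_depth = 0) {
  stopifnot(inherits(pmf, "pmf_curve") || all(c("z", "pmf") %in% names(pmf)))
  ok <- !is.na(pmf$pmf)
  pl_frac <- attr(pmf, "plateau_fraction") %||% 0.1
  idx <- which(ok)
  n_pl <- max(1L, round(pl_frac * length(idx)))
  plateau_idx <- idx[(length(idx) - n_pl + 1):length(idx)]
  plateau <- mean(pmf$pmf[plateau_idx])
  interior <- setdiff(idx, plateau_idx)
  i_min <- interior[which.min(pmf$pmf[interior])]
  depth <- plateau - pmf$pmf[i_min]
  if (!length(i_min) || depth <= min_depth) {
    out <- list(dG = 0, dG_per_ligand = 0, z_min = NA_real_,
                plateau = plateau, bound = FALSE)
  } else {
    out <- list(dG = depth, dG_per_ligand = depth / per_ligand_divisor,
                z_min = pmf$z[i_min], plateau = plateau, bound = TRUE)
  }
  structure(out, class = "pmf_dg")
}

#' @export
print.pmf_dg <- function(x, ...) {
  if (x$bound) {
    cat(sprintf("<pmf_dg> Delta G = %.2f kJ/mol (minimum at z = %.3f nm)",
                x$dG, x$z_min))
    if (x$dG != x$dG_per_ligand) {
      cat(sprintf("; %.2f kJ/mol per ligand", x$dG_per_ligand))
    }
    cat("\n")
  } else {
    cat("<pmf_dg> no interior minimum below the plateau: unbound, Delta G = 0\n")
  }
  invisible(x)
}

#' Langmuir-isotherm inputs from an equilibrium trajectory
#'
#' q_e is the time-averaged number of bound divalent ions (any contact
#' within `total_max`) over the final `window` fraction of frames; q_m is
#' the total divalent-ion count (all ions could bind, since there are fewer
#' ions than binding sites); C_e is the time-averaged molar concentration of
#' unbound ions in the solution volume.
#'
#' @param x Motif-assignment tibble, [ion_trajectory()], or
#'   [generate_labeled_trajectory()] result.
#' @param window Final fraction of frames to average (default 0.5,
#'   mirroring "the last half of the production run").
#' @param n_divalent_total q_m; default the number of distinct ions in the
#'   assignments. Set to the lattice site count to use the alternative
#'   site-limited reading.
#' @param volume_L Solution volume in liters; default computed as box
#'   cross-section times the water-slab height above the headgroup plane,
#'   `lx * ly * (lz - z_plane) * 1e-24`.
#' @param box,z_plane Used for the default volume; `z_plane` defaults to 0.
#' @inheritParams bound_count_series
#' @return A `langmuir_inputs` one-row tibble: `q_e`, `q_m`, `C_e` (mol/L),
#'   `n_frames_used`, `all_bound` flag (C_e = 0, infinite K_0).
#' @export
estimate_langmuir_inputs <- function(x, window = 0.5, n_divalent_total = NULL,
                                     volume_L = NULL, box = NULL,
                                     z_plane = 0, headgroups = NULL,
                                     cutoffs = NULL) {
  if (inherits(x, "labeled_trajectory")) {
    box <- box %||% x$trajectory$box
  } else if (inherits(x, "ion_trajectory")) {
    box <- box %||% x$box
  }
  assignments <- if (is.data.frame(x) && "bound" %in% names(x)) x else
    classify_trajectory(x, headgroups, cutoffs)
  frames <- sort(unique(assignments$frame))
  n_keep <- max(1L, ceiling(window * length(frames)))
  keep <- frames[(length(frames) - n_keep + 1):length(frames)]
  sub <- assignments[assignments$frame %in% keep, ]
  per_frame <- dplyr::summarise(dplyr::group_by(sub, .data$frame),
                                n_bound = sum(.data$bound),
                                n_free = sum(!.data$bound), .groups = "drop")
  q_e <- mean(per_frame$n_bound)
  q_m <- n_divalent_total %||% length(unique(assignments$id))
  if (is.null(volume_L)) {
    if (is.null(box)) stop("supply either volume_L or box")
    volume_L <- box$lx * box$ly * (box$lz - z_plane) * 1e-24
  }
  C_e <- mean(per_frame$n_free) / (md_constants$NA_mol * volume_L)
  structure(tibble::new_tibble(list(
    q_e = q_e, q_m = as.numeric(q_m), C_e = C_e,
    n_frames_used = length(keep), all_bound = C_e == 0),
    nrow = 1L, class = "langmuir_inputs"))
}

#' Standard binding free energy from the Langmuir isotherm
#'
#' Evaluates the standard equilibrium adsorption constant
#' `K_0 = q_e / (q_m - q_e) * C_0 / C_e` and
#' `Delta G0 = -R T log(K_0)` (kJ/mol). The q's are ion counts (the ratio
#' is dimensionless); [ions_to_mg_per_g()] provides the mg-per-g reporting
#' view.
#'
#' @param q_e Equilibrium absorbed amount (bound-ion count), `0 <= q_e <
#'   q_m`. May also be a `langmuir_inputs` row, in which case `q_m` and
#'   `C_e` are taken from it.
#' @param q_m Maximum absorption capacity (total divalent ions).
#' @param C_e Equilibrium concentration of unbound absorbate, mol/L (> 0).
#' @param C_0 Standard-state concentration, mol/L (default 1).
#' @param temperature K (default 300).
#' @return A `langmuir_result` one-row tibble: `q_e`, `q_m`, `C_e`, `C_0`,
#'   `K_0`, `dG0` (kJ/mol), `temperature`.
#' @examples
#' langmuir_dg(q_e = 90, q_m = 100, C_e = 0.065)
#' @export
langmuir_dg <- function(q_e, q_m = NULL, C_e = NULL, C_0 = 1,
                        temperature = 300) {
  if (is.data.frame(q_e)) {
    li <- q_e
    if (isTRUE(li$all_bound[1])) {
      stop("all ions bound in every frame: C_e = 0 gives infinite K_0")
    }
    q_m <- li$q_m[1]; C_e <- li$C_e[1]; q_e <- li$q_e[1]
  }
  if (!(q_e >= 0 && q_e < q_m)) {
    stop(sprintf("need 0 <= q_e < q_m (got q_e = %g, q_m = %g)", q_e, q_m))
  }
  if (!(C_e > 0)) stop("C_e must be > 0 (all-bound systems have no finite K_0)")
  K_0 <- q_e / (q_m - q_e) * C_0 / C_e
  dG0 <- -.kB * temperature * log(K_0)
  structure(tibble::new_tibble(list(
    q_e = q_e, q_m = q_m, C_e = C_e, C_0 = C_0, K_0 = K_0, dG0 = dG0,
    temperature = temperature), nrow = 1L, class = "langmuir_result"))
}

#' @export
glance.langmuir_result <- function(x, ...) tibble::as_tibble(x)

#' Convert an ion count to milligrams of absorbate per gram of absorbent
#'
#' Reporting view for absorption capacities. Molar masses are the standard
#' atomic weights (g/mol).
#'
#' @param n_ions Ion count.
#' @param species One of `"Mg2+"`, `"Ca2+"`, `"Sr2+"`, `"Ba2+"`.
#' @param absorbent_g Mass of the absorbent (monolayer), g.
#' @return mg of absorbate per g of absorbent.
#' @export
ions_to_mg_per_g <- function(n_ions, species, absorbent_g) {
  mm <- c("Mg2+" = 24.305, "Ca2+" = 40.078, "Sr2+" = 87.62,
          "Ba2+" = 137.327)
  if (!species %in% names(mm)) {
    stop("no molar mass for species ", species)
  }
  stopifnot(absorbent_g > 0)
  n_ions / md_constants$NA_mol * mm[[species]] * 1e3 / absorbent_g
}

#' Convert an AFM adhesion force to a binding free energy
#'
#' Work picture: `Delta G_bind = N_A * F_AD * L` with L the length of the
#' binding group — here the 0.22 nm carboxylate O-O distance, the distance
#' traversed when one carboxylate leaves an ion-bridge complex. Reported per
#' mole; optionally also per carboxylate group on the tip.
#'
#' @param f_ad Adhesion force, pN (>= 0). Vectorized.
#' @param L Interaction length, nm (> 0).
#' @param coverage Optional carboxylate-group count (or range, e.g.
#'   `c(12, 27)`) on the tip for the per-group view.
#' @param temperature K, for the dimensionless `dG_over_kT` view.
#' @return Tibble: `f_ad`, `L`, `dG_bind` (kJ/mol), `dG_over_kT`, and when
#'   `coverage` is given `dG_per_group_min`/`_max` (kJ/mol).
#' @examples
#' afm_force_to_dg(78.4, 0.332)   # the 15.7 kJ/mol worked example
#' @export
afm_force_to_dg <- function(f_ad, L, coverage = NULL, temperature = 300) {
  stopifnot(all(f_ad >= 0), L > 0)
  dG <- md_constants$NA_mol * (f_ad * 1e-12) * (L * 1e-9) / 1e3
  out <- tibble::tibble(f_ad = f_ad, L = L, dG_bind = dG,
                        dG_over_kT = dG / (.kB * temperature))
  if (!is.null(coverage)) {
    out$dG_per_group_min <- dG / max(coverage)
    out$dG_per_group_max <- dG / min(coverage)
  }
  out
}

#' Friddle equilibrium estimator: free energy from the adhesion force
#'
#' In the equilibrium limit (adhesion force independent of loading rate)
#' the binding free energy is proportional to the square of the equilibrium
#' force: `Delta G = N_A * F_eq^2 / (2 k)` with k the cantilever spring
#' constant.
#'
#' @param f_eq Equilibrium (adhesion) force, pN. Vectorized.
#' @param k_cantilever Cantilever spring constant, N/m (> 0).
#' @return Delta G in kJ/mol.
#' @examples
#' friddle_dg(78.4, 0.09)   # the 20.6 kJ/mol comparison value
#' @export
friddle_dg <- function(f_eq, k_cantilever) {
  stopifnot(k_cantilever > 0)
  md_constants$NA_mol * (f_eq * 1e-12)^2 / (2 * k_cantilever) / 1e3
}
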
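#' Monolayer structural observables
#'
#' Chain tilt angles, carboxylate O-O distances, per-species number-density
#' profiles along z, and the electrostatic potential obtained by double
#' integration of the charge density (Poisson's equation in planar
#' geometry).
#'
#' @name structure_analysis
NULL

#' Chain tilt angles relative to the surface normal
#'
#' The chain axis is the principal axis of the chain atoms (the
#' least-squares line through them), which is robust to kinks; the
#' first-to-last-atom vector is available as an alternative. Angles are
#' measured against +z and folded into \[0, 90\] degrees, so they are
#' invariant under chain reversal.
#'
#' @param chains Tibble with columns `ligand_id`, `x`, `y`, `z` (nm), >= 2
#'   atoms per chain; typically full-chain ligand coordinates from an
#'   external all-atom trajectory.
#' @param method `"principal"` (default) or `"endpoints"`.
#' @return A `tilt_result` list: `per_ligand` (tibble `ligand_id`,
#'   `angle_deg`), `mean`, `std`; degenerate chains (all atoms coincident)
#'   are skipped with a warning.
#' @export
tilt_angles <- function(chains, method = c("principal", "endpoints")) {
  method <- match.arg(method)
  per <- lapply(split(chains, chains$ligand_id), function(ch) {
    m <- as.matrix(ch[, c("x", "y", "z")])
    if (nrow(m) < 2) stop("need >= 2 atoms per chain")
    mc <- sweep(m, 2, colMeans(m))
    if (all(abs(mc) < 1e-12)) {
      warning("degenerate chain (coincident atoms) for ligand ",
              ch$ligand_id[1], "; skipped")
      return(NULL)
    }
    axis <- if (method == "principal") {
      svd(mc, nu = 0, nv = 1)$v[, 1]
    } else {
      as.numeric(m[nrow(m), ] - m[1, ])
    }
    cosang <- abs(axis[3]) / sqrt(sum(axis^2))
    tibble::tibble(ligand_id = ch$ligand_id[1],
                   angle_deg = acos(pmin(1, cosang)) * 180 / pi)
  })
  per <- dplyr::bind_rows(per)
  if (nrow(per) == 0) stop("no non-degenerate chains")
  structure(list(per_ligand = per, mean = mean(per$angle_deg),
                 std = if (nrow(per) > 1) stats::sd(per$angle_deg) else 0),
            class = "tilt_result")
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf("<tilt_result> %.1f +/- %.1f degrees over %d chains\n",
              x$mean, x$std, nrow(x$per_ligand)))
  invisible(x)
}

#' Tidy per-ligand tilt angles
#' @param x A `tilt_result`.
#' @param ... Unused.
#' @return Tibble `ligand_id`, `angle_deg`.
#' @export
tidy.tilt_result <- function(x, ...) x$per_ligand

#' Carboxylate O-O distances: intramolecular mean and intermolecular RDF
#'
#' The intramolecular O-O distance is averaged over ligands (0.22 nm by
#' construction for the rigid headgroup builder). The intermolecular O-O
#' RDF excludes same-ligand pairs; the maximum of its second peak (after
#' smoothing) characterizes the headgroup spacing order.
#'
#' @param headgroups Headgroup table from [build_headgroups()] (or multiple
#'   frames' worth row-bound with a `frame` column).
#' @param box A [sim_box()].
#' @param r_max,dr RDF range and bin width, nm.
#' @param smoothing Moving-average window (bins) before peak search.
#' @return A list: `intra_mean` (nm), `inter_rdf` (tibble `r`, `g`),
#'   `second_peak_r` (nm; `NA` with fewer than 2 ligands or no resolvable
#'   second peak).
#' @export
oo_rdf_peaks <- function(headgroups, box, r_max = 1.2, dr = 0.005,
                         smoothing = 5) {
  if (!"frame" %in% names(headgroups)) headgroups$frame <- 0L
  o <- headgroups[headgroups$atom %in% c("O1", "O2"), ]
  intra <- dplyr::summarise(
    dplyr::group_by(o, .data$frame, .data$ligand_id),
    d = sqrt(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2),
    .groups = "drop")
  intra_mean <- mean(intra$d)
  n_lig <- length(unique(o$ligand_id))
  if (n_lig < 2) {
    return(list(intra_mean = intra_mean, inter_rdf = NULL,
                second_peak_r = NA_real_))
  }
  breaks <- seq(0, r_max, by = dr)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- numeric(length(centers))
  n_pairs_norm <- 0
  for (fr in split(o, o$frame)) {
    d <- slab_distances(fr[, c("x", "y", "z")], fr[, c("x", "y", "z")], box)
    same <- outer(fr$ligand_id, fr$ligand_id, "==")
    d[same] <- Inf                     # excludes self and intra-ligand pairs
    dv <- d[d < r_max]
    counts <- counts + tabulate(findInterval(dv, breaks, left.open = TRUE),
                                nbins = length(centers))
    n_pairs_norm <- n_pairs_norm + nrow(fr) * (nrow(fr) - 2)
  }
  # density normalization against the uniform expectation in the slab
  vol <- box$lx * box$ly * box$lz
  g <- counts * vol / (n_pairs_norm * 4 * pi * centers^2 * dr)
  gs <- .smooth_ma(g, smoothing)
  pk <- pracma::findpeaks(gs, minpeakheight = 0.05 * max(gs),
                          minpeakdistance = 2)
  second_peak_r <- if (!is.null(pk) && nrow(pk) >= 2) {
    centers[sort(pk[, 2])[2]]
  } else NA_real_
  list(intra_mean = intra_mean,
       inter_rdf = tibble::tibble(r = centers, g = g),
       second_peak_r = second_peak_r)
}

#' Per-species number-density profiles along z
#'
#' Histograms each species' z coordinates over the trajectory, normalized
#' by bin volume (lx * ly * dz) and frame count, so the profile integrates
#' back to the per-frame particle count.
#'
#' @param traj An [ion_trajectory()].
#' @param species Species labels to profile; default all.
#' @param dz Bin width, nm.
#' @return A `density_profile` tibble: `z` (bin centers), `species`,
#'   `density` (nm^-3); attributes `dz`, `area`, `n_frames`.
#' @export
density_profile <- function(traj, species = NULL, dz = 0.05) {
  stopifnot(inherits(traj, "ion_trajectory"), dz > 0)
  box <- traj$box
  species <- species %||% unique(traj$frames$species)
  breaks <- seq(0, box$lz + dz, by = dz)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nf <- n_frames(traj)
  area <- box$lx * box$ly
  out <- purrr::map_dfr(species, function(sp) {
    zz <- traj$frames$z[traj$frames$species == sp]
    counts <- tabulate(findInterval(zz, breaks, left.open = TRUE),
                       nbins = length(centers))
    tibble::tibble(z = centers, species = sp,
                   density = counts / (area * dz * nf))
  })
  structure(tibble::new_tibble(out, class = "density_profile"),
            dz = dz, area = area, n_frames = nf)
}

#' Charge density along z from density profiles and fixed charges
#'
#' @param profile A [density_profile()] tibble.
#' @param charges Named charges (e) per species, e.g.
#'   `c("Ca2+" = 2, "Cl-" = -1)`; species absent from the map contribute 0.
#' @param fixed Optional tibble with `z`, `charge` of static charges (e.g.
#'   headgroup atoms), smeared into the same bins as areal contributions.
#' @return Tibble `z`, `rho` (e nm^-3).
#' @export
charge_density <- function(profile, charges, fixed = NULL) {
  dz <- attr(profile, "dz")
  area <- attr(profile, "area")
  q <- charges[profile$species]
  q[is.na(q)] <- 0
  rho <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(z = profile$z,
                                   part = profile$density * as.numeric(q)),
                    .data$z),
    rho = sum(.data$part), .groups = "drop")
  if (!is.null(fixed)) {
    zc <- sort(unique(profile$z))
    idx <- findInterval(fixed$z, c(zc - dz / 2, max(zc) + dz / 2),
                        left.open = TRUE)
    add <- tapply(fixed$charge, factor(idx, levels = seq_along(zc)),
                  sum, default = 0)
    rho$rho <- rho$rho + as.numeric(add) / (area * dz)
  }
  rho
}

#' Electrostatic potential from a planar charge-density profile
#'
#' Integrates Poisson's equation in slab geometry with psi(0) = 0 and
#' E(0) = 0: `psi(z) = -(1/(eps0 epsr)) * double cumulative integral of
#' rho`, by trapezoidal cumulative integration. For an overall-neutral
#' profile the field vanishes beyond the charged region (Gauss), and a sign
#' change of psi inside the ion region flags charge inversion.
#'
#' @param rho Tibble with `z` (nm) and `rho` (e nm^-3), e.g. from
#'   [charge_density()].
#' @param eps_r Relative dielectric; 78.5 for the implicit-solvent system,
#'   1 for vacuum-referenced profiles.
#' @return Tibble `z`, `rho`, `field` (V/nm), `psi` (V); attribute
#'   `charge_inversion` (logical: psi changes sign in the interior).
#' @export
electrostatic_potential <- function(rho, eps_r = 78.5) {
  stopifnot(all(c("z", "rho") %in% names(rho)), eps_r > 0)
  z <- rho$z
  # E(z) = (1/eps0 epsr) int_0^z rho dz'  (V/nm), then psi = -int E dz
  field <- md_constants$e_over_eps0 / eps_r *
    pracma::cumtrapz(z, rho$rho)[, 1]
  psi <- -pracma::cumtrapz(z, field)[, 1]
  inversion <- any(psi > 1e-12) && any(psi < -1e-12)
  structure(tibble::new_tibble(
    list(z = z, rho = rho$rho, field = field, psi = psi),
    class = "potential_profile"),
    charge_inversion = inversion, eps_r = eps_r,
    total_charge = pracma::trapz(z, rho$rho))
}
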
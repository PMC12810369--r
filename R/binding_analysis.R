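#' Ion-carboxylate binding analysis
#'
#' The binding observable is the distance from the carboxylate carbon to the
#' ion. Radial distribution functions (RDFs) of that distance show a first
#' peak for bidentate direct binding (both carboxylate oxygens coordinate),
#' a second peak for monodentate direct binding, and a further solvent-shared
#' ("indirect") region; the minima between peaks define distance-band
#' cutoffs, and per-ion combinations of band contacts define binding motifs
#' ("B", "M", "I" and composites such as "B+M+I").
#'
#' @name binding_analysis
NULL

#' Distance-band cutoff scheme for motif classification
#'
#' @param bidentate_max End of the first carbon-ion RDF peak, nm: contacts
#'   closer than this are bidentate direct ("B").
#' @param direct_max End of the second peak, nm: B or monodentate direct
#'   ("M").
#' @param total_max End of the indirect (solvent-shared) region, nm.
#' @param indirect_split Optional internal dip splitting the indirect band
#'   into a two-hydrogen-bond and a one-hydrogen-bond subtype (the Mg-style
#'   dip at 0.45 nm inside a 0.38-0.59 nm region); must lie strictly inside
#'   `(direct_max, total_max)`.
#' @param source `"derived"` (from an RDF) or `"manual"`.
#' @return A `cutoff_scheme` list.
#' @examples
#' cutoff_scheme(0.30, 0.42, 0.59, indirect_split = 0.45)
#' @export
cutoff_scheme <- function(bidentate_max, direct_max, total_max,
                          indirect_split = NULL, source = "manual") {
  if (!(0 < bidentate_max && bidentate_max < direct_max &&
        direct_max < total_max)) {
    stop("cutoffs must satisfy 0 < bidentate_max < direct_max < total_max")
  }
  if (!is.null(indirect_split) &&
      !(indirect_split > direct_max && indirect_split < total_max)) {
    stop("indirect_split must lie inside (direct_max, total_max)")
  }
  structure(list(bidentate_max = bidentate_max, direct_max = direct_max,
                 total_max = total_max, indirect_split = indirect_split,
                 source = source),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("<cutoff_scheme> B <= %.3f < M <= %.3f < I <= %.3f nm (%s)%s\n",
              x$bidentate_max, x$direct_max, x$total_max, x$source,
              if (!is.null(x$indirect_split))
                sprintf("; indirect split at %.3f", x$indirect_split) else ""))
  invisible(x)
}

# Histogram pair distances for one frame; returns per-bin counts.
.pair_hist <- function(pos_a, pos_b, box, breaks, same_group) {
  d <- slab_distances(pos_a, pos_b, box)
  if (same_group) diag(d) <- Inf
  d <- d[d < breaks[length(breaks)]]
  tabulate(findInterval(d, breaks, left.open = TRUE),
           nbins = length(breaks) - 1L)
}

#' Radial distribution function in slab geometry
#'
#' g(r) between two labeled particle groups with minimum image in x,y and
#' bounded z. Normalization accounts for the slab: for a reference particle
#' at height z the spherical shell of radius r is clipped to the box
#' `[0, lz]` (zone area 2 pi r h with h the clipped diameter), which makes
#' g(r) -> 1 for an ideal gas even near the walls. The running coordination
#' number n(r) counts B particles within r of an A particle.
#'
#' @param traj An [ion_trajectory()] whose frames contain both groups.
#' @param group_a,group_b Species label(s) selecting the reference (A) and
#'   partner (B) particles, e.g. `"C_carb"` and `"Ca2+"`.
#' @param r_max Maximum distance, nm; must not exceed half the smaller of
#'   lx, ly.
#' @param dr Bin width, nm.
#' @return An `rdf_result` tibble with columns `r` (bin centers), `g`,
#'   `coordination`; attributes `pair_spec`, `n_frames`, `dr`.
#' @export
compute_rdf <- function(traj, group_a, group_b, r_max = 1.0, dr = 0.005) {
  stopifnot(inherits(traj, "ion_trajectory"), r_max > 0, dr > 0)
  box <- traj$box
  if (r_max > min(box$lx, box$ly) / 2 + 1e-9) {
    stop("r_max must be <= min(lx, ly)/2 for the minimum-image convention")
  }
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  frames <- split(traj$frames, traj$frames$frame)

  counts <- numeric(length(centers))
  shell_norm <- numeric(length(centers))
  n_a_tot <- 0L
  n_b_tot <- 0L
  same <- setequal(group_a, group_b)
  vol <- box$lx * box$ly * box$lz
  for (fr in frames) {
    a <- fr[fr$species %in% group_a, c("x", "y", "z")]
    b <- fr[fr$species %in% group_b, c("x", "y", "z")]
    if (nrow(a) == 0 || nrow(b) == 0) {
      stop("empty particle group (A: ", nrow(a), ", B: ", nrow(b), " rows)")
    }
    counts <- counts + .pair_hist(a, b, box, breaks, same)
    # clipped-shell volumes summed over reference particles; the zone-area
    # integrand 2 pi r min(h, 2r) is integrated over each bin by Simpson
    for (k in seq_along(centers)) {
      rr <- breaks[k] + diff(breaks)[k] * c(0, 0.25, 0.5, 0.75, 1)
      wts <- c(1, 4, 2, 4, 1) / 12 * diff(breaks)[k]
      v <- vapply(rr, function(r) {
        h <- pmin(box$lz, a$z + r) - pmax(0, a$z - r)
        sum(2 * pi * r * pmin(h, 2 * r))
      }, numeric(1))
      shell_norm[k] <- shell_norm[k] + sum(wts * v)
    }
    n_a_tot <- n_a_tot + nrow(a)
    n_b_tot <- n_b_tot + nrow(b)
  }
  nf <- length(frames)
  rho_b <- (n_b_tot / nf - as.integer(same)) / vol
  g <- counts / (shell_norm * rho_b)
  coordination <- cumsum(counts) / (n_a_tot)
  structure(tibble::new_tibble(
    list(r = centers, g = g, coordination = coordination),
    class = "rdf_result"),
    pair_spec = c(a = paste(group_a, collapse = "|"),
                  b = paste(group_b, collapse = "|")),
    n_frames = nf, dr = dr)
}

# Centered moving average used before extremum detection; window is forced
# odd, endpoints use the available part of the window.
.smooth_ma <- function(y, window) {
  if (window <= 1) return(y)
  if (window %% 2 == 0) window <- window + 1
  half <- (window - 1) / 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Derive distance-band cutoffs from a carbon-ion RDF
#'
#' Smooths g(r) with a centered moving average, locates the peaks, and
#' places each cutoff at the first local minimum after each peak:
#' `bidentate_max` after the first peak, `direct_max` after the second,
#' `total_max` at the minimum terminating the indirect region (after the
#' last resolvable indirect peak). When the indirect region itself shows two
#' sub-peaks (Mg-style), the dip between them becomes `indirect_split`.
#'
#' @param rdf An `rdf_result` from [compute_rdf()].
#' @param smoothing Moving-average window in bins (default 5).
#' @param min_peak_frac Peaks lower than this fraction of the global maximum
#'   are ignored (default 0.05).
#' @return A [cutoff_scheme()] with `source = "derived"`.
#' @export
derive_cutoffs <- function(rdf, smoothing = 5, min_peak_frac = 0.05) {
  gs <- .smooth_ma(rdf$g, smoothing)
  pk <- pracma::findpeaks(gs, minpeakheight = min_peak_frac * max(gs),
                          minpeakdistance = 2)
  if (is.null(pk) || nrow(pk) < 2) {
    stop(paste("fewer than 2 resolvable RDF peaks; supply manual cutoffs",
               "via cutoff_scheme()"))
  }
  peaks <- sort(pk[, 2])
  first_min_after <- function(i_peak, i_next) {
    seg <- gs[i_peak:i_next]
    # first qualifying local minimum (tie-break: first)
    for (j in 2:(length(seg) - 1)) {
      if (seg[j] <= seg[j - 1] && seg[j] < seg[j + 1]) {
        return(i_peak + j - 1)
      }
    }
    i_peak + which.min(seg) - 1
  }
  n <- length(gs)
  np <- length(peaks)
  m1 <- first_min_after(peaks[1], peaks[2])
  if (np < 3) {
    stop(paste("no resolvable indirect region (only two RDF peaks);",
               "supply manual cutoffs via cutoff_scheme()"))
  }
  m2 <- first_min_after(peaks[2], peaks[3])
  if (np >= 4) {
    split_idx <- first_min_after(peaks[3], peaks[4])
    m3 <- first_min_after(peaks[4], n)
    indirect_split <- rdf$r[split_idx]
  } else {
    m3 <- first_min_after(peaks[3], n)
    indirect_split <- NULL
  }
  cutoff_scheme(rdf$r[m1], rdf$r[m2], rdf$r[m3],
                indirect_split = indirect_split, source = "derived")
}

# Band-count the carbon-ion distances for a block of ion rows against one
# set of ligand carbons; returns n_b/n_m/n_i count columns.
.band_counts <- function(ions, carbons, box, cutoffs) {
  n <- nrow(ions)
  n_b <- integer(n); n_m <- integer(n); n_i <- integer(n)
  for (j in seq_len(nrow(carbons))) {
    dx <- min_image(ions$x - carbons$x[j], box$lx)
    dy <- min_image(ions$y - carbons$y[j], box$ly)
    dz <- ions$z - carbons$z[j]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    n_b <- n_b + (d <= cutoffs$bidentate_max)
    n_m <- n_m + (d > cutoffs$bidentate_max & d <= cutoffs$direct_max)
    n_i <- n_i + (d > cutoffs$direct_max & d <= cutoffs$total_max)
  }
  list(n_b = n_b, n_m = n_m, n_i = n_i)
}

.finish_assignment <- function(ions, counts) {
  cat_str <- function(b, m, i) {
    parts <- c("B", "M", "I")[c(b > 0, m > 0, i > 0)]
    if (length(parts) == 0) "unbound" else paste(parts, collapse = "+")
  }
  tibble::tibble(
    frame = ions$frame, id = ions$id, species = ions$species,
    n_b = counts$n_b, n_m = counts$n_m, n_i = counts$n_i,
    n_direct = counts$n_b + counts$n_m,
    n_total = counts$n_b + counts$n_m + counts$n_i,
    category = mapply(cat_str, counts$n_b, counts$n_m, counts$n_i),
    bound = counts$n_b + counts$n_m + counts$n_i > 0)
}

#' Classify the binding motif of every ion in one frame
#'
#' Maps each ligand-ion carboxylate-carbon distance to a contact type — B
#' (<= `bidentate_max`), M (<= `direct_max`), I (<= `total_max`), else no
#' contact — and reduces each ion's contact-type set to a category string
#' ("B", "B+M", "B+M+I", ..., "unbound").
#'
#' @param frame One frame's tibble (e.g. from [get_frame()]), containing the
#'   ion rows; headgroup rows in the frame are ignored.
#' @param headgroups Headgroup table from [build_headgroups()] (only the C
#'   atoms are used), or any tibble of carbon sites with `x`, `y`, `z`.
#' @param cutoffs A [cutoff_scheme()].
#' @param box A [sim_box()] for the minimum-image convention.
#' @param ion_species Labels treated as ions; default: every species not
#'   ending in `"_carb"`.
#' @return A motif-assignment tibble: `frame`, `id`, `species`, per-ion
#'   ligand counts `n_b`, `n_m`, `n_i`, `n_direct`, `n_total`, `category`,
#'   `bound`.
#' @export
classify_frame <- function(frame, headgroups, cutoffs, box,
                           ion_species = NULL) {
  stopifnot(inherits(cutoffs, "cutoff_scheme"), inherits(box, "sim_box"))
  if (is.null(ion_species)) {
    ion_species <- setdiff(unique(frame$species),
                           grep("_carb$", unique(frame$species), value = TRUE))
  }
  ions <- frame[frame$species %in% ion_species, ]
  if (!"frame" %in% names(ions)) ions$frame <- 0L
  carbons <- if ("atom" %in% names(headgroups)) {
    headgroups[headgroups$atom == "C", ]
  } else headgroups
  .finish_assignment(ions, .band_counts(ions, carbons, box, cutoffs))
}

#' Classify every frame of a trajectory
#'
#' Vectorized across frames (loops only over ligands), so long synthetic
#' trajectories classify in seconds.
#'
#' @param traj An [ion_trajectory()] or a [generate_labeled_trajectory()]
#'   result (whose own headgroups and cutoffs are then the defaults).
#' @inheritParams classify_frame
#' @return Motif-assignment tibble as in [classify_frame()], all frames.
#' @export
classify_trajectory <- function(traj, headgroups = NULL, cutoffs = NULL,
                                ion_species = NULL) {
  if (inherits(traj, "labeled_trajectory")) {
    headgroups <- headgroups %||% traj$headgroups
    cutoffs <- cutoffs %||% traj$cutoffs
    traj <- traj$trajectory
  }
  stopifnot(inherits(traj, "ion_trajectory"),
            !is.null(headgroups), inherits(cutoffs, "cutoff_scheme"))
  if (is.null(ion_species)) {
    ion_species <- setdiff(unique(traj$frames$species),
                           grep("_carb$", unique(traj$frames$species),
                                value = TRUE))
  }
  ions <- traj$frames[traj$frames$species %in% ion_species, ]
  carbons <- if ("atom" %in% names(headgroups)) {
    headgroups[headgroups$atom == "C", ]
  } else headgroups
  .finish_assignment(ions, .band_counts(ions, carbons, traj$box, cutoffs))
}

#' Time-averaged binding statistics from motif assignments
#'
#' Summarizes a motif-assignment table with the reference column semantics:
#' an ion counts as "bidentate" if it has at least one bidentate contact,
#' "direct" with at least one B or M contact, "total" with any contact
#' including indirect; ligands-per-ion means are taken over the ions in each
#' of those states.
#'
#' @param assignments Tibble from [classify_frame()]/[classify_trajectory()].
#' @return A `binding_stats` list: `mean_bound`, `std_bound` (per-frame
#'   bound-ion count), `ligands_per_ion` (named means for
#'   bidentate/direct/total), `motif_histogram` (tibble of mean ion count
#'   per category), `n_frames`, `n_ions`.
#' @export
binding_statistics <- function(assignments) {
  stopifnot(nrow(assignments) >= 1)
  per_frame <- dplyr::summarise(dplyr::group_by(assignments, .data$frame),
                                n_bound = sum(.data$bound), .groups = "drop")
  cats <- dplyr::count(assignments, .data$frame, .data$category)
  all_cats <- unique(assignments$category)
  hist <- tidyr::complete(cats, frame = unique(assignments$frame),
                          category = all_cats, fill = list(n = 0L)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(mean_ions = mean(.data$n), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_ions))
  lig <- c(
    bidentate = mean(assignments$n_b[assignments$n_b >= 1]),
    direct = mean(assignments$n_direct[assignments$n_direct >= 1]),
    total = mean(assignments$n_total[assignments$n_total >= 1]))
  structure(list(
    mean_bound = mean(per_frame$n_bound),
    std_bound = stats::sd(per_frame$n_bound),
    ligands_per_ion = lig,
    motif_histogram = hist,
    n_frames = nrow(per_frame),
    n_ions = length(unique(assignments$id))),
    class = "binding_stats")
}

#' @export
print.binding_stats <- function(x, ...) {
  cat(sprintf("<binding_stats> %.2f +/- %.2f ions bound (%d frames, %d ions)\n",
              x$mean_bound, ifelse(is.na(x$std_bound), 0, x$std_bound),
              x$n_frames, x$n_ions))
  cat(sprintf("ligands per bound ion: bidentate %.2f, direct %.2f, total %.2f\n",
              x$ligands_per_ion["bidentate"], x$ligands_per_ion["direct"],
              x$ligands_per_ion["total"]))
  print(x$motif_histogram)
  invisible(x)
}

#' Tidy binding statistics: the motif histogram
#' @param x A `binding_stats` object.
#' @param ... Unused.
#' @return The motif histogram tibble (`category`, `mean_ions`).
#' @export
tidy.binding_stats <- function(x, ...) x$motif_histogram

#' One-row summary of binding statistics
#' @param x A `binding_stats` object.
#' @param ... Unused.
#' @return One-row tibble with the headline statistics.
#' @export
glance.binding_stats <- function(x, ...) {
  tibble::tibble(mean_bound = x$mean_bound, std_bound = x$std_bound,
                 ligands_bidentate = unname(x$ligands_per_ion["bidentate"]),
                 ligands_direct = unname(x$ligands_per_ion["direct"]),
                 ligands_total = unname(x$ligands_per_ion["total"]),
                 n_frames = x$n_frames, n_ions = x$n_ions)
}

#' Bound-ion count per frame with a convergence verdict
#'
#' Produces the bound-count time series and flags convergence when, within
#' the final `window` frames, the two half-window means differ by less than
#' `tol` ions (the reference simulations' observed run-to-run standard
#' deviation of about one ion motivates the default).
#'
#' @param x A motif-assignment tibble, an [ion_trajectory()], or a
#'   [generate_labeled_trajectory()] result.
#' @param window Number of final frames examined (must be < series length).
#' @param tol Convergence tolerance in ions (default 1).
#' @inheritParams classify_frame
#' @return A `bound_series` tibble (`frame`, `time`, `n_bound`) with
#'   attributes `converged`, `half_mean_diff`, `window`.
#' @export
bound_count_series <- function(x, window, tol = 1, headgroups = NULL,
                               cutoffs = NULL) {
  assignments <- if (is.data.frame(x) && "bound" %in% names(x)) x else
    classify_trajectory(x, headgroups, cutoffs)
  series <- dplyr::summarise(dplyr::group_by(assignments, .data$frame),
                             n_bound = sum(.data$bound), .groups = "drop")
  series$time <- series$frame
  nfr <- nrow(series)
  if (window >= nfr) stop("window must be shorter than the series")
  tail_part <- series$n_bound[(nfr - window + 1):nfr]
  h <- floor(window / 2)
  diff_means <- abs(mean(tail_part[1:h]) -
                    mean(tail_part[(window - h + 1):window]))
  structure(tibble::new_tibble(series[, c("frame", "time", "n_bound")],
                               class = "bound_series"),
            converged = diff_means < tol, half_mean_diff = diff_means,
            window = window, tol = tol)
}
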
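#' Simulation box for a periodic slab geometry
#'
#' The box is periodic in x and y (minimum-image convention) and bounded in z
#' by reflecting walls at 0 and `lz` — the reduced-geometry stand-in for a
#' solvated monolayer slab.
#'
#' @param lx,ly,lz Box edge lengths, nm (> 0). Defaults mirror the
#'   60.6 x 52.0 x 70.0 Angstrom monolayer solvation box.
#' @return A `sim_box` list with `lx`, `ly`, `lz` and a `periodic` flag
#'   vector.
#' @examples
#' sim_box()
#' sim_box(4, 4, 8)
#' @export
sim_box <- function(lx = 6.06, ly = 5.20, lz = 7.00) {
  stopifnot(lx > 0, ly > 0, lz > 0)
  structure(list(lx = lx, ly = ly, lz = lz,
                 periodic = c(x = TRUE, y = TRUE, z = FALSE)),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("<sim_box> %.3f x %.3f x %.3f nm (periodic x,y; z walls)\n",
              x$lx, x$ly, x$lz))
  invisible(x)
}

#' Assemble a trajectory object
#'
#' A trajectory is a time-ordered set of coordinate frames for labeled
#' particles in a [sim_box()]. Internally it is a long tibble — one row per
#' particle per frame — which [tidy.ion_trajectory()] exposes directly.
#'
#' @param frames Tibble with columns `frame` (0-based integer), `time` (ps),
#'   `id` (particle index), `species` (label), `x`, `y`, `z` (nm).
#' @param box A [sim_box()].
#' @param dt_out Output interval between frames, ps.
#' @param provenance Named list recording how the trajectory was produced
#'   (config, seed); free-form.
#' @return An `ion_trajectory` object.
#' @export
ion_trajectory <- function(frames, box, dt_out = NA_real_, provenance = list()) {
  req <- c("frame", "time", "id", "species", "x", "y", "z")
  stopifnot(is.data.frame(frames), all(req %in% names(frames)),
            inherits(box, "sim_box"))
  if (nrow(frames) == 0) stop("a trajectory needs at least one frame")
  counts <- table(frames$frame)
  if (length(unique(counts)) != 1) {
    stop("particle count must be constant across frames")
  }
  structure(list(frames = tibble::as_tibble(frames), box = box,
                 dt_out = dt_out, provenance = provenance),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat(sprintf("<ion_trajectory> %d frame%s x %d particles (dt_out = %s ps)\n",
              nf, if (nf == 1) "" else "s", n_particles(x),
              format(x$dt_out)))
  print(x$box)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `ion_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(unique(traj$frames$frame))

#' Number of particles per frame
#' @param traj An `ion_trajectory`.
#' @return Integer particle count.
#' @export
n_particles <- function(traj) sum(traj$frames$frame == traj$frames$frame[1])

#' Extract one frame of a trajectory as a tibble
#' @param traj An `ion_trajectory`.
#' @param i Frame index (0-based, matching the `frame` column).
#' @return Tibble of particles in frame `i`.
#' @export
get_frame <- function(traj, i) {
  out <- dplyr::filter(traj$frames, .data$frame == i)
  if (nrow(out) == 0) stop("no frame with index ", i)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into its long coordinate table
#'
#' @param x An `ion_trajectory`.
#' @param ... Unused.
#' @return The `frames` tibble (one row per particle per frame).
#' @export
tidy.ion_trajectory <- function(x, ...) x$frames

#' Minimum-image displacement components in a periodic slab
#'
#' Wraps dx, dy into `[-L/2, L/2)`; z is untouched (bounded direction).
#'
#' @param d Numeric vector of raw displacements.
#' @param L Box length for the periodic direction.
#' @return Wrapped displacements.
#' @keywords internal
min_image <- function(d, L) d - L * round(d / L)

#' Pairwise minimum-image distances between two coordinate sets
#'
#' @param a,b Matrices (n x 3), columns x,y,z in nm.
#' @param box A [sim_box()]; x,y periodic, z direct.
#' @return An `nrow(a)` x `nrow(b)` distance matrix, nm.
#' @export
slab_distances <- function(a, b, box) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box$lx)
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box$ly)
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}
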
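#' Idealized deprotonated-thiol monolayer geometry
#'
#' The monolayer is modeled as carboxylate headgroups anchored on the
#' (sqrt3 x sqrt3)R30-degree triangular lattice that alkanethiols adopt on
#' Au(111). The default nearest-neighbor spacing of 0.497 nm is sqrt(3) times
#' the Au(111) lattice constant — the standard value for that adlattice; the
#' alkyl chains are not represented, only the charged headgroup sites that
#' act as ion-binding targets.
#'
#' @name monolayer
NULL

#' Specify a triangular headgroup lattice
#'
#' @param nx,ny Array dimensions (columns, rows); the reference monolayer is
#'   a 14 x 11 array of 154 ligands.
#' @param spacing Nearest-neighbor distance, nm.
#' @param origin Length-2 numeric xy offset of the first site, nm.
#' @return A `lattice_spec` list.
#' @examples
#' lattice_spec(14, 11)
#' @export
lattice_spec <- function(nx = 14, ny = 11, spacing = 0.497, origin = c(0, 0)) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0, length(origin) == 2)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 spacing = spacing, origin = as.numeric(origin)),
            class = "lattice_spec")
}

#' Build the sulfur-site positions of a triangular lattice
#'
#' Sites are laid out row-major (row `iy`, then column `ix`) on a triangular
#' (hexagonal close-packed in 2D) lattice: odd rows are shifted by half a
#' spacing, rows are `spacing * sqrt(3)/2` apart, so every interior site has
#' six neighbors at exactly `spacing`.
#'
#' @param spec A [lattice_spec()].
#' @return Tibble with columns `site` (1-based index), `ix`, `iy` (0-based
#'   grid coordinates) and `x`, `y` (nm).
#' @examples
#' nrow(build_lattice(lattice_spec(14, 11)))  # 154
#' @export
build_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  grid <- tidyr::expand_grid(iy = seq_len(spec$ny) - 1L,
                             ix = seq_len(spec$nx) - 1L)
  dplyr::mutate(grid,
    site = dplyr::row_number(),
    x = spec$origin[1] + (.data$ix + (.data$iy %% 2) / 2) * spec$spacing,
    y = spec$origin[2] + .data$iy * spec$spacing * sqrt(3) / 2,
    .before = 1) |>
    dplyr::select("site", "ix", "iy", "x", "y")
}

#' Place rigid carboxylate headgroups on lattice sites
#'
#' Each ligand contributes a carboxylate carbon at the site position raised
#' to `height`, and two oxygens placed symmetrically about the carbon in the
#' xy-plane, separated by `oo_distance` at a random azimuth. Each deprotonated
#' ligand carries a net charge of -1 e, split by `charge_o` over the two
#' oxygens (carbon carries the remainder).
#'
#' @param lattice Tibble from [build_lattice()].
#' @param height z position of the carboxylate carbons, nm.
#' @param oo_distance Intramolecular O-O distance, nm; default 0.22 (the
#'   2.2 Angstrom carboxylate O-O separation).
#' @param charge_o Partial charge per oxygen, e; default -0.5 so C carries 0.
#' @param seed Integer seed for the azimuth draw; same seed, same geometry.
#' @return Tibble with `ligand_id`, `atom` ("C", "O1", "O2"), `x`, `y`, `z`
#'   (nm) and `charge` (e).
#' @examples
#' hg <- build_headgroups(build_lattice(lattice_spec(2, 2)), seed = 1)
#' @export
build_headgroups <- function(lattice, height = 1.0, oo_distance = 0.22,
                             charge_o = -0.5, seed = 1L) {
  stopifnot(oo_distance > 0)
  old <- .Random.seed_exists()
  set.seed(seed)
  az <- stats::runif(nrow(lattice), 0, 2 * pi)
  .restore_seed(old)
  charge_c <- -1 - 2 * charge_o
  half <- oo_distance / 2
  purrr::pmap_dfr(
    list(lattice$site, lattice$x, lattice$y, az),
    function(id, x, y, a) {
      tibble::tibble(
        ligand_id = id,
        atom = c("C", "O1", "O2"),
        x = c(x, x + half * cos(a), x - half * cos(a)),
        y = c(y, y + half * sin(a), y - half * sin(a)),
        z = height,
        charge = c(charge_c, charge_o, charge_o))
    })
}

#' @keywords internal
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Carboxylate-carbon coordinates of a headgroup table
#'
#' @param headgroups Tibble from [build_headgroups()].
#' @return Tibble with `ligand_id`, `x`, `y`, `z` for the C atoms only.
#' @export
headgroup_carbons <- function(headgroups) {
  dplyr::filter(headgroups, .data$atom == "C") |>
    dplyr::select("ligand_id", "x", "y", "z")
}

#' Default counterion composition of the reference scenario
#'
#' The reference simulation composition: 100 divalent cations, 54 Na+, and
#' 100 Cl- (divalent chloride salt) or 60 Cl- (mixed-salt variant), chosen so
#' the total system including the 154 carboxylates (-154 e) is neutral for
#' the 100-Cl- case with +2 cations.
#'
#' @param divalent Species label of the divalent cation.
#' @param n_divalent,n_na,n_cl Ion counts.
#' @return Tibble with `species` and `n`.
#' @export
scenario_composition <- function(divalent = "Ca2+", n_divalent = 100,
                                 n_na = 54, n_cl = 100) {
  tibble::tibble(species = c(divalent, "Na+", "Cl-"),
                 n = c(n_divalent, n_na, n_cl))
}
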
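#' Nonbonded ion force-field parameters and pairwise interactions
#'
#' The ion-monolayer energetics use a nonbonded potential: a 12-6
#' Lennard-Jones term for van der Waals interactions plus a Coulomb term,
#'
#'   U(r) = eps_ij \[ (Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6 \] + kC f Q_i Q_j / r
#'
#' with eps_ij the well depth (kJ/mol), Rmin_ij the position of the LJ
#' minimum (nm), Q the point charges (e) and f an optional
#' electronic-continuum-correction (ECC) charge-scaling factor.
#' sigma_ij = Rmin_ij / 2^(1/6).
#'
#' @name forcefield
NULL

#' Build a table of per-species ion parameters
#'
#' @param species Character vector of species labels, e.g. "Mg2+", "Cl-".
#' @param q Point charges in elementary-charge units e.
#' @param epsilon Lennard-Jones well depths, kJ/mol (>= 0).
#' @param rmin_half R_min/2 in nm (> 0); sigma = 2 * rmin_half / 2^(1/6).
#' @return A tibble with columns `species`, `q`, `epsilon`, `rmin_half`.
#' @examples
#' ion_params("Mg2+", q = 2, epsilon = 0.0427, rmin_half = 0.136)
#' @export
ion_params <- function(species, q, epsilon, rmin_half) {
  stopifnot(length(species) == length(q),
            length(q) == length(epsilon),
            length(epsilon) == length(rmin_half))
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  if (any(rmin_half <= 0)) stop("rmin_half must be > 0")
  if (any(abs(q) > 2 + 1e-12)) stop("|q| must be <= 2 e for shipped species")
  tibble::tibble(species = as.character(species),
                 q = as.numeric(q),
                 epsilon = as.numeric(epsilon),
                 rmin_half = as.numeric(rmin_half))
}

#' Construct a named force-field set
#'
#' A force-field set bundles per-species ion parameters with the ECC charge
#' scaling factor and the pairwise combining rule in force when two species
#' interact.
#'
#' @param name Set label, e.g. `"li_tip3p"`.
#' @param params Tibble from [ion_params()] (rows may be concatenated with
#'   `dplyr::bind_rows()`).
#' @param ecc_factor ECC scaling factor f in (0, 1]; `1` disables scaling.
#'   f = 1/sqrt(eps_el) with eps_el the electronic dielectric constant of the
#'   solvent; the conventional aqueous value is f = 0.80.
#' @param water_model_tag Provenance string naming the water model the set was
#'   parametrized for.
#' @param combining_rule Currently `"lorentz-berthelot"` (arithmetic mean of
#'   R_min, geometric mean of epsilon).
#' @param provenance_notes Free text recording the experimental targets the
#'   set was parametrized against.
#' @return An object of class `forcefield_set`.
#' @seealso [load_forcefield()] for the shipped parameter tables.
#' @export
forcefield_set <- function(name, params, ecc_factor = 1,
                           water_model_tag = "",
                           combining_rule = "lorentz-berthelot",
                           provenance_notes = "") {
  stopifnot(is.data.frame(params),
            all(c("species", "q", "epsilon", "rmin_half") %in% names(params)))
  if (!(ecc_factor > 0 && ecc_factor <= 1)) {
    stop("ecc_factor must lie in (0, 1]")
  }
  combining_rule <- match.arg(combining_rule, "lorentz-berthelot")
  structure(
    list(name = name,
         water_model_tag = water_model_tag,
         params = tibble::as_tibble(params),
         ecc_factor = ecc_factor,
         combining_rule = combining_rule,
         provenance_notes = provenance_notes),
    class = "forcefield_set")
}

#' @export
print.forcefield_set <- function(x, ...) {
  cat("<forcefield_set>", x$name,
      sprintf("(water model: %s, ECC f = %g, %s combining)\n",
              x$water_model_tag, x$ecc_factor, x$combining_rule))
  print(x$params)
  invisible(x)
}

#' List the parameter sets shipped with the package
#'
#' @return Character vector of set names accepted by [load_forcefield()].
#' @export
list_forcefields <- function() {
  files <- list.files(system.file("extdata", package = "ionlayer"),
                      pattern = "^ff_.*\\.yaml$")
  sub("^ff_(.*)\\.yaml$", "\\1", files)
}

#' Load a force-field set from the shipped tables or a YAML file
#'
#' Shipped sets: `"li_tip3p"` (12-6 parameters targeting hydration free
#' energies and coordination numbers with TIP3P water, all four alkaline-earth
#' ions plus Na+/Cl-), `"mamatkulov"` (targets additionally activity-
#' coefficient derivatives and water residence times), `"mendes"` (ECC-scaled
#' set, Mg2+ and Ca2+ only, f = 0.80). The numeric values are transcriptions
#' from the cited primary literature recorded in each file's
#' `provenance_notes`; supply your own YAML table to override.
#'
#' @param name A shipped set name (see [list_forcefields()]) or a path to a
#'   YAML file with fields `name`, `water_model`, `ecc_factor`, `ions:` a list
#'   of `{species, q, epsilon_kJmol, rmin_half_nm}`.
#' @param ecc Apply ECC charge scaling? If `NULL` (default) the set's own
#'   `ecc_factor` is kept; `FALSE` forces f = 1; `TRUE` keeps or sets
#'   `ecc_f`.
#' @param ecc_f Scaling factor used when `ecc = TRUE`; default 0.80.
#' @return A [forcefield_set()].
#' @examples
#' ff <- load_forcefield("li_tip3p")
#' ff$params
#' @export
load_forcefield <- function(name, ecc = NULL, ecc_f = 0.80) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("ff_", name, ".yaml"), package = "ionlayer")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown force field '", name, "'; shipped sets: ",
         paste(list_forcefields(), collapse = ", "))
  }
  y <- yaml::read_yaml(path)
  ions <- purrr::map_dfr(y$ions, function(i) {
    ion_params(i$species, i$q, i$epsilon_kJmol, i$rmin_half_nm)
  })
  f <- if (is.null(y$ecc_factor)) 1 else y$ecc_factor
  if (isFALSE(ecc)) f <- 1
  if (isTRUE(ecc)) f <- ecc_f
  forcefield_set(name = y$name, params = ions, ecc_factor = f,
                 water_model_tag = if (is.null(y$water_model)) "" else y$water_model,
                 combining_rule = if (is.null(y$combining_rule))
                   "lorentz-berthelot" else y$combining_rule,
                 provenance_notes = if (is.null(y$provenance_notes)) ""
                   else y$provenance_notes)
}

#' Serialize a force-field set to YAML
#'
#' Inverse of [load_forcefield()]: the written file reloads to an identical
#' set (round-trip tested).
#'
#' @param ff A [forcefield_set()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "forcefield_set"))
  y <- list(
    name = ff$name,
    water_model = ff$water_model_tag,
    ecc_factor = ff$ecc_factor,
    combining_rule = ff$combining_rule,
    provenance_notes = ff$provenance_notes,
    ions = purrr::pmap(ff$params, function(species, q, epsilon, rmin_half) {
      list(species = species, q = q, epsilon_kJmol = epsilon,
           rmin_half_nm = rmin_half)
    }))
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' Apply electronic-continuum-correction charge scaling
#'
#' ECC treats the electronic polarizability of the solvent as a mean field by
#' scaling ionic charges by f = 1/sqrt(eps_el), where eps_el is the
#' electronic (high-frequency) dielectric constant. For water f = 0.80 is the
#' conventional value.
#'
#' @param q Charge(s), e.
#' @param f Scaling factor in (0, 1].
#' @return `f * q`.
#' @examples
#' apply_ecc(2, 0.80)          # +1.6 e
#' 1 / sqrt(1.5625)            # the eps_el that yields f = 0.80
#' @export
apply_ecc <- function(q, f) {
  if (!(is.numeric(f) && length(f) == 1 && f > 0 && f <= 1)) {
    stop("ECC factor f must be a scalar in (0, 1]")
  }
  f * q
}

#' Combine two species' parameters into one pair interaction
#'
#' Lorentz-Berthelot combining: geometric mean of the well depths, arithmetic
#' mean of the R_min values. The charge product is stored pre-scaled as
#' `qq_scaled = f * Q_a * Q_b` (see Details for how this interacts with ECC).
#'
#' @details When ECC is enabled for both partners (e.g. two ions), scale each
#' charge with [apply_ecc()] before calling and leave `f = 1`, which yields
#' the f^2 energy scaling of full ECC; passing `f` here scales the *product*
#' once, the convention used when only the ion (not the monolayer) charge is
#' scaled.
#'
#' @param a,b Single-row tibbles from [ion_params()] (or any list with
#'   `q`, `epsilon`, `rmin_half`).
#' @param f Charge-product scale factor in (0, 1]; default 1.
#' @return A `pair_interaction` list with `eps_ij` (kJ/mol), `rmin_ij` (nm),
#'   `qq_scaled` (e^2) and `coulomb_constant` (kJ mol^-1 nm e^-2).
#' @examples
#' mg <- ion_params("Mg2+", 2, 0.0427, 0.136)
#' cl <- ion_params("Cl-", -1, 0.6276, 0.227)
#' make_pair_params(mg, cl)
#' @export
make_pair_params <- function(a, b, f = 1) {
  eps_ij <- sqrt(a$epsilon * b$epsilon)
  rmin_ij <- (2 * a$rmin_half + 2 * b$rmin_half) / 2
  if (!is.finite(rmin_ij) || rmin_ij <= 0) stop("combined R_min must be > 0")
  if (!(f > 0 && f <= 1)) stop("scale factor f must lie in (0, 1]")
  structure(
    list(eps_ij = eps_ij, rmin_ij = rmin_ij,
         qq_scaled = f * a$q * b$q,
         coulomb_constant = .kC),
    class = "pair_interaction")
}

#' Nonbonded pair energy
#'
#' Evaluates the 12-6 Lennard-Jones plus Coulomb potential at separation `r`.
#'
#' @param r Separation(s), nm (> 0). Vectorized.
#' @param p A `pair_interaction` from [make_pair_params()].
#' @return Energy in kJ/mol.
#' @examples
#' p <- make_pair_params(ion_params("A", 0, 0.5, 0.15),
#'                       ion_params("B", 0, 0.5, 0.15))
#' pair_energy(p$rmin_ij, p)  # -eps_ij at the LJ minimum
#' @export
pair_energy <- function(r, p) {
  if (any(r <= 0)) stop("separation r must be > 0")
  sr6 <- (p$rmin_ij / r)^6
  p$eps_ij * (sr6^2 - 2 * sr6) + p$coulomb_constant * p$qq_scaled / r
}

#' Nonbonded pair force (radial component)
#'
#' Analytic -dU/dr of [pair_energy()]. Positive values are repulsive (force
#' directed along increasing separation).
#'
#' @inheritParams pair_energy
#' @return Force in kJ mol^-1 nm^-1.
#' @export
pair_force <- function(r, p) {
  if (any(r <= 0)) stop("separation r must be > 0")
  sr6 <- (p$rmin_ij / r)^6
  12 * p$eps_ij * (sr6^2 - sr6) / r + p$coulomb_constant * p$qq_scaled / r^2
}
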
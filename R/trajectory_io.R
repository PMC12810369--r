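#' Coordinate and series file I/O
#'
#' Hand-rolled readers/writers for the three plain-text formats the pipeline
#' touches: fixed-column GRO coordinates (nm), XYZ coordinates (Angstrom by
#' convention, converted to nm on read), and two-column XVG-dialect series
#' ('#' and '@' lines are comments). All pairs are mutually inverse up to
#' format precision; parsers never silently drop rows.
#'
#' @name trajectory_io
NULL

#' Read a multi-frame GRO or XYZ coordinate file
#'
#' @param path File path.
#' @param format `"gro"` or `"xyz"` (default: from the file extension).
#' @param box A [sim_box()] for XYZ input (XYZ carries no box); for GRO the
#'   box line of the first frame is used.
#' @param xyz_unit Unit of XYZ coordinates: `"angstrom"` (default, converted
#'   to nm) or `"nm"`.
#' @return An [ion_trajectory()]. Times are taken from `t=` tags in GRO
#'   title lines when present, else the frame index.
#' @export
read_coordinates <- function(path, format = NULL, box = NULL,
                             xyz_unit = c("angstrom", "nm")) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "xyz"))
  lines <- readLines(path)
  if (format == "gro") .read_gro(lines, path) else
    .read_xyz(lines, path, box, match.arg(xyz_unit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_gro <- function(lines, path) {
  frames <- list()
  i <- 1L
  fidx <- 0L
  box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || i + 1L + natoms + 1L > length(lines)) {
      stop(sprintf("truncated GRO frame %d in %s", fidx, path))
    }
    t_match <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(t_match)) {
      as.numeric(sub("t=\\s*", "", t_match))
    } else fidx
    atom_lines <- lines[(i + 2L):(i + 1L + natoms)]
    species <- trimws(substr(atom_lines, 11L, 15L))
    if (any(!nzchar(species))) {
      stop(sprintf("empty atom label(s) in GRO frame %d of %s", fidx, path))
    }
    xyz <- vapply(atom_lines, function(l) {
      c(as.numeric(substr(l, 21L, 28L)),
        as.numeric(substr(l, 29L, 36L)),
        as.numeric(substr(l, 37L, 44L)))
    }, numeric(3), USE.NAMES = FALSE)
    if (anyNA(xyz)) {
      stop(sprintf("unparseable coordinates in GRO frame %d of %s",
                   fidx, path))
    }
    bl <- suppressWarnings(as.numeric(strsplit(trimws(
      lines[i + 2L + natoms]), "\\s+")[[1]]))
    if (length(bl) < 3 || anyNA(bl[1:3])) {
      stop(sprintf("bad box line in GRO frame %d of %s", fidx, path))
    }
    if (is.null(box)) box <- sim_box(bl[1], bl[2], bl[3])
    frames[[fidx + 1L]] <- tibble::tibble(
      frame = fidx, time = time, id = seq_len(natoms), species = species,
      x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
    fidx <- fidx + 1L
    i <- i + 2L + natoms + 1L
  }
  if (fidx == 0L) stop("no frames found in ", path)
  message(sprintf("read %d frame(s) x %d atoms from %s", fidx,
                  nrow(frames[[1]]), path))
  ion_trajectory(dplyr::bind_rows(frames), box,
                 provenance = list(source = path, format = "gro"))
}

.read_xyz <- function(lines, path, box, unit) {
  if (is.null(box)) stop("XYZ carries no box information; supply `box`")
  scale <- if (unit == "angstrom") 0.1 else 1
  frames <- list()
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(natoms) || i + 1L + natoms > length(lines)) {
      stop(sprintf("truncated XYZ frame %d in %s", fidx, path))
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + natoms)]), "\\s+")
    bad <- which(lengths(rows) < 4L)
    if (length(bad)) {
      stop(sprintf("malformed XYZ atom line %d in frame %d of %s",
                   bad[1], fidx, path))
    }
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (anyNA(m)) {
      stop(sprintf("non-numeric coordinates in XYZ frame %d of %s",
                   fidx, path))
    }
    frames[[fidx + 1L]] <- tibble::tibble(
      frame = fidx, time = fidx, id = seq_len(natoms),
      species = vapply(rows, `[`, "", 1L),
      x = m[, 1] * scale, y = m[, 2] * scale, z = m[, 3] * scale)
    fidx <- fidx + 1L
    i <- i + 2L + natoms
  }
  if (fidx == 0L) stop("no frames found in ", path)
  message(sprintf("read %d frame(s) x %d atoms from %s (%s -> nm)",
                  fidx, nrow(frames[[1]]), path, unit))
  ion_trajectory(dplyr::bind_rows(frames), box,
                 provenance = list(source = path, format = "xyz"))
}

#' Write a trajectory to a GRO or XYZ file
#'
#' GRO uses the standard fixed-column layout (coordinates in nm, %8.3f, so
#' round-trip precision is 10^-3 nm); XYZ is written in Angstrom. Velocities
#' are neither read nor written. Species order within each frame is
#' preserved.
#'
#' @param traj An [ion_trajectory()].
#' @param path Output path.
#' @param format `"gro"` or `"xyz"` (default: from the extension).
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(traj, path, format = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (n_frames(traj) == 0) stop("refusing to write a zero-frame trajectory")
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("gro", "xyz"))
  con <- file(path, "w")
  on.exit(close(con))
  frames <- split(traj$frames, traj$frames$frame)
  for (fr in frames) {
    if (format == "gro") {
      writeLines(sprintf("ionlayer frame t= %.6f ps (0-based frames)",
                         fr$time[1]), con)
      writeLines(sprintf("%5d", nrow(fr)), con)
      resname <- substr(gsub("[+-]", "", fr$species), 1, 5)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         fr$id %% 100000L, resname,
                         substr(fr$species, 1, 5), fr$id %% 100000L,
                         fr$x, fr$y, fr$z), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f",
                         traj$box$lx, traj$box$ly, traj$box$lz), con)
    } else {
      writeLines(sprintf("%d", nrow(fr)), con)
      writeLines(sprintf("ionlayer frame t= %.6f ps (Angstrom)", fr$time[1]),
                 con)
      writeLines(sprintf("%-5s %12.6f %12.6f %12.6f", fr$species,
                         fr$x * 10, fr$y * 10, fr$z * 10), con)
    }
  }
  invisible(path)
}

#' Read a two-column XVG-dialect series
#'
#' Lines starting with `#` or `@` are header comments and are captured in
#' the `metadata` attribute; the remainder must be rows of two numbers.
#'
#' @param path File path.
#' @return A `series_record` tibble with columns `x`, `y`; attributes
#'   `metadata` (comment lines) and `source`.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_comment <- grepl("^\\s*[#@]", lines)
  is_blank <- !nzchar(trimws(lines))
  data_idx <- which(!is_comment & !is_blank)
  if (length(data_idx) == 0) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines[data_idx]), "\\s+")
  for (k in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[k]][1:2]))
    if (length(parts[[k]]) < 2 || anyNA(v)) {
      stop(sprintf("non-numeric series row at line %d of %s",
                   data_idx[k], path))
    }
  }
  m <- t(vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (is.unsorted(m[, 1])) {
    warning("series abscissa is not monotone non-decreasing in ", path)
  }
  message(sprintf("read %d series row(s) from %s", nrow(m), path))
  structure(tibble::new_tibble(list(x = m[, 1], y = m[, 2]),
                               class = "series_record"),
            metadata = lines[is_comment], source = path)
}

#' Write a two-column series in XVG dialect
#'
#' @param x,y Numeric vectors of equal length, or a data frame with columns
#'   `x`, `y` passed as `x` (then `y` is ignored).
#' @param path Output path.
#' @param metadata Character vector of comment lines (written with a
#'   leading `#` or `@` preserved, added if missing).
#' @return `path`, invisibly.
#' @export
write_series <- function(x, y = NULL, path, metadata = character()) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  stopifnot(length(x) == length(y))
  meta <- ifelse(grepl("^[#@]", metadata), metadata, paste("#", metadata))
  writeLines(c(meta,
               "# columns: x (time ps or distance nm), y (force or count)",
               sprintf("%.10g %.10g", x, y)), path)
  invisible(path)
}
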
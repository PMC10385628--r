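# Regular 3-D grids for scalar and vector fields, plus volumetric writers.

#' Define a regular 3-D grid
#'
#' @param origin numeric length-3, position of the first voxel center
#'   (angstroms).
#' @param spacing voxel spacing per axis (scalar or length 3, angstroms, > 0).
#' @param dims integer length-3 voxel counts (each >= 2).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  dims <- as.integer(rep(dims, length.out = 3))
  if (any(spacing <= 0)) stop_cz("grid spacing must be > 0")
  if (any(dims < 2)) stop_cz("grid dims must be >= 2 per axis")
  structure(list(origin = as.numeric(origin), spacing = spacing, dims = dims),
            class = "grid_spec")
}

#' Grid covering one or more models with a margin
#'
#' @param models a `mol_model` or list of them.
#' @param spacing voxel spacing, angstroms.
#' @param margin extension beyond the joint bounding box, angstroms.
#' @param center_on_origin if `TRUE`, symmetrize the grid extent about the
#'   coordinate origin (useful for symmetry fixtures).
#' @return a `grid_spec`.
#' @export
make_grid_spec <- function(models, spacing = 0.2, margin = 4,
                           center_on_origin = FALSE) {
  if (inherits(models, "mol_model")) models <- list(models)
  xyz <- do.call(rbind, lapply(models, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  if (center_on_origin) {
    half <- pmax(abs(lo), abs(hi))
    lo <- -half; hi <- half
  }
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(lo, spacing, dims)
}

grid_axes <- function(spec) {
  lapply(1:3, function(k)
    spec$origin[k] + spec$spacing[k] * (seq_len(spec$dims[k]) - 1))
}

#' Voxel-center coordinates of a grid
#' @param spec a `grid_spec`.
#' @return numeric (prod(dims)) x 3 matrix in array (x-fastest) order.
#' @export
voxel_centers <- function(spec) {
  ax <- grid_axes(spec)
  cbind(rep(ax[[1]], times = spec$dims[2] * spec$dims[3]),
        rep(rep(ax[[2]], each = spec$dims[1]), times = spec$dims[3]),
        rep(ax[[3]], each = spec$dims[1] * spec$dims[2]))
}

#' Scalar field on a grid
#' @param spec a `grid_spec`.
#' @param values numeric array of dimension `spec$dims` (units context
#'   dependent, e.g. e per cubic angstrom for electron density).
#' @param unit optional unit string carried as metadata.
#' @return object of class `scalar_grid`.
#' @export
scalar_grid <- function(spec, values, unit = NULL) {
  if (!identical(dim(values), NULL) && !identical(as.integer(dim(values)), spec$dims))
    stop_cz("values dimension does not match grid dims")
  structure(list(spec = spec, values = array(values, spec$dims), unit = unit),
            class = "scalar_grid")
}

#' Vector field on a grid
#' @param spec a `grid_spec`.
#' @param values numeric array of dimension `c(spec$dims, 3)`.
#' @param unit optional unit string.
#' @return object of class `vector_grid`.
#' @export
vector_grid <- function(spec, values, unit = NULL) {
  structure(list(spec = spec, values = array(values, c(spec$dims, 3)),
                 unit = unit), class = "vector_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("<scalar_grid> %s  dims %s  spacing %s A  range [%g, %g]\n",
              x$unit %||% "", paste(x$spec$dims, collapse = "x"),
              paste(signif(x$spec$spacing, 3), collapse = ","),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Write a scalar grid in Gaussian cube format
#'
#' Header lengths are emitted in Bohr with positive voxel counts, as the cube
#' convention requires; the data values themselves are written unchanged (for
#' electron density that means e per cubic angstrom, stated in the title
#' line). Data loop runs z fastest, x slowest.
#'
#' @param grid a `scalar_grid`.
#' @param path output path.
#' @param model optional `mol_model` whose atoms are listed in the header.
#' @param comment title line for the header.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, model = NULL,
                       comment = "contactzones scalar field") {
  spec <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  unit <- grid$unit %||% "arbitrary"
  writeLines(c(comment, paste("values in", unit,
                              "(header lengths in Bohr)")), con)
  natom <- if (is.null(model)) 0L else n_atoms(model)
  o <- spec$origin * BOHR_PER_ANGSTROM
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", natom, o[1], o[2], o[3]), con)
  for (k in 1:3) {
    v <- c(0, 0, 0)
    v[k] <- spec$spacing[k] * BOHR_PER_ANGSTROM
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", spec$dims[k], v[1], v[2], v[3]),
               con)
  }
  if (!is.null(model)) {
    zmap <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)
    a <- model$atoms
    z <- zmap[a$element]; z[is.na(z)] <- 0
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", z, z,
                       a$x * BOHR_PER_ANGSTROM, a$y * BOHR_PER_ANGSTROM,
                       a$z * BOHR_PER_ANGSTROM), con)
  }
  v <- grid$values
  for (i in seq_len(spec$dims[1])) for (j in seq_len(spec$dims[2])) {
    row <- v[i, j, ]
    for (s in seq(1, length(row), by = 6)) {
      writeLines(paste(sprintf("%13.5e", row[s:min(s + 5, length(row))]),
                       collapse = ""), con)
    }
  }
  invisible(path)
}

#' Write a scalar grid as a CCP4/MRC mode-2 map
#'
#' Little-endian binary, axis order X=columns, Y=rows, Z=sections; the unit
#' cell is set to the orthogonal grid extent. Origin is carried in the
#' ORIGIN header words (angstroms).
#'
#' @param grid a `scalar_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(grid, path) {
  spec <- grid$spec
  con <- file(path, "wb")
  on.exit(close(con))
  d <- spec$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                                   # NC NR NS
  wi(2)                                   # MODE float32
  wi(c(0, 0, 0))                          # start
  wi(d)                                   # intervals
  wf(spec$spacing * d)                    # cell lengths (A)
  wf(c(90, 90, 90))                       # cell angles
  wi(c(1, 2, 3))                          # axis order
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))
  wi(c(1, 0))                             # ISPG, NSYMBT
  wi(rep(0, 25))                          # extra
  wf(spec$origin)                         # ORIGIN (words 50-52)
  writeChar("MAP ", con, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.vector(v)))
  wi(0)                                   # NLABL
  writeBin(raw(800), con)
  wf(as.vector(v))                        # x fastest: matches array order
  invisible(path)
}
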
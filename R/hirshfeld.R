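# Triangulated Hirshfeld interface between two molecular moieties.
#
# The w = 0.5 isosurface of the Hirshfeld weight field is extracted by
# marching tetrahedra (each grid cube split into six tetrahedra sharing a
# body diagonal; crossings linearly interpolated along tet edges). The
# tetrahedral split has no ambiguous sign cases, so the mesh is watertight on
# the grid without a case table.

# cube corner offsets, order v1..v8
MT_OFFSETS <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
                    c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
# six tetrahedra sharing the v1-v7 diagonal
MT_TETS <- rbind(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
                 c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))

# triangles cut from one tetrahedron; p: 4 x 3 positions, v: signed field
tet_triangles <- function(p, v) {
  neg <- v < 0
  n <- sum(neg)
  if (n == 0L || n == 4L) return(NULL)
  ip <- function(a, b) p[a, ] + (v[a] / (v[a] - v[b])) * (p[b, ] - p[a, ])
  if (n == 1L || n == 3L) {
    a <- if (n == 1L) which(neg) else which(!neg)
    o <- setdiff(1:4, a)
    return(rbind(ip(a, o[1]), ip(a, o[2]), ip(a, o[3])))
  }
  a <- which(neg); b <- which(!neg)
  q1 <- ip(a[1], b[1]); q2 <- ip(a[1], b[2])
  q3 <- ip(a[2], b[2]); q4 <- ip(a[2], b[1])
  rbind(q1, q2, q3, q1, q3, q4)
}

# Extract the iso-level triangle soup of a gridded scalar field.
# Returns a (3*n_tri) x 3 matrix of vertices, consecutive triples forming
# triangles.
mt_isosurface <- function(values, spec, iso = 0.5) {
  f <- values - iso
  f[f == 0] <- .Machine$double.xmin  # nudge exact hits off the level set
  d <- dim(f)
  i1 <- seq_len(d[1] - 1L); j1 <- seq_len(d[2] - 1L); k1 <- seq_len(d[3] - 1L)
  corner <- function(o) f[i1 + o[1], j1 + o[2], k1 + o[3], drop = FALSE]
  cs <- lapply(seq_len(8), function(m) corner(MT_OFFSETS[m, ]))
  mn <- do.call(pmin, cs)
  mx <- do.call(pmax, cs)
  act <- which(mn < 0 & mx > 0 & is.finite(mn) & is.finite(mx))
  if (!length(act)) return(matrix(numeric(0), 0, 3))
  dc <- d - 1L
  ii <- (act - 1L) %% dc[1]
  jj <- ((act - 1L) %/% dc[1]) %% dc[2]
  kk <- (act - 1L) %/% (dc[1] * dc[2])
  tris <- vector("list", length(act) * 2L)
  nt <- 0L
  sp <- spec$spacing
  org <- spec$origin
  for (q in seq_along(act)) {
    base <- c(ii[q], jj[q], kk[q])
    vals8 <- vapply(seq_len(8), function(m)
      f[base[1] + MT_OFFSETS[m, 1] + 1L, base[2] + MT_OFFSETS[m, 2] + 1L,
        base[3] + MT_OFFSETS[m, 3] + 1L], numeric(1))
    pos8 <- sweep(MT_OFFSETS + rep(base, each = 8L), 2, sp, `*`)
    pos8 <- sweep(pos8, 2, org, `+`)
    for (t in seq_len(6)) {
      idx <- MT_TETS[t, ]
      tri <- tet_triangles(pos8[idx, , drop = FALSE], vals8[idx])
      if (!is.null(tri)) {
        nt <- nt + 1L
        tris[[nt]] <- tri
      }
    }
  }
  if (!nt) return(matrix(numeric(0), 0, 3))
  do.call(rbind, tris[seq_len(nt)])
}

tri_areas <- function(verts) {
  # verts: (3n) x 3, triples are triangles
  p1 <- verts[seq(1, nrow(verts), 3), , drop = FALSE]
  p2 <- verts[seq(2, nrow(verts), 3), , drop = FALSE]
  p3 <- verts[seq(3, nrow(verts), 3), , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

tri_midpoints <- function(verts) {
  (verts[seq(1, nrow(verts), 3), , drop = FALSE] +
     verts[seq(2, nrow(verts), 3), , drop = FALSE] +
     verts[seq(3, nrow(verts), 3), , drop = FALSE]) / 3
}

# Recursively subdivide triangles straddling the density cutoff so that the
# keep-by-midpoint rule converges at the trimmed rim. cutfun maps an n x 3
# point matrix to the density tested against `cutoff`.
trim_triangles <- function(verts, cutfun, cutoff, depth) {
  if (!nrow(verts)) return(verts)
  ntri <- nrow(verts) / 3L
  vpass <- matrix(cutfun(verts) > cutoff, nrow = 3)
  mids <- tri_midpoints(verts)
  mpass <- cutfun(mids) > cutoff
  npass <- colSums(vpass) + mpass
  keep <- npass == 4L
  drop <- npass == 0L
  border <- !(keep | drop)
  kept <- verts[rep(keep, each = 3L), , drop = FALSE]
  if (!any(border)) return(kept)
  bv <- verts[rep(border, each = 3L), , drop = FALSE]
  if (depth <= 0L) {
    # terminal rule: keep a border facet iff its midpoint passes the cutoff
    bm <- mpass[border]
    return(rbind(kept, bv[rep(bm, each = 3L), , drop = FALSE]))
  }
  p1 <- bv[seq(1, nrow(bv), 3), , drop = FALSE]
  p2 <- bv[seq(2, nrow(bv), 3), , drop = FALSE]
  p3 <- bv[seq(3, nrow(bv), 3), , drop = FALSE]
  m12 <- (p1 + p2) / 2; m13 <- (p1 + p3) / 2; m23 <- (p2 + p3) / 2
  nb <- nrow(p1)
  sub <- matrix(0, nb * 12L, 3)
  rows <- function(a, b, c) {
    out <- matrix(0, nb * 3L, 3)
    out[seq(1, nb * 3L, 3), ] <- a
    out[seq(2, nb * 3L, 3), ] <- b
    out[seq(3, nb * 3L, 3), ] <- c
    out
  }
  sub[seq_len(nb * 3L), ] <- rows(p1, m12, m13)
  sub[nb * 3L + seq_len(nb * 3L), ] <- rows(m12, p2, m23)
  sub[nb * 6L + seq_len(nb * 3L), ] <- rows(m13, m23, p3)
  sub[nb * 9L + seq_len(nb * 3L), ] <- rows(m12, m23, m13)
  rbind(kept, trim_triangles(sub, cutfun, cutoff, depth - 1L))
}

#' Build the Hirshfeld interface between two moieties
#'
#' Computes promolecule densities of both sides on a common grid, extracts
#' the w = 0.5 isosurface of the Hirshfeld weight `w = rho_a/(rho_a + rho_b)`
#' by marching tetrahedra, and trims away surface exposed to bulk solvent by
#' keeping only facets whose midpoint density exceeds `density_cutoff`
#' (default 0.0013 e per cubic angstrom). Facets straddling the cutoff rim
#' are subdivided `refine_depth` times before the midpoint rule is applied,
#' so the trimmed area converges under grid refinement. Each kept facet is
#' assigned to the atom on either side contributing most density at its
#' midpoint (see [assign_patches()]).
#'
#' @param side_a,side_b typed `mol_model` objects for the two moieties
#'   (e.g. peptide and protein-plus-structural-waters).
#' @param spacing grid spacing, angstroms.
#' @param density_cutoff solvent-exposure cutoff, e per cubic angstrom. The
#'   density tested is chosen by `cutoff_on`.
#' @param cutoff_on `"total"` tests `rho_a + rho_b` at the facet midpoint
#'   (default); `"partner"` tests the opposing side's density `rho_b`.
#' @param margin grid margin beyond the joint bounding box, angstroms.
#' @param refine_depth rim-subdivision depth (0 disables refinement).
#' @param assign_rule facet-to-atom rule: `"density"` (largest promolecule
#'   contribution, default) or `"nearest"` (closest atom).
#' @return an object of class `interface_patches`: fields `verts`
#'   ((3n) x 3 vertex matrix), `area`, `midpoint`, `atom_in`, `atom_out`,
#'   `type_in`, `type_out`, `total_area` and `meta`. An empty interface (no
#'   crossing, or everything trimmed) is returned with zero facets and
#'   `meta$empty = TRUE`, not as an error.
#' @examples
#' cx <- make_two_atom_complex("C", 3)
#' p <- build_interface(cx$a, cx$b, spacing = 0.25)
#' p$total_area
#' @export
build_interface <- function(side_a, side_b, spacing = 0.2,
                            density_cutoff = 0.0013,
                            cutoff_on = c("total", "partner"), margin = 4,
                            refine_depth = 2, assign_rule = c("density", "nearest")) {
  cutoff_on <- match.arg(cutoff_on)
  assign_rule <- match.arg(assign_rule)
  if (spacing <= 0) stop_cz("spacing must be > 0")
  if (!n_atoms(side_a) || !n_atoms(side_b))
    stop_cz("both sides must be non-empty")
  spec <- make_grid_spec(list(side_a, side_b), spacing = spacing,
                         margin = margin)
  ga <- promolecule_on_grid(side_a, spec)
  gb <- promolecule_on_grid(side_b, spec)
  tot <- ga$values + gb$values
  w <- ga$values / tot
  verts <- mt_isosurface(w, spec, iso = 0.5)
  cutfun <- if (cutoff_on == "total") {
    function(p) promolecule_at(side_a, p) + promolecule_at(side_b, p)
  } else {
    function(p) promolecule_at(side_b, p)
  }
  if (nrow(verts)) {
    verts <- trim_triangles(verts, cutfun, density_cutoff,
                            as.integer(refine_depth))
  }
  meta <- list(spacing = spacing, density_cutoff = density_cutoff,
               cutoff_on = cutoff_on, refine_depth = refine_depth,
               assign_rule = assign_rule,
               density_model = "spherical promolecule (sum of exponentials)",
               empty = nrow(verts) == 0L)
  if (!nrow(verts)) {
    return(structure(list(verts = verts, area = numeric(0),
                          midpoint = matrix(numeric(0), 0, 3),
                          atom_in = integer(0), atom_out = integer(0),
                          type_in = character(0), type_out = character(0),
                          total_area = 0, meta = meta),
                     class = "interface_patches"))
  }
  area <- tri_areas(verts)
  good <- area > 1e-12
  verts <- verts[rep(good, each = 3L), , drop = FALSE]
  area <- area[good]
  patches <- structure(list(verts = verts, area = area,
                            midpoint = tri_midpoints(verts),
                            atom_in = integer(length(area)),
                            atom_out = integer(length(area)),
                            type_in = character(length(area)),
                            type_out = character(length(area)),
                            total_area = sum(area), meta = meta),
                       class = "interface_patches")
  assign_patches(patches, side_a, side_b, rule = assign_rule)
}

#' Assign interface facets to contributing atoms
#'
#' For every facet midpoint, `atom_in` is the atom of side A with the largest
#' individual promolecule density contribution there and `atom_out` likewise
#' for side B (`rule = "density"`); `rule = "nearest"` uses plain distance
#' instead. Facet types are copied from the atoms' interaction types when the
#' models are typed.
#'
#' @param patches an `interface_patches` object built from the same models.
#' @param side_a,side_b the two `mol_model` objects.
#' @param rule `"density"` or `"nearest"`.
#' @return the patch set with `atom_in`, `atom_out`, `type_in`, `type_out`
#'   filled (atom ids refer to the models' `id` column).
#' @export
assign_patches <- function(patches, side_a, side_b,
                           rule = c("density", "nearest")) {
  rule <- match.arg(rule)
  if (!length(patches$area)) return(patches)
  pick <- function(model) {
    if (rule == "density") {
      contrib <- promolecule_at(model, patches$midpoint, per_atom = TRUE)
      max.col(contrib, ties.method = "first")
    } else {
      xyz <- coords(model)
      d2 <- outer(rowSums(patches$midpoint^2), rowSums(xyz^2), "+") -
        2 * patches$midpoint %*% t(xyz)
      max.col(-d2, ties.method = "first")
    }
  }
  ia <- pick(side_a)
  ib <- pick(side_b)
  patches$atom_in <- side_a$atoms$id[ia]
  patches$atom_out <- side_b$atoms$id[ib]
  patches$type_in <- as.character(side_a$atoms$type[ia])
  patches$type_out <- as.character(side_b$atoms$type[ib])
  patches$meta$assign_rule <- rule
  patches
}

#' @export
print.interface_patches <- function(x, ...) {
  cat(sprintf("<interface_patches> %d facets, total area %.3f A^2 (spacing %g A, cutoff %g e/A^3 on %s)\n",
              length(x$area), x$total_area, x$meta$spacing,
              x$meta$density_cutoff, x$meta$cutoff_on))
  invisible(x)
}

#' Number of facets in a patch set
#' @param patches an `interface_patches` object.
#' @return integer facet count.
#' @export
n_facets <- function(patches) length(patches$area)

#' Export an interface mesh as Wavefront OBJ
#' @param patches an `interface_patches` with geometry.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(patches, path) {
  v <- patches$verts
  if (!nrow(v)) stop_cz("patch set has no geometry to export")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# contactzones Hirshfeld interface (angstroms)", con)
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  idx <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  writeLines(sprintf("f %d %d %d", idx[, 1], idx[, 2], idx[, 3]), con)
  invisible(path)
}

#' Export an interface mesh as ASCII PLY
#' @param patches an `interface_patches` with geometry.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(patches, path) {
  v <- patches$verts
  if (!nrow(v)) stop_cz("patch set has no geometry to export")
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nrow(v) / 3L
  writeLines(c("ply", "format ascii 1.0",
               "comment contactzones Hirshfeld interface (angstroms)",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  idx <- matrix(seq_len(nrow(v)) - 1L, ncol = 3, byrow = TRUE)
  writeLines(sprintf("3 %d %d %d", idx[, 1], idx[, 2], idx[, 3]), con)
  invisible(path)
}

#' Export the facet table as TSV
#' @param patches an `interface_patches` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patch_tsv <- function(patches, path) {
  df <- data.frame(facet = seq_along(patches$area), area = patches$area,
                   atom_in = patches$atom_in, atom_out = patches$atom_out,
                   type_in = patches$type_in, type_out = patches$type_out)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
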
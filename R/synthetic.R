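# Seeded synthetic fixtures: toy complexes with analytic interfaces,
# composition-controlled random complexes for the enrichment null,
# point-charge systems with known basins, and Gaussian pseudo-ensembles.
# All randomness flows through with_seed(); a seed fully determines a fixture.

element_for_type <- c(C = "C", Hc = "H", N = "N", `Ho/n` = "H", O = "O",
                      W = "O")

single_atom_model <- function(element, pos, id = 1L, side = NA_character_,
                              type = NA_character_, resname = "FIX",
                              resno = 1L, chain = "A") {
  mol_model(data.frame(id = id, element = element, name = element,
                       resname = resname, resno = resno, chain = chain,
                       x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0,
                       alt = "", type = type, stringsAsFactors = FALSE),
            side = side)
}

#' Two-atom complex with an analytic interface
#'
#' Places two atoms of the same element on the x axis at `+/- distance/2`,
#' each forming its own side. For a homonuclear pair the Hirshfeld interface
#' is exactly the bisector plane x = 0, which makes this the basic geometry
#' fixture.
#'
#' @param element element symbol.
#' @param distance separation, angstroms (> 0).
#' @return list with `mol_model` members `a` and `b`, typed.
#' @export
make_two_atom_complex <- function(element = "C", distance = 3.0) {
  if (distance <= 0) stop_cz("distance must be > 0")
  type <- if (element == "H") "Hc" else if (element %in% c("C", "S")) "C"
  else element
  list(a = single_atom_model(element, c(-distance / 2, 0, 0), id = 1L,
                             side = "a", type = type, chain = "A"),
       b = single_atom_model(element, c(distance / 2, 0, 0), id = 2L,
                             side = "b", type = type, chain = "B"))
}

#' Random two-sided complex with controlled type composition
#'
#' Draws atom interaction types independently from `composition` and places
#' the atoms in two abutting half-boxes (side a in x < 0, side b in x > 0)
#' with a minimum separation enforced. Positions are uniform
#' (`placement = "uniform"`, rejection-sampled) or a jittered lattice
#' (`placement = "lattice"`, packing guaranteed at high counts).
#'
#' @param n_per_side atoms per side.
#' @param composition named percentage vector over [contact_types()]
#'   (must sum to 100); a list of two such vectors applies one per side.
#' @param box full box edge length, angstroms.
#' @param min_sep minimum interatomic separation, angstroms (> 0).
#' @param seed integer seed.
#' @param placement `"uniform"` or `"lattice"`.
#' @param max_attempts rejection-sampling budget per atom.
#' @return list with typed `mol_model` members `a` and `b`.
#' @export
make_random_complex <- function(n_per_side, composition, box = 20,
                                min_sep = 1.0, seed = 1,
                                placement = c("uniform", "lattice"),
                                max_attempts = 200) {
  placement <- match.arg(placement)
  if (min_sep <= 0) stop_cz("min_sep must be > 0")
  comps <- if (is.list(composition)) composition
  else list(composition, composition)
  for (cmp in comps) {
    if (abs(sum(cmp) - 100) > 0.5)
      stop_cz("composition must sum to 100")
    if (any(!names(cmp) %in% contact_types()))
      stop_cz("unknown type in composition")
  }
  with_seed(seed, {
    place_side <- function(sign_x) {
      lo <- c(if (sign_x < 0) -box / 2 else min_sep / 2, -box / 2, -box / 2)
      hi <- c(if (sign_x < 0) -min_sep / 2 else box / 2, box / 2, box / 2)
      if (placement == "lattice") {
        ncell <- ceiling(n_per_side^(1 / 3))
        ax <- lapply(1:3, function(k)
          seq(lo[k], hi[k], length.out = ncell + 2)[2:(ncell + 1)])
        g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
        g <- g[sample.int(nrow(g), n_per_side), , drop = FALSE]
        jit <- min(min_sep / 4, min(hi - lo) / (4 * ncell))
        return(g + matrix(runif(3 * n_per_side, -jit, jit), ncol = 3))
      }
      pts <- matrix(NA_real_, n_per_side, 3)
      for (i in seq_len(n_per_side)) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          p <- runif(3, lo, hi)
          if (i == 1 || min(row_norms(sweep(pts[seq_len(i - 1), , drop = FALSE],
                                            2, p))) >= min_sep) {
            pts[i, ] <- p
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop_cz("could not place atom ", i, " after ", max_attempts,
                  " attempts; enlarge the box or lower min_sep")
      }
      pts
    }
    build <- function(pts, cmp, side, chain, id0) {
      ty <- sample(names(cmp), nrow(pts), replace = TRUE,
                   prob = as.numeric(cmp))
      mol_model(data.frame(id = id0 + seq_len(nrow(pts)),
                           element = unname(element_for_type[ty]), name = ty,
                           resname = ifelse(ty == "W", "HOH", "FIX"),
                           resno = seq_len(nrow(pts)), chain = chain,
                           x = pts[, 1], y = pts[, 2], z = pts[, 3],
                           occ = 1, b = 0, alt = "", type = ty,
                           stringsAsFactors = FALSE), side = side)
    }
    pa <- place_side(-1)
    pb <- place_side(+1)
    list(a = build(pa, comps[[1]], "a", "A", 0L),
         b = build(pb, comps[[2]], "b", "B", n_per_side))
  })
}

#' Synthetic interface patch set with independently drawn facet types
#'
#' Builds an `interface_patches` object of `n_facets` unit-area facets whose
#' side types are independent draws from the two stated compositions — the
#' random-mixing null for calibrating enrichment ratios (all E should be
#' near 1). No geometry is attached.
#'
#' @param n_facets number of facets.
#' @param comp_a,comp_b named percentage compositions per side (sum 100).
#' @param seed integer seed.
#' @param area facet area (scalar or per-facet vector).
#' @return an `interface_patches` object (without vertices).
#' @export
make_random_patches <- function(n_facets, comp_a, comp_b, seed = 1, area = 1) {
  for (cmp in list(comp_a, comp_b))
    if (abs(sum(cmp) - 100) > 0.5) stop_cz("composition must sum to 100")
  with_seed(seed, {
    ta <- sample(names(comp_a), n_facets, replace = TRUE,
                 prob = as.numeric(comp_a))
    tb <- sample(names(comp_b), n_facets, replace = TRUE,
                 prob = as.numeric(comp_b))
    area <- rep(area, length.out = n_facets)
    structure(list(verts = matrix(numeric(0), 0, 3), area = area,
                   midpoint = matrix(NA_real_, n_facets, 3),
                   atom_in = seq_len(n_facets), atom_out = seq_len(n_facets),
                   type_in = ta, type_out = tb, total_area = sum(area),
                   meta = list(synthetic = "independent type draws",
                               seed = seed)),
              class = "interface_patches")
  })
}

#' Gaussian pseudo-ensemble around a model
#'
#' Each frame displaces every atom by independent isotropic Gaussian noise
#' (`sigma` per coordinate, scalar or per-atom). A static ensemble
#' (`sigma = 0`) reproduces the model in every frame.
#'
#' @param model a `mol_model`.
#' @param sigma per-coordinate standard deviation(s), angstroms (>= 0).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @return a `mol_ensemble`.
#' @export
make_gaussian_ensemble <- function(model, sigma, n_frames, seed = 1) {
  if (n_frames < 2) stop_cz("n_frames must be >= 2")
  if (any(sigma < 0)) stop_cz("sigma must be >= 0")
  n <- n_atoms(model)
  sigma <- rep(sigma, length.out = n)
  base <- coords(model)
  with_seed(seed, {
    xyz <- array(NA_real_, c(n, 3, n_frames))
    for (k in seq_len(n_frames))
      xyz[, , k] <- base + matrix(rnorm(3 * n, sd = rep(sigma, 3)), n, 3)
    mol_ensemble(model$atoms, xyz)
  })
}

#' Point-charge system from an explicit specification
#'
#' @param positions n x 3 matrix of charge positions, angstroms.
#' @param q length-n vector of charges, elementary units (finite).
#' @param element element symbol used for the pseudo-atoms.
#' @return a charged `mol_model`; attribute `total_charge` reports the sum.
#' @export
make_charge_system <- function(positions, q, element = "O") {
  positions <- matrix(positions, ncol = 3)
  if (length(q) != nrow(positions)) stop_cz("positions and q differ in length")
  if (any(!is.finite(q))) stop_cz("charges must be finite")
  n <- nrow(positions)
  m <- mol_model(data.frame(id = seq_len(n), element = element,
                            name = paste0("Q", seq_len(n)), resname = "CHG",
                            resno = seq_len(n), chain = "A",
                            x = positions[, 1], y = positions[, 2],
                            z = positions[, 3], occ = 1, b = 0, alt = "",
                            type = NA_character_, charge = q,
                            stringsAsFactors = FALSE), side = "charges")
  attr(m, "total_charge") <- sum(q)
  m
}
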
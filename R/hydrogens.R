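# Riding-hydrogen placement at idealized geometry.
#
# X-H bond lengths follow neutron-normalized conventions (C-H 1.083,
# N-H 1.009, O-H 0.967, S-H 1.34 angstroms), the lengths multipolar density
# libraries expect, rather than the shorter X-ray apparent distances.

XH_LENGTHS <- c(C = 1.083, N = 1.009, O = 0.967, S = 1.340)

# expected number of hydrogens given element and heavy-bond count (neutral
# valence completion), overridden for charged standard-residue groups below
expected_h <- function(element, n_heavy, resname, name, is_nterm) {
  if (element == "N") {
    if (resname == "ARG" && name %in% c("NH1", "NH2")) return(2L)
    if (resname == "LYS" && name == "NZ") return(3L)
    if (resname == "PRO" && name == "N") return(if (is_nterm) 1L else 0L)
    if (name == "N" && is_nterm) return(3L)   # protonated terminal amine
    return(max(0L, 3L - n_heavy))
  }
  if (element == "C") return(max(0L, 4L - n_heavy))
  if (element == "O") {
    # carboxylate / carbonyl oxygens bound to one carbon carry no H
    if (n_heavy >= 1 && name %in% c("O", "OD1", "OD2", "OE1", "OE2", "OXT"))
      return(0L)
    return(max(0L, 2L - n_heavy))
  }
  0L
}

unit3 <- function(v) v / sqrt(sum(v * v))

any_perp <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(u - sum(u * v) * v)
}

h_directions <- function(nbr_units, n_h) {
  k <- nrow(nbr_units)
  if (k == 0) {                      # isolated atom: arbitrary frame
    nbr_units <- matrix(c(0, 0, -1), 1)
    k <- 1
  }
  if (k >= 3) {                      # complete tetrahedron: opposite the sum
    return(matrix(unit3(-colSums(nbr_units)), 1))
  }
  if (k == 2) {
    bis <- -unit3(nbr_units[1, ] + nbr_units[2, ])
    ax <- unit3(pracma_cross(nbr_units[1, ], nbr_units[2, ]))
    if (n_h == 1) return(matrix(bis, 1))
    half <- 0.5 * (109.47 * pi / 180)
    return(rbind(cos(half) * bis + sin(half) * ax,
                 cos(half) * bis - sin(half) * ax))
  }
  # k == 1: cone around -neighbor at tetrahedral (sp3) or trigonal angle
  axis <- -nbr_units[1, ]
  perp <- any_perp(axis)
  perp2 <- pracma_cross(axis, perp)
  ang <- if (n_h <= 2) (180 - 120) else (180 - 109.47)
  ang <- ang * pi / 180
  tors <- seq(0, 2 * pi, length.out = n_h + 1)[seq_len(n_h)]
  t(vapply(tors, function(phi) {
    unit3(cos(ang) * axis + sin(ang) * (cos(phi) * perp + sin(phi) * perp2))
  }, numeric(3)))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Add riding hydrogens at standard geometry
#'
#' Places hydrogens on C, N, O (and S) atoms to complete their valence at
#' idealized tetrahedral/trigonal geometry, with neutron-normalized X-H bond
#' lengths. Charged groups of standard residues (terminal amine, Lys NZ, Arg
#' guanidinium) get their protonated hydrogen counts. Water molecules are left
#' bare: interface typing treats the water oxygen as a single `W` site.
#' Torsions around single-neighbor atoms are arbitrary; the placement is meant
#' for interface typing and promolecule densities, not for energetics.
#'
#' @param model a `mol_model` of heavy atoms (existing hydrogens are kept and
#'   their sites not re-filled).
#' @return a `mol_model` with hydrogens appended (ids continue after the
#'   current maximum).
#' @export
place_hydrogens <- function(model) {
  a <- model$atoms
  bonds <- derive_bonds(model)
  nbrs <- vector("list", nrow(a))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  xyz <- coords(model)
  # first residue per chain is treated as the N-terminus
  chain_first <- tapply(a$resno, a$chain, min)
  new <- list()
  next_id <- max(a$id, 0) + 1L
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    if (!el %in% c("C", "N", "O", "S")) next
    if (is_water_resname(a$resname[i])) next
    nb <- nbrs[[i]] %||% integer(0)
    heavy <- nb[a$element[nb] != "H"]
    n_have <- sum(a$element[nb] == "H")
    is_nterm <- el == "N" && a$name[i] == "N" &&
      a$resno[i] == chain_first[[a$chain[i]]]
    n_h <- expected_h(el, length(heavy), a$resname[i], a$name[i], is_nterm)
    n_h <- n_h - n_have
    if (n_h <= 0) next
    units <- if (length(heavy))
      t(apply(xyz[heavy, , drop = FALSE], 1, function(p) unit3(p - xyz[i, ])))
    else matrix(numeric(0), 0, 3)
    dirs <- h_directions(units, n_h)
    len <- XH_LENGTHS[[el]]
    for (k in seq_len(min(n_h, nrow(dirs)))) {
      p <- xyz[i, ] + len * dirs[k, ]
      new[[length(new) + 1]] <- data.frame(
        id = next_id, element = "H",
        name = paste0("H", a$name[i], if (n_h > 1) k else ""),
        resname = a$resname[i], resno = a$resno[i], chain = a$chain[i],
        x = p[1], y = p[2], z = p[3], occ = a$occ[i], b = a$b[i], alt = "",
        type = NA_character_, stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
  }
  if (!length(new)) return(model)
  add <- do.call(rbind, new)
  for (cc in setdiff(names(a), names(add))) add[[cc]] <- NA
  mol_model(rbind(a, add[, names(a)]), side = model$side)
}
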
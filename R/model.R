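#' Molecular model container
#'
#' A `mol_model` holds one conformer of a molecular moiety as a data frame of
#' atoms plus a side label ("protein", "peptide", ...). Atom columns follow
#' PDB semantics: author chain identifiers and 1-based author residue
#' numbering are preserved as read.
#'
#' @param atoms data frame with columns `id`, `element`, `name`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z` and optionally `occ` (occupancy,
#'   default 1), `b` (isotropic B factor in squared angstroms, default 0),
#'   `alt` (alternate-location indicator, default ""), `type` (chemical
#'   interaction type, default `NA`), `charge` (partial charge, e).
#' @param side character label for the moiety this model represents.
#' @return an object of class `mol_model`.
#' @seealso [read_structure()], [assign_interaction_types()]
#' @export
mol_model <- function(atoms, side = NA_character_) {
  need <- c("id", "element", "name", "resname", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop_cz("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$type)) atoms$type <- NA_character_
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop_cz("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0, na.rm = TRUE)) stop_cz("B factors must be >= 0")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, side = side), class = "mol_model")
}

#' @export
print.mol_model <- function(x, ...) {
  cat(sprintf("<mol_model> side=%s  %d atoms, %d residues, chains: %s\n",
              x$side, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(unique(x$atoms$chain), collapse = " ")))
  if (all(!is.na(x$atoms$type)))
    cat("  typed: ", paste(names(table(x$atoms$type)), table(x$atoms$type),
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `mol_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Cartesian coordinates of a model
#' @param model a `mol_model`.
#' @return numeric n x 3 matrix (angstroms).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Subset a model by atom indices
#' @param model a `mol_model`.
#' @param idx integer or logical index into the atom table.
#' @param side optional new side label.
#' @return a `mol_model` with the selected atoms.
#' @export
model_subset <- function(model, idx, side = model$side) {
  mol_model(model$atoms[idx, , drop = FALSE], side = side)
}

#' Concatenate two models into one
#'
#' Used e.g. to merge structural water molecules into the protein side before
#' interface construction.
#'
#' @param a,b `mol_model` objects.
#' @param side side label of the result (defaults to `a`'s).
#' @return a `mol_model`.
#' @export
merge_models <- function(a, b, side = a$side) {
  cols <- union(names(a$atoms), names(b$atoms))
  for (cc in setdiff(cols, names(a$atoms))) a$atoms[[cc]] <- NA
  for (cc in setdiff(cols, names(b$atoms))) b$atoms[[cc]] <- NA
  mol_model(rbind(a$atoms[, cols], b$atoms[, cols]), side = side)
}

#' Parse an atom selection expression
#'
#' Selection grammar (comma-separated terms are unioned):
#' * `chain:A` — all atoms of chain A
#' * `A/320` — residue 320 of chain A (author numbering)
#' * `A/296-300` — inclusive residue range
#' * `A/320/OD1` — a named atom of one residue
#' * keywords `all`, `backbone` (N, CA, C, O), `calpha`, `heavy`, `water`
#'
#' @param model a `mol_model`.
#' @param expr selection string, or `NULL`/`"all"` for everything.
#' @return integer vector of atom indices (possibly empty).
#' @export
parse_selection <- function(model, expr = NULL) {
  at <- model$atoms
  if (is.null(expr) || identical(expr, "all")) return(seq_len(nrow(at)))
  terms <- trimws(strsplit(expr, ",", fixed = TRUE)[[1]])
  hit <- rep(FALSE, nrow(at))
  for (tm in terms) {
    if (tm == "backbone") {
      hit <- hit | (at$name %in% c("N", "CA", "C", "O") & !is_water_resname(at$resname))
    } else if (tm == "calpha") {
      hit <- hit | at$name == "CA"
    } else if (tm == "heavy") {
      hit <- hit | at$element != "H"
    } else if (tm == "water") {
      hit <- hit | is_water_resname(at$resname)
    } else if (grepl("^chain:", tm)) {
      hit <- hit | at$chain == sub("^chain:", "", tm)
    } else if (grepl("/", tm, fixed = TRUE)) {
      p <- strsplit(tm, "/", fixed = TRUE)[[1]]
      if (length(p) < 2 || length(p) > 3)
        stop_cz("cannot parse selection term: ", tm)
      sel <- at$chain == p[1]
      if (grepl("-", p[2], fixed = TRUE)) {
        rng <- as.integer(strsplit(p[2], "-", fixed = TRUE)[[1]])
        sel <- sel & at$resno >= rng[1] & at$resno <= rng[2]
      } else {
        sel <- sel & at$resno == as.integer(p[2])
      }
      if (length(p) == 3) sel <- sel & at$name == p[3]
      hit <- hit | sel
    } else {
      stop_cz("cannot parse selection term: ", tm)
    }
  }
  which(hit)
}

is_water_resname <- function(resname) {
  toupper(resname) %in% c("HOH", "WAT", "H2O", "DOD", "TIP", "SOL")
}

#' Conformational ensemble over a fixed atom roster
#'
#' @param atoms atom table shared by every frame (see [mol_model()]).
#' @param xyz numeric array of dimension `c(n_atoms, 3, n_frames)`.
#' @param dt optional frame interval metadata (e.g. ps per frame).
#' @return an object of class `mol_ensemble`.
#' @export
mol_ensemble <- function(atoms, xyz, dt = NA_real_) {
  if (length(dim(xyz)) != 3 || dim(xyz)[2] != 3)
    stop_cz("xyz must be an n_atoms x 3 x n_frames array")
  if (dim(xyz)[1] != nrow(atoms))
    stop_cz("frame roster (", dim(xyz)[1], ") does not match atom table (",
            nrow(atoms), ")")
  structure(list(atoms = atoms, xyz = xyz, dt = dt), class = "mol_ensemble")
}

#' @export
print.mol_ensemble <- function(x, ...) {
  cat(sprintf("<mol_ensemble> %d atoms x %d frames\n",
              dim(x$xyz)[1], dim(x$xyz)[3]))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `mol_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$xyz)[3]

#' Extract one frame of an ensemble as a model
#' @param ensemble a `mol_ensemble`.
#' @param i frame index.
#' @param side side label for the returned model.
#' @return a `mol_model`.
#' @export
ensemble_frame <- function(ensemble, i, side = NA_character_) {
  set_coords(mol_model(ensemble$atoms, side = side),
             matrix(ensemble$xyz[, , i], ncol = 3))
}
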
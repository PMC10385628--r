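# Reading/writing molecular models, chemical-type assignment, residue
# contacts and sequence isoelectric points.

KNOWN_ELEMENTS <- c("H", "D", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                    "NA", "MG", "K", "CA", "ZN", "FE", "MN", "CU", "SE")

# single-bond covalent radii (angstroms), Cordero-style values
COVALENT_RADII <- c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66,
                    S = 1.05, P = 1.07, F = 0.57, CL = 1.02, SE = 1.20)

#' Read a structure file into a model or ensemble
#'
#' Wraps the bio3d readers. ATOM and HETATM records are both returned, with
#' author chain identifiers and residue numbering preserved. A multi-model
#' PDB file yields a [mol_ensemble()] over the shared atom roster; a
#' single-model file yields one [mol_model()].
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` (mmCIF) or `"auto"` (by extension).
#' @param side side label attached to the returned model.
#' @param strict_elements if `TRUE`, an element symbol outside the known set
#'   raises an error naming the offending atom.
#' @return a `mol_model`, or a `mol_ensemble` for multi-model files.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(make_two_atom_complex("C", 3)$a, pdb)
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           side = NA_character_, strict_elements = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_cz("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop_cz("failed to parse ", path, " as ", format, ": ",
                                conditionMessage(e)))
  at <- pdb$atom
  elem <- toupper(trimws(as.character(at$elesy)))
  bad <- !nzchar(elem) | is.na(elem)
  if (any(bad)) elem[bad] <- guess_element(at$elety[bad])
  if (strict_elements && any(!elem %in% KNOWN_ELEMENTS)) {
    i <- which(!elem %in% KNOWN_ELEMENTS)[1]
    stop_cz("unknown element '", elem[i], "' for atom ", at$eleno[i],
            " (", at$elety[i], " ", at$resid[i], at$resno[i], ")")
  }
  elem[elem == "D"] <- "H"
  atoms <- data.frame(
    id = as.integer(at$eleno), element = elem,
    name = trimws(as.character(at$elety)),
    resname = trimws(as.character(at$resid)),
    resno = as.integer(at$resno), chain = as.character(at$chain),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (nmod > 1) {
    xyz <- array(NA_real_, c(nrow(atoms), 3, nmod))
    for (k in seq_len(nmod))
      xyz[, , k] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    return(mol_ensemble(atoms, xyz))
  }
  mol_model(atoms, side = side)
}

guess_element <- function(name) {
  nm <- toupper(gsub("[0-9' ]", "", trimws(name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% KNOWN_ELEMENTS & nchar(nm) > 1 &
           !substr(nm, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
         two, substr(nm, 1, 1))
}

#' Write a model or ensemble as PDB
#'
#' Single models go through `bio3d::write.pdb`; ensembles are written as
#' standard multi-model PDB (MODEL/ENDMDL records) with the shared roster.
#' Coordinates are written at the format's 3-decimal precision.
#'
#' @param x a `mol_model` or `mol_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "mol_ensemble")) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(pdb_atom_lines(ensemble_frame(x, k)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  a <- x$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords(x))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resname, eleno = a$id, elety = a$name,
                   chain = ifelse(nzchar(trimws(a$chain)), a$chain, " "),
                   o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

pdb_atom_lines <- function(model) {
  a <- model$atoms
  name4 <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
                  sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  sprintf("ATOM  %5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$id %% 100000, name4, substr(a$alt, 1, 1), a$resname,
          substr(paste0(a$chain, " "), 1, 1), a$resno,
          a$x, a$y, a$z, a$occ, a$b, a$element)
}

#' Reduce alternate locations to one conformer
#'
#' Keeps, for each (chain, residue, atom name), the conformer with the highest
#' occupancy; ties are broken in favour of altloc "A" (then alphabetically).
#' All surface and field computations expect single-conformer input.
#'
#' @param model a `mol_model`.
#' @return a `mol_model` without duplicate altloc records.
#' @export
filter_altloc <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$resname, a$name, sep = "\r")
  ord <- order(key, -a$occ, a$alt)
  keep <- !duplicated(key[ord])
  model_subset(model, sort(ord[keep]))
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of their covalent
#' radii plus `slack`. Suitable for protonated protein models; no CONECT
#' records are required.
#'
#' @param model a `mol_model`.
#' @param slack distance slack in angstroms added to the radius sum.
#' @return two-column integer matrix of atom-index pairs (i < j).
#' @export
derive_bonds <- function(model, slack = 0.4) {
  xyz <- coords(model)
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  rad <- COVALENT_RADII[model$atoms$element]
  rad[is.na(rad)] <- 1.2
  out <- vector("list", n)
  maxr <- max(rad) * 2 + slack
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d2 <- (xyz[j, 1] - xyz[i, 1])^2 + (xyz[j, 2] - xyz[i, 2])^2 +
      (xyz[j, 3] - xyz[i, 3])^2
    near <- j[d2 <= maxr^2]
    if (!length(near)) next
    lim <- (rad[i] + rad[near] + slack)^2
    d2n <- (xyz[near, 1] - xyz[i, 1])^2 + (xyz[near, 2] - xyz[i, 2])^2 +
      (xyz[near, 3] - xyz[i, 3])^2
    hit <- near[d2n <= lim]
    if (length(hit)) out[[i]] <- cbind(i, hit)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), 0, 2) else unname(res)
}

#' Assign chemical interaction types to every atom
#'
#' Types follow the six-class scheme used for interface contact statistics:
#' `C` carbon, `Hc` hydrogen covalently bonded to carbon, `N` nitrogen
#' (sp2 peptide and guanidinium nitrogens, treated as hydrophobic), `Ho/n`
#' electropositive hydrogen bonded to nitrogen or oxygen, `O` oxygen, and `W`
#' the oxygen atom of a water molecule. Waters are treated as bare oxygens;
#' sulfur is classed with carbon (hydrophobic). A hydrogen with no bonded
#' heavy atom raises an error naming it.
#'
#' @param model a `mol_model` (hydrogens present for non-water residues if the
#'   typed model is to feed interface statistics).
#' @param bonds optional bond matrix from [derive_bonds()]; derived if `NULL`.
#' @param type_overrides optional named character vector mapping atom `id` to a
#'   type, e.g. to mark specific nitrogen atoms hydrophilic.
#' @return the model with its `type` column filled (a "typed model").
#' @export
assign_interaction_types <- function(model, bonds = NULL, type_overrides = NULL) {
  a <- model$atoms
  type <- rep(NA_character_, nrow(a))
  water <- is_water_resname(a$resname)
  type[a$element == "C"] <- "C"
  type[a$element == "S"] <- "C"
  type[a$element == "N"] <- "N"
  type[a$element == "O"] <- "O"
  type[a$element == "O" & water] <- "W"
  hyd <- which(a$element == "H")
  if (length(hyd)) {
    if (is.null(bonds)) bonds <- derive_bonds(model)
    partner <- rep(NA_integer_, nrow(a))
    if (nrow(bonds)) {
      for (r in seq_len(nrow(bonds))) {
        i <- bonds[r, 1]; j <- bonds[r, 2]
        if (a$element[i] == "H" && a$element[j] != "H") partner[i] <- j
        if (a$element[j] == "H" && a$element[i] != "H") partner[j] <- i
      }
    }
    for (i in hyd) {
      p <- partner[i]
      if (is.na(p))
        stop_cz("hydrogen atom ", a$id[i], " (", a$name[i], " ", a$resname[i],
                a$resno[i], ") has no bonded heavy atom within tolerance")
      type[i] <- if (a$element[p] == "C") "Hc" else "Ho/n"
    }
  }
  untyped <- which(is.na(type))
  if (length(untyped))
    stop_cz("no interaction type for element '", a$element[untyped[1]],
            "' (atom ", a$id[untyped[1]], ")")
  if (!is.null(type_overrides)) {
    idx <- match(as.integer(names(type_overrides)), a$id)
    if (anyNA(idx)) stop_cz("type_overrides names unknown atom id")
    bad <- !type_overrides %in% contact_types()
    if (any(bad)) stop_cz("invalid override type: ", type_overrides[bad][1])
    type[idx] <- unname(type_overrides)
  }
  model$atoms$type <- type
  model
}

#' Write a typed-model report as TSV
#' @param model a typed `mol_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_typed_report <- function(model, path) {
  a <- model$atoms
  df <- data.frame(id = a$id, name = a$name,
                   residue = paste0(a$resname, a$resno), chain = a$chain,
                   type = a$type, side = model$side)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' List intermolecular residue contacts
#'
#' A residue pair is a contact when any interatomic distance between the two
#' models falls below `cutoff` (default 4 angstroms). The minimum distance is
#' reported, and the pair is flagged as hydrogen bonded when some
#' nitrogen/oxygen pair across it lies within `hbond_max`.
#'
#' @param model_a,model_b `mol_model` objects (non-empty).
#' @param cutoff contact distance threshold, angstroms (> 0).
#' @param hbond_max donor-acceptor heavy-atom distance criterion, angstroms.
#' @return data frame with one row per contacting residue pair: chain/number/
#'   name on both sides, `min_distance` and `is_hbond`.
#' @export
residue_contacts <- function(model_a, model_b, cutoff = 4.0, hbond_max = 3.5) {
  if (cutoff <= 0) stop_cz("cutoff must be > 0")
  if (!n_atoms(model_a) || !n_atoms(model_b)) stop_cz("models must be non-empty")
  xa <- coords(model_a); xb <- coords(model_b)
  aa <- model_a$atoms; ab <- model_b$atoms
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  ra <- paste(aa$chain, aa$resno, aa$resname, sep = "\r")
  rb <- paste(ab$chain, ab$resno, ab$resname, sep = "\r")
  hit <- which(d < cutoff, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resname_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resname_b = character(0),
                      min_distance = numeric(0), is_hbond = logical(0)))
  }
  key <- paste(ra[hit[, 1]], rb[hit[, 2]], sep = "\n")
  dmin <- tapply(d[hit], key, min)
  polar <- function(e) e %in% c("N", "O")
  hb <- tapply(seq_along(key), key, function(ii) {
    any(d[hit[ii, , drop = FALSE]] < hbond_max &
          polar(aa$element[hit[ii, 1]]) & polar(ab$element[hit[ii, 2]]))
  })
  parts <- strsplit(names(dmin), "\n", fixed = TRUE)
  pa <- do.call(rbind, strsplit(vapply(parts, `[`, "", 1), "\r", fixed = TRUE))
  pb <- do.call(rbind, strsplit(vapply(parts, `[`, "", 2), "\r", fixed = TRUE))
  out <- data.frame(chain_a = pa[, 1], resno_a = as.integer(pa[, 2]),
                    resname_a = pa[, 3], chain_b = pb[, 1],
                    resno_b = as.integer(pb[, 2]), resname_b = pb[, 3],
                    min_distance = as.numeric(dmin),
                    is_hbond = as.logical(hb))
  out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
}
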
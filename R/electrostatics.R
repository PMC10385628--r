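# Point-charge electrostatics and nucleophilic influence zones (NIZ).
#
# The potential is the vacuum Coulomb sum phi(r) = sum q_i / |r - r_i| in
# reduced units of e/angstrom; E = -grad phi is evaluated analytically.
# Field lines are integrated in the direction of the force on a positive test
# charge, so they converge on nucleophilic (negative) sites; the basin of
# seeds whose lines terminate on a given atom is that atom's nucleophilic
# influence zone.

#' Conversion constant from reduced potential units to kcal/mol per e
#'
#' Multiplying a potential in e/angstrom by this constant gives the
#' interaction energy of a unit positive test charge in kcal/mol.
#'
#' @return 332.0637 (kcal mol^-1 angstrom e^-2).
#' @export
coulomb_kcal <- function() 332.0637

#' Attach partial charges to a typed model
#'
#' Charges are matched with decreasing specificity: an explicit per-atom
#' override (by atom id), a residue-name + atom-name row, an interaction-type
#' row, then an element row. Unmatched atoms default to 0 with a warning
#' report (or an error when `strict`).
#'
#' @param model a `mol_model` (typed if the table matches on types).
#' @param charge_table data frame with columns `resname`, `name`, `type`,
#'   `element` (use `"*"` as wildcard) and `charge` (e); or a path to such a
#'   TSV; `NULL` loads the packaged generic set.
#' @param overrides optional named numeric vector of charges keyed by atom id.
#' @param strict error (instead of warn) on unmatched atoms.
#' @return the model with a `charge` column; total charge and any unmatched
#'   atoms are reported via attributes `total_charge` and `unmatched`.
#' @export
assign_charges <- function(model, charge_table = NULL, overrides = NULL,
                           strict = FALSE) {
  if (is.null(charge_table))
    charge_table <- cz_extdata("point_charges_generic.tsv")
  if (is.character(charge_table))
    charge_table <- read.table(charge_table, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE)
  need <- c("resname", "name", "type", "element", "charge")
  miss <- setdiff(need, names(charge_table))
  if (length(miss)) stop_cz("charge table missing column(s): ",
                            paste(miss, collapse = ", "))
  a <- model$atoms
  q <- rep(NA_real_, nrow(a))
  ct <- charge_table
  match_row <- function(i) {
    cand <- (ct$resname == "*" | ct$resname == a$resname[i]) &
      (ct$name == "*" | ct$name == a$name[i]) &
      (ct$type == "*" | (!is.na(a$type[i]) & ct$type == a$type[i])) &
      (ct$element == "*" | ct$element == a$element[i])
    if (!any(cand)) return(NA_real_)
    spec <- (ct$resname != "*") * 8 + (ct$name != "*") * 4 +
      (ct$type != "*") * 2 + (ct$element != "*")
    spec[!cand] <- -1
    ct$charge[which.max(spec)]
  }
  for (i in seq_len(nrow(a))) q[i] <- match_row(i)
  if (!is.null(overrides)) {
    idx <- match(as.integer(names(overrides)), a$id)
    if (anyNA(idx)) stop_cz("charge override names unknown atom id")
    q[idx] <- as.numeric(overrides)
  }
  unmatched <- which(is.na(q))
  if (length(unmatched)) {
    msg <- paste0(length(unmatched), " atom(s) matched no charge rule (first: atom ",
                  a$id[unmatched[1]], " ", a$name[unmatched[1]], " ",
                  a$resname[unmatched[1]], a$resno[unmatched[1]], ")")
    if (strict) stop_cz(msg)
    warning(msg, "; defaulting to charge 0")
    q[unmatched] <- 0
  }
  if (any(!is.finite(q))) stop_cz("charges must be finite")
  model$atoms$charge <- q
  attr(model, "total_charge") <- sum(q)
  attr(model, "unmatched") <- a$id[unmatched]
  model
}

charged_sources <- function(model, exclude = NULL) {
  if (is.null(model$atoms$charge)) stop_cz("model has no charges; run assign_charges()")
  keep <- seq_len(n_atoms(model))
  if (!is.null(exclude)) {
    if (is.character(exclude)) exclude <- parse_selection(model, exclude)
    keep <- setdiff(keep, exclude)
  }
  if (!length(keep)) stop_cz("no source atoms remain after exclusion")
  list(pos = coords(model)[keep, , drop = FALSE],
       q = model$atoms$charge[keep], idx = keep,
       id = model$atoms$id[keep])
}

# phi and E of point charges at arbitrary points; E rows are the field vector
coulomb_at <- function(points, pos, q, want_phi = TRUE) {
  points <- matrix(points, ncol = 3)
  dimnames(points) <- dimnames(pos) <- NULL
  m <- nrow(points)
  phi <- if (want_phi) numeric(m) else NULL
  E <- matrix(0, m, 3)
  for (i in seq_along(q)) {
    d <- cbind(points[, 1] - pos[i, 1], points[, 2] - pos[i, 2],
               points[, 3] - pos[i, 3])
    r2 <- d[, 1]^2 + d[, 2]^2 + d[, 3]^2
    r <- sqrt(r2)
    if (want_phi) phi <- phi + q[i] / r
    E <- E + q[i] * d / (r2 * r)
  }
  list(phi = phi, E = E)
}

#' Electrostatic potential and field on a grid
#'
#' Vacuum point-charge sums in reduced units (e/angstrom for the potential;
#' multiply by [coulomb_kcal()] for kcal/mol per unit charge). Voxels within
#' `mask_radius` of a source atom are masked `NA` to avoid the singularities.
#'
#' @param model a charged `mol_model` (see [assign_charges()]).
#' @param spec a `grid_spec`, or `NULL` to derive one from the model.
#' @param exclude atom selection (indices or selection string) removed from
#'   the source set, e.g. the ligand when mapping the protein's influence.
#' @param mask_radius singularity mask radius, angstroms.
#' @param spacing,margin grid construction parameters when `spec` is `NULL`.
#' @return list with `phi` (a `scalar_grid`) and `E` (a `vector_grid`).
#' @export
potential_and_field <- function(model, spec = NULL, exclude = NULL,
                                mask_radius = 0.05, spacing = 0.5, margin = 4) {
  src <- charged_sources(model, exclude)
  if (is.null(spec)) spec <- make_grid_spec(model, spacing, margin)
  pts <- voxel_centers(spec)
  ce <- coulomb_at(pts, src$pos, src$q)
  d2min <- rep(Inf, nrow(pts))
  for (i in seq_along(src$q)) {
    d2 <- (pts[, 1] - src$pos[i, 1])^2 + (pts[, 2] - src$pos[i, 2])^2 +
      (pts[, 3] - src$pos[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  masked <- d2min < mask_radius^2
  ce$phi[masked] <- NA_real_
  ce$E[masked, ] <- NA_real_
  list(phi = scalar_grid(spec, ce$phi, unit = "e/A"),
       E = vector_grid(spec, ce$E, unit = "e/A^2"))
}

#' Trace electric field lines from many seed points
#'
#' Integrates `dr/ds = E/|E|` (force direction on a positive test charge)
#' with fixed-step 4th-order Runge-Kutta. A line terminates when it (i)
#' enters the capture radius of any source atom, (ii) leaves the domain box
#' (escaped), or (iii) the field magnitude drops below `stagnation_field` or
#' the arc length exceeds `max_length` (stagnated).
#'
#' @param starts n x 3 matrix of seed positions, angstroms.
#' @param model a charged `mol_model`.
#' @param exclude source exclusion as in [potential_and_field()]; excluded
#'   atoms neither generate field nor capture lines.
#' @param step integration step, angstroms.
#' @param capture_radius capture distance around every remaining atom,
#'   angstroms.
#' @param max_length maximum arc length, angstroms.
#' @param domain 2 x 3 matrix of lower/upper box bounds, or `NULL` for the
#'   seed bounding box plus 2 angstroms.
#' @param stagnation_field field-magnitude floor, reduced units.
#' @return data frame with one row per seed: `terminal` ("atom", "escaped",
#'   "stagnated"), `atom` (id of the capturing atom or `NA`) and
#'   `arc_length`.
#' @export
trace_field_lines <- function(starts, model, exclude = NULL, step = 0.05,
                              capture_radius = 0.4, max_length = 200,
                              domain = NULL, stagnation_field = 1e-8) {
  src <- charged_sources(model, exclude)
  starts <- matrix(starts, ncol = 3)
  n <- nrow(starts)
  if (is.null(domain)) {
    domain <- rbind(apply(starts, 2, min) - 2, apply(starts, 2, max) + 2)
  }
  pos <- starts
  alive <- rep(TRUE, n)
  terminal <- rep(NA_character_, n)
  atom <- rep(NA_integer_, n)
  arc <- rep(0, n)
  unit_field <- function(p) {
    E <- coulomb_at(p, src$pos, src$q, want_phi = FALSE)$E
    nm <- sqrt(rowSums(E * E))
    list(u = E / pmax(nm, .Machine$double.xmin), nm = nm)
  }
  capture_check <- function(p) {
    # returns per-row index of capturing source, 0 if none
    best_d2 <- rep(Inf, nrow(p))
    best_i <- integer(nrow(p))
    for (i in seq_along(src$q)) {
      d2 <- (p[, 1] - src$pos[i, 1])^2 + (p[, 2] - src$pos[i, 2])^2 +
        (p[, 3] - src$pos[i, 3])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_i[upd] <- i
    }
    ifelse(best_d2 < capture_radius^2, best_i, 0L)
  }
  nsteps <- ceiling(max_length / step)
  for (s in seq_len(nsteps)) {
    act <- which(alive)
    if (!length(act)) break
    p <- pos[act, , drop = FALSE]
    f1 <- unit_field(p)
    stag <- f1$nm < stagnation_field
    if (any(stag)) {
      terminal[act[stag]] <- "stagnated"
      alive[act[stag]] <- FALSE
      act <- act[!stag]
      if (!length(act)) break
      p <- p[!stag, , drop = FALSE]
      f1 <- list(u = f1$u[!stag, , drop = FALSE], nm = f1$nm[!stag])
    }
    k1 <- f1$u
    k2 <- unit_field(p + (step / 2) * k1)$u
    k3 <- unit_field(p + (step / 2) * k2)$u
    k4 <- unit_field(p + step * k3)$u
    pnew <- p + (step / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    arc[act] <- arc[act] + step
    cap <- capture_check(pnew)
    hit <- cap > 0L
    if (any(hit)) {
      terminal[act[hit]] <- "atom"
      atom[act[hit]] <- src$id[cap[hit]]
      alive[act[hit]] <- FALSE
    }
    out <- pnew[, 1] < domain[1, 1] | pnew[, 1] > domain[2, 1] |
      pnew[, 2] < domain[1, 2] | pnew[, 2] > domain[2, 2] |
      pnew[, 3] < domain[1, 3] | pnew[, 3] > domain[2, 3]
    esc <- !hit & out
    if (any(esc)) {
      terminal[act[esc]] <- "escaped"
      alive[act[esc]] <- FALSE
    }
    pos[act, ] <- pnew
  }
  terminal[is.na(terminal)] <- "stagnated"  # exceeded max_length
  data.frame(terminal = terminal, atom = atom, arc_length = arc)
}

#' Trace a single field line, keeping the polyline
#'
#' Same integrator and termination rules as [trace_field_lines()], recording
#' every vertex.
#'
#' @inheritParams trace_field_lines
#' @param start length-3 start position, angstroms.
#' @return object of class `field_line`: `vertices` (polyline matrix),
#'   `terminal`, `atom`, `arc_length`.
#' @export
trace_field_line <- function(start, model, exclude = NULL, step = 0.05,
                             capture_radius = 0.4, max_length = 200,
                             domain = NULL, stagnation_field = 1e-8) {
  src <- charged_sources(model, exclude)
  if (is.null(domain))
    domain <- rbind(apply(src$pos, 2, min) - 10, apply(src$pos, 2, max) + 10)
  p <- matrix(as.numeric(start), 1, 3)
  verts <- p
  arc <- 0
  terminal <- "stagnated"; atom <- NA_integer_
  uf <- function(pp) {
    E <- coulomb_at(pp, src$pos, src$q, want_phi = FALSE)$E
    nm <- sqrt(sum(E * E))
    list(u = E / max(nm, .Machine$double.xmin), nm = nm)
  }
  nsteps <- ceiling(max_length / step)
  for (s in seq_len(nsteps)) {
    f1 <- uf(p)
    if (f1$nm < stagnation_field) { terminal <- "stagnated"; break }
    k1 <- f1$u
    k2 <- uf(p + (step / 2) * k1)$u
    k3 <- uf(p + (step / 2) * k2)$u
    k4 <- uf(p + step * k3)$u
    p <- p + (step / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    arc <- arc + step
    verts <- rbind(verts, p)
    d <- row_norms(sweep(src$pos, 2, as.numeric(p)))
    if (min(d) < capture_radius) {
      terminal <- "atom"
      atom <- src$id[which.min(d)]
      break
    }
    if (any(p < domain[1, ] | p > domain[2, ])) { terminal <- "escaped"; break }
  }
  structure(list(vertices = verts, terminal = terminal, atom = atom,
                 arc_length = arc), class = "field_line")
}

#' Map nucleophilic influence zones as field-line basins
#'
#' Seeds a field line at every voxel center of the analysis grid (except
#' voxels already inside an atom's capture radius) and labels each voxel by
#' where its line terminates: one of the target atoms (its NIZ), another sink
#' atom, escaped, or stagnated. Basin volumes are voxel counts times the
#' voxel volume.
#'
#' @param model a charged `mol_model`.
#' @param targets atom ids (or a selection string) of the nucleophilic sites
#'   of interest; must be non-empty.
#' @param spec analysis `grid_spec`, or `NULL` to derive one.
#' @param exclude source exclusion (e.g. ligand atoms).
#' @param spacing,margin grid construction when `spec` is `NULL`.
#' @param ... tracer parameters passed to [trace_field_lines()].
#' @return object of class `niz_map`: `spec`, `labels` (character array over
#'   voxels: atom id as character, "other", "escaped", "stagnated",
#'   "source"), `volumes` (data frame per target, cubic angstroms), `result`
#'   (per-seed trace table) and `params`.
#' @export
niz_map <- function(model, targets, spec = NULL, exclude = NULL,
                    spacing = 0.5, margin = 4, ...) {
  if (is.character(targets) && length(targets) == 1 &&
      !targets %in% as.character(model$atoms$id))
    targets <- model$atoms$id[parse_selection(model, targets)]
  targets <- as.integer(targets)
  if (!length(targets)) stop_cz("targets must be non-empty")
  src <- charged_sources(model, exclude)
  if (!all(targets %in% src$id))
    stop_cz("target atom(s) not among the (non-excluded) model atoms")
  if (is.null(spec)) spec <- make_grid_spec(model, spacing, margin)
  pts <- voxel_centers(spec)
  dots <- list(...)
  capture_radius <- dots$capture_radius %||% 0.4
  d2min <- rep(Inf, nrow(pts))
  for (i in seq_along(src$q)) {
    d2 <- (pts[, 1] - src$pos[i, 1])^2 + (pts[, 2] - src$pos[i, 2])^2 +
      (pts[, 3] - src$pos[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  seed <- d2min >= capture_radius^2
  res <- do.call(trace_field_lines,
                 c(list(starts = pts[seed, , drop = FALSE], model = model,
                        exclude = exclude), dots))
  lab <- rep("source", nrow(pts))
  sl <- res$terminal
  sl[sl == "atom"] <- ifelse(res$atom[res$terminal == "atom"] %in% targets,
                             as.character(res$atom[res$terminal == "atom"]),
                             "other")
  lab[seed] <- sl
  vox <- prod(spec$spacing)
  volumes <- data.frame(
    target = targets,
    voxels = vapply(targets, function(t) sum(lab == as.character(t)), numeric(1)))
  volumes$volume <- volumes$voxels * vox
  volumes$fraction_of_seeds <- volumes$voxels / sum(seed)
  structure(list(spec = spec, labels = array(lab, spec$dims),
                 volumes = volumes, result = res,
                 params = c(list(capture_radius = capture_radius), dots),
                 n_seeds = sum(seed)),
            class = "niz_map")
}

#' @export
print.niz_map <- function(x, ...) {
  cat(sprintf("<niz_map> %d seeds over %s grid\n", x$n_seeds,
              paste(x$spec$dims, collapse = "x")))
  print(x$volumes, row.names = FALSE)
  other <- table(x$labels[!x$labels %in% c(as.character(x$volumes$target), "source")])
  if (length(other)) cat("non-target:", paste(names(other), other, sep = "=",
                                              collapse = " "), "\n")
  invisible(x)
}

#' Export a NIZ basin map and volume summary
#'
#' The basin labels are written as a Gaussian cube of integer codes (index
#' into the target list; -1 other sink, -2 escaped, -3 stagnated, -4 inside a
#' capture sphere), and the volume table as JSON.
#'
#' @param map a `niz_map`.
#' @param cube_path path for the label cube (`NULL` to skip).
#' @param json_path path for the volume summary (`NULL` to skip).
#' @return invisible `NULL`.
#' @export
write_niz <- function(map, cube_path = NULL, json_path = NULL) {
  if (!is.null(cube_path)) {
    code <- array(-4, map$spec$dims)
    lab <- map$labels
    code[lab == "other"] <- -1
    code[lab == "escaped"] <- -2
    code[lab == "stagnated"] <- -3
    for (k in seq_len(nrow(map$volumes)))
      code[lab == as.character(map$volumes$target[k])] <- k
    write_cube(scalar_grid(map$spec, code, unit = "basin index"), cube_path,
               comment = "contactzones NIZ basin labels")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(volumes = map$volumes, n_seeds = map$n_seeds,
                              params = map$params,
                              model = "vacuum point-charge Coulomb"),
                         json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(NULL)
}

#' Export a traced field line as a PDB pseudo-atom trace
#' @param line a `field_line`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_line_pdb <- function(line, path) {
  v <- line$vertices
  n <- nrow(v)
  lines <- sprintf(
    "HETATM%5d  X   FLN A%4d    %8.3f%8.3f%8.3f  1.00  0.00           X",
    seq_len(n) %% 100000, rep(1, n), v[, 1], v[, 2], v[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}
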
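# End-to-end pipelines wiring the modules together, with machine-readable
# provenance records. These functions back the command-line front-end in
# inst/cli/contactzones.R.

provenance <- function(parameters) {
  list(tool = "contactzones",
       version = as.character(utils::packageVersion("contactzones")),
       parameters = parameters,
       substitutions = c(
         "spherical promolecule densities (sum-of-exponential shells)",
         "vacuum point-charge electrostatics"),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_provenance <- function(parameters, path) {
  jsonlite::write_json(provenance(parameters), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

resolve_side <- function(config, key, selkey, default_side) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (is.null(config$structure)) stop_cz("config needs '", key,
                                         "' or 'structure'")
  model <- if (inherits(config$structure, "mol_model")) config$structure
  else read_structure(config$structure)
  idx <- parse_selection(model, config[[selkey]])
  if (!length(idx)) stop_cz("selection '", config[[selkey]],
                            "' matches no atoms")
  model_subset(model, idx, side = default_side)
}

has_standard_residues <- function(model) {
  std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  any(model$atoms$resname %in% std)
}

prepare_side <- function(model, place_h) {
  model <- filter_altloc(model)
  if (has_standard_residues(model) && !any(model$atoms$element == "H")) {
    if (!place_h)
      stop_cz("side '", model$side, "' has no hydrogen atoms; supply a ",
              "protonated model or set place_hydrogens = TRUE")
    model <- place_hydrogens(model)
  }
  assign_interaction_types(model)
}

#' Run the interface contact-enrichment pipeline
#'
#' Reads/receives the two sides, optionally merges listed structural waters
#' into side b, types the atoms, builds the Hirshfeld interface, and writes
#' the contact table (TSV + JSON), the facet table and a provenance record.
#'
#' @param config named list. Model input: either `side_a`/`side_b`
#'   (`mol_model`s) or `structure` (path or model) with selection strings
#'   `sel_a`/`sel_b`. Options: `waters` (selection merged into side b),
#'   `place_hydrogens` (default `FALSE`), `spacing`, `density_cutoff`,
#'   `cutoff_on`, `refine_depth`, `assign_rule` (see [build_interface()]),
#'   `outdir` (default: no files written).
#' @return the `contact_table`, invisibly; attribute `patches` carries the
#'   interface.
#' @export
run_enrich <- function(config) {
  side_a <- resolve_side(config, "side_a", "sel_a", "a")
  side_b <- resolve_side(config, "side_b", "sel_b", "b")
  atom_sig <- function(m) paste(m$atoms$chain, m$atoms$resno, m$atoms$name,
                                round(m$atoms$x, 3), round(m$atoms$y, 3),
                                round(m$atoms$z, 3))
  shared <- intersect(atom_sig(side_a), atom_sig(side_b))
  if (length(shared)) stop_cz("side selections overlap (e.g. ", shared[1], ")")
  place_h <- isTRUE(config$place_hydrogens)
  side_a <- prepare_side(side_a, place_h)
  side_b <- prepare_side(side_b, place_h)
  if (!is.null(config$waters)) {
    src <- if (inherits(config$structure, "mol_model")) config$structure
    else read_structure(config$structure)
    widx <- parse_selection(src, config$waters)
    if (length(widx)) {
      w <- assign_interaction_types(filter_altloc(model_subset(src, widx)))
      side_b <- merge_models(side_b, w)
    }
  }
  patches <- build_interface(
    side_a, side_b,
    spacing = config$spacing %||% 0.2,
    density_cutoff = config$density_cutoff %||% 0.0013,
    cutoff_on = config$cutoff_on %||% "total",
    refine_depth = config$refine_depth %||% 2,
    assign_rule = config$assign_rule %||% "density")
  if (!n_facets(patches)) {
    warning("empty interface: no contact statistics computed")
    return(invisible(structure(list(), patches = patches)))
  }
  tbl <- contact_table(patches)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_contact_table(tbl, file.path(config$outdir, "contact_table.tsv"))
    write_contact_table(tbl, file.path(config$outdir, "contact_table.json"),
                        format = "json")
    write_patch_tsv(patches, file.path(config$outdir, "patches.tsv"))
    write_provenance(config[!vapply(config, is.object, logical(1))],
                     file.path(config$outdir, "provenance.json"))
  }
  attr(tbl, "patches") <- patches
  invisible(tbl)
}

#' Run the nucleophilic-influence-zone pipeline
#'
#' Assigns charges, maps field-line basins for the requested target atoms and
#' writes the basin cube, volume summary and provenance.
#'
#' @param config named list: `model` (charged or typed `mol_model`) or
#'   `structure` (path); `targets` (atom ids or selection string);
#'   `exclude` (selection removed from sources, e.g. the ligand);
#'   `charge_table`, `spacing`, `margin`, tracer parameters `step`,
#'   `capture_radius`, `max_length`; `outdir`.
#' @return the `niz_map`, invisibly.
#' @export
run_niz <- function(config) {
  model <- config$model %||% read_structure(config$structure)
  if (is.null(model$atoms$charge))
    model <- assign_charges(model, config$charge_table)
  args <- list(model = model, targets = config$targets,
               exclude = config$exclude,
               spacing = config$spacing %||% 0.5,
               margin = config$margin %||% 4)
  for (p in c("step", "capture_radius", "max_length"))
    if (!is.null(config[[p]])) args[[p]] <- config[[p]]
  if (!is.null(config$spec)) args$spec <- config$spec
  map <- do.call(niz_map, args)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_niz(map, cube_path = file.path(config$outdir, "niz_basins.cube"),
              json_path = file.path(config$outdir, "niz_volumes.json"))
    write_provenance(config[!vapply(config, is.object, logical(1))],
                     file.path(config$outdir, "provenance.json"))
  }
  invisible(map)
}

#' Run the fluctuation-analytics pipeline
#'
#' Computes a per-residue RMSF profile from an ensemble and/or an RMSTD
#' profile from a B-factor-bearing structure; when both are present on a
#' common residue set their Pearson correlation is reported.
#'
#' @param config named list: `ensemble` (a `mol_ensemble` or multi-model PDB
#'   path), `structure` (a `mol_model` or path), `selection` (e.g.
#'   `"calpha"`, default), `align_selection`, `outdir`.
#' @return list with `rmsf`, `rmstd` (fluctuation profiles or `NULL`) and
#'   `correlation` (Pearson r or `NA`), invisibly.
#' @export
run_flucts <- function(config) {
  ens <- config$ensemble
  if (is.character(ens)) ens <- read_structure(ens)
  model <- config$structure
  if (is.character(model)) model <- read_structure(model)
  sel <- config$selection %||% "calpha"
  prof_f <- prof_t <- NULL
  if (!is.null(ens)) {
    if (!inherits(ens, "mol_ensemble")) stop_cz("'ensemble' must be multi-model")
    prof_f <- rmsf(ens, selection = sel,
                   align_selection = config$align_selection)
  }
  if (!is.null(model)) prof_t <- rmstd_profile(model, selection = NULL)
  r <- NA_real_
  if (!is.null(prof_f) && !is.null(prof_t)) {
    key_f <- paste(prof_f$chain, prof_f$resno)
    key_t <- paste(prof_t$chain, prof_t$resno)
    common <- intersect(key_f, key_t)
    if (length(common) < 3) {
      if (!is.null(ens) && !is.null(model) &&
          dim(ens$xyz)[1] != n_atoms(model))
        stop_cz("ensemble roster does not match structure (",
                dim(ens$xyz)[1], " vs ", n_atoms(model), " atoms)")
    } else {
      r <- correlate_profiles(prof_f$value[match(common, key_f)],
                              prof_t$value[match(common, key_t)])
    }
  }
  out <- list(rmsf = prof_f, rmstd = prof_t, correlation = r)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(prof_f))
      write.table(prof_f, file.path(config$outdir, "rmsf.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(prof_t))
      write.table(prof_t, file.path(config$outdir, "rmstd.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.na(r))
      jsonlite::write_json(list(pearson_r = r),
                           file.path(config$outdir, "correlation.json"),
                           auto_unbox = TRUE, digits = NA)
    write_provenance(config[!vapply(config, is.object, logical(1))],
                     file.path(config$outdir, "provenance.json"))
  }
  invisible(out)
}
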
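# Surface compositions, contact proportions, equiprobable contacts and
# enrichment ratios on a Hirshfeld interface, with the hydrophobic/
# hydrophilic grouping.

#' The chemical interaction types used for contact statistics
#'
#' @return character vector `c("C", "Hc", "N", "Ho/n", "O", "W")`:
#'   carbon, carbon-bound hydrogen, nitrogen, nitrogen/oxygen-bound hydrogen,
#'   oxygen, and water oxygen.
#' @export
contact_types <- function() c("C", "Hc", "N", "Ho/n", "O", "W")

#' Default hydrophobic/hydrophilic grouping of the contact types
#'
#' Carbon, carbon-bound hydrogens and the lone-pair-free sp2 nitrogens are
#' grouped as hydrophobic; polar hydrogens, oxygens and water oxygens as
#' hydrophilic.
#'
#' @return named list of type vectors.
#' @export
default_grouping <- function() {
  list(Hphob = c("C", "Hc", "N"), Hphil = c("Ho/n", "O", "W"))
}

# canonical unordered pair key "X|Y" with X before Y in the given type order
pair_key <- function(x, y, types = contact_types()) {
  ix <- match(x, types); iy <- match(y, types)
  if (anyNA(ix) || anyNA(iy))
    stop_cz("unknown contact type: ",
            paste(unique(c(x[is.na(ix)], y[is.na(iy)])), collapse = ", "))
  ifelse(ix <= iy, paste(x, y, sep = "|"), paste(y, x, sep = "|"))
}

all_pair_keys <- function(types = contact_types()) {
  n <- length(types)
  out <- character(0)
  for (i in seq_len(n)) for (j in i:n)
    out <- c(out, paste(types[i], types[j], sep = "|"))
  out
}

full_vec <- function(x, keys) {
  out <- setNames(numeric(length(keys)), keys)
  if (!is.null(x)) {
    if (is.null(names(x))) stop_cz("expected a named vector")
    unknown <- setdiff(names(x), keys)
    if (length(unknown)) stop_cz("unknown name(s): ", paste(unknown, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

#' Chemical composition of one side of the interface
#'
#' `S_X` = percentage of the interface area whose facet on the requested side
#' is assigned to an atom of type X.
#'
#' @param patches an `interface_patches` with facet types filled.
#' @param side `"a"` (interior) or `"b"` (exterior).
#' @return named percentage vector over [contact_types()], summing to 100.
#' @export
surface_composition <- function(patches, side = c("a", "b")) {
  side <- match.arg(side)
  if (!n_facets(patches)) stop_cz("patch set is empty")
  ty <- if (side == "a") patches$type_in else patches$type_out
  if (anyNA(ty) || any(!nzchar(ty)))
    stop_cz("untyped facet atom encountered (facet ",
            which(is.na(ty) | !nzchar(ty))[1], "); type the models first")
  bad <- setdiff(unique(ty), contact_types())
  if (length(bad)) stop_cz("unknown contact type: ", bad[1])
  s <- tapply(patches$area, factor(ty, levels = contact_types()), sum,
              default = 0)
  100 * as.numeric(s) / patches$total_area -> out
  setNames(out, contact_types())
}

#' Observed contact proportions on the interface
#'
#' `C_{X,Y}` = percentage of the interface area whose facets join an atom of
#' type X on one side with type Y on the other, pooled over the unordered
#' pair.
#'
#' @param patches an `interface_patches` with facet types filled.
#' @return named percentage vector over unordered type pairs (`"X|Y"` keys),
#'   summing to 100.
#' @export
contact_proportions <- function(patches) {
  if (!n_facets(patches)) stop_cz("patch set is empty")
  key <- pair_key(patches$type_in, patches$type_out)
  keys <- all_pair_keys()
  cc <- tapply(patches$area, factor(key, levels = keys), sum, default = 0)
  setNames(100 * as.numeric(cc) / patches$total_area, keys)
}

#' Equiprobable (random-mixing) contact proportions
#'
#' Probability products of the two sides' surface compositions:
#' `R_{X,Y} = (S_a[X] S_b[Y] + S_a[Y] S_b[X]) / 100` for X != Y and
#' `R_{X,X} = S_a[X] S_b[X] / 100`. If the two compositions each sum to 100,
#' so does R.
#'
#' @param S_a,S_b named percentage vectors over [contact_types()] (missing
#'   types count as 0).
#' @return named percentage vector over unordered type pairs.
#' @export
random_contacts <- function(S_a, S_b) {
  types <- contact_types()
  sa <- full_vec(S_a, types)
  sb <- full_vec(S_b, types)
  if (any(sa < 0) || any(sb < 0)) stop_cz("surface compositions must be >= 0")
  for (nm in c("S_a", "S_b")) {
    s <- if (nm == "S_a") sa else sb
    if (abs(sum(s) - 100) > 0.5)
      warning(nm, " sums to ", round(sum(s), 2), ", expected 100")
  }
  keys <- all_pair_keys()
  out <- setNames(numeric(length(keys)), keys)
  n <- length(types)
  for (i in seq_len(n)) for (j in i:n) {
    k <- paste(types[i], types[j], sep = "|")
    out[k] <- if (i == j) sa[i] * sb[i] / 100
    else (sa[i] * sb[j] + sa[j] * sb[i]) / 100
  }
  out
}

#' Contact enrichment ratios
#'
#' `E = C / R` wherever the random-mixing proportion R exceeds `eps`
#' (default 0.05 percentage points); pairs with `R <= eps` are undefined and
#' reported as `NA` (or 0 with `undefined = "zero"`, matching tabulated
#' presentations that print 0 for impossible self-contacts).
#'
#' @param C observed contact proportions (named over pair keys).
#' @param R equiprobable proportions from [random_contacts()].
#' @param eps definability threshold on R, percentage points.
#' @param undefined `"na"` or `"zero"`.
#' @return named vector of enrichment ratios over the keys of `R`.
#' @export
enrichment <- function(C, R, eps = 0.05, undefined = c("na", "zero")) {
  undefined <- match.arg(undefined)
  keys <- names(R)
  extra <- setdiff(names(C), keys)
  if (length(extra)) stop_cz("C has pairs absent from R: ", extra[1])
  cc <- full_vec(C, keys)
  e <- ifelse(R > eps, cc / ifelse(R > 0, R, NA_real_), NA_real_)
  if (undefined == "zero") e[is.na(e)] <- 0
  setNames(e, keys)
}

#' Full contact table from an interface patch set
#'
#' Convenience wrapper computing side compositions, observed and equiprobable
#' contact proportions, enrichment ratios and the grouped hydrophobic/
#' hydrophilic summary in one object.
#'
#' @param patches an `interface_patches` with facet types filled.
#' @param grouping type grouping for the summary block (see
#'   [default_grouping()]).
#' @param eps definability threshold passed to [enrichment()].
#' @return an object of class `contact_table` with fields `S_a`, `S_b`, `C`,
#'   `R`, `E`, `grouped` and `meta`.
#' @export
contact_table <- function(patches, grouping = default_grouping(), eps = 0.05) {
  S_a <- surface_composition(patches, "a")
  S_b <- surface_composition(patches, "b")
  C <- contact_proportions(patches)
  contact_table_from_composition(S_a, S_b, C, grouping = grouping, eps = eps,
                                 meta = patches$meta)
}

#' Contact table from given compositions and contact proportions
#'
#' Builds the same object as [contact_table()] directly from surface
#' compositions and observed contact proportions, e.g. published values.
#'
#' @param S_a,S_b named surface compositions (percent per type).
#' @param C named observed contact proportions (percent per `"X|Y"` pair).
#' @param grouping,eps see [contact_table()].
#' @param meta optional metadata list.
#' @return a `contact_table`.
#' @export
contact_table_from_composition <- function(S_a, S_b, C,
                                           grouping = default_grouping(),
                                           eps = 0.05, meta = list()) {
  S_a <- full_vec(S_a, contact_types())
  S_b <- full_vec(S_b, contact_types())
  C <- full_vec(C, all_pair_keys())
  R <- random_contacts(S_a, S_b)
  E <- enrichment(C, R, eps = eps)
  tbl <- structure(list(S_a = S_a, S_b = S_b, C = C, R = R, E = E,
                        grouped = NULL, meta = meta),
                   class = "contact_table")
  tbl$grouped <- group_hydrophobic(tbl, grouping = grouping, eps = eps)
  tbl
}

#' Group contact statistics into hydrophobic/hydrophilic classes
#'
#' Sums member surface shares and contact shares per group, then applies the
#' same probability-product and ratio formulas to the grouped values. The
#' grouping must partition the type set. A degenerate grouping with one group
#' per type reproduces the ungrouped table.
#'
#' @param table a `contact_table`.
#' @param grouping named list of type vectors partitioning [contact_types()].
#' @param eps definability threshold passed to [enrichment()].
#' @return list with grouped `S_a`, `S_b`, `C`, `R`, `E` (named over groups
#'   and group pairs).
#' @export
group_hydrophobic <- function(table, grouping = default_grouping(),
                              eps = 0.05) {
  members <- unlist(grouping, use.names = FALSE)
  if (length(members) != length(contact_types()) ||
      !setequal(members, contact_types()) || anyDuplicated(members))
    stop_cz("grouping must partition the contact type set")
  gnames <- names(grouping)
  gof <- function(ty) gnames[vapply(gnames, function(g) ty %in% grouping[[g]],
                                    logical(1))]
  gmap <- vapply(contact_types(), gof, character(1))
  gS <- function(S) {
    out <- setNames(numeric(length(gnames)), gnames)
    for (g in gnames) out[g] <- sum(S[grouping[[g]]])
    out
  }
  S_a <- gS(table$S_a); S_b <- gS(table$S_b)
  # grouped observed contacts: pool pair shares by their groups
  ng <- length(gnames)
  gkeys <- character(0)
  for (i in seq_len(ng)) for (j in i:ng)
    gkeys <- c(gkeys, paste(gnames[i], gnames[j], sep = "|"))
  C <- setNames(numeric(length(gkeys)), gkeys)
  types <- contact_types()
  for (i in seq_along(types)) for (j in i:length(types)) {
    key <- paste(types[i], types[j], sep = "|")
    gi <- gmap[[types[i]]]; gj <- gmap[[types[j]]]
    oi <- match(gi, gnames); oj <- match(gj, gnames)
    gk <- if (oi <= oj) paste(gi, gj, sep = "|") else paste(gj, gi, sep = "|")
    C[gk] <- C[gk] + table$C[key]
  }
  R <- setNames(numeric(length(gkeys)), gkeys)
  for (i in seq_len(ng)) for (j in i:ng) {
    k <- paste(gnames[i], gnames[j], sep = "|")
    R[k] <- if (i == j) S_a[i] * S_b[i] / 100
    else (S_a[i] * S_b[j] + S_a[j] * S_b[i]) / 100
  }
  E <- ifelse(R > eps, C / ifelse(R > 0, R, NA_real_), NA_real_)
  list(S_a = S_a, S_b = S_b, C = C, R = R, E = setNames(E, gkeys))
}

#' @export
print.contact_table <- function(x, digits_share = 1, digits_e = 2, ...) {
  types <- contact_types()
  fmt <- function(v, d) formatC(round(v, d), format = "f", digits = d, width = 6)
  cat("Interface contact statistics (percent of interface area)\n")
  cat(sprintf("%-10s%s\n", "type", paste(formatC(types, width = 6), collapse = " ")))
  cat(sprintf("%-10s%s\n", "S side a", paste(fmt(x$S_a, digits_share), collapse = " ")))
  cat(sprintf("%-10s%s\n", "S side b", paste(fmt(x$S_b, digits_share), collapse = " ")))
  block <- function(v, d, label) {
    cat(label, "\n")
    for (i in seq_along(types)) {
      row <- vapply(i:length(types), function(j)
        v[paste(types[i], types[j], sep = "|")], numeric(1))
      cat(sprintf("%-6s%s%s\n", types[i],
                  strrep("       ", i - 1), paste(fmt(row, d), collapse = " ")))
    }
  }
  block(x$C, digits_share, "C (observed contacts)")
  e <- x$E; e[is.na(e)] <- 0
  block(e, digits_e, "E (enrichment; undefined printed as 0)")
  g <- x$grouped
  cat("grouped:", paste(names(g$S_a), fmt(g$S_a, 1), collapse = " "),
      "(side a) |", paste(names(g$S_b), fmt(g$S_b, 1), collapse = " "),
      "(side b)\n")
  cat("grouped E:", paste(names(g$E), fmt(g$E, 2), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a contact table
#'
#' TSV output mirrors the tabulated layout (surface rows, observed-contact
#' triangle, enrichment triangle, grouped block; shares rounded to one
#' decimal, enrichments to two). JSON output carries full precision.
#'
#' @param table a `contact_table`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(S_a = as.list(round(table$S_a, 4)),
                S_b = as.list(round(table$S_b, 4)),
                C = as.list(round(table$C, 4)), R = as.list(round(table$R, 4)),
                E = as.list(round(table$E, 4)),
                grouped = lapply(table$grouped, function(v) as.list(round(v, 4))),
                meta = table$meta)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  types <- contact_types()
  con <- file(path, "w")
  on.exit(close(con))
  line <- function(...) writeLines(paste(..., sep = "\t"), con)
  line("atom_type", paste(types, collapse = "\t"))
  line("surface_a", paste(round(table$S_a, 1), collapse = "\t"))
  line("surface_b", paste(round(table$S_b, 1), collapse = "\t"))
  tri <- function(v, d, label) {
    line(label)
    for (i in seq_along(types)) {
      row <- vapply(i:length(types), function(j)
        v[paste(types[i], types[j], sep = "|")], numeric(1))
      line(types[i], paste(c(rep("", i - 1), round(row, d)), collapse = "\t"))
    }
  }
  tri(table$C, 1, "C_XY_percent")
  e <- table$E; e[is.na(e)] <- 0
  tri(e, 2, "E_XY")
  g <- table$grouped
  line("group", paste(names(g$S_a), collapse = "\t"))
  line("surface_a", paste(round(g$S_a, 1), collapse = "\t"))
  line("surface_b", paste(round(g$S_b, 1), collapse = "\t"))
  line("contacts", paste(names(g$C), collapse = "\t"))
  line("C_percent", paste(round(g$C, 1), collapse = "\t"))
  line("E", paste(round(g$E, 2), collapse = "\t"))
  invisible(path)
}

#' Published interface composition of the NRP1-b1/KDKPPR complex
#'
#' Surface compositions and observed contact proportions on the Hirshfeld
#' interface between the PPR moiety of the KDKPPR peptide (side a) and the
#' neuropilin-1 b1 domain with four structural waters (side b), as tabulated
#' for the deposited crystal structure of the complex. Shares are percent of
#' the interface area, one-decimal precision.
#'
#' @return list with `S_a` (peptide side), `S_b` (protein side) and `C`
#'   (observed contact proportions over `"X|Y"` pair keys).
#' @export
kdkppr_reference_composition <- function() {
  tab <- read.table(cz_extdata("nrp1b1_kdkppr_interface_composition.tsv"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  s <- tab[tab$block == "surface", ]
  S_a <- setNames(s$value[s$row == "peptide"], s$col[s$row == "peptide"])
  S_b <- setNames(s$value[s$row == "protein"], s$col[s$row == "protein"])
  cc <- tab[tab$block == "contacts", ]
  C <- setNames(cc$value, pair_key(cc$row, cc$col))
  list(S_a = full_vec(S_a, contact_types()),
       S_b = full_vec(S_b, contact_types()), C = full_vec(C, all_pair_keys()))
}
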
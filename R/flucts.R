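# Ensemble and crystallographic fluctuation analytics: Kabsch superposition,
# RMSD series, RMSF profiles, RMSTD from B factors, profile correlation.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD of
#' `mobile` onto `reference` (SVD solution; a reflection-requiring case is
#' resolved to the best proper rotation). The transform maps a point x to
#' `x %*% rotation + translation`.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, equal sizes.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (angstroms, weighted) and `xyz` (transformed mobile coordinates).
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(x, x)$rmsd
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop_cz("mobile and reference must have matching dimensions")
  n <- nrow(mobile)
  if (n < 3) stop_cz("need at least 3 points")
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w < 0)) stop_cz("invalid weights")
  sw <- sum(w)
  cm <- colSums(mobile * w) / sw
  cr <- colSums(reference * w) / sw
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  xyz <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((xyz - Y)^2)) / sw)
  xyz <- sweep(xyz, 2, cr, `+`)
  list(rotation = R, translation = cr - as.numeric(cm %*% R), rmsd = rmsd,
       xyz = xyz)
}

#' Root mean square deviation between two coordinate sets
#' @param a,b n x 3 matrices.
#' @param weights optional per-point weights.
#' @param fit superpose `a` onto `b` first (default `TRUE`).
#' @return RMSD in angstroms.
#' @export
rmsd <- function(a, b, weights = NULL, fit = TRUE) {
  if (fit) return(kabsch_superpose(a, b, weights)$rmsd)
  w <- weights %||% rep(1, nrow(a))
  sqrt(sum(w * rowSums((a - b)^2)) / sum(w))
}

resolve_selection_idx <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.character(selection))
    return(parse_selection(mol_model(atoms), selection))
  as.integer(selection)
}

#' Per-frame RMSD series of an ensemble
#'
#' Each frame is superposed onto the reference on the selection, and the RMSD
#' of the selection reported — the usual trajectory drift monitor (e.g. on
#' backbone heavy atoms relative to the initial crystallographic structure).
#'
#' @param ensemble a `mol_ensemble`.
#' @param reference a `mol_model` on the same roster, or a frame index
#'   (default 1).
#' @param selection atom selection (indices or selection string, e.g.
#'   `"backbone"`); must be non-empty.
#' @return numeric vector of per-frame RMSD values, angstroms.
#' @export
rmsd_series <- function(ensemble, reference = 1L, selection = NULL) {
  idx <- resolve_selection_idx(ensemble$atoms, selection)
  if (!length(idx)) stop_cz("empty selection")
  ref <- if (inherits(reference, "mol_model")) {
    if (n_atoms(reference) != dim(ensemble$xyz)[1])
      stop_cz("reference roster does not match ensemble")
    coords(reference)
  } else ensemble$xyz[, , as.integer(reference)]
  vapply(seq_len(n_frames(ensemble)), function(k)
    kabsch_superpose(ensemble$xyz[idx, , k], ref[idx, , drop = FALSE])$rmsd,
    numeric(1))
}

#' Per-atom root mean square fluctuation profile
#'
#' Frames are first superposed on `align_selection` onto the reference frame
#' (removing rigid-body drift), then each atom's RMSF is computed as
#' `sqrt(mean |r - center|^2)` over frames, where the center is the ensemble
#' mean position (`about = "mean"`, default) or the reference position
#' (`about = "reference"`).
#'
#' @param ensemble a `mol_ensemble` with >= 2 frames.
#' @param selection atoms to report (indices or selection string); default all.
#' @param align_selection atoms used for the superposition (default
#'   `"backbone"` when present, else all).
#' @param align superpose frames before measuring (default `TRUE`).
#' @param about `"mean"` or `"reference"`.
#' @param reference reference frame index for alignment/centering.
#' @return a `fluctuation_profile` data frame: atom identifiers plus `value`
#'   (angstroms), with attribute `kind = "RMSF"`.
#' @export
rmsf <- function(ensemble, selection = NULL, align_selection = NULL,
                 align = TRUE, about = c("mean", "reference"),
                 reference = 1L) {
  about <- match.arg(about)
  if (n_frames(ensemble) < 2) stop_cz("need at least 2 frames")
  atoms <- ensemble$atoms
  idx <- resolve_selection_idx(atoms, selection)
  if (!length(idx)) stop_cz("empty selection")
  xyz <- ensemble$xyz
  if (align) {
    aidx <- if (!is.null(align_selection))
      resolve_selection_idx(atoms, align_selection)
    else {
      bb <- which(atoms$name %in% c("N", "CA", "C", "O") &
                    !is_water_resname(atoms$resname))
      if (length(bb) >= 3) bb else seq_len(nrow(atoms))
    }
    ref <- xyz[aidx, , reference, drop = FALSE][, , 1]
    for (k in seq_len(n_frames(ensemble))) {
      fit <- kabsch_superpose(xyz[aidx, , k], ref)
      xyz[, , k] <- sweep(xyz[, , k] %*% fit$rotation, 2, fit$translation, `+`)
    }
  }
  sub <- xyz[idx, , , drop = FALSE]
  center <- if (about == "mean") apply(sub, c(1, 2), mean)
  else sub[, , reference]
  # dev2 has dims (n_idx, 3, n_frames); RMSF is the frame-mean squared
  # 3-D displacement per atom
  dev2 <- (sub - array(center, dim(sub)))^2
  val <- sqrt(apply(dev2, 1, sum) / n_frames(ensemble))
  out <- data.frame(atoms[idx, c("id", "name", "resname", "resno", "chain")],
                    value = val)
  attr(out, "kind") <- "RMSF"
  class(out) <- c("fluctuation_profile", class(out))
  out
}

#' Root mean square thermal displacement from a B factor
#'
#' `RMSTD = sqrt(B / (8 pi^2))`, the isotropic mean displacement implied by a
#' crystallographic thermal parameter.
#'
#' @param b B factor(s), squared angstroms (>= 0).
#' @return displacement(s), angstroms.
#' @examples
#' rmstd_from_b(8 * pi^2)  # 1 angstrom
#' @export
rmstd_from_b <- function(b) {
  if (any(b < 0)) stop_cz("B factors must be >= 0")
  sqrt(b / (8 * pi^2))
}

#' Inverse of [rmstd_from_b()]
#' @param rmstd displacement(s), angstroms (>= 0).
#' @return B factor(s), squared angstroms.
#' @export
b_from_rmstd <- function(rmstd) {
  if (any(rmstd < 0)) stop_cz("displacements must be >= 0")
  8 * pi^2 * rmstd^2
}

#' Per-residue RMSTD profile from a model's B factors
#'
#' Reports the C-alpha atoms of the selection; residues without a C-alpha are
#' skipped with a warning.
#'
#' @param model a `mol_model` with B factors.
#' @param selection optional atom selection restricting the residues.
#' @return a `fluctuation_profile` with attribute `kind = "RMSTD"`.
#' @export
rmstd_profile <- function(model, selection = NULL) {
  idx <- resolve_selection_idx(model$atoms, selection)
  a <- model$atoms[idx, , drop = FALSE]
  res <- unique(a[, c("chain", "resno")])
  ca <- a[a$name == "CA", , drop = FALSE]
  missing <- nrow(res) - nrow(unique(ca[, c("chain", "resno")]))
  if (missing > 0)
    warning(missing, " residue(s) without a C-alpha atom skipped")
  out <- data.frame(ca[, c("id", "name", "resname", "resno", "chain")],
                    value = rmstd_from_b(ca$b))
  attr(out, "kind") <- "RMSTD"
  class(out) <- c("fluctuation_profile", class(out))
  out
}

#' Pearson correlation between two fluctuation profiles
#'
#' @param p1,p2 `fluctuation_profile` objects or plain numeric vectors of
#'   equal length >= 3 with nonzero variance.
#' @return Pearson r in `[-1, 1]`.
#' @export
correlate_profiles <- function(p1, p2) {
  v1 <- if (is.data.frame(p1)) p1$value else as.numeric(p1)
  v2 <- if (is.data.frame(p2)) p2$value else as.numeric(p2)
  if (length(v1) != length(v2)) stop_cz("profiles differ in length")
  if (length(v1) < 3) stop_cz("need at least 3 points")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_cz("correlation undefined: a profile has zero variance")
  stats::cor(v1, v2)
}
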
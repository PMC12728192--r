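# ---------------------------------------------------------------------------
# Kabsch least-squares rigid superposition and RMSD reporting.
# ---------------------------------------------------------------------------

# Least-squares rigid transform mapping point set xb onto xa (k x 3 each).
# Returns list(rotation, translation): x' = R x + t. Reflections excluded.
.kabsch <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  A <- sweep(xa, 2, ca); B <- sweep(xb, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(ca - R %*% cb)
  list(rotation = R, translation = t_vec)
}

.apply_rt <- function(x, rotation, translation) {
  sweep(x %*% t(rotation), 2, translation, "+")
}

#' Apply a rigid transform to all models of a structure
#'
#' @param s structure.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return transformed structure.
#' @export
transform_structure <- function(s, rotation, translation) {
  x <- as.matrix(s$atoms[, c("x", "y", "z")])
  x <- .apply_rt(x, rotation, translation)
  s$atoms$x <- x[, 1]; s$atoms$y <- x[, 2]; s$atoms$z <- x[, 3]
  s
}

.rmsd_points <- function(xa, xb) {
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Kabsch superposition of one structure onto another
#'
#' Computes the least-squares rigid transform (rotation + translation,
#' reflection excluded) of `b` onto `a` over the corresponding atoms named in
#' `atom_names`, and the RMSD of the paired atoms after the transform.
#'
#' @param a reference structure.
#' @param b moving structure.
#' @param corr a [build_correspondence()] or [explicit_correspondence()].
#' @param atom_names atoms used for the fit (default `"CA"`).
#' @return list of class `gatescope_superposition` with elements `rotation`
#'   (3x3, orthonormal, det +1), `translation`, `rmsd` (Angstrom), `n_pairs`.
#' @export
kabsch_superpose <- function(a, b, corr, atom_names = "CA") {
  pc <- .paired_coords(a, b, corr, atom_names)
  if (nrow(pc$xa) < 3)
    stop("insufficient pairs for superposition: need >= 3, have ", nrow(pc$xa))
  # collinearity check: rank of centered coordinates
  cen <- sweep(pc$xb, 2, colMeans(pc$xb))
  sv0 <- svd(cen)
  if (sum(sv0$d > 1e-8 * max(sv0$d, 1)) < 2)
    warning("degenerate (collinear) point set; superposition is not unique")
  rt <- .kabsch(pc$xa, pc$xb)
  xb2 <- .apply_rt(pc$xb, rt$rotation, rt$translation)
  res <- list(rotation = rt$rotation, translation = rt$translation,
              rmsd = .rmsd_points(pc$xa, xb2), n_pairs = nrow(pc$xa))
  class(res) <- "gatescope_superposition"
  res
}

#' @export
print.gatescope_superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, RMSD %.4f A\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' RMSD over a reporting selection after fitting on another
#'
#' Superposes `b` onto `a` using the pairs restricted to `fit_sel` (or `sel`
#' if `fit_sel` is NULL), then reports the RMSD over the pairs restricted to
#' `sel`. Symmetric in `(a, b)` to numerical precision because the fit is
#' least-squares.
#'
#' @param a,b structures.
#' @param corr residue correspondence.
#' @param sel [selection()] defining the atoms RMSD is reported over.
#' @param fit_sel optional [selection()] defining the atoms used for the fit.
#' @return RMSD in Angstrom.
#' @export
rmsd_subset <- function(a, b, corr, sel, fit_sel = NULL) {
  if (is.null(fit_sel)) fit_sel <- sel
  af <- select_atoms(a, fit_sel); bf <- select_atoms(b, fit_sel)
  an <- unique(af$atoms$name)
  fitres <- kabsch_superpose(af, bf, corr, atom_names = an)
  ar <- select_atoms(a, sel); br <- select_atoms(b, sel)
  pc <- .paired_coords(ar, br, corr, atom_names = unique(ar$atoms$name))
  if (nrow(pc$xa) < 1) stop("no report pairs under selection")
  xb2 <- .apply_rt(pc$xb, fitres$rotation, fitres$translation)
  .rmsd_points(pc$xa, xb2)
}
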
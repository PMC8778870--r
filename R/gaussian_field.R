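## Theoretical hydrophobicity field: a 3D Gaussian spread over the body of
## the molecule, maximal at the centre and ~0 on the surface (all residues
## lie within 3 sigma of the centre along each principal axis).

#' Fit the 3D Gaussian field to a structure
#'
#' The field is centred on the mean of the effective atoms, oriented along
#' the principal axes of the point cloud, and sized so that every residue
#' lies within the 3-sigma ellipsoid: along each principal axis j,
#' `sigma_j = max(|coordinate_j|) * (1 + sigma_margin) / 3` after centering
#' and rotation.  Axes are ordered by decreasing variance and their signs
#' fixed (first non-zero loading positive) so the rotation is deterministic.
#'
#' @param structure an `"eff_structure"` (or `"fod_atoms"`).
#' @param sigma_margin fractional margin added to the extent before the
#'   division by 3 (default 0: the surface sits exactly at 3 sigma).
#' @param sigma_floor lower bound in Angstrom applied to each sigma; flat or
#'   elongated fragments with near-zero extent along an axis are floored
#'   with a warning rather than producing a degenerate field.
#' @return an object of class `"gaussian_field"`: list with `center` (xyz),
#'   `rotation` (3x3 orthonormal, molecule frame -> principal frame) and
#'   `sigmas` (3 positive values, Angstrom).
#' @export
fit_gaussian <- function(structure, sigma_margin = 0, sigma_floor = 1.0) {
  es <- as_eff_structure(structure)
  pts <- eff_points(es)
  if (nrow(pts) < 3)
    fodm_stop("need at least 3 effective points to fit the Gaussian field",
              "fodm_geometry_error")
  center <- colMeans(pts)
  x <- sweep(pts, 2, center)
  if (max(abs(x)) < 1e-8)
    fodm_stop("all effective points coincide; Gaussian field undefined",
              "fodm_geometry_error")
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  rot <- ev$vectors                      # columns = principal axes
  # deterministic sign: first loading of magnitude > tol positive
  for (j in 1:3) {
    v <- rot[, j]
    k <- which(abs(v) > 1e-8)[1]
    if (!is.na(k) && v[k] < 0) rot[, j] <- -v
  }
  xp <- x %*% rot
  extent <- apply(abs(xp), 2, max)
  sigmas <- extent * (1 + sigma_margin) / 3
  if (any(sigmas < sigma_floor)) {
    fodm_warn(sprintf(
      "degenerate extent along %d axis/axes; sigma floored at %.1f A",
      sum(sigmas < sigma_floor), sigma_floor))
    sigmas <- pmax(sigmas, sigma_floor)
  }
  structure(list(center = center, rotation = rot, sigmas = sigmas),
            class = "gaussian_field")
}

#' @export
print.gaussian_field <- function(x, ...) {
  cat(sprintf("<gaussian_field> center (%.2f, %.2f, %.2f) A, sigma (%.2f, %.2f, %.2f) A\n",
              x$center[1], x$center[2], x$center[3],
              x$sigmas[1], x$sigmas[2], x$sigmas[3]))
  invisible(x)
}

#' Theoretical hydrophobicity profile T
#'
#' Evaluates the fitted 3D Gaussian at each residue's effective atom (in the
#' principal-axis frame) and normalises to sum 1:
#' `Ti` is proportional to
#' `exp(-x'^2 / 2 sigma_x^2) exp(-y'^2 / 2 sigma_y^2) exp(-z'^2 / 2 sigma_z^2)`.
#'
#' @param structure an `"eff_structure"` whose residues to evaluate.
#' @param field a [fit_gaussian()] result; by default fitted to `structure`
#'   itself.  Pass the parent's field to evaluate a fragment inside a larger
#'   body.
#' @param ... passed to [fit_gaussian()] when `field` is `NULL`.
#' @return a T-role [fod_profile], one value per residue.
#' @export
t_profile <- function(structure, field = NULL, ...) {
  es <- as_eff_structure(structure)
  if (is.null(field)) field <- fit_gaussian(es, ...)
  xp <- sweep(eff_points(es), 2, field$center) %*% field$rotation
  q <- sweep(xp, 2, field$sigmas, "/")
  fod_profile(exp(-0.5 * rowSums(q^2)), role = "T",
              selection = attr(es, "label"))
}
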
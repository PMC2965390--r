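## Shrake-Rupley solvent accessible surface area.

# van der Waals radii by element (Angstrom); unlisted elements fall back
# to carbon
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Theoretical maximum accessible surface per residue type (Angstrom^2),
# Tien et al. 2013 theoretical values; used to normalise residue SASA to
# relative accessibility.
MAX_ASA_REF <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, V = 174, W = 285, Y = 263
)

#' Deterministic quasi-uniform points on the unit sphere (golden spiral)
#' @noRd
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA by the test-point method: `n_sphere_points` points are
#' spread quasi-uniformly on each atom's probe-expanded sphere (van der
#' Waals radius + probe radius) and a point is accessible unless it falls
#' strictly inside any neighbouring atom's expanded sphere. Atom SASA is
#' the accessible fraction of the expanded-sphere area; residue SASA sums
#' its atoms. Coincident identical atoms occlude each other's points — no
#' error is raised.
#'
#' @param x a [protein_structure()].
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_sphere_points test points per atom (default 960, minimum 100).
#' @return object of class `accessibility_profile`: list with `atom_sasa`
#'   (per atom, Angstrom^2), `residue_sasa` (named by residue index),
#'   `res_index`, `probe_radius`, `n_sphere_points`.
#' @export
compute_sasa <- function(x, probe_radius = 1.4, n_sphere_points = 960L) {
  stopifnot(inherits(x, "protein_structure"))
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 100L) stop("need at least 100 sphere points")
  atoms <- x$atoms
  n <- nrow(atoms)
  if (n == 0L) stop("empty structure")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  vdw <- VDW_RADII[atoms$element]
  vdw[is.na(vdw)] <- VDW_RADII[["C"]]
  R <- vdw + probe_radius
  pts <- sphere_points(n_sphere_points)
  # neighbour candidates: centre distance below sum of expanded radii
  d2 <- as.matrix(stats::dist(xyz))^2
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    test <- sweep(pts * R[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      # boundary counts as occluded so coincident identical atoms (all
      # test points exactly on the twin's sphere) bury each other
      accessible <- accessible & dj2 > R[j]^2 * (1 + 1e-9)
      if (!any(accessible)) break
    }
    atom_sasa[i] <- 4 * pi * R[i]^2 * mean(accessible)
  }
  res_sasa <- tapply(atom_sasa, atoms$res_index, sum)
  out <- list(
    atom_sasa = atom_sasa,
    residue_sasa = as.numeric(res_sasa),
    res_index = as.integer(names(res_sasa)),
    probe_radius = probe_radius,
    n_sphere_points = as.integer(n_sphere_points)
  )
  class(out) <- "accessibility_profile"
  out
}

#' Relative accessibility and burial flags
#'
#' Divides each residue's absolute SASA by the maximum reference area of
#' its amino-acid type and flags residues with relative accessibility
#' strictly below `burial_threshold` as buried. Relative values may exceed
#' 1 for terminal or isolated residues. Residue types absent from the
#' reference table (X) get `NA` and are excluded from burial statistics.
#'
#' @param profile an `accessibility_profile` from [compute_sasa()].
#' @param sequence per-residue one-letter codes (vector or single string).
#' @param reference named vector of maximum areas per residue type;
#'   default [MAX_ASA_REF].
#' @param burial_threshold strict burial cutoff on relative accessibility
#'   (default 0.16).
#' @return the profile with added `relative` and `buried` vectors and the
#'   threshold used.
#' @export
relative_accessibility <- function(profile, sequence,
                                   reference = MAX_ASA_REF,
                                   burial_threshold = 0.16) {
  stopifnot(inherits(profile, "accessibility_profile"))
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) != length(profile$residue_sasa)) {
    stop("sequence length does not match the profile")
  }
  ref <- reference[toupper(sequence)]
  rel <- profile$residue_sasa / as.numeric(ref)
  profile$relative <- rel
  profile$buried <- rel < burial_threshold
  profile$burial_threshold <- burial_threshold
  profile
}

#' @export
print.accessibility_profile <- function(x, ...) {
  cat(sprintf(
    "accessibility_profile: %d residues, total SASA %.1f A^2 (probe %.2f A, %d points)\n",
    length(x$residue_sasa), sum(x$residue_sasa), x$probe_radius,
    x$n_sphere_points
  ))
  invisible(x)
}
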
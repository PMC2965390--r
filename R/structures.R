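## Toy protein structures with analytically auditable geometry.
## Poly-alanine chains (backbone N, CA, C, O plus CB) are built from ideal
## bond lengths/angles and prescribed (phi, psi) dihedrals, so contacts,
## burial and secondary structure are known by construction.

# ideal backbone internal coordinates (Angstrom, degrees)
.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.4,
  omega = 180
)

#' Construct a protein-structure object
#'
#' @param atoms data.frame with columns `res_index`, `aa` (one-letter),
#'   `atom` (PDB atom name), `element`, `x`, `y`, `z`.
#' @param chain_id single chain identifier.
#' @param flagged_residues indices of residues parsed without a CA atom.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, chain_id = "A",
                              flagged_residues = integer(0)) {
  need <- c("res_index", "aa", "atom", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (is.unsorted(atoms$res_index)) {
    atoms <- atoms[order(atoms$res_index), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  structure(
    list(chain_id = chain_id, atoms = atoms,
         flagged_residues = flagged_residues),
    class = "protein_structure"
  )
}

#' Number of residues in a structure
#' @param x a `protein_structure`.
#' @export
n_residues <- function(x) length(unique(x$atoms$res_index))

#' One-letter sequence of a structure, in residue order
#' @param x a `protein_structure`.
#' @export
structure_sequence <- function(x) {
  idx <- !duplicated(x$atoms$res_index)
  x$atoms$aa[idx]
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("protein_structure: chain %s, %d residues, %d atoms\n",
              x$chain_id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Place an atom from internal coordinates (natural extension reference
#' frame): bond length to c, angle b-c-d, torsion a-b-c-d.
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # frame below is left-handed in the torsion
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @noRd
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build an ideal poly-alanine backbone from (phi, psi) per residue
#'
#' phi of the first residue and psi of the last are unused (undefined at
#' termini). Returns the atom table of a [protein_structure()].
#' @noRd
build_backbone <- function(phi, psi, omega = .geom$omega) {
  L <- length(phi)
  stopifnot(length(psi) == L, L >= 2)
  g <- .geom
  coords <- vector("list", L)
  # seed frame for residue 1
  n1 <- c(0, 0, 0)
  ca1 <- n1 + c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  c1 <- ca1 + g$b_ca_c * c(cos(th), sin(th), 0)
  prev <- list(N = n1, CA = ca1, C = c1)
  coords[[1]] <- prev
  for (i in seq_len(L)[-1]) {
    N <- nerf_place(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA <- nerf_place(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, omega)
    C <- nerf_place(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi[i])
    prev <- list(N = N, CA = CA, C = C)
    coords[[i]] <- prev
  }
  rows <- list()
  for (i in seq_len(L)) {
    at <- coords[[i]]
    # carbonyl O: torsion N-CA-C-O = psi + 180 (next N is trans to O)
    psi_i <- if (i < L) psi[i] else 180
    O <- nerf_place(at$N, at$CA, at$C, g$b_c_o, g$a_ca_c_o, psi_i + 180)
    CB <- nerf_place(at$C, at$N, at$CA, g$b_ca_cb, g$a_n_ca_cb, 122.6)
    xyz <- rbind(N = at$N, CA = at$CA, C = at$C, O = O, CB = CB)
    rows[[i]] <- data.frame(
      res_index = i, aa = "A", atom = rownames(xyz),
      element = c("N", "C", "C", "O", "C"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Generate a toy structure with known contacts
#'
#' Idealized poly-alanine fixtures:
#' \describe{
#'   \item{extended}{fully extended chain (phi = psi = 180 degrees);
#'     consecutive C-alpha atoms 3.8 A apart along one axis and no
#'     non-adjacent residue contacts.}
#'   \item{helix}{ideal alpha helix (phi = -57, psi = -47).}
#'   \item{hairpin}{two antiparallel extended segments of `length %/% 2`
#'     and `length - length %/% 2` residues, registered so that residue i
#'     faces residue `length + 1 - i` across a 4.6 A strand gap; the
#'     cross-strand pairs are forced contacts.}
#'   \item{cluster}{C-alpha-only residues at packed random positions in a
#'     ball (minimum spacing 3.8 A), or at user-supplied `ca_positions`.}
#' }
#' The returned `contacts` element is the generator's ground-truth contact
#' map, enumerated directly from the emitted coordinates (all non-hydrogen
#' atom pairs, 4.5 A cutoff, sequence separation >= 2).
#'
#' @param kind one of `"extended"`, `"helix"`, `"hairpin"`, `"cluster"`.
#' @param length residue count (>= 2).
#' @param seed integer seed (used by `"cluster"` placement).
#' @param ca_positions optional numeric matrix (`length` rows x 3) of
#'   C-alpha coordinates for `kind = "cluster"`.
#' @param cutoff,min_separation contact definition for the ground-truth
#'   enumeration.
#' @return list with elements `structure` (a [protein_structure()]) and
#'   `contacts` (a `contact_map` object; see [contact_map()]).
#' @export
make_structure <- function(kind = c("extended", "helix", "hairpin", "cluster"),
                           length, seed = 1L, ca_positions = NULL,
                           cutoff = 4.5, min_separation = 2L) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (is.na(length) || length < 2L) stop("length must be >= 2")
  atoms <- switch(kind,
    extended = build_backbone(rep(180, length), rep(180, length)),
    helix = build_backbone(rep(-57, length), rep(-47, length)),
    hairpin = make_hairpin_atoms(length),
    cluster = make_cluster_atoms(length, seed, ca_positions)
  )
  st <- protein_structure(atoms)
  truth <- enumerate_contacts(st, cutoff = cutoff,
                              min_separation = min_separation)
  list(structure = st, contacts = truth)
}

#' @noRd
make_hairpin_atoms <- function(length) {
  n1 <- length %/% 2L
  n2 <- length - n1
  if (n1 < 1L || n2 < 1L) stop("hairpin needs length >= 2")
  s1 <- build_backbone(rep(180, n1), rep(180, n1))
  s2 <- build_backbone(rep(180, n2), rep(180, n2))
  # strand 2 runs antiparallel above strand 1: rotate 180 deg about z,
  # then translate so residue length+1-i sits over residue i.
  xyz2 <- as.matrix(s2[, c("x", "y", "z")])
  xyz2[, 1] <- -xyz2[, 1]
  xyz2[, 2] <- -xyz2[, 2]
  ca1 <- as.matrix(s1[s1$atom == "CA", c("x", "y", "z")])
  ca2 <- cbind(-as.matrix(s2[s2$atom == "CA", c("x", "y", "z")])[, 1],
               -as.matrix(s2[s2$atom == "CA", c("x", "y", "z")])[, 2],
               as.matrix(s2[s2$atom == "CA", c("x", "y", "z")])[, 3])
  # residue n1+k of the full chain (k-th of strand 2) must face residue
  # length+1-(n1+k) = n2+1-k of strand 1; strand-2 residue order reversed
  # by the rotation already, align residue n2 of strand 2 over residue 1.
  target <- ca1[n2 + 1 - n2, ] + c(0, 4.6, 0)     # over residue 1
  shift <- target - ca2[n2, ]
  xyz2 <- sweep(xyz2, 2, shift, "+")
  s2$x <- xyz2[, 1]
  s2$y <- xyz2[, 2]
  s2$z <- xyz2[, 3]
  s2$res_index <- n1 + s2$res_index
  rbind(s1, s2)
}

#' @noRd
make_cluster_atoms <- function(length, seed, ca_positions) {
  if (is.null(ca_positions)) {
    rng <- local_rng(seed)
    radius <- max(4, 2.5 * length^(1 / 3))
    pts <- matrix(NA_real_, length, 3)
    placed <- 0L
    tries <- 0L
    while (placed < length) {
      tries <- tries + 1L
      if (tries > 10000L) stop("could not pack cluster; increase radius")
      p <- rng$runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      if (placed > 0L) {
        d2 <- rowSums(sweep(pts[seq_len(placed), , drop = FALSE], 2, p)^2)
        if (min(d2) < 3.8^2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- p
    }
    ca_positions <- pts
  }
  ca_positions <- as.matrix(ca_positions)
  if (nrow(ca_positions) != length || ncol(ca_positions) != 3) {
    stop("ca_positions must be a length x 3 matrix")
  }
  data.frame(
    res_index = seq_len(length), aa = "A", atom = "CA", element = "C",
    x = ca_positions[, 1], y = ca_positions[, 2], z = ca_positions[, 3],
    stringsAsFactors = FALSE
  )
}

#' Direct all-atom contact enumeration used as generator ground truth
#' @noRd
enumerate_contacts <- function(st, cutoff = 4.5, min_separation = 2L) {
  atoms <- st$atoms
  res <- sort(unique(atoms$res_index))
  L <- length(res)
  by_res <- split(as.matrix(atoms[, c("x", "y", "z")]), atoms$res_index)
  by_res <- lapply(by_res, function(v) matrix(v, ncol = 3))
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j - i < min_separation) next
      pi_ <- by_res[[as.character(res[i])]]
      pj <- by_res[[as.character(res[j])]]
      hit <- FALSE
      for (r in seq_len(nrow(pi_))) {
        d2 <- rowSums(sweep(pj, 2, pi_[r, ])^2)
        if (any(d2 < cutoff^2)) {
          hit <- TRUE
          break
        }
      }
      if (hit) pairs <- rbind(pairs, c(i, j))
    }
  }
  new_contact_map(L = L, pairs = pairs, min_separation = min_separation,
                  cutoff = cutoff)
}
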
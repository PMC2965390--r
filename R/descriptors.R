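#' @noRd
new_contact_map <- function(L, pairs, min_separation, cutoff) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0) {
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  structure(
    list(L = as.integer(L), contacts = pairs,
         min_separation = as.integer(min_separation), cutoff = cutoff),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: L = %d, %d contacts (cutoff %.2f A, |j-i| >= %d)\n",
              x$L, nrow(x$contacts), x$cutoff, x$min_separation))
  invisible(x)
}

#' Residue contact map from atomic coordinates
#'
#' Two non-adjacent residues are in contact when any two of their
#' non-hydrogen atoms are closer than `cutoff` (strict `<`). Non-adjacent
#' means sequence separation `j - i >= min_separation`; the default 2
#' excludes self and immediate neighbours. Each residue pair is counted
#' once regardless of how many atom pairs qualify.
#'
#' @param x a [protein_structure()].
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @param min_separation minimum sequence separation (default 2).
#' @return object of class `contact_map`: list with `L` (residue count),
#'   `contacts` (two-column integer matrix of pairs, i < j),
#'   `min_separation`, `cutoff`.
#' @export
contact_map <- function(x, cutoff = 4.5, min_separation = 2L) {
  stopifnot(inherits(x, "protein_structure"))
  atoms <- x$atoms
  L <- n_residues(x)
  if (L < 2L) stop("need at least 2 residues")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  res <- match(atoms$res_index, sort(unique(atoms$res_index)))
  d2 <- as.matrix(stats::dist(xyz))^2
  close_atoms <- d2 < cutoff^2
  # collapse the atom-pair adjacency to residue pairs
  hit <- rowsum(t(rowsum(close_atoms + 0, res)), res) > 0
  pairs <- which(hit, arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= min_separation, , drop = FALSE]
  new_contact_map(L = L, pairs = pairs, min_separation = min_separation,
                  cutoff = cutoff)
}

#' Contact density: non-adjacent contacts per residue
#'
#' Returns `N / L`, with `N` the number of distinct contacting residue
#' pairs and `L` the residue count (each pair counted once).
#'
#' @param map a `contact_map`.
#' @export
contact_density <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  nrow(map$contacts) / map$L
}

#' Contact order
#'
#' `(L * N)^-1 * sum over contacts of delta_S_ij`, where `delta_S_ij` is
#' the sequence separation of the contacting pair. The separation
#' convention is `j - i` by default; set `separation_offset = 1` to use
#' the number of residues strictly between the pair (`j - i - 1`).
#'
#' @param map a `contact_map`.
#' @param separation_offset subtracted from `j - i` (default 0).
#' @export
contact_order <- function(map, separation_offset = 0) {
  stopifnot(inherits(map, "contact_map"))
  N <- nrow(map$contacts)
  if (N == 0L) stop("contact order undefined: structure has no contacts")
  sum(map$contacts[, 2] - map$contacts[, 1] - separation_offset) / (map$L * N)
}

#' Classify residues as charged, hydrophobic, or other
#'
#' Default sets: charged D, E, K, R (histidine excluded as pH-ambiguous);
#' hydrophobic A, V, L, I, M, F, W, C. The classes are exhaustive and
#' mutually exclusive; unknown letters are labelled `other` with a
#' warning.
#'
#' @param sequence character vector of one-letter codes (or one string).
#' @param charged,hydrophobic class membership sets.
#' @return character vector of labels `"charged"`, `"hydrophobic"`,
#'   `"other"`.
#' @export
residue_classes <- function(sequence,
                            charged = c("D", "E", "K", "R"),
                            hydrophobic = c("A", "V", "L", "I", "M", "F",
                                            "W", "C")) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  known <- c(charged, hydrophobic, "G", "S", "T", "N", "Q", "H", "P", "Y",
             "X")
  if (any(!sequence %in% known)) {
    warning("unknown residue letter(s) classified as 'other': ",
            paste(unique(setdiff(sequence, known)), collapse = ", "))
  }
  ifelse(sequence %in% charged, "charged",
         ifelse(sequence %in% hydrophobic, "hydrophobic", "other"))
}

#' Fraction of residues in loops
#'
#' Fraction of residues whose secondary-structure label is not helix or
#' strand; accepts the DSSP alphabet (H, G, I are helices; E, B strands;
#' T, S, `-` and everything else loop) or the simplified H/E/C alphabet.
#'
#' @param ss character vector of per-residue labels.
#' @export
loop_fraction <- function(ss) {
  if (length(ss) == 1L && nchar(ss) > 1L) ss <- strsplit(ss, "")[[1]]
  if (length(ss) == 0L) stop("no labels")
  structured <- c("H", "G", "I", "E", "B")
  known <- c(structured, "T", "S", "-", "C", " ", "P")
  if (any(!ss %in% known)) {
    warning("unknown secondary-structure label(s) counted as loop: ",
            paste(unique(setdiff(ss, known)), collapse = ", "))
  }
  mean(!ss %in% structured)
}

#' Backbone-dihedral secondary-structure assignment
#'
#' Approximate three-state assignment from phi/psi dihedrals: helix (H)
#' for phi in \[-100, -30\] and psi in \[-80, -5\] degrees over runs of at
#' least 4 residues; strand (E) for phi in \[-180, -80\] and psi in
#' \[80, 180\] or \[-180, -170\] over runs of at least 3; coil (C)
#' otherwise. Terminal residues (undefined phi or psi) and residues with
#' missing backbone atoms are coil.
#'
#' @param x a [protein_structure()].
#' @return character vector of per-residue labels in `{"H", "E", "C"}`.
#' @export
assign_secondary_structure <- function(x) {
  stopifnot(inherits(x, "protein_structure"))
  tor <- backbone_dihedrals(x)
  # wrap to [-180, 180) so a fully extended +180 reads as -180
  tor$phi <- ((tor$phi + 180) %% 360) - 180
  tor$psi <- ((tor$psi + 180) %% 360) - 180
  L <- nrow(tor)
  helix_ok <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi >= -100 & tor$phi <= -30 & tor$psi >= -80 & tor$psi <= -5
  strand_ok <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi >= -180 & tor$phi <= -80 &
    ((tor$psi >= 80 & tor$psi <= 180) | (tor$psi >= -180 & tor$psi <= -170))
  labels <- rep("C", L)
  labels[run_mask(helix_ok, 4L)] <- "H"
  labels[run_mask(strand_ok, 3L) & labels == "C"] <- "E"
  labels
}

#' TRUE where `ok` holds in a run of at least `min_run` consecutive TRUEs
#' @noRd
run_mask <- function(ok, min_run) {
  r <- rle(ok)
  keep <- r$values & r$lengths >= min_run
  rep(keep, r$lengths)
}

#' Phi/psi dihedrals per residue (NA at termini or missing atoms)
#' @noRd
backbone_dihedrals <- function(x) {
  res <- sort(unique(x$atoms$res_index))
  get_atom <- function(r, nm) {
    row <- x$atoms[x$atoms$res_index == r & x$atoms$atom == nm, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  L <- length(res)
  phi <- rep(NA_real_, L)
  psi <- rep(NA_real_, L)
  for (k in seq_len(L)) {
    N <- get_atom(res[k], "N")
    CA <- get_atom(res[k], "CA")
    C <- get_atom(res[k], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k > 1L) {
      Cp <- get_atom(res[k - 1L], "C")
      if (!is.null(Cp)) phi[k] <- dihedral(Cp, N, CA, C)
    }
    if (k < L) {
      Nn <- get_atom(res[k + 1L], "N")
      if (!is.null(Nn)) psi[k] <- dihedral(N, CA, C, Nn)
    }
  }
  data.frame(res_index = res, phi = phi, psi = psi)
}

#' Signed dihedral angle (degrees) of four points
#' @noRd
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Joint burial/class composition fractions
#'
#' Fractions over all residues of (buried AND hydrophobic) and
#' (exposed AND charged).
#'
#' @param profile an `accessibility_profile` from
#'   [relative_accessibility()] (needs its `buried` flags).
#' @param classes per-residue labels from [residue_classes()].
#' @return list with `frac_buried_hydrophobic` and `frac_exposed_charged`.
#' @export
buried_exposed_class_fractions <- function(profile, classes) {
  buried <- profile$buried
  if (length(buried) != length(classes)) {
    stop("profile and class labels differ in length (",
         length(buried), " vs ", length(classes), ")")
  }
  ok <- !is.na(buried)
  L <- length(buried)
  list(
    frac_buried_hydrophobic =
      sum(buried[ok] & classes[ok] == "hydrophobic") / L,
    frac_exposed_charged =
      sum(!buried[ok] & classes[ok] == "charged") / L
  )
}

#' All structural descriptors of one structure
#'
#' Convenience wrapper computing the full descriptor row used by the
#' expression-association analysis: chain length, contact density,
#' contact order (NA when the structure has no contacts), burial/class
#' composition fractions, loop fraction, and overall charged and
#' hydrophobic fractions.
#'
#' @param x a [protein_structure()].
#' @param cutoff,min_separation contact definition.
#' @param burial_threshold relative accessibility below which a residue is
#'   buried (default 0.16, strict `<`).
#' @param probe_radius,n_sphere_points SASA parameters.
#' @param ss optional per-residue secondary-structure labels; computed via
#'   [assign_secondary_structure()] when missing.
#' @return one-row data.frame.
#' @export
structure_descriptors <- function(x, cutoff = 4.5, min_separation = 2L,
                                  burial_threshold = 0.16,
                                  probe_radius = 1.4, n_sphere_points = 960L,
                                  ss = NULL) {
  stopifnot(inherits(x, "protein_structure"))
  cm <- contact_map(x, cutoff = cutoff, min_separation = min_separation)
  co <- if (nrow(cm$contacts) > 0) contact_order(cm) else NA_real_
  seq1 <- structure_sequence(x)
  sasa <- compute_sasa(x, probe_radius = probe_radius,
                       n_sphere_points = n_sphere_points)
  prof <- relative_accessibility(sasa, seq1,
                                 burial_threshold = burial_threshold)
  classes <- residue_classes(seq1)
  be <- buried_exposed_class_fractions(prof, classes)
  if (is.null(ss)) ss <- assign_secondary_structure(x)
  data.frame(
    L = cm$L,
    contact_density = contact_density(cm),
    contact_order = co,
    frac_buried_hydrophobic = be$frac_buried_hydrophobic,
    frac_exposed_charged = be$frac_exposed_charged,
    frac_loop = loop_fraction(ss),
    frac_charged = mean(classes == "charged"),
    frac_hydrophobic = mean(classes == "hydrophobic")
  )
}
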
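#' Parse a PDB file into a protein structure
#'
#' Reads ATOM records of one chain from PDB-format text. Only the first
#' model of a multi-model (NMR-style) file is kept; HETATM records and
#' waters are skipped; hydrogen (and deuterium) atoms are dropped;
#' alternate locations are resolved by keeping the highest-occupancy copy
#' of each atom, ties broken by alternate-location identifier order.
#' Residues are renumbered 1..L in order of appearance (author numbering
#' with insertion codes collapsed to sequential order); residues lacking a
#' CA atom are retained and listed in `flagged_residues`.
#'
#' @param pdb path to a PDB file, or a character vector of PDB lines.
#' @param chain chain identifier to extract; `NULL` (default) takes the
#'   first chain with ATOM records.
#' @return a [protein_structure()].
#' @export
parse_structure <- function(pdb, chain = NULL) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  # truncate at the end of model 1
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec == "ATOM  ")
  if (length(atom_idx) == 0L) stop("no ATOM records in input")

  fld <- function(i, from, to) substr(lines[i], from, to)
  chains <- substr(lines[atom_idx], 22, 22)
  if (is.null(chain)) chain <- chains[1]
  atom_idx <- atom_idx[chains == chain]
  if (length(atom_idx) == 0L) stop("no ATOM records for chain '", chain, "'")

  num <- function(i, from, to, what) {
    v <- suppressWarnings(as.numeric(fld(i, from, to)))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("malformed ", what, " field at line ", i[bad[1]])
    }
    v
  }
  name <- trimws(substr(lines[atom_idx], 13, 16))
  altloc <- substr(lines[atom_idx], 17, 17)
  resname <- trimws(substr(lines[atom_idx], 18, 20))
  resseq <- trimws(substr(lines[atom_idx], 23, 26))
  icode <- substr(lines[atom_idx], 27, 27)
  x <- num(atom_idx, 31, 38, "x coordinate")
  y <- num(atom_idx, 39, 46, "y coordinate")
  z <- num(atom_idx, 47, 54, "z coordinate")
  occ <- suppressWarnings(as.numeric(substr(lines[atom_idx], 55, 60)))
  occ[is.na(occ)] <- 1
  element <- trimws(substr(lines[atom_idx], 77, 78))
  guess <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  element <- ifelse(nzchar(element), toupper(element), guess)

  keep <- !(resname %in% c("HOH", "WAT", "DOD")) & !(element %in% c("H", "D"))
  if (!any(keep)) stop("no non-hydrogen protein atoms for chain '", chain, "'")
  df <- data.frame(
    name = name, altloc = altloc, resname = resname,
    reskey = paste0(resseq, icode), x = x, y = y, z = z, occ = occ,
    element = element, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]

  # altloc resolution: per residue+atom keep highest occupancy, then
  # lowest altloc identifier; restore file order afterwards
  df$orig <- seq_len(nrow(df))
  o <- order(match(df$reskey, unique(df$reskey)), df$name, -df$occ, df$altloc)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c("reskey", "name")]), , drop = FALSE]
  df <- df[order(df$orig), , drop = FALSE]

  res_index <- match(df$reskey, unique(df$reskey))
  aa <- aa3to1(df$resname)
  atoms <- data.frame(
    res_index = res_index, aa = aa, atom = df$name, element = df$element,
    x = df$x, y = df$y, z = df$z, stringsAsFactors = FALSE
  )
  has_ca <- tapply(atoms$atom == "CA", atoms$res_index, any)
  flagged <- as.integer(names(has_ca)[!has_ca])
  protein_structure(atoms, chain_id = chain, flagged_residues = flagged)
}

#' @noRd
aa3to1 <- function(resname) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M", SEC = "C")
  out <- map[resname]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Read per-residue secondary structure from a DSSP output file
#'
#' Parses the per-residue table of a DSSP file (the block following the
#' `#  RESIDUE` header) and returns the one-character structure code for
#' each residue; blank codes become `"-"` (coil). Chain-break rows
#' (`!` markers) are skipped.
#'
#' @param path DSSP output file.
#' @return data.frame with columns `res_index` (1-based order of
#'   appearance), `aa`, `ss`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP file: per-residue header missing")
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" & nzchar(trimws(aa))
  body <- body[keep]
  ss <- substr(body, 17, 17)
  ss[!nzchar(trimws(ss))] <- "-"
  data.frame(
    res_index = seq_along(body), aa = substr(body, 14, 14), ss = ss,
    stringsAsFactors = FALSE
  )
}
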
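test_that("PDB parsing keeps one altloc copy and only the first model", {
  st <- parse_structure(paste(pdb_altloc_text(), collapse = "\n"))
  expect_equal(nrow(st$atoms), 3L)            # one N, one CA, one C
  n_row <- st$atoms[st$atoms$atom == "N", ]
  expect_equal(n_row$x, 0.5)                  # higher-occupancy B copy

  st2 <- parse_structure(paste(pdb_two_model_text(), collapse = "\n"))
  expect_equal(nrow(st2$atoms), 2L)
  expect_equal(st2$atoms$x, c(0, 3.8))

  expect_error(parse_structure("REMARK nothing"), "no ATOM records")
  bad <- sub("0.000   0.000   0.000", "0.0xx   0.000   0.000",
             pdb_altloc_text()[1])
  expect_error(parse_structure(paste(c(bad, "END"), collapse = "\n")),
               "line 1")
})

test_that("parsed fixtures agree with bio3d on coordinates", {
  fx <- make_structure("helix", 10)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(fx$structure, pdb)
  st <- parse_structure(pdb)
  ref <- bio3d::read.pdb(pdb)
  expect_equal(nrow(st$atoms), nrow(ref$atom))
  expect_equal(st$atoms$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(st$atoms$res_index, ref$atom$resno)
})

test_that("contact_map equals the brute-force all-atom oracle", {
  for (kind in c("extended", "helix", "hairpin", "cluster")) {
    fx <- make_structure(kind, 20, seed = 4)
    cm <- contact_map(fx$structure)
    bf <- brute_force_contacts(fx$structure)
    expect_equal(unname(cm$contacts), unname(bf), label = kind)
  }
})

test_that("contact density and order follow their defining formulas", {
  empty <- clockcost:::new_contact_map(10, matrix(integer(0), 0, 2), 2, 4.5)
  expect_equal(contact_density(empty), 0)
  expect_error(contact_order(empty), "no contacts")

  one <- clockcost:::new_contact_map(3, rbind(c(1, 3)), 2, 4.5)
  expect_equal(contact_density(one), 1 / 3)

  co1 <- clockcost:::new_contact_map(10, rbind(c(2, 7)), 2, 4.5)
  expect_equal(contact_order(co1), 0.5)
  co2 <- clockcost:::new_contact_map(10, rbind(c(1, 3), c(1, 10)), 2, 4.5)
  expect_equal(contact_order(co2), 0.55)
  expect_equal(contact_order(co2, separation_offset = 1), 0.45)

  # hairpin: hand recomputation from the brute-force list
  fx <- make_structure("hairpin", 12)
  cm <- contact_map(fx$structure)
  bf <- brute_force_contacts(fx$structure)
  expect_equal(contact_order(cm), sum(bf[, 2] - bf[, 1]) / (12 * nrow(bf)))
  expect_equal(contact_density(cm), nrow(bf) / 12)
})

test_that("descriptors are invariant under rigid-body motion", {
  fx <- make_structure("hairpin", 16)
  st <- fx$structure
  set.seed(7)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% (Rx %*% Rz)
  xyz <- sweep(xyz, 2, c(11.3, -4.2, 8.8), "+")
  st2 <- st
  st2$atoms$x <- xyz[, 1]
  st2$atoms$y <- xyz[, 2]
  st2$atoms$z <- xyz[, 3]
  cm1 <- contact_map(st)
  cm2 <- contact_map(st2)
  expect_identical(cm1$contacts, cm2$contacts)
  expect_equal(contact_order(cm1), contact_order(cm2), tolerance = 1e-9)
  # the test-point grid is fixed in the lab frame, so SASA is rotation
  # invariant only up to discretization error
  s1 <- compute_sasa(st, n_sphere_points = 960)
  s2 <- compute_sasa(st2, n_sphere_points = 960)
  expect_equal(s1$residue_sasa, s2$residue_sasa, tolerance = 0.02)
  expect_gt(contact_order(cm1), 0)
  expect_lte(contact_order(cm1), 1)
})

test_that("residue classes partition the alphabet as documented", {
  expect_true(all(residue_classes("DEKR") == "charged"))
  expect_true(all(residue_classes("AVLIMFWC") == "hydrophobic"))
  expect_true(all(residue_classes("GSTNQ") == "other"))
  expect_warning(cls <- residue_classes("ABZ"), "unknown")
  expect_equal(cls[2], "other")
  # configurable sets: histidine can be declared charged
  expect_equal(residue_classes("H", charged = c("D", "E", "K", "R", "H")),
               "charged")
})

test_that("loop fraction counts non-helix non-strand labels", {
  expect_equal(loop_fraction(rep("H", 8)), 0)
  expect_equal(loop_fraction(rep("-", 5)), 1)
  expect_equal(loop_fraction("HHHH----EEEE"), 4 / 12)
  expect_equal(loop_fraction(c("H", "G", "I", "E", "B", "T", "S", "-")),
               3 / 8)
  expect_warning(lf <- loop_fraction(c("H", "Q")), "unknown")
  expect_equal(lf, 1 / 2)
})

test_that("dihedral-based secondary structure matches ideal geometry", {
  hx <- make_structure("helix", 20)$structure
  lab_h <- assign_secondary_structure(hx)
  expect_gte(mean(lab_h[2:19] == "H"), 0.9)
  ex <- make_structure("extended", 20)$structure
  lab_e <- assign_secondary_structure(ex)
  expect_gte(mean(lab_e[2:19] == "E"), 0.9)
  tiny <- make_structure("extended", 2)$structure
  expect_equal(assign_secondary_structure(tiny), c("C", "C"))
})

test_that("buried/exposed class fractions come from set intersections", {
  prof <- structure(list(buried = c(FALSE, FALSE, FALSE, FALSE)),
                    class = "accessibility_profile")
  cls <- residue_classes("DEKR")
  be <- buried_exposed_class_fractions(prof, cls)
  expect_equal(be$frac_exposed_charged, 1)
  expect_equal(be$frac_buried_hydrophobic, 0)

  prof$buried <- rep(TRUE, 4)
  be2 <- buried_exposed_class_fractions(prof, cls)
  expect_equal(be2$frac_exposed_charged, 0)

  # mixed case against a direct recount
  set.seed(21)
  buried <- sample(c(TRUE, FALSE), 40, TRUE)
  seqv <- sample(c("D", "K", "A", "L", "G", "S"), 40, TRUE)
  prof$buried <- buried
  cls <- residue_classes(seqv)
  be3 <- buried_exposed_class_fractions(prof, cls)
  expect_equal(be3$frac_buried_hydrophobic,
               sum(buried & seqv %in% c("A", "L")) / 40)
  expect_equal(be3$frac_exposed_charged,
               sum(!buried & seqv %in% c("D", "K")) / 40)
  expect_error(buried_exposed_class_fractions(prof, cls[-1]), "length")
})

test_that("redundancy filter keeps pairwise identity at or below the cap", {
  s <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
  mutate_at <- function(s, pos, to = "G") {
    v <- strsplit(s, "")[[1]]
    v[pos] <- to
    paste(v, collapse = "")
  }
  near <- mutate_at(s, c(3, 9))            # 58/60 identical: > 0.9
  far <- paste(rep("WYWYWYWYWYWYWYWYWYWY", 3), collapse = "")
  seqs <- c(a = s, b = near, c = far)
  kept <- filter_redundant(seqs)
  expect_identical(names(kept), c("a", "c"))

  kept2 <- filter_redundant(c(x = s, y = s))
  expect_identical(names(kept2), "x")

  # all pairwise identities below 0.5: everything retained
  set.seed(33)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- vapply(1:4, function(i) paste(sample(aas, 50, TRUE), collapse = ""),
                character(1))
  names(rnd) <- paste0("r", 1:4)
  expect_identical(names(filter_redundant(rnd)), names(rnd))
})

test_that("structure descriptor rows assemble all quantities", {
  fx <- make_structure("hairpin", 14)
  row <- structure_descriptors(fx$structure, n_sphere_points = 240)
  expect_equal(row$L, 14L)
  expect_true(all(unlist(row[c("frac_buried_hydrophobic",
                               "frac_exposed_charged", "frac_loop",
                               "frac_charged", "frac_hydrophobic")]) >= 0))
  expect_equal(row$frac_hydrophobic, 1)  # poly-alanine
  expect_gt(row$contact_density, 0)
})

test_that("DSSP-format files provide loop fractions", {
  dssp <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A A  H  >  S+     0   0   75",
    "    2    2 A A  H  3  S+     0   0   45",
    "    3    3 A A     <         0   0  102",
    "    4    4 A A  E    S-      0   0   33"
  )
  f <- tempfile(fileext = ".dssp")
  writeLines(dssp, f)
  ss <- read_dssp(f)
  expect_equal(ss$ss, c("H", "H", "-", "E"))
  expect_equal(loop_fraction(ss$ss), 1 / 4)
})
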
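# PDB parsing and residue descriptors

test_that("parsing a poly-alanine fixture yields the constructed residues", {
  s <- parse_structure(ala_line_pdb(5), id = "ala5")
  expect_equal(nrow(s$residues), 5)
  expect_true(all(s$residues$aa == "A"))
  s2 <- parse_structure(ala_line_pdb(5), id = "ala5")
  expect_identical(s$residues, s2$residues)   # repeated parse is bit-stable
})

test_that("residues missing a backbone atom are excluded, not fatal", {
  s <- parse_structure(ala_line_pdb(5, drop_ca_at = 3), id = "ala4")
  expect_equal(nrow(s$residues), 4)
  expect_equal(s$n_excluded, 1)
})

test_that("unparseable coordinates raise an error naming the line", {
  bad <- ala_line_pdb(3)
  substr(bad[5], 31, 38) <- "  oops  "
  expect_error(parse_structure(bad), "line 5")
})

test_that("zero usable residues is an explicit error", {
  expect_error(parse_structure(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O", "END")),
               "no usable protein residues")
})

test_that("alternate locations resolve to the highest occupancy", {
  lines <- ala_line_pdb(3)
  # inject two CB conformers for residue 2: B has higher occupancy
  cb <- grep("CB  ALA A   2", lines, fixed = TRUE)
  a <- lines[cb]; b <- lines[cb]
  substr(a, 17, 17) <- "A"; substr(a, 55, 60) <- "  0.40"
  substr(b, 17, 17) <- "B"; substr(b, 55, 60) <- "  0.60"
  substr(b, 31, 38) <- "   9.000"
  lines <- c(lines[seq_len(cb - 1)], a, b, lines[(cb + 1):length(lines)])
  s <- parse_structure(lines)
  expect_equal(s$residues$cx[2], 9.0, tolerance = 1e-6)
})

test_that("torsion domains map canonical angles and termini correctly", {
  expect_equal(torsion_domain_label(-57, -47), "A")   # canonical alpha
  expect_equal(torsion_domain_label(-120, 130), "B")  # canonical beta
  expect_equal(torsion_domain_label(NA, 100), "U")
  s <- assign_torsion_domain(fixture_structure())
  n <- nrow(s$residues)
  expect_equal(s$residues$t[1], "U")
  expect_equal(s$residues$t[n], "U")
  expect_true(all(s$residues$t %in% TORSION_ALPHABET))
})

test_that("every (phi, psi) pair maps to exactly one label", {
  grid <- expand.grid(phi = seq(-180, 180, by = 7.3),
                      psi = seq(-180, 180, by = 7.3))
  labs <- mapply(torsion_domain_label, grid$phi, grid$psi)
  expect_true(all(labs %in% setdiff(TORSION_ALPHABET, "U")))
})

test_that("backbone dihedrals agree with bio3d on a toy structure", {
  pdb_lines <- make_toy_structure(12, "mixed", seed = 2)
  # bio3d's torsion scan assumes standard side chains, so feed it the
  # backbone only; our parser sees the full file
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines[!grepl("^ATOM.{8} SC ", pdb_lines)], tf)
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(tf, verbose = FALSE))
  s <- assign_torsion_domain(parse_structure(pdb_lines))
  for (ang in c("phi", "psi")) {
    ours <- s$residues[[ang]]
    ok <- !is.na(ours) & !is.na(ref[[ang]])
    expect_true(sum(ok) >= 10)
    expect_equal(ours[ok], unname(ref[[ang]][ok]), tolerance = 1e-3)
  }
})

test_that("an isolated residue is essentially fully accessible", {
  s <- compute_accessibility(parse_structure(ala_line_pdb(1)))
  expect_gte(s$residues$a[1], 95)
})

test_that("a residue enclosed in a dense atom cage is buried", {
  # central alanine inside two dense shells of occluding atoms centered on
  # its C-alpha; the shell residues lack backbones, so only the central
  # residue enters the descriptor table, but their atoms still occlude
  lines <- ala_line_pdb(1)
  lines <- lines[lines != "END"]
  serial <- 10
  for (shell_r in c(4.5, 6.0)) {
    pts <- stabscan:::.fibonacci_sphere(350) * shell_r
    for (p in seq_len(nrow(pts))) {
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  CB  ALA B%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, serial, pts[p, 1] + 1.46, pts[p, 2], pts[p, 3], 1.00, 0.00))
    }
  }
  s <- parse_structure(c(lines, "END"))
  expect_equal(nrow(s$residues), 1)
  s <- compute_accessibility(s)
  expect_lt(s$residues$a[1], 5)
})

test_that("accessibility is converged in the sphere sample size", {
  s <- fixture_structure()
  a1 <- compute_accessibility(s, n_points = 960)$residues$a
  a2 <- compute_accessibility(s, n_points = 1920)$residues$a
  expect_lt(max(abs(a1 - a2)), 2)
})

test_that("centroid distances match geometry and the cutoff", {
  # 3-4-5 triangle between residues 1 and 3 (gap to evade |i-j| >= 2)
  lines <- character(0)
  serial <- 0
  mk <- function(name, resno, x, y, z) {
    serial <<- serial + 1
    sprintf("ATOM  %5d %4s ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            serial, sprintf(" %-3s", name), resno, x, y, z, 1.0, 0.0,
            substr(name, 1, 1))
  }
  for (i in 1:3) {
    ox <- switch(i, 0, 50, 0)   # residue 2 far away
    oy <- switch(i, 0, 0, 4)
    cbx <- switch(i, 0, 50, 3)
    lines <- c(lines, mk("N", i, ox, oy, 0), mk("CA", i, ox + 1, oy, 0),
               mk("C", i, ox + 2, oy, 0), mk("CB", i, cbx, oy, 0))
  }
  s <- pairwise_centroid_distances(parse_structure(c(lines, "END")),
                                   cutoff = 8)
  expect_equal(nrow(s$pairs), 1)
  expect_equal(s$pairs$d[1], 5, tolerance = 1e-9)
  s6 <- pairwise_centroid_distances(parse_structure(c(lines, "END")),
                                    cutoff = 4.9)
  expect_equal(nrow(s6$pairs), 0)   # pair beyond the cutoff is absent
})

test_that("the distance map equals a brute-force all-pairs oracle", {
  s <- fixture_structure()
  ref <- oracle_pair_map(s, 8)
  expect_equal(nrow(s$pairs), nrow(ref))
  expect_equal(as.matrix(s$pairs), unname(ref), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("adjacent residues are excluded from the distance map", {
  s <- fixture_structure()
  expect_true(all(abs(s$pairs$i - s$pairs$j) >= 2))
})

test_that("core/surface classification follows the 10% boundary rule", {
  s <- fixture_structure()
  s$residues$a[1:3] <- c(0, 100, 10)
  cls <- classify_core_surface(s)
  expect_equal(cls[1:3], c("core", "surface", "surface"))
  s$residues$a[4] <- NA
  expect_true(is.na(classify_core_surface(s)[4]))
})

test_that("descriptors are invariant under rigid-body motion", {
  pdb <- make_toy_structure(20, "mixed", seed = 5)
  s1 <- annotate_structure(pdb)
  s2 <- annotate_structure(rotate_structure_atoms(pdb))
  expect_equal(s1$residues$t, s2$residues$t)
  # coordinates are written at 1e-3 A precision, so allow ~1e-2 slack
  expect_equal(s1$residues$a, s2$residues$a, tolerance = 1e-2)
  expect_equal(s1$pairs$d, s2$pairs$d, tolerance = 1e-2)
  expect_equal(s1$pairs[, c("i", "j")], s2$pairs[, c("i", "j")])
})

test_that("the descriptor table is emitted with one row per residue", {
  s <- fixture_structure()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_residue_table(s, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), nrow(s$residues))
  expect_named(tab, c("chain", "resnum", "aa", "t", "a", "class"))
})
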
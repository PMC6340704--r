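# Strand assignment from coordinates: dihedrals, labelling, hydrogen
# bonds, assembly, directions, and alternative-structure variants.

pdb_line <- function(serial, name, alt, res3, resno, x, y, z, occ = 1) {
  sprintf(
    "ATOM  %5d %-4s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           ",
    serial, paste0(" ", name), alt, res3, resno, x, y, z, occ, 0
  )
}

test_that("computed dihedrals agree with an independent torsion oracle", {
  b <- generate_barrel(barrel_spec(8, seed = 7))
  path <- tempfile(fileext = ".pdb")
  write_pdb(b, path)
  ours <- compute_dihedrals(read_backbone(path))
  ref <- bio3d::torsion.pdb(bio3d::read.pdb(path, verbose = FALSE))
  expect_equal(ours$phi[-1], ref$phi[-1], tolerance = 1e-3,
               ignore_attr = TRUE)
  n <- nrow(ours)
  expect_equal(ours$psi[-n], ref$psi[-n], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_true(is.na(ours$phi[1]))
  expect_true(is.na(ours$psi[n]))
})

test_that("ideal beta and alpha geometries read back their torsions", {
  # chains built from internal coordinates are an independent construction
  # of the torsion the analyzer must recover
  beta <- barreltopo:::build_chain(6, -120, 130)
  res <- tibble::tibble(
    seq_index = 1:6, aa = "A",
    n_x = beta$N[, 1], n_y = beta$N[, 2], n_z = beta$N[, 3],
    ca_x = beta$CA[, 1], ca_y = beta$CA[, 2], ca_z = beta$CA[, 3],
    c_x = beta$C[, 1], c_y = beta$C[, 2], c_z = beta$C[, 3],
    o_x = beta$O[, 1], o_y = beta$O[, 2], o_z = beta$O[, 3]
  )
  d <- compute_dihedrals(res)
  expect_equal(d$phi[2:5], rep(-120, 4), tolerance = 1e-6)
  expect_equal(d$psi[2:5], rep(130, 4), tolerance = 1e-6)
  helix <- barreltopo:::build_chain(6, -57, -47)
  res$n_x <- helix$N[, 1]; res$n_y <- helix$N[, 2]; res$n_z <- helix$N[, 3]
  res$ca_x <- helix$CA[, 1]; res$ca_y <- helix$CA[, 2]
  res$ca_z <- helix$CA[, 3]
  res$c_x <- helix$C[, 1]; res$c_y <- helix$C[, 2]; res$c_z <- helix$C[, 3]
  dh <- compute_dihedrals(res)
  expect_equal(dh$phi[2:5], rep(-57, 4), tolerance = 1e-6)
  expect_equal(dh$psi[2:5], rep(-47, 4), tolerance = 1e-6)
  expect_error(compute_dihedrals(res[1:2, ]), "3 residues")
})

test_that("phi/psi windows label strand, helix and other", {
  g <- tibble::tibble(seq_index = 1:3,
                      phi = c(-120, -57, 60), psi = c(130, -47, 60))
  expect_identical(label_residues(g)$label,
                   c("strand_like", "helix_like", "other"))
  # psi wrap: fully extended chains sit at psi ~ -180
  g2 <- tibble::tibble(seq_index = 1, phi = -150, psi = -175)
  expect_identical(label_residues(g2)$label, "strand_like")
})

test_that("hydrogen-bond detection respects cutoff and sequence separation", {
  res <- tibble::tibble(
    seq_index = 1:5, aa = "A",
    n_x = c(0, 10, 20, 30, 3.4), n_y = 0, n_z = 0,
    ca_x = c(1, 11, 21, 31, 41), ca_y = 1, ca_z = 0,
    c_x = c(2, 12, 22, 32, 42), c_y = 0, c_z = 0,
    o_x = c(0, 10, 20, 30, 40), o_y = 0.5, o_z = 0
  )
  hb <- detect_hbonds(res, cutoff = 3.5, min_sep = 3)
  # N(5) at x=3.4 is 3.44 A from O(1): kept; O(4) at 35.6 A from N(5) but
  # |5-4| = 1 would be excluded anyway
  expect_identical(hb, tibble::tibble(donor = 5L, acceptor = 1L))
  res$n_x[5] <- 4.2  # beyond a 3.5 A cutoff
  expect_identical(nrow(detect_hbonds(res, cutoff = 3.5)), 0L)
})

test_that("strand assembly requires hydrogen-bonded partner runs", {
  b <- generate_barrel(barrel_spec(8, seed = 13))
  labels <- label_residues(compute_dihedrals(b$residues))
  hb <- detect_hbonds(b$residues)
  ann <- assemble_strands(labels, hb)
  expect_identical(nrow(ann), 8L)
  # a lone strand-like run with no bonded partner is not a strand
  lone <- tibble::tibble(seq_index = 1:20,
                         label = rep(c("other", "strand_like"), each = 10))
  no_bonds <- tibble::tibble(donor = integer(), acceptor = integer())
  expect_error(assemble_strands(lone, no_bonds), "no barrel")
  all_helix <- tibble::tibble(seq_index = 1:20, label = "helix_like")
  expect_error(assemble_strands(all_helix, no_bonds), "no barrel")
})

test_that("strand recovery matches the planted barrel across sizes", {
  for (n in c(8, 14, 20, 26)) {
    b <- generate_barrel(barrel_spec(n, seed = n + 1))
    ann <- annotate_structure(write_pdb(b))
    expect_identical(nrow(ann), as.integer(n))
    expect_identical(ann$direction, rep(c(1L, -1L), n / 2))
    # recovered intervals overlap planted intervals by >= 90% of residues
    planted <- b$annotation
    overlap <- sum(vapply(seq_len(n), function(i) {
      length(intersect(seq(ann$start[i], ann$end[i]),
                       seq(planted$start[i], planted$end[i])))
    }, numeric(1)))
    expect_gte(overlap / sum(planted$end - planted$start + 1), 0.9)
  }
})

test_that("labelling is invariant under rigid-body motion", {
  b <- generate_barrel(barrel_spec(10, seed = 3))
  res <- b$residues
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- res
  for (at in c("n", "ca", "c", "o")) {
    M <- as.matrix(res[, paste0(at, c("_x", "_y", "_z"))]) %*% R
    M <- sweep(M, 2, c(5, -3, 12), "+")
    rot[, paste0(at, c("_x", "_y", "_z"))] <- M
  }
  l1 <- label_residues(compute_dihedrals(res))
  l2 <- label_residues(compute_dihedrals(rot))
  expect_identical(l1, l2)
})

test_that("mirrored coordinates give the same directions after the termini rule", {
  b <- generate_barrel(barrel_spec(8, seed = 17))
  ann <- strand_directions(b$annotation, b$residues)
  mir <- b$residues
  for (at in c("n", "ca", "c", "o")) {
    mir[[paste0(at, "_z")]] <- -mir[[paste0(at, "_z")]]
  }
  ann_m <- strand_directions(b$annotation, mir)
  expect_identical(ann$direction, ann_m$direction)
})

test_that("altloc conformers resolve by occupancy and HETATM-only input errors", {
  lines <- c(
    pdb_line(1, "N", " ", "ALA", 1, 0, 0, 0),
    pdb_line(2, "CA", " ", "ALA", 1, 1.5, 0, 0),
    pdb_line(3, "C", " ", "ALA", 1, 2.5, 0, 0),
    pdb_line(4, "O", " ", "ALA", 1, 3, 0, 0),
    pdb_line(5, "N", " ", "GLY", 2, 4, 0, 0),
    pdb_line(6, "CA", "A", "GLY", 2, 5.0, 0, 0, occ = 0.3),
    pdb_line(7, "CA", "B", "GLY", 2, 5.5, 0, 0, occ = 0.7),
    pdb_line(8, "C", " ", "GLY", 2, 6, 0, 0),
    pdb_line(9, "O", " ", "GLY", 2, 6.5, 0, 0),
    "END"
  )
  rb <- read_backbone(lines)
  expect_equal(rb$ca_x, c(1.5, 5.5))
  expect_identical(rb$aa, c("A", "G"))
  het <- c(paste0("HETATM    1  O   HOH A   1       0.000   0.000",
                  "   0.000  1.00  0.00           O"), "END")
  expect_error(read_backbone(het), "no polymer")
})

test_that("residues without CA are dropped with a warning", {
  lines <- c(
    pdb_line(1, "N", " ", "ALA", 1, 0, 0, 0),
    pdb_line(2, "CA", " ", "ALA", 1, 1.5, 0, 0),
    pdb_line(3, "C", " ", "ALA", 1, 2.5, 0, 0),
    pdb_line(4, "O", " ", "ALA", 1, 3, 0, 0),
    pdb_line(5, "N", " ", "GLY", 2, 4, 0, 0),
    pdb_line(6, "C", " ", "GLY", 2, 6, 0, 0),
    "END"
  )
  expect_warning(rb <- read_backbone(lines), "without CA")
  expect_identical(nrow(rb), 1L)
  expect_identical(rb$seq_index, 1L)
})

test_that("alternative-structure variants take per-strand union and intersection", {
  a1 <- tibble::tibble(strand = 1:4, start = c(5, 20, 40, 60),
                       end = c(15, 30, 50, 70), direction = c(1L, -1L, 1L, -1L))
  a2 <- a1
  a2$start[1] <- 6
  a2$end[1] <- 14
  v <- annotation_variants(list(a1, a2))
  expect_identical(v$longest$start[1], 5)
  expect_identical(v$longest$end[1], 15)
  expect_identical(v$shortest$start[1], 6)
  expect_identical(v$shortest$end[1], 14)
  single <- annotation_variants(list(a1))
  expect_identical(single$longest, single$shortest)
  a3 <- a1[1:3, ]
  v2 <- annotation_variants(list(a1, a3))
  expect_match(v2$flags, "changes strand count")
})
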
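test_that("fixed-column ATOM/HETATM records parse into the expected atoms", {
  txt <- c(
    pdb_line("ATOM", 1, "N",  "GLY", "A", 1, 1.000, 2.000, 3.000),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 1, 2.500, 2.000, 3.000),
    pdb_line("ATOM", 3, "C",  "GLY", "A", 1, 3.200, 3.100, 3.000)
  )
  m <- parse_structure(txt)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$chain, rep("A", 3))
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  expect_equal(m$atoms$x, c(1.0, 2.5, 3.2))
  expect_equal(m$atoms$element, c("N", "C", "C"))
  expect_false(any(m$atoms$is_hetero))
})

test_that("parser agrees with bio3d on coordinates of the same fixture", {
  skip_if_not_installed("bio3d")
  toy <- generate_toy_structure(n_residues = 6, geometry = "helix", seed = 42)
  tmp <- tempfile(fileext = ".pdb")
  writeLines(toy$pdb, tmp)
  mine <- read_structure(tmp)
  ref <- suppressWarnings(bio3d::read.pdb(tmp))
  expect_equal(nrow(mine$atoms), nrow(ref$atom))
  expect_equal(mine$atoms$x, ref$atom$x, tolerance = 1e-8)
  expect_equal(mine$atoms$y, ref$atom$y, tolerance = 1e-8)
  expect_equal(mine$atoms$z, ref$atom$z, tolerance = 1e-8)
  expect_equal(mine$atoms$resno, ref$atom$resno)
})

test_that("altloc resolution keeps the highest-occupancy conformer, ties prefer A", {
  txt <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.60, altloc = "A"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 1, 1, 0, 0, occ = 0.40, altloc = "B")
  )
  m <- parse_structure(txt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$altloc, "A")
  expect_equal(m$atoms$x, 0)

  # occupancy tie broken toward altloc A even when B is listed first
  txt2 <- c(
    pdb_line("ATOM", 1, "CA", "SER", "A", 1, 1, 0, 0, occ = 0.50, altloc = "B"),
    pdb_line("ATOM", 2, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.50, altloc = "A")
  )
  m2 <- parse_structure(txt2)
  expect_equal(m2$atoms$altloc, "A")
})

test_that("degenerate and malformed inputs error informatively", {
  expect_error(parse_structure(""), "empty structure")
  expect_error(parse_structure("REMARK hello"), "empty structure")
  bad <- pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0)
  substr(bad, 31, 38) <- "  xx.yyy"
  expect_error(parse_structure(bad), "line 1")
})

test_that("proximity site ranks residues by minimum heavy-atom distance", {
  txt <- toy_pocket_pdb(xs = c(3, 1, 5, 2, 4))  # resno 1..5 at 3,1,5,2,4 A
  m <- parse_structure(txt)
  site <- define_site_by_proximity(m, toy_ligand(), k = 3)
  expect_equal(site$residues$resno, c(2, 4, 1))
  expect_equal(site$residues$min_distance, c(1, 2, 3))
  # k exceeding the residue count returns everything, still sorted
  all5 <- define_site_by_proximity(m, toy_ligand(), k = 99)
  expect_equal(nrow(all5$residues), 5L)
  expect_equal(all5$residues$min_distance, 1:5)
  expect_error(define_site_by_proximity(m, toy_ligand(), k = 0), "positive")
  expect_error(
    define_site_by_proximity(m, ligand_selection("Z", "XXX", 9)),
    "not found")
})

test_that("hydrogens are ignored on both sides of the distance", {
  txt <- c(
    pdb_line("ATOM", 1, "CB", "ALA", "A", 1, 6, 0, 0, element = "C"),
    pdb_line("ATOM", 2, "HB1", "ALA", "A", 1, 0.5, 0, 0, element = "H"),
    pdb_line("ATOM", 3, "CB", "ALA", "A", 2, 2, 0, 0, element = "C"),
    pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 0, 0, 0)
  )
  m <- parse_structure(txt)
  site <- define_site_by_proximity(m, toy_ligand(), k = 1)
  expect_equal(site$residues$resno, 2L)
  expect_equal(site$residues$min_distance, 2)
})

test_that("contact shell applies the cutoff inclusively and is monotone", {
  m <- parse_structure(toy_pocket_pdb(xs = c(3.9, 4.1, 1.0, 2.0, 5.0, 6.5, 7.0)))
  cont <- contact_residues(m, toy_ligand(), cutoff = 4.0)
  expect_setequal(cont$resno, c(1, 3, 4))
  expect_true(all(cont$min_distance <= 4.0))
  # tight cutoff on a non-clashing toy is empty
  expect_equal(nrow(contact_residues(m, toy_ligand(), cutoff = 0.1)), 0L)
  # nested cutoffs give nested residue sets
  for (cuts in list(c(1, 2), c(2, 4), c(4, 7))) {
    inner <- contact_residues(m, toy_ligand(), cutoff = cuts[1])$resno
    outer <- contact_residues(m, toy_ligand(), cutoff = cuts[2])$resno
    expect_true(all(inner %in% outer))
  }
  expect_error(contact_residues(m, toy_ligand(), cutoff = -1), "positive")
})

test_that("site definition equals brute-force distance sorting on random toys", {
  for (seed in 1:100) {
    toy <- generate_toy_structure(n_residues = 8, geometry = "sphere",
                                  seed = seed)
    m <- toy$model
    site <- define_site_by_proximity(m, toy_ligand(), k = 4)
    # brute force: all heavy-atom pairwise distances, aggregated by residue
    a <- m$atoms
    prot <- a[!a$is_hetero & a$element != "H", ]
    lig <- a[a$is_hetero, ]
    d <- vapply(split(prot, prot$resno), function(res) {
      min(apply(as.matrix(res[, c("x", "y", "z")]), 1, function(p) {
        min(sqrt((lig$x - p[1])^2 + (lig$y - p[2])^2 + (lig$z - p[3])^2))
      }))
    }, numeric(1))
    expected <- as.integer(names(sort(d))[1:4])
    expect_equal(site$residues$resno, expected)
    expect_equal(site$residues$min_distance, unname(sort(d)[1:4]))
  }
})

test_that("ties at the cut rank break deterministically by chain then residue", {
  txt <- c(
    pdb_line("ATOM", 1, "CA", "GLY", "B", 7, 2, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "B", 3, 0, 2, 0),
    pdb_line("ATOM", 3, "CA", "GLY", "B", 5, 0, 0, 2),
    pdb_line("HETATM", 4, "C1", "LIG", "L", 1, 0, 0, 0)
  )
  m <- parse_structure(txt)
  site <- define_site_by_proximity(m, toy_ligand(), k = 2)
  expect_equal(site$residues$resno, c(3, 5))
})
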
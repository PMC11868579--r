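test_that("reference position mapping skips gap columns", {
  aln <- alignment(c("ref", "o"), c("A-CD", "AACD"), "ref")
  expect_equal(map_reference_positions(aln), c(1L, 3L, 4L))
  # gapless reference maps position i to column i
  aln2 <- alignment(c("ref", "o"), c("ACDEFG", "ACDEYG"), "ref")
  expect_equal(map_reference_positions(aln2), 1:6)
  expect_error(
    map_reference_positions(alignment(c("ref", "o"), c("----", "ACDE"), "ref")),
    "all gaps")
})

test_that("pairwise identity matches hand counts", {
  aln <- toy_alignment()   # ref ACDEFG, orthA ACDEYG, orthB identical
  expect_equal(pairwise_identity(aln, "orthB"), 100)
  expect_equal(pairwise_identity(aln, "orthA"), 100 * 5 / 6, tolerance = 1e-12)
  # restricted to the single mismatching reference position 5
  expect_equal(pairwise_identity(aln, "orthA", columns = 5), 0)
  # restricted to columns where they agree
  expect_equal(pairwise_identity(aln, "orthA", columns = 1:4), 100)
  expect_error(pairwise_identity(aln, "missing"), "not present")
  expect_error(pairwise_identity(aln, "orthA", columns = 99), "outside")
})

test_that("gap and X handling follows the counting rules", {
  aln <- alignment(c("ref", "o"), c("AC-DEF", "A-CD-F"), "ref")
  # counted columns: 1,2,4,5,6 (ref non-gap); matches at 1,4,6; gap at 2,5
  expect_equal(pairwise_identity(aln, "o"), 100 * 3 / 5)
  # pairwise rule drops ortholog-gap columns from the denominator
  expect_equal(pairwise_identity(aln, "o", gap_rule = "pairwise"), 100)
  # X never matches, even X against X
  alnx <- alignment(c("ref", "o"), c("AXC", "AXC"), "ref")
  expect_equal(pairwise_identity(alnx, "o"), 100 * 2 / 3)
  # all columns excluded -> undefined, not zero
  expect_error(pairwise_identity(aln, "o", columns = 3), "undefined")
})

test_that("identity is unaffected by record order and reference-gap columns", {
  aln <- alignment(c("ref", "a", "b"),
                   c("AC-DEF", "ACQDEF", "GCWDEF"), "ref")
  shuffled <- alignment(c("b", "ref", "a"),
                        c("GCWDEF", "AC-DEF", "ACQDEF"), "ref")
  for (id in c("a", "b")) {
    expect_equal(pairwise_identity(aln, id), pairwise_identity(shuffled, id))
  }
  # mutating the inserted (reference-gap) column changes nothing
  aln2 <- alignment(c("ref", "a", "b"),
                    c("AC-DEF", "ACWDEF", "GCQDEF"), "ref")
  expect_equal(pairwise_identity(aln, "a"), pairwise_identity(aln2, "a"))
})

test_that("conservation profile separates a conserved site from background", {
  # 4-column site perfectly conserved, background diverged by hand
  aln <- alignment(c("ref", "o1", "o2"),
                   c("ACDEFGHIKL", "ACDEYWHIKL", "ACDEFGHMNP"),
                   "ref")
  site <- site_definition("core", 1:4)
  prof <- conservation_profile(aln, list(site))
  expect_s3_class(prof, "conservation_result")
  expect_equal(prof$core_identity, c(100, 100))
  expect_equal(prof$global_identity, c(80, 70))
  expect_true(all(prof$core_identity > prof$global_identity))
  # empty site list yields a global-only table
  glob <- conservation_profile(aln)
  expect_named(glob, c("id", "global_identity"))
  # a site position beyond the reference errors naming the position
  expect_error(conservation_profile(aln, list(site_definition("bad", 99))),
               "99")
})

test_that("construct numbering offsets shift site positions", {
  aln <- alignment(c("ref", "o"), c("ACDEFG", "ACDEYG"), "ref")
  # author numbering starts at 36: residue 40 is ungapped position 5
  site <- site_definition("s", 40, offset = 35)
  expect_equal(site$positions, 5L)
  expect_equal(conservation_profile(aln, list(site))$s_identity, 0)
})

test_that("generated families are more conserved at the site than globally", {
  gaps <- numeric(20)
  for (seed in 1:20) {
    fam <- generate_ortholog_family(length = 120, n_orthologs = 15,
                                    p_global = 0.15, p_site = 0.03,
                                    seed = seed)
    prof <- conservation_profile(fam$alignment, list(fam$site))
    gaps[seed] <- mean(prof$site_identity) - mean(prof$global_identity)
  }
  expect_true(all(gaps >= 0))
  # zero substitution everywhere forces a flat 100/100 profile
  flat <- generate_ortholog_family(length = 50, n_orthologs = 5,
                                   p_global = 0, p_site = 0, seed = 1)
  pflat <- conservation_profile(flat$alignment, list(flat$site))
  expect_true(all(pflat$global_identity == 100 & pflat$site_identity == 100))
})

test_that("aligned FASTA round-trips through read_alignment", {
  fam <- generate_ortholog_family(length = 60, n_orthologs = 4, seed = 8)
  tmp <- tempfile(fileext = ".fasta")
  writeLines(fam$fasta, tmp)
  aln <- read_alignment(tmp, reference_id = "reference")
  expect_equal(aln$ids, fam$alignment$ids)
  expect_equal(aln$seqs, fam$alignment$seqs, ignore_attr = TRUE)
})
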
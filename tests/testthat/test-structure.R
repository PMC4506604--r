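test_that("helix fixtures load with the expected chains, residues and C-alphas", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  make_helix(20, path = pdb)
  s <- load_structure(pdb)
  expect_s3_class(s, "protein_structure")
  expect_equal(chains(s), "A")
  res <- residue_table(s, "A")
  expect_equal(nrow(res), 20L)
  expect_true(all(res$has_ca))
  expect_equal(res$resno, 1:20)
  expect_equal(res$aa1, rep("A", 20))
})

test_that("multi-model files use the first model with a warning; empty files error", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  make_helix(10, path = pdb)
  atom_lines <- grep("^ATOM", readLines(pdb), value = TRUE)
  multi <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", atom_lines, "ENDMDL",
               "MODEL     2", atom_lines, "ENDMDL", "END"), multi)
  expect_warning(s <- load_structure(multi), "first model")
  expect_equal(nrow(s$atoms), 10L)
  expect_equal(s$n_models, 2L)

  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(load_structure(empty), "empty")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  s <- load_structure(pdb)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(residue_table(s, "A")$x[1], 9.0)
})

test_that("waters are dropped and hetero groups are kept separately", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C1  LIG A 101       1.000   1.000   1.000  1.00  0.00           C",
    "HETATM    3  O   HOH A 201       5.000   5.000   5.000  1.00  0.00           O",
    "END"), pdb)
  s <- load_structure(pdb)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(nrow(s$het), 1L)
  expect_equal(s$het$resid, "LIG")
})

test_that("identifier resolution honours cache and offline mode", {
  cache <- withr::local_tempdir()
  make_helix(5, path = file.path(cache, "1abc.pdb"))
  s <- load_structure("1abc", cache_dir = cache, offline = TRUE)
  expect_equal(s$structure_id, "1ABC")
  expect_error(load_structure("2xyz", cache_dir = cache, offline = TRUE),
               "offline miss")
  expect_error(load_structure("not-an-id-or-file", cache_dir = cache),
               "neither")
})

test_that("structure selection maximizes sequence span with deterministic ties", {
  cat_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein\tpdb_id\tfirst_res\tlast_res",
               "P1\t1AAA\t10\t100",
               "P1\t1BBB\t1\t300",
               "P2\t2BBB\t1\t50",
               "P2\t2AAA\t11\t60"), cat_file)
  expect_equal(select_structure("P1", cat_file), "1BBB")
  expect_equal(select_structure("P2", cat_file), "2AAA")  # equal span: lexicographic
  expect_equal(select_structure("P1", cat_file, preferred = "9XYZ"), "9XYZ")
  expect_error(select_structure("P9", cat_file), "no structure")
})

test_that("direct mapping verifies the wild type and reports C-alpha coordinates", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  make_helix(20, path = pdb)
  s <- load_structure(pdb)
  f <- withr::local_tempfile(fileext = ".tsv")
  make_variant_tsv(f, data.frame(gene = "TOY", protein_change = c("A5G", "W5G")))
  v <- parse_tsv(f)$variants
  m <- map_variants(v, s)
  a5 <- m[m$sub == "A5G", ]
  expect_equal(a5$status, "mapped")
  expect_equal(a5$resno, 5L)
  expect_equal(a5$offset_applied, 0L)
  # generator coordinate, bit-exact against the written file's 3-decimal value
  ang <- 100 * pi / 180 * 4
  expect_equal(calpha_of(a5),
               round(c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * 4), 3))
  w5 <- m[m$sub == "W5G", ]
  expect_equal(w5$status, "unmapped")
  expect_equal(w5$reason, "wt_mismatch")
  expect_error(calpha_of(w5), "unmapped")
  out_of_range <- map_variants(data.frame(
    gene = "TOY", wt = "W", pos = 500L, mut = "G", chrom = NA, genomic_pos = NA,
    ref = NA, alt = NA, pdb = NA, source_line = 1L), s)
  expect_equal(out_of_range$reason, "not_in_structure")
})

test_that("a consistent renumbering offset is recovered from variant consensus", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  seq20 <- "ACDEFGHIKLMNPQRSTVWY"
  make_helix(20, offset = 10L, path = pdb, sequence = seq20)
  s <- load_structure(pdb)
  v <- data.frame(gene = "TOY", wt = c("C", "L", "W"), pos = c(2L, 10L, 19L),
                  mut = c("G", "G", "G"), chrom = NA, genomic_pos = NA,
                  ref = NA, alt = NA, pdb = NA, source_line = 1:3)
  m <- map_variants(v, s)
  expect_true(all(m$status == "mapped"))
  expect_true(all(m$offset_applied == 10L))
  expect_equal(m$resno, c(12L, 20L, 29L))
})

test_that("mapping is deterministic and wild types always verify on mapped rows", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  make_helix(20, path = pdb, sequence = "ACDEFGHIKLMNPQRSTVWY")
  s <- load_structure(pdb)
  v <- data.frame(gene = "TOY", wt = c("A", "F", "Y"), pos = c(1L, 5L, 20L),
                  mut = c("G", "L", "C"), chrom = NA, genomic_pos = NA,
                  ref = NA, alt = NA, pdb = NA, source_line = 1:3)
  m1 <- map_variants(v, s)
  m2 <- map_variants(v, s)
  expect_identical(m1, m2)
  res <- residue_table(s, "A")
  for (i in which(m1$status == "mapped")) {
    expect_equal(res$aa1[res$resno == m1$resno[i]], m1$wt[i])
  }
})

test_that("a mapped residue without a C-alpha atom is demoted", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), pdb)
  s <- load_structure(pdb)
  v <- data.frame(gene = "TOY", wt = "A", pos = 2L, mut = "G", chrom = NA,
                  genomic_pos = NA, ref = NA, alt = NA, pdb = NA, source_line = 1L)
  m <- map_variants(v, s)
  expect_equal(m$status, "unmapped")
  expect_equal(m$reason, "no_calpha")
})
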
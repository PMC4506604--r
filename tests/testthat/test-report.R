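test_that("a full run populates every section and conserves variant counts", {
  bundle <- build_toy_bundle(withr::local_tempdir())
  out <- withr::local_tempdir()
  res <- run_pipeline(toy_bundle_config(bundle, out))
  expect_s3_class(res, "run_result")
  # conservation: every input line is a record, a reject or a skip
  expect_equal(nrow(res$variants) + nrow(res$parsed$rejects) + res$parsed$skipped,
               res$parsed$n_data_lines)
  # every parsed variant appears exactly once per chain in the mapped table
  expect_equal(nrow(res$mapped), nrow(res$variants) * length(chains(res$structure)))
  expect_true(all(c("report.html", "variants.tsv", "clusters.tsv", "pockets.tsv",
                    "flagged.pdb", "viewer_script.txt", "run.json")
                  %in% list.files(out)))
  html <- readLines(file.path(out, "report.html"))
  expect_true(any(grepl("Clusters", html)))
  expect_true(any(grepl("Provenance", html)))
  # one variant table row per variant-chain pair
  vt <- utils::read.delim(file.path(out, "variants.tsv"))
  expect_equal(nrow(vt), nrow(res$mapped))
  # annotation lands in the per-variant table; unannotated cells read n/a
  expect_match(vt$annotations[vt$variant == "F5L"], "pathogenic")
  expect_equal(vt$annotations[vt$variant == "A1G"], "n/a")
  # summary counts in the HTML equal the table sums
  expect_true(any(grepl(sprintf("%d of %d variant-chain pairs mapped",
                                sum(res$mapped$status == "mapped"),
                                nrow(res$mapped)), html)))
  prov <- jsonlite::read_json(file.path(out, "run.json"))
  expect_equal(prov$cluster_threshold, 20)
  expect_equal(prov$structure_id, "HELIX")
})

test_that("a run with zero mappable variants degrades to an explicit empty report", {
  dir <- withr::local_tempdir()
  helix <- file.path(dir, "helix.pdb")
  make_helix(10, path = helix)  # poly-ALA: tryptophan variants cannot map
  variants <- file.path(dir, "v.tsv")
  writeLines(c("gene\tprotein_change", "TOY1\tW2G"), variants)
  cfg <- pipeline_config(input = variants, format = "tsv", pdb = helix,
                         out_dir = file.path(dir, "out"),
                         timestamp = "2026-01-01 00:00:00 UTC")
  res <- run_pipeline(cfg)
  expect_true(any(grepl("no variants could be mapped", res$warnings)))
  expect_null(res$tree)
  html <- readLines(file.path(dir, "out", "report.html"))
  expect_true(any(grepl("no clusters at threshold", html)))
})

test_that("pocket detection on a convex structure reports an empty, noted section", {
  dir <- withr::local_tempdir()
  convex <- file.path(dir, "convex.pdb")
  make_convex(30, convex)
  variants <- file.path(dir, "v.tsv")
  writeLines(c("gene\tprotein_change", "TOY1\tA1G"), variants)
  cfg <- pipeline_config(input = variants, format = "tsv", pdb = convex,
                         pockets = TRUE, out_dir = file.path(dir, "out"),
                         timestamp = "2026-01-01 00:00:00 UTC")
  res <- run_pipeline(cfg)
  expect_equal(nrow(res$pockets), 0L)
  expect_true(any(grepl("no buried cleft", res$warnings)))
  html <- readLines(file.path(dir, "out", "report.html"))
  expect_true(any(grepl("no buried cleft", html)))
})

test_that("flagged structures carry cluster indices as B-factors and preserve coordinates", {
  dir <- withr::local_tempdir()
  helix <- file.path(dir, "helix.pdb")
  make_helix(20, path = helix)
  variants <- file.path(dir, "v.tsv")
  # two tight pairs plus one remote singleton, cut at 5 A
  writeLines(c("gene\tprotein_change", "TOY1\tA1G", "TOY1\tA2G",
               "TOY1\tA10G", "TOY1\tA11G", "TOY1\tA19G"), variants)
  cfg <- pipeline_config(input = variants, format = "tsv", pdb = helix,
                         cluster_threshold = 5,
                         out_dir = file.path(dir, "out"),
                         timestamp = "2026-01-01 00:00:00 UTC")
  res <- run_pipeline(cfg)
  expect_equal(nrow(res$cut$clusters), 2L)
  flagged <- bio3d::read.pdb(file.path(dir, "out", "flagged.pdb"), verbose = FALSE)
  expect_setequal(unique(flagged$atom$b), c(0, 1, 2))
  flagged_res <- flagged$atom$resno[flagged$atom$b > 0]
  expect_setequal(flagged_res, c(1L, 2L, 10L, 11L))
  # round trip: coordinates survive bit-exactly
  orig <- bio3d::read.pdb(helix, verbose = FALSE)
  expect_identical(flagged$atom$x, orig$atom$x)
  expect_identical(flagged$atom$y, orig$atom$y)
  expect_identical(flagged$atom$z, orig$atom$z)
  script <- readLines(file.path(dir, "out", "viewer_script.txt"))
  expect_true(any(grepl("cluster1", script)))
  expect_true(any(grepl("cluster2", script)))
  expect_true(any(grepl("singletons", script)))
})

test_that("a single flagged variant gets B-factor 0 everywhere", {
  dir <- withr::local_tempdir()
  helix <- file.path(dir, "helix.pdb")
  make_helix(10, path = helix)
  variants <- file.path(dir, "v.tsv")
  writeLines(c("gene\tprotein_change", "TOY1\tA5G"), variants)
  cfg <- pipeline_config(input = variants, format = "tsv", pdb = helix,
                         out_dir = file.path(dir, "out"),
                         timestamp = "2026-01-01 00:00:00 UTC")
  run_pipeline(cfg)
  flagged <- bio3d::read.pdb(file.path(dir, "out", "flagged.pdb"), verbose = FALSE)
  expect_equal(unique(flagged$atom$b), 0)
})

test_that("inputs spanning several genes require an explicit structure", {
  dir <- withr::local_tempdir()
  variants <- file.path(dir, "v.tsv")
  writeLines(c("gene\tprotein_change", "G1\tA1G", "G2\tA2G"), variants)
  cfg <- pipeline_config(input = variants, format = "tsv")
  expect_error(run_pipeline(cfg), "one protein at a time")
})
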
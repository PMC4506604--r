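# A standard toy analysis bundle: a diverse-sequence helix structure, a
# variant table exercising mapped/unmapped/rejected paths, and toy database
# snapshots. Used by the pipeline and acceptance tests.
build_toy_bundle <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  helix <- file.path(dir, "helix.pdb")
  make_helix(20, path = helix, sequence = "ACDEFGHIKLMNPQRSTVWY")
  variants <- file.path(dir, "variants.tsv")
  writeLines(c("gene\tprotein_change",
               "TOY1\tA1G",      # mapped, cluster with F5L
               "TOY1\tF5L",      # mapped, annotated pathogenic
               "TOY1\tY20C",     # mapped singleton at the far end
               "TOY1\tW3G",      # wild-type mismatch (position 3 is D)
               "TOY1\tbroken"),  # parser reject
             variants)
  humsavar <- file.path(dir, "humsavar.txt")
  make_humsavar_snippet(humsavar, data.frame(
    gene = "TOY1", acc = "P00001", ftid = "VAR_000010",
    change = "p.Phe5Leu", category = "LP/P", dbsnp = "rs10", disease = "toy"))
  clinvar <- file.path(dir, "clinvar.tsv")
  make_clinvar_snippet(clinvar, data.frame(
    gene = "TOY1", significance = "Uncertain significance", assembly = "GRCh37",
    chrom = "1", pos = 1000, ref = "A", alt = "G",
    name = "NM_000001.1(TOY1):c.58T>C (p.Tyr20Cys)"))
  list(dir = dir, helix = helix, variants = variants,
       humsavar = humsavar, clinvar = clinvar)
}

toy_bundle_config <- function(bundle, out_dir = NULL, ...) {
  pipeline_config(
    input = bundle$variants, format = "tsv", pdb = bundle$helix,
    humsavar = bundle$humsavar, clinvar = bundle$clinvar,
    cluster_threshold = 20, pockets = TRUE, stability = "baseline",
    out_dir = out_dir, timestamp = "2026-01-01 00:00:00 UTC", ...)
}
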
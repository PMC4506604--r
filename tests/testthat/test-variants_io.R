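test_that("protein-change tokens parse in compact and HGVS forms", {
  expect_equal(parse_protein_change("L527I"), list(wt = "L", pos = 527L, mut = "I"))
  expect_equal(parse_protein_change("p.Tyr370Cys"), list(wt = "Y", pos = 370L, mut = "C"))
  expect_equal(parse_protein_change("p.M384V"), list(wt = "M", pos = 384L, mut = "V"))
  expect_error(parse_protein_change("L527L"), "synonymous")
  expect_error(parse_protein_change("p.Xxx12Tyr"), "unknown amino-acid")
  expect_error(parse_protein_change("527LI"), "malformed")
  expect_error(parse_protein_change("B12C"), "unknown amino-acid")
})

test_that("simple TSV parsing keeps records, rejects and line numbers", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  make_variant_tsv(tsv, data.frame(
    gene = c("JUP", "SMYD2", "SMYD2"),
    protein_change = c("L527I", "Y370C", "M384V")))
  p <- parse_tsv(tsv)
  expect_equal(nrow(p$variants), 3L)
  expect_equal(nrow(p$rejects), 0L)
  expect_equal(p$variants$gene, c("JUP", "SMYD2", "SMYD2"))
  expect_equal(p$variants$pos, c(527L, 370L, 384L))

  # one malformed token among 4 lines: 3 records + 1 reject with line number
  writeLines(c("gene\tprotein_change",
               "JUP\tL527I", "SMYD2\tY370C", "SMYD2\tbroken", "VCL\tR230H"), tsv)
  p2 <- parse_tsv(tsv)
  expect_equal(nrow(p2$variants), 3L)
  expect_equal(nrow(p2$rejects), 1L)
  expect_equal(p2$rejects$line, 4L)
  expect_match(p2$rejects$reason, "malformed")

  # empty file with valid header
  writeLines("gene\tprotein_change", tsv)
  expect_equal(nrow(parse_tsv(tsv)$variants), 0L)

  writeLines("gene\tsomething", tsv)
  expect_error(parse_tsv(tsv), "protein_change")
})

test_that("TSV parsing deduplicates repeated substitutions with a warning", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tprotein_change", "JUP\tL527I", "JUP\tL527I"), tsv)
  expect_warning(p <- parse_tsv(tsv), "duplicate")
  expect_equal(nrow(p$variants), 1L)
  expect_equal(p$skipped, 1L)
})

test_that("ANNOVAR tables keep only nonsynonymous SNVs and fall back across transcripts", {
  av <- withr::local_tempfile(fileext = ".txt")
  make_annovar_table(av, data.frame(
    class = c("nonsynonymous SNV", "synonymous SNV", "nonsynonymous SNV"),
    annotation = c("JUP:NM_002230:exon10:c.C1579A:p.L527I,",
                   "JUP:NM_002230:exon5:c.C700T:p.L234L,",
                   "SMYD2:NM_020193:exon1:c.foo,SMYD2:NM_020193b:exon8:c.A1109G:p.Y370C,"),
    chrom = c("chr17", "chr17", "chr1"),
    start = c(39913793, 39920000, 214454322),
    end = c(39913793, 39920000, 214454322),
    ref = c("G", "C", "T"), alt = c("T", "T", "C")))
  p <- parse_annovar(av)
  expect_equal(nrow(p$variants), 2L)
  expect_equal(p$skipped, 1L)
  # the second line's first transcript entry has no p. token -> fallback
  subs <- paste0(p$variants$wt, p$variants$pos, p$variants$mut)
  expect_equal(subs, c("L527I", "Y370C"))
  expect_equal(p$variants$chrom, c("17", "1"))
  expect_equal(p$variants$genomic_pos, c(39913793L, 214454322L))

  # empty annotation string on a nonsynonymous line is a reject, not a crash
  make_annovar_table(av, data.frame(class = "nonsynonymous SNV", annotation = "",
                                    chrom = "chr1", start = 1, end = 1,
                                    ref = "A", alt = "G"))
  p2 <- parse_annovar(av)
  expect_equal(nrow(p2$variants), 0L)
  expect_equal(nrow(p2$rejects), 1L)

  writeLines("too\tfew\tcolumns", av)
  expect_error(parse_annovar(av), "layout")
})

test_that("minimal VCF parsing expands multi-allelic records and counts skips", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  make_minimal_vcf(vcf, data.frame(
    chrom = c("17", "1"), pos = c(100L, 200L), ref = c("A", "C"),
    alt = c("G", "T"), ann = c("JUP|L527I", "SMYD2|p.Tyr370Cys")))
  p <- parse_minimal_vcf(vcf, "PCH")
  expect_equal(nrow(p$variants), 2L)
  expect_equal(p$variants$ref, c("A", "C"))

  # multi-allelic ALT: one record per annotated ALT allele
  make_minimal_vcf(vcf, data.frame(
    chrom = "1", pos = 200L, ref = "C", alt = "T,A",
    ann = "SMYD2|Y370C,SMYD2|Y370S"))
  p2 <- parse_minimal_vcf(vcf, "PCH")
  expect_equal(nrow(p2$variants), 2L)
  expect_equal(p2$variants$alt, c("T", "A"))
  expect_equal(p2$variants$mut, c("C", "S"))

  # zero annotated records: empty list plus a counted warning
  make_minimal_vcf(vcf, data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                                   ann = NA))
  expect_warning(p3 <- parse_minimal_vcf(vcf, "PCH"), "0 annotated")
  expect_equal(nrow(p3$variants), 0L)
  expect_equal(p3$skipped, 1L)

  notvcf <- withr::local_tempfile(fileext = ".txt")
  writeLines("gene\tprotein_change", notvcf)
  expect_error(parse_minimal_vcf(notvcf, "PCH"), "not a VCF")
})

test_that("TSV round trip reproduces the record list", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  make_variant_tsv(tsv, data.frame(
    gene = c("JUP", "VCL"), protein_change = c("L527I", "R230H"),
    chrom = c("17", "."), pos = c("39913793", "."),
    ref = c("G", "."), alt = c("T", "."), pdb = c("1ABC", ".")))
  p <- parse_tsv(tsv)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(p$variants, out)
  p2 <- parse_tsv(out)
  for (colname in c("gene", "wt", "pos", "mut", "chrom", "genomic_pos",
                    "ref", "alt", "pdb")) {
    expect_equal(p2$variants[[colname]], p$variants[[colname]], info = colname)
  }
})
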
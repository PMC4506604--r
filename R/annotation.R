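# Pathogenicity annotation from local database snapshots: the UniProt
# HUMSAVAR catalogue of human missense variants and an NCBI ClinVar
# variant_summary table. Snapshots are user-supplied files — nothing is ever
# downloaded — and label normalization is driven by a shipped, editable
# mapping table so further databases can be added without touching code.

normalization_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "label_normalization.tsv", package = "structvar")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Normalize a pathogenicity label
#'
#' Exact matches against the shipped mapping table win. Unmapped ClinVar
#' labels (free-text combinations) fall back to a containment rule: a label
#' mentioning "benign" but not "pathogenic" is benign, "pathogenic" but not
#' "benign" is pathogenic, both or "uncertain" is uncertain, anything else is
#' other.
#'
#' @param source `"humsavar"` or `"clinvar"`.
#' @param label raw label string.
#' @return one of `"benign"`, `"pathogenic"`, `"uncertain"`, `"other"`.
#' @export
normalize_label <- function(source, label) {
  map <- normalization_map()
  hit <- map$normalized[map$source == source & map$label == label]
  if (length(hit) >= 1L) return(hit[1])
  l <- tolower(label)
  has_b <- grepl("benign", l); has_p <- grepl("pathogenic", l)
  if (has_b && !has_p) return("benign")
  if (has_p && !has_b) return("pathogenic")
  if ((has_b && has_p) || grepl("uncertain|conflicting", l)) return("uncertain")
  "other"
}

#' Load a HUMSAVAR snapshot
#'
#' Parses the HUMSAVAR flat file (free-text preamble followed by fixed-layout
#' data lines: gene symbol, Swiss-Prot accession, FTId, `p.` change, variant
#' category, dbSNP identifier, disease name). Both the legacy categories
#' (`Disease` / `Polymorphism` / `Unclassified`) and the current ones
#' (`LP/P` / `LB/B` / `US`) are accepted and normalized.
#'
#' @param path path to the snapshot file.
#' @return lookup table keyed by `gene:wt:pos:mut`, class `humsavar_table`.
#' @export
load_humsavar <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  data <- grep("^\\S+\\s+\\S+\\s+VAR_\\d+\\s+p\\.", lines, value = TRUE)
  if (length(data) == 0L) {
    stop(sprintf("no parsable HUMSAVAR data line in %s", path))
  }
  rows <- list()
  for (ln in data) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 5L) next
    p <- tryCatch(parse_protein_change(f[4]), error = function(e) NULL)
    if (is.null(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = f[1], acc = f[2], ftid = f[3],
      wt = p$wt, pos = p$pos, mut = p$mut,
      label = f[5],
      normalized = normalize_label("humsavar", f[5]),
      dbsnp = if (length(f) >= 6L) f[6] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop(sprintf("no parsable HUMSAVAR data line in %s", path))
  tab <- do.call(rbind, rows)
  tab$key <- paste(tab$gene, tab$wt, tab$pos, tab$mut, sep = ":")
  structure(list(table = tab, path = path), class = "humsavar_table")
}

#' Load a ClinVar variant-summary snapshot
#'
#' Reads a tab-delimited `variant_summary`-style table by column name. Rows
#' whose assembly is not GRCh37 are ignored (the pipeline's genomic
#' coordinates are hg19). Two lookup keys are built per retained row: a
#' genomic key (chromosome, position, ref, alt) and — when the `Name` column
#' carries a parsable `p.` change — a protein key (gene, wt, pos, mut).
#'
#' @param path path to the snapshot file.
#' @param assembly assembly to retain (default `"GRCh37"`).
#' @return lookup table, class `clinvar_table`.
#' @export
load_clinvar <- function(path, assembly = "GRCh37") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  colnames(df) <- sub("^#", "", colnames(df))
  need <- c("GeneSymbol", "ClinicalSignificance", "Assembly", "Chromosome",
            "PositionVCF", "ReferenceAlleleVCF", "AlternateAlleleVCF", "Name")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop(sprintf("ClinVar snapshot %s lacks column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df <- df[df$Assembly == assembly, , drop = FALSE]
  df$normalized <- vapply(df$ClinicalSignificance,
                          function(l) normalize_label("clinvar", l), character(1),
                          USE.NAMES = FALSE)
  df$genomic_key <- paste(df$Chromosome, df$PositionVCF,
                          df$ReferenceAlleleVCF, df$AlternateAlleleVCF, sep = ":")
  pkey <- rep(NA_character_, nrow(df))
  hit <- regexpr("p\\.[A-Za-z]{3}[0-9]+[A-Za-z]{3}", df$Name) > 0
  for (i in which(hit)) {
    p <- tryCatch(parse_protein_change(
      regmatches(df$Name[i], regexpr("p\\.[A-Za-z]{3}[0-9]+[A-Za-z]{3}", df$Name[i]))),
      error = function(e) NULL)
    if (!is.null(p)) pkey[i] <- paste(df$GeneSymbol[i], p$wt, p$pos, p$mut, sep = ":")
  }
  df$protein_key <- pkey
  structure(list(table = df, path = path, assembly = assembly),
            class = "clinvar_table")
}

#' Attach pathogenicity annotations to one variant
#'
#' HUMSAVAR is matched on the protein key (gene, wild type, position,
#' mutant). ClinVar is matched on the genomic key when the variant carries
#' genomic coordinates, falling back to the protein key; a genomic match
#' takes precedence and suppresses the protein-key match within ClinVar.
#' Both sources report independently; conflicting labels are both retained,
#' never merged.
#'
#' @param variant one row of the canonical variant table.
#' @param humsavar a `humsavar_table`, or `NULL`.
#' @param clinvar a `clinvar_table`, or `NULL`.
#' @return data.frame with `source`, `label`, `normalized`, `match_key`
#'   (zero rows when the variant is absent from every table).
#' @export
annotate_variant <- function(variant, humsavar = NULL, clinvar = NULL) {
  out <- list()
  pkey <- paste(variant$gene, variant$wt, variant$pos, variant$mut, sep = ":")
  if (!is.null(humsavar)) {
    hit <- humsavar$table[humsavar$table$key == pkey, , drop = FALSE]
    for (i in seq_len(nrow(hit))) {
      out[[length(out) + 1L]] <- data.frame(
        source = "humsavar", label = hit$label[i], normalized = hit$normalized[i],
        match_key = sprintf("protein:%s", pkey), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(clinvar)) {
    tab <- clinvar$table
    hit <- NULL
    if (!is.na(variant$chrom) && !is.na(variant$genomic_pos) &&
        !is.na(variant$ref) && !is.na(variant$alt)) {
      gkey <- paste(variant$chrom, variant$genomic_pos, variant$ref, variant$alt,
                    sep = ":")
      g <- tab[tab$genomic_key == gkey, , drop = FALSE]
      if (nrow(g) > 0L) hit <- list(rows = g, how = sprintf("genomic:%s", gkey))
    }
    if (is.null(hit)) {
      p <- tab[!is.na(tab$protein_key) & tab$protein_key == pkey, , drop = FALSE]
      if (nrow(p) > 0L) hit <- list(rows = p, how = sprintf("protein:%s", pkey))
    }
    if (!is.null(hit)) {
      for (i in seq_len(nrow(hit$rows))) {
        out[[length(out) + 1L]] <- data.frame(
          source = "clinvar", label = hit$rows$ClinicalSignificance[i],
          normalized = hit$rows$normalized[i], match_key = hit$how,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(source = character(), label = character(),
                      normalized = character(), match_key = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Annotate a whole variant table
#'
#' @param variants canonical variant data.frame.
#' @inheritParams annotate_variant
#' @return data.frame with one row per annotation record, keyed by the
#'   variant's `gene` and substitution `sub`.
#' @export
annotate_variants <- function(variants, humsavar = NULL, clinvar = NULL) {
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    ann <- annotate_variant(variants[v, , drop = FALSE], humsavar, clinvar)
    if (nrow(ann) > 0L) {
      ann$gene <- variants$gene[v]
      ann$sub <- paste0(variants$wt[v], variants$pos[v], variants$mut[v])
      rows[[length(rows) + 1L]] <- ann
    }
  }
  if (!length(rows)) {
    return(data.frame(source = character(), label = character(),
                      normalized = character(), match_key = character(),
                      gene = character(), sub = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
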
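# Parsers turning variant inputs (simple TSV, ANNOVAR exonic table, minimal
# VCF) into a canonical variant table. The canonical form is a data.frame with
# one row per non-synonymous substitution:
#   gene, wt, pos, mut, chrom, genomic_pos, ref, alt, pdb, source_line
# wt/mut are one-letter codes; pos is the 1-based protein sequence position.

empty_variants <- function() {
  data.frame(
    gene = character(), wt = character(), pos = integer(), mut = character(),
    chrom = character(), genomic_pos = integer(),
    ref = character(), alt = character(), pdb = character(),
    source_line = integer(), stringsAsFactors = FALSE
  )
}

empty_rejects <- function() {
  data.frame(line = integer(), text = character(), reason = character(),
             stringsAsFactors = FALSE)
}

new_variant_parse <- function(variants, rejects, skipped, n_data_lines, source) {
  structure(
    list(variants = variants, rejects = rejects, skipped = skipped,
         n_data_lines = n_data_lines, source = source),
    class = "variant_parse"
  )
}

#' @export
print.variant_parse <- function(x, ...) {
  cat(sprintf("Variant parse of %s\n", x$source))
  cat(sprintf("  %d data line(s): %d record(s), %d reject(s), %d skipped\n",
              x$n_data_lines, nrow(x$variants), nrow(x$rejects), x$skipped))
  invisible(x)
}

#' Parse a protein-change token
#'
#' Accepts the compact one-letter form (`"L527I"`) and the HGVS protein form
#' with three-letter (`"p.Leu527Ile"`) or one-letter (`"p.L527I"`) codes.
#' Three-letter codes are converted to one-letter internally.
#'
#' @param token a single protein-change string.
#' @return list with `wt`, `pos`, `mut` (one-letter codes, integer position).
#'   Synonymous tokens (wild-type equals mutant) and unknown amino-acid codes
#'   are errors: a substitution that changes nothing is not a missense variant.
#' @examples
#' parse_protein_change("L527I")
#' parse_protein_change("p.Tyr370Cys")
#' @export
parse_protein_change <- function(token) {
  if (length(token) != 1L || !is.character(token) || is.na(token)) {
    stop("protein change token must be a single string")
  }
  tok <- trimws(token)
  m3 <- regmatches(tok, regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", tok))[[1]]
  m1 <- regmatches(tok, regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", tok))[[1]]
  if (length(m3) == 4L) {
    wt <- aa_three_to_one(m3[2]); mut <- aa_three_to_one(m3[4]); pos <- as.integer(m3[3])
    if (is.na(wt) || is.na(mut)) {
      stop(sprintf("unknown amino-acid code in '%s'", tok))
    }
  } else if (length(m1) == 4L) {
    wt <- toupper(m1[2]); mut <- toupper(m1[4]); pos <- as.integer(m1[3])
    if (!is_standard_aa1(wt) || !is_standard_aa1(mut)) {
      stop(sprintf("unknown amino-acid code in '%s'", tok))
    }
  } else {
    stop(sprintf("malformed protein change token '%s'", tok))
  }
  if (is.na(pos) || pos < 1L) stop(sprintf("invalid position in '%s'", tok))
  if (wt == mut) stop(sprintf("synonymous change '%s' (wild type equals mutant)", tok))
  list(wt = wt, pos = pos, mut = mut)
}

variant_row <- function(gene, change, line,
                        chrom = NA_character_, genomic_pos = NA_integer_,
                        ref = NA_character_, alt = NA_character_,
                        pdb = NA_character_) {
  p <- parse_protein_change(change)
  data.frame(
    gene = gene, wt = p$wt, pos = p$pos, mut = p$mut,
    chrom = chrom, genomic_pos = genomic_pos, ref = ref, alt = alt,
    pdb = pdb, source_line = line, stringsAsFactors = FALSE
  )
}

# De-duplicate on gene + substitution; duplicates are counted as skipped so
# records + rejects + skipped still equals the number of data lines.
dedup_variants <- function(variants) {
  if (nrow(variants) == 0L) return(list(variants = variants, n_dropped = 0L))
  key <- paste(variants$gene, variants$wt, variants$pos, variants$mut)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicate variant(s) dropped (same gene and substitution)",
                    sum(dup)), call. = FALSE)
  }
  list(variants = variants[!dup, , drop = FALSE], n_dropped = sum(dup))
}

#' Parse a simple tab-separated variant table
#'
#' Dialect: UTF-8, tab-separated, `#` comment lines, mandatory header columns
#' `gene` and `protein_change`; optional `chrom`, `pos`, `ref`, `alt`, `pdb`
#' (a preferred PDB identifier or local model file for that variant's protein).
#'
#' Data lines whose protein-change token fails to parse are collected in the
#' `rejects` table with their line number and reason, never silently dropped.
#' Exact duplicates of gene + substitution are dropped with a warning and
#' counted as skipped.
#'
#' @param path path to the TSV file.
#' @return a `variant_parse` object: `variants` (canonical variant data.frame),
#'   `rejects`, `skipped` count and `n_data_lines`.
#' @export
parse_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("file contains no header line")
  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  required <- c("gene", "protein_change")
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop(sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")))
  }
  data_idx <- idx[-1]
  recs <- list(); rejects <- empty_rejects()
  col <- function(fields, name) {
    j <- match(name, header)
    if (is.na(j) || j > length(fields)) return(NA_character_)
    v <- trimws(fields[j])
    if (!nzchar(v) || v == ".") NA_character_ else v
  }
  for (ln in data_idx) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    res <- tryCatch(
      variant_row(
        gene = col(fields, "gene"), change = col(fields, "protein_change"),
        line = ln,
        chrom = col(fields, "chrom"),
        genomic_pos = suppressWarnings(as.integer(col(fields, "pos"))),
        ref = col(fields, "ref"), alt = col(fields, "alt"),
        pdb = col(fields, "pdb")
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      rejects <- rbind(rejects, data.frame(line = ln, text = lines[ln],
                                           reason = res, stringsAsFactors = FALSE))
    } else {
      recs[[length(recs) + 1L]] <- res
    }
  }
  variants <- if (length(recs)) do.call(rbind, recs) else empty_variants()
  dd <- dedup_variants(variants)
  new_variant_parse(dd$variants, rejects, dd$n_dropped, length(data_idx), path)
}

#' Parse an ANNOVAR exonic variant-function table
#'
#' Expects the tab-separated `exonic_variant_function` layout: column 1 a line
#' identifier, column 2 the functional class, column 3 the comma-separated
#' `gene:transcript:exon:c.:p.` annotation string, then the original input
#' columns chromosome, start, end, reference allele, alternate allele (hg19
#' coordinates).
#'
#' Only lines whose functional class is exactly `"nonsynonymous SNV"` yield
#' records; lines of other classes are counted as skipped, not errors. Where
#' the annotation string lists several transcripts, the first entry with a
#' parsable `p.` change is used.
#'
#' @param path path to the ANNOVAR table.
#' @return a `variant_parse` object.
#' @export
parse_annovar <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  recs <- list(); rejects <- empty_rejects(); skipped <- 0L
  for (ln in keep) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8L) {
      stop(sprintf("line %d: not an ANNOVAR exonic_variant_function layout (found %d columns, need >= 8)",
                   ln, length(fields)))
    }
    class_ <- trimws(fields[2])
    if (class_ != "nonsynonymous SNV") { skipped <- skipped + 1L; next }
    anno <- trimws(fields[3])
    entries <- strsplit(anno, ",", fixed = TRUE)[[1]]
    entries <- entries[nzchar(trimws(entries))]
    built <- NULL
    for (entry in entries) {
      parts <- strsplit(trimws(entry), ":", fixed = TRUE)[[1]]
      ptok <- parts[grepl("^p\\.", parts)]
      if (length(ptok) == 0L) next
      res <- tryCatch(
        variant_row(
          gene = parts[1], change = ptok[1], line = ln,
          chrom = sub("^chr", "", fields[4]),
          genomic_pos = suppressWarnings(as.integer(fields[5])),
          ref = fields[7], alt = fields[8]
        ),
        error = function(e) NULL
      )
      if (!is.null(res)) { built <- res; break }
    }
    if (is.null(built)) {
      rejects <- rbind(rejects, data.frame(
        line = ln, text = lines[ln],
        reason = "no parsable p. annotation entry", stringsAsFactors = FALSE))
    } else {
      recs[[length(recs) + 1L]] <- built
    }
  }
  variants <- if (length(recs)) do.call(rbind, recs) else empty_variants()
  dd <- dedup_variants(variants)
  new_variant_parse(dd$variants, rejects, skipped + dd$n_dropped, length(keep), path)
}

#' Parse a minimally annotated VCF
#'
#' Supports VCF 4.x files whose records carry an INFO field (named by the
#' caller) with one `GENE|PROTEIN_CHANGE` value per ALT allele, comma-separated
#' in ALT order; `.` marks an un-annotated allele. Records lacking the key are
#' counted as skipped with a warning. CHROM/POS/REF/ALT are copied onto the
#' records; multi-allelic sites expand to one record per annotated ALT allele.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param info_key name of the INFO field carrying the annotation.
#' @return a `variant_parse` object. Conservation is accounted per VCF record
#'   line: a line counts as a record line if at least one of its alleles
#'   parsed, otherwise as a reject or a skip.
#' @export
parse_minimal_vcf <- function(path, info_key) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !grepl("^##fileformat=VCF", first)) {
    stop(sprintf("not a VCF file (missing ##fileformat header): %s", path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  recs <- list(); rejects <- empty_rejects(); skipped <- 0L
  info <- if (n > 0L) vcfR::extract.info(vcf, element = info_key) else character()
  for (i in seq_len(n)) {
    val <- info[i]
    if (is.na(val) || !nzchar(val)) { skipped <- skipped + 1L; next }
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    anns <- strsplit(val, ",", fixed = TRUE)[[1]]
    line_recs <- list(); line_reason <- NULL
    for (a in seq_along(anns)) {
      ann <- trimws(anns[a])
      if (!nzchar(ann) || ann == ".") next
      parts <- strsplit(ann, "|", fixed = TRUE)[[1]]
      if (length(parts) != 2L) { line_reason <- sprintf("malformed %s value '%s'", info_key, ann); next }
      res <- tryCatch(
        variant_row(
          gene = parts[1], change = parts[2], line = i,
          chrom = fix[i, "CHROM"],
          genomic_pos = suppressWarnings(as.integer(fix[i, "POS"])),
          ref = fix[i, "REF"],
          alt = if (a <= length(alts)) alts[a] else NA_character_
        ),
        error = function(e) conditionMessage(e)
      )
      if (is.character(res)) line_reason <- res else line_recs[[length(line_recs) + 1L]] <- res
    }
    if (length(line_recs) > 0L) {
      recs <- c(recs, line_recs)
    } else if (!is.null(line_reason)) {
      rejects <- rbind(rejects, data.frame(line = i, text = val,
                                           reason = line_reason, stringsAsFactors = FALSE))
    } else {
      skipped <- skipped + 1L
    }
  }
  if (length(recs) == 0L) {
    warning(sprintf("0 annotated record(s) out of %d total in %s", n, path), call. = FALSE)
  }
  variants <- if (length(recs)) do.call(rbind, recs) else empty_variants()
  dd <- dedup_variants(variants)
  new_variant_parse(dd$variants, rejects, skipped + dd$n_dropped, n, path)
}

#' Write a canonical variant table as simple TSV
#'
#' Inverse of [parse_tsv()]: re-parsing the written file yields the same
#' variant records.
#'
#' @param variants canonical variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  out <- data.frame(
    gene = variants$gene,
    protein_change = paste0(variants$wt, variants$pos, variants$mut),
    chrom = ifelse(is.na(variants$chrom), ".", variants$chrom),
    pos = ifelse(is.na(variants$genomic_pos), ".", as.character(variants$genomic_pos)),
    ref = ifelse(is.na(variants$ref), ".", variants$ref),
    alt = ifelse(is.na(variants$alt), ".", variants$alt),
    pdb = ifelse(is.na(variants$pdb), ".", variants$pdb),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
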
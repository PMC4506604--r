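# Structure loading and variant-to-residue mapping.
#
# Coordinate files are parsed with bio3d; this module normalizes them into a
# light container: protein atoms (standard amino acids), hetero atoms (ligands
# and modified residues, kept separately for the pocket atom set), waters
# dropped. Author residue numbering, as printed in the file, is the matching
# convention throughout.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Load a protein structure from a PDB file or identifier
#'
#' `source` may be a local file path, or a 4-character PDB identifier resolved
#' against `cache_dir/<id>.pdb` and — only when `offline = FALSE` — fetched
#' from the RCSB download service into the cache. Parsing rules: first model
#' only for multi-model (NMR) files, with a warning; alternate locations
#' resolved to the highest-occupancy conformer; waters excluded; non-amino-acid
#' hetero groups kept in a separate table (excluded from residue mapping).
#'
#' @param source PDB file path or 4-character identifier.
#' @param cache_dir directory used to resolve and store fetched identifiers.
#' @param offline if `TRUE`, an identifier absent from the cache is an error
#'   ("offline miss") rather than a download attempt.
#' @return a `protein_structure`: `structure_id`, `atoms` (protein atom table
#'   with chain, author `resno`, insertion code, 3-letter `resid`, atom name
#'   `elety`, element `elesy`, Cartesian `x`, `y`, `z` in Angstrom), `het`
#'   (hetero atoms in the same layout) and `n_models` found in the file.
#' @export
load_structure <- function(source, cache_dir = NULL, offline = FALSE) {
  path <- resolve_structure_source(source, cache_dir, offline)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("empty structure file: %s", path))
  n_models <- sum(grepl("^MODEL ", lines))
  read_path <- path
  if (n_models > 1L) {
    warning(sprintf("%d models in %s; using the first model only", n_models, path),
            call. = FALSE)
    endmdl <- grep("^ENDMDL", lines)[1]
    read_path <- tempfile(fileext = ".pdb")
    writeLines(c(lines[seq_len(endmdl)], "END"), read_path)
    on.exit(unlink(read_path))
  }
  pdb <- tryCatch(bio3d::read.pdb(read_path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop(sprintf("unparsable PDB file %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L) stop(sprintf("no atom records in %s", path))
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  atom$o[is.na(atom$o)] <- 1
  # element symbol: trust the file's column, fall back to the atom-name letters
  fallback <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", atom$elety))
  atom$elesy <- ifelse(is.na(atom$elesy) | !nzchar(trimws(atom$elesy)),
                       fallback, toupper(trimws(atom$elesy)))
  # alternate locations: keep the highest-occupancy conformer per atom site
  ord <- order(atom$chain, atom$resno, atom$insert, atom$elety, -atom$o, atom$alt,
               method = "radix")
  atom <- atom[ord, , drop = FALSE]
  site <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  atom <- atom[!duplicated(site), , drop = FALSE]
  atom <- atom[order(match(rownames(atom), rownames(pdb$atom))), , drop = FALSE]
  atom <- atom[!(atom$resid %in% WATER_RESIDUES), , drop = FALSE]
  is_protein <- atom$resid %in% names(AA_THREE_TO_ONE)
  cols <- c("type", "eleno", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "b", "elesy")
  protein <- atom[is_protein, cols, drop = FALSE]
  het <- atom[!is_protein, cols, drop = FALSE]
  rownames(protein) <- NULL; rownames(het) <- NULL
  has_ca <- nrow(protein) > 0L && any(protein$elety == "CA")
  if (!has_ca) {
    stop(sprintf("%s contains no amino-acid residue with a C-alpha atom", path))
  }
  structure(
    list(structure_id = structure_id_of(source), atoms = protein, het = het,
         n_models = max(n_models, 1L), source_path = path),
    class = "protein_structure"
  )
}

structure_id_of <- function(source) {
  if (grepl("^[0-9][0-9A-Za-z]{3}$", source)) return(toupper(source))
  toupper(tools::file_path_sans_ext(basename(source)))
}

resolve_structure_source <- function(source, cache_dir, offline) {
  if (file.exists(source)) return(source)
  if (!grepl("^[0-9][0-9A-Za-z]{3}$", source)) {
    stop(sprintf("structure source '%s' is neither an existing file nor a 4-character PDB id",
                 source))
  }
  id <- tolower(source)
  if (!is.null(cache_dir)) {
    cached <- file.path(cache_dir, paste0(id, ".pdb"))
    if (file.exists(cached)) return(cached)
  }
  if (offline) {
    stop(sprintf("offline miss: PDB id '%s' not found in cache%s", toupper(id),
                 if (is.null(cache_dir)) " (no cache directory given)" else
                   sprintf(" directory %s", cache_dir)))
  }
  if (is.null(cache_dir)) cache_dir <- tempdir()
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(id, ".pdb"))
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0L,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0L) {
    unlink(dest)
    stop(sprintf("could not fetch PDB id '%s' from %s", toupper(id), url))
  }
  dest
}

#' @export
print.protein_structure <- function(x, ...) {
  ch <- chains(x)
  cat(sprintf("Protein structure %s: %d chain(s) [%s], %d protein atom(s), %d hetero atom(s)\n",
              x$structure_id, length(ch), paste(ch, collapse = ","),
              nrow(x$atoms), nrow(x$het)))
  invisible(x)
}

#' Chain identifiers of a structure
#' @param structure a `protein_structure`.
#' @return character vector of chain ids, in file order.
#' @export
chains <- function(structure) unique(structure$atoms$chain)

#' Residue table of one chain
#'
#' One row per (author residue number, insertion code), with the residue name,
#' its one-letter translation (`NA` for residues whose name has no standard
#' translation) and the C-alpha coordinate when present.
#'
#' @param structure a `protein_structure`.
#' @param chain chain identifier.
#' @return data.frame with `resno`, `insert`, `resid`, `aa1`, `has_ca`,
#'   `x`, `y`, `z`.
#' @export
residue_table <- function(structure, chain) {
  at <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  key <- paste(at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  res <- at[first, c("resno", "insert", "resid"), drop = FALSE]
  res$aa1 <- aa_three_to_one(res$resid)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$resno, ca$insert, sep = "\r")
  m <- match(paste(res$resno, res$insert, sep = "\r"), ca_key)
  res$has_ca <- !is.na(m)
  res$x <- ca$x[m]; res$y <- ca$y[m]; res$z <- ca$z[m]
  rownames(res) <- NULL
  res
}

#' Select a structure for a protein from a local catalog
#'
#' The catalog is a frozen TSV snapshot of UniProt PDB cross-references with
#' columns `protein`, `pdb_id`, `first_res`, `last_res`. The entry with the
#' largest sequence span `last_res - first_res + 1` wins; ties break to the
#' lexicographically smallest identifier. A variant-level preferred structure
#' always overrides the catalog.
#'
#' @param gene_or_accession protein key to look up.
#' @param catalog path to the catalog TSV.
#' @param preferred optional preferred PDB id or model file path; returned
#'   unchanged when given.
#' @return a PDB identifier (or the preferred source).
#' @export
select_structure <- function(gene_or_accession, catalog = NULL, preferred = NULL) {
  if (!is.null(preferred) && !is.na(preferred) && nzchar(preferred)) return(preferred)
  if (is.null(catalog)) {
    stop(sprintf("no structure for '%s': no preferred structure and no catalog given",
                 gene_or_accession))
  }
  cat_df <- utils::read.delim(catalog, stringsAsFactors = FALSE)
  need <- c("protein", "pdb_id", "first_res", "last_res")
  if (!all(need %in% colnames(cat_df))) {
    stop(sprintf("catalog %s lacks column(s): %s", catalog,
                 paste(setdiff(need, colnames(cat_df)), collapse = ", ")))
  }
  hits <- cat_df[cat_df$protein == gene_or_accession, , drop = FALSE]
  if (nrow(hits) == 0L) {
    stop(sprintf("no structure: protein '%s' absent from catalog %s",
                 gene_or_accession, catalog))
  }
  span <- hits$last_res - hits$first_res + 1L
  best <- hits[span == max(span), , drop = FALSE]
  sort(best$pdb_id)[1]
}

#' Map variants onto structure residues
#'
#' For each selected chain and each variant: (1) direct lookup of the author
#' residue number equal to the variant's sequence position; a wild-type match
#' gives a mapping with offset 0. (2) Otherwise a constant-offset scan over
#' `k` in `-offset_range..offset_range`: `k` is accepted only if residue
#' `position + k` matches the variant's wild type and at least `offset_frac`
#' of all the protein's variants match their wild types under the same `k`
#' (variants falling outside the chain count as non-matching, which keeps a
#' lone in-range coincidence from faking consensus). A unique accepted `k`
#' maps the variant with `offset_applied = k`; several accepted values give
#' `ambiguous_offset`. (3) Otherwise the variant is unmapped with reason
#' `wt_mismatch` (position present, wrong residue) or `not_in_structure`.
#' A mapped residue without a C-alpha atom is demoted to `no_calpha`.
#'
#' @param variants canonical variant data.frame (one protein).
#' @param structure a `protein_structure`.
#' @param chains_sel `"all"` or a character vector of chain ids.
#' @param offset_range maximum |offset| scanned (residues).
#' @param offset_frac consensus fraction required to accept an offset.
#' @return data.frame with one row per (variant, chain): the substitution,
#'   chain, mapped author residue number, C-alpha coordinate, `status`
#'   (`mapped`/`unmapped`), `reason`, `offset_applied` and a display `label`
#'   like `"Y370C (A)"`.
#' @export
map_variants <- function(variants, structure, chains_sel = "all",
                         offset_range = 30L, offset_frac = 0.8) {
  sel <- if (identical(chains_sel, "all")) chains(structure) else {
    bad <- setdiff(chains_sel, chains(structure))
    if (length(bad)) stop(sprintf("chain(s) not in structure: %s", paste(bad, collapse = ",")))
    chains_sel
  }
  out <- list()
  ks <- seq.int(-offset_range, offset_range)
  for (ch in sel) {
    res <- residue_table(structure, ch)
    aa_by_resno <- res$aa1[!duplicated(res$resno)]
    names(aa_by_resno) <- res$resno[!duplicated(res$resno)]
    # match_mat[v, j]: does variant v's wild type sit at position + ks[j]?
    match_mat <- vapply(ks, function(k) {
      got <- aa_by_resno[as.character(variants$pos + k)]
      !is.na(got) & got == variants$wt
    }, logical(nrow(variants)))
    if (nrow(variants) == 1L) match_mat <- matrix(match_mat, nrow = 1L)
    consensus <- colSums(match_mat) / max(nrow(variants), 1L)
    for (v in seq_len(nrow(variants))) {
      pos <- variants$pos[v]; wt <- variants$wt[v]
      sub <- paste0(variants$wt[v], pos, variants$mut[v])
      status <- "unmapped"; reason <- NA_character_
      resno <- NA_integer_; offset <- NA_integer_
      direct <- aa_by_resno[as.character(pos)]
      if (!is.na(direct) && direct == wt) {
        status <- "mapped"; resno <- pos; offset <- 0L
      } else {
        cand <- ks[match_mat[v, ] & consensus >= offset_frac]
        if (length(cand) == 1L) {
          status <- "mapped"; offset <- cand; resno <- pos + cand
        } else if (length(cand) > 1L) {
          reason <- "ambiguous_offset"
        } else if (as.character(pos) %in% names(aa_by_resno)) {
          reason <- "wt_mismatch"
        } else {
          reason <- "not_in_structure"
        }
      }
      x <- y <- z <- NA_real_
      if (status == "mapped") {
        ri <- which(res$resno == resno)[1]
        if (!res$has_ca[ri]) {
          status <- "unmapped"; reason <- "no_calpha"
          resno <- NA_integer_; offset <- NA_integer_
        } else {
          x <- res$x[ri]; y <- res$y[ri]; z <- res$z[ri]
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = variants$gene[v], wt = wt, pos = pos, mut = variants$mut[v],
        sub = sub, chain = ch, resno = resno, x = x, y = y, z = z,
        status = status, reason = reason, offset_applied = offset,
        label = sprintf("%s (%s)", sub, ch), stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(out)) do.call(rbind, out) else data.frame()
  rownames(df) <- NULL
  df
}

#' C-alpha coordinate of a mapped variant
#'
#' @param mapped a single row of the [map_variants()] table.
#' @return numeric length-3 coordinate (Angstrom).
#' @export
calpha_of <- function(mapped) {
  if (nrow(mapped) != 1L) stop("calpha_of expects exactly one mapped-variant row")
  if (!identical(mapped$status, "mapped")) {
    stop(sprintf("calpha_of called on unmapped variant %s (%s)",
                 mapped$label, mapped$reason))
  }
  c(mapped$x, mapped$y, mapped$z)
}
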
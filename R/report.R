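# Pipeline orchestration and report rendering. A run executes: variant
# parsing -> structure selection/loading -> residue mapping -> spatial
# clustering -> (optional) pocket detection -> (optional) database
# annotation -> (optional) stability prediction -> report. Optional stages
# degrade to warning sections; only variant parsing and structure loading
# are hard failures. All outputs are deterministic given an injected
# timestamp.

#' Pipeline configuration
#'
#' @param input variant input file.
#' @param format `"tsv"`, `"annovar"` or `"vcf"`.
#' @param vcf_info_key INFO key carrying `GENE|PROTEIN_CHANGE` (VCF input).
#' @param pdb structure source: PDB id or local file; overrides the catalog.
#' @param catalog structure catalog TSV (see [select_structure()]).
#' @param cache_dir PDB cache directory.
#' @param offline forbid structure downloads.
#' @param humsavar,clinvar optional snapshot paths.
#' @param cluster_threshold cluster-cut threshold in Angstrom. Default 20 A:
#'   variant clusters of interest in the literature sit at 9-19 A C-alpha
#'   distance, so 20 A contains them while keeping chain-scale distances out.
#'   Always printed prominently in the report.
#' @param pockets run pocket detection.
#' @param pocket_args parameters for [pocket_params()].
#' @param hit_radius variant-to-pocket-center proximity cutoff, Angstrom.
#' @param stability `"off"`, `"baseline"` or `"adapter"`.
#' @param adapter_exe external stability predictor executable.
#' @param adapter_timeout per-variant adapter timeout, seconds.
#' @param chains `"all"` or a character vector of chain ids.
#' @param out_dir output directory (created if missing); `NULL` for none.
#' @param timestamp injected timestamp string (fixed for reproducible bytes).
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(input, format = c("tsv", "annovar", "vcf"),
                            vcf_info_key = "PCH", pdb = NULL, catalog = NULL,
                            cache_dir = NULL, offline = FALSE,
                            humsavar = NULL, clinvar = NULL,
                            cluster_threshold = 20.0, pockets = FALSE,
                            pocket_args = list(), hit_radius = 8.0,
                            stability = c("off", "baseline", "adapter"),
                            adapter_exe = NULL, adapter_timeout = 120,
                            chains = "all", out_dir = NULL,
                            timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")) {
  list(input = input, format = match.arg(format), vcf_info_key = vcf_info_key,
       pdb = pdb, catalog = catalog, cache_dir = cache_dir, offline = offline,
       humsavar = humsavar, clinvar = clinvar,
       cluster_threshold = cluster_threshold, pockets = pockets,
       pocket_args = pocket_args, hit_radius = hit_radius,
       stability = match.arg(stability), adapter_exe = adapter_exe,
       adapter_timeout = adapter_timeout, chains = chains, out_dir = out_dir,
       timestamp = timestamp)
}

#' Run the full pipeline
#'
#' @param config list from [pipeline_config()].
#' @return a `run_result`: parsed variants (with rejects), the structure,
#'   mapped variants, cluster tree and cut, pockets and pocket hits,
#'   annotations, stability rows, accumulated stage warnings, and provenance
#'   (inputs, structure id, parameter values, timestamp) complete enough to
#'   re-run bit-identically. When `config$out_dir` is set the report files
#'   are written there as a side effect.
#' @export
run_pipeline <- function(config) {
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)

  parsed <- switch(config$format,
    tsv = parse_tsv(config$input),
    annovar = parse_annovar(config$input),
    vcf = parse_minimal_vcf(config$input, config$vcf_info_key))
  variants <- parsed$variants
  if (nrow(parsed$rejects) > 0L) {
    note(sprintf("%d input line(s) rejected by the parser", nrow(parsed$rejects)))
  }

  genes <- unique(variants$gene)
  preferred <- unique(stats::na.omit(variants$pdb))
  source <- config$pdb
  if (is.null(source) && length(preferred) == 1L) source <- preferred
  if (is.null(source)) {
    if (length(genes) != 1L) {
      stop(sprintf("input covers %d genes (%s) and no explicit structure was given; run one protein at a time",
                   length(genes), paste(genes, collapse = ", ")))
    }
    source <- select_structure(genes, config$catalog)
  }
  structure_ <- load_structure(source, cache_dir = config$cache_dir,
                               offline = config$offline)

  mapped <- map_variants(variants, structure_, config$chains)
  n_mapped <- sum(mapped$status == "mapped")
  if (n_mapped == 0L) note("no variants could be mapped onto the structure")

  tree <- NULL; cut <- NULL; dm <- NULL
  if (n_mapped >= 1L) {
    dm <- distance_matrix(mapped)
    tree <- average_linkage(dm)
    cut <- cut_tree(tree, config$cluster_threshold)
  }

  pockets <- NULL; hits <- NULL
  if (isTRUE(config$pockets)) {
    res <- tryCatch({
      pk <- find_pockets(structure_, do.call(pocket_params, config$pocket_args))
      list(pockets = pk, hits = variant_pocket_hits(mapped, pk, config$hit_radius))
    }, error = function(e) {
      note(sprintf("pocket detection failed: %s", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) { pockets <- res$pockets; hits <- res$hits }
    if (!is.null(pockets) && nrow(pockets) == 0L) {
      note("pocket detection found no buried cleft")
    }
  }

  annotations <- NULL
  if (!is.null(config$humsavar) || !is.null(config$clinvar)) {
    annotations <- tryCatch({
      hs <- if (!is.null(config$humsavar)) load_humsavar(config$humsavar) else NULL
      cv <- if (!is.null(config$clinvar)) load_clinvar(config$clinvar) else NULL
      annotate_variants(variants, hs, cv)
    }, error = function(e) {
      note(sprintf("annotation stage failed: %s", conditionMessage(e)))
      NULL
    })
  }

  stability <- NULL
  if (config$stability != "off") {
    stability <- tryCatch({
      adapter <- if (config$stability == "adapter") {
        list(exe = config$adapter_exe, timeout = config$adapter_timeout)
      } else NULL
      predict_stability(variants,
                        sequence = structure_sequence(structure_, mapped),
                        adapter_config = adapter)
    }, error = function(e) {
      note(sprintf("stability stage failed: %s", conditionMessage(e)))
      NULL
    })
  }

  result <- structure(list(
    parsed = parsed, variants = variants, structure = structure_,
    mapped = mapped, dm = dm, tree = tree, cut = cut,
    pockets = pockets, hits = hits, annotations = annotations,
    stability = stability, warnings = warnings,
    provenance = list(
      input = config$input, format = config$format,
      structure_id = structure_$structure_id,
      structure_source = structure_$source_path,
      n_models = structure_$n_models,
      model_policy = "first model; alternate locations by highest occupancy",
      cluster_threshold = config$cluster_threshold,
      pockets = config$pockets, hit_radius = config$hit_radius,
      stability = config$stability,
      humsavar = config$humsavar %||% NA, clinvar = config$clinvar %||% NA,
      chains = config$chains, timestamp = config$timestamp,
      package_version = as.character(utils::packageVersion("structvar"))
    )
  ), class = "run_result")

  if (!is.null(config$out_dir)) write_outputs(result, config$out_dir)
  result
}

# Best-effort one-letter sequence for the stability predictor: positions come
# from the variant coordinate system, so invert the mapping offset where one
# was applied and read residues off the first chain that mapped.
structure_sequence <- function(structure_, mapped) {
  ch <- mapped$chain[mapped$status == "mapped"][1]
  if (is.na(ch)) ch <- chains(structure_)[1]
  off <- mapped$offset_applied[mapped$status == "mapped" & mapped$chain == ch][1]
  if (is.na(off)) off <- 0L
  res <- residue_table(structure_, ch)
  pos <- res$resno - off
  keep <- !is.na(res$aa1) & pos >= 1L
  seq_chars <- rep("X", max(pos[keep], 1L))
  seq_chars[pos[keep]] <- res$aa1[keep]
  paste(seq_chars, collapse = "")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Pipeline run on %s (structure %s)\n", x$provenance$input,
              x$provenance$structure_id))
  cat(sprintf("  variants: %d parsed, %d rejected; mapped rows: %d of %d\n",
              nrow(x$variants), nrow(x$parsed$rejects),
              sum(x$mapped$status == "mapped"), nrow(x$mapped)))
  if (!is.null(x$cut)) {
    cat(sprintf("  clusters at %.1f A: %d multi-member, %d singleton(s)\n",
                x$cut$threshold, nrow(x$cut$clusters), length(x$cut$singletons)))
  }
  if (!is.null(x$pockets)) cat(sprintf("  pockets: %d\n", nrow(x$pockets)))
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}

write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    rows <- apply(df, 1L, function(r) paste(ifelse(is.na(r), "n/a", trimws(r)),
                                            collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

variant_report_table <- function(result) {
  m <- result$mapped
  if (nrow(m) == 0L) {
    return(data.frame(variant = character(), chain = character(),
                      status = character(), residue = character(),
                      cluster = character(), annotations = character(),
                      stability = character(), pocket_hits = character(),
                      stringsAsFactors = FALSE))
  }
  ann_cell <- function(gene, sub) {
    a <- result$annotations
    if (is.null(a) || nrow(a) == 0L) return("n/a")
    rows <- a[a$gene == gene & a$sub == sub, , drop = FALSE]
    if (nrow(rows) == 0L) return("n/a")
    paste(sprintf("%s:%s (%s)", rows$source, rows$label, rows$normalized),
          collapse = "; ")
  }
  stab_cell <- function(sub) {
    s <- result$stability
    if (is.null(s)) return("n/a")
    rows <- s[s$variant_key == sub, , drop = FALSE]
    if (nrow(rows) == 0L) return("n/a")
    sprintf("%s [%s]", rows$direction[1], rows$method[1])
  }
  hit_cell <- function(label) {
    h <- result$hits
    if (is.null(h)) return("n/a")
    rows <- h[h$label == label, , drop = FALSE]
    if (nrow(rows) == 0L) return("none")
    paste(sprintf("pocket %d (%.1f A)", rows$pocket, rows$distance), collapse = "; ")
  }
  cl_cell <- function(label) {
    if (is.null(result$cut)) return("n/a")
    a <- result$cut$assignment
    if (!label %in% names(a)) return("n/a")
    if (a[[label]] == 0L) "singleton" else as.character(a[[label]])
  }
  data.frame(
    variant = m$sub, chain = m$chain,
    status = ifelse(m$status == "mapped",
                    ifelse(m$offset_applied != 0L,
                           sprintf("mapped (offset %+d)", m$offset_applied),
                           "mapped"),
                    sprintf("unmapped (%s)", m$reason)),
    residue = ifelse(is.na(m$resno), "n/a", as.character(m$resno)),
    cluster = vapply(m$label, cl_cell, character(1)),
    annotations = mapply(ann_cell, m$gene, m$sub, USE.NAMES = FALSE),
    stability = vapply(m$sub, stab_cell, character(1), USE.NAMES = FALSE),
    pocket_hits = vapply(m$label, hit_cell, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write all run outputs into a directory
#'
#' Emits `report.html`, `variants.tsv`, `clusters.tsv`, `pockets.tsv`,
#' `flagged.pdb`, `viewer_script.txt` and `run.json`.
#'
#' @param result a `run_result`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  render_html(result, file.path(out_dir, "report.html"))
  write_tsv_file(variant_report_table(result), file.path(out_dir, "variants.tsv"))
  cl <- if (!is.null(result$cut)) result$cut$clusters else
    data.frame(cluster = integer(), members = character(), size = integer(),
               height = numeric())
  cl$height <- sprintf("%.1f", as.numeric(cl$height))
  write_tsv_file(cl, file.path(out_dir, "clusters.tsv"))
  pk <- if (!is.null(result$pockets)) result$pockets else
    data.frame(rank = integer(), x = numeric(), y = numeric(), z = numeric(),
               weight = numeric(), n_probes = integer())
  pk <- data.frame(rank = pk$rank, x = sprintf("%.3f", pk$x),
                   y = sprintf("%.3f", pk$y), z = sprintf("%.3f", pk$z),
                   weight = pk$weight, n_probes = pk$n_probes)
  write_tsv_file(pk, file.path(out_dir, "pockets.tsv"))
  if (sum(result$mapped$status == "mapped") > 0L) {
    write_flagged_structure(result, file.path(out_dir, "flagged.pdb"),
                            file.path(out_dir, "viewer_script.txt"))
  }
  if (!is.null(result$pockets)) {
    write_pockets_pdb(result$pockets, file.path(out_dir, "pocket_centers.pdb"))
  }
  prov <- result$provenance
  jsonlite::write_json(prov, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0L) return("<p><em>empty</em></p>")
  head <- paste(sprintf("<th>%s</th>", html_escape(colnames(df))), collapse = "")
  body <- apply(df, 1L, function(r) {
    paste0("<tr>", paste(sprintf("<td>%s</td>",
                                 html_escape(ifelse(is.na(r), "n/a", trimws(r)))),
                         collapse = ""), "</tr>")
  })
  paste0("<table><thead><tr>", head, "</tr></thead><tbody>",
         paste(body, collapse = "\n"), "</tbody></table>")
}

#' Render the HTML information page
#'
#' A single self-contained HTML file with a summary, the per-variant table
#' (substitution, chain, mapping status, cluster, annotations, stability
#' direction, pocket hits), the cluster table, the pocket table and full
#' provenance. Byte output is deterministic given the injected timestamp.
#'
#' @param result a `run_result`.
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
render_html <- function(result, path) {
  prov <- result$provenance
  m <- result$mapped
  n_mapped <- sum(m$status == "mapped")
  parts <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>structvar report: %s</title>", html_escape(prov$structure_id)),
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;}",
    "td,th{border:1px solid #999;padding:4px 8px;}th{background:#eee;}",
    "h2{border-bottom:1px solid #ccc;}em{color:#666;}</style></head><body>",
    sprintf("<h1>Variant-structure report &mdash; %s</h1>", html_escape(prov$structure_id)),
    "<h2>Summary</h2>",
    "<ul>",
    sprintf("<li>%d variant(s) parsed from %s (%s format); %d reject(s), %d skipped</li>",
            nrow(result$variants), html_escape(prov$input), prov$format,
            nrow(result$parsed$rejects), result$parsed$skipped),
    sprintf("<li>structure %s: %d chain(s), %d protein atom(s)</li>",
            html_escape(prov$structure_id), length(chains(result$structure)),
            nrow(result$structure$atoms)),
    sprintf("<li>%d of %d variant-chain pairs mapped</li>", n_mapped, nrow(m)),
    sprintf("<li><strong>cluster threshold: %.1f &Aring;</strong></li>",
            prov$cluster_threshold),
    "</ul>")
  if (length(result$warnings)) {
    parts <- c(parts, "<h2>Warnings</h2><ul>",
               sprintf("<li>%s</li>", html_escape(result$warnings)), "</ul>")
  }
  parts <- c(parts, "<h2>Variants</h2>")
  if (n_mapped == 0L && nrow(m) == 0L) {
    parts <- c(parts, "<p><em>no mapped variants</em></p>")
  } else {
    parts <- c(parts, html_table(variant_report_table(result)))
    if (n_mapped == 0L) {
      parts <- c(parts, "<p><em>no mapped variants</em></p>")
    }
  }
  parts <- c(parts, sprintf("<h2>Clusters (cut at %.1f &Aring;)</h2>",
                            prov$cluster_threshold))
  if (is.null(result$cut) || nrow(result$cut$clusters) == 0L) {
    parts <- c(parts, sprintf("<p><em>no clusters at threshold %.1f &Aring;</em></p>",
                              prov$cluster_threshold))
    if (!is.null(result$cut) && length(result$cut$singletons)) {
      parts <- c(parts, sprintf("<p>singletons: %s</p>",
                                html_escape(paste(result$cut$singletons, collapse = ", "))))
    }
  } else {
    cl <- result$cut$clusters
    cl$height <- sprintf("%.1f", cl$height)
    parts <- c(parts, html_table(cl))
    if (length(result$cut$singletons)) {
      parts <- c(parts, sprintf("<p>singletons: %s</p>",
                                html_escape(paste(result$cut$singletons, collapse = ", "))))
    }
  }
  parts <- c(parts, "<h2>Pockets</h2>")
  if (is.null(result$pockets)) {
    parts <- c(parts, "<p><em>pocket detection not run</em></p>")
  } else if (nrow(result$pockets) == 0L) {
    parts <- c(parts, "<p><em>no buried cleft detected</em></p>")
  } else {
    pk <- result$pockets
    pk <- data.frame(rank = pk$rank, x = sprintf("%.3f", pk$x),
                     y = sprintf("%.3f", pk$y), z = sprintf("%.3f", pk$z),
                     weight = pk$weight, n_probes = pk$n_probes)
    parts <- c(parts, html_table(pk))
  }
  parts <- c(parts, "<h2>Provenance</h2>",
             html_table(data.frame(key = names(prov),
                                   value = vapply(prov, function(v)
                                     paste(as.character(v), collapse = ","),
                                     character(1)),
                                   stringsAsFactors = FALSE)),
             "</body></html>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(parts, con)
  invisible(path)
}

#' Write the cluster-flagged structure and viewer script
#'
#' Writes a PDB-format copy of the structure in which the atoms of every
#' mapped mutated residue carry the variant's cluster index as B-factor
#' (singletons 0, multi-member clusters 1..k; all other atoms 0), plus a
#' plain-text viewer command script (PyMOL syntax, one selection and colour
#' per cluster) so an external molecular viewer reproduces the
#' cluster-affiliation colouring.
#'
#' @param result a `run_result` with at least one mapped variant.
#' @param pdb_path output PDB path.
#' @param script_path output viewer-script path.
#' @return `pdb_path`, invisibly.
#' @export
write_flagged_structure <- function(result, pdb_path, script_path) {
  m <- result$mapped[result$mapped$status == "mapped", , drop = FALSE]
  if (nrow(m) == 0L) stop("no mapped variants to flag")
  assignment <- if (!is.null(result$cut)) result$cut$assignment else
    stats::setNames(rep(0L, nrow(m)), m$label)
  at <- rbind(result$structure$atoms, result$structure$het)
  b <- rep(0, nrow(at))
  for (i in seq_len(nrow(m))) {
    sel <- at$chain == m$chain[i] & at$resno == m$resno[i]
    b[sel] <- assignment[[m$label[i]]]
  }
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = pdb_path, xyz = xyz, type = at$type,
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(nzchar(at$insert), at$insert, ""),
                   elety = at$elety, b = b, o = at$o, elesy = at$elesy)
  colors <- c("red", "orange", "yellow", "green", "cyan", "blue", "purple",
              "magenta", "salmon", "teal")
  lines <- c("# viewer commands reproducing the cluster colouring (PyMOL syntax)",
             sprintf("load %s", basename(pdb_path)),
             "color grey80")
  ks <- sort(unique(assignment[m$label]))
  for (k in ks) {
    labs <- m[assignment[m$label] == k, , drop = FALSE]
    sel <- paste(sprintf("(chain %s and resi %d)", labs$chain, labs$resno),
                 collapse = " or ")
    name <- if (k == 0L) "singletons" else sprintf("cluster%d", k)
    col <- if (k == 0L) "wheat" else colors[(k - 1L) %% length(colors) + 1L]
    lines <- c(lines,
               sprintf("select %s, %s", name, sel),
               sprintf("color %s, %s", col, name),
               sprintf("show spheres, %s and name CA", name))
  }
  con <- file(script_path, open = "wb")
  writeLines(lines, con)
  close(con)
  invisible(pdb_path)
}
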
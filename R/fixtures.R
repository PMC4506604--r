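# Deterministic synthetic fixtures: small PDB files with analytically known
# geometry (ideal helices, spherical cavity shells, convex tetrahedra), toy
# variant tables, and toy HUMSAVAR/ClinVar snapshots. Everything every module
# consumes can be regenerated offline, byte-identically, from code; fixtures
# are written as real PDB files so the I/O paths are exercised, not bypassed.

HELIX_RISE <- 1.5       # Angstrom per residue along the axis
HELIX_TWIST <- 100      # degrees per residue
HELIX_RADIUS <- 2.3     # C-alpha ring radius, Angstrom

#' Analytic C-alpha spacing of the ideal helix fixture
#'
#' Closed form from the generator constants: consecutive C-alpha atoms of the
#' ideal helix are `sqrt(2 r^2 (1 - cos(twist)) + rise^2)` apart
#' (about 3.83 A for rise 1.5 A, twist 100 degrees, radius 2.3 A).
#'
#' @return numeric scalar, Angstrom.
#' @export
helix_ca_spacing <- function() {
  sqrt(2 * HELIX_RADIUS^2 * (1 - cos(HELIX_TWIST * pi / 180)) + HELIX_RISE^2)
}

helix_ca_coords <- function(n, rise = HELIX_RISE, twist = HELIX_TWIST,
                            radius = HELIX_RADIUS) {
  i <- seq_len(n) - 1L
  ang <- twist * pi / 180 * i
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = rise * i)
}

write_fixture_pdb <- function(path, xyz, resno, resid, chain,
                              elety = "CA", elesy = "C") {
  n <- nrow(xyz)
  if (length(elety) == 1L) elety <- rep(elety, n)
  if (length(elesy) == 1L) elesy <- rep(elesy, n)
  if (length(chain) == 1L) chain <- rep(chain, n)
  if (length(resid) == 1L) resid <- rep(resid, n)
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), elety, resid, chain, resno,
    round(xyz[, 1], 3), round(xyz[, 2], 3), round(xyz[, 3], 3),
    1.00, 0.00, elesy)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}

#' Ideal alpha-helix C-alpha trace fixture
#'
#' Writes an ideal alpha-helix C-alpha trace (rise 1.5 A, 100-degree twist
#' per residue, ring radius 2.3 A) as a standard PDB file, poly-alanine by
#' default. Author numbering starts at `1 + offset`, which makes renumbered
#' copies for offset-recovery tests one argument away. Coordinates are
#' analytically known, so tests can assert them in closed form; identical
#' arguments give byte-identical files.
#'
#' @param n number of residues (at least 2).
#' @param offset added to every author residue number.
#' @param path output PDB path.
#' @param sequence optional one-letter sequence of length `n` (defaults to
#'   poly-alanine); distinct residue types make wild-type verification
#'   informative.
#' @param chain chain identifier.
#' @return `path`, invisibly.
#' @export
make_helix <- function(n, offset = 0L, path = tempfile(fileext = ".pdb"),
                       sequence = NULL, chain = "A") {
  if (n < 2L) stop("a helix fixture needs at least 2 residues")
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (nchar(sequence) != n) stop("sequence length must equal n")
  aa3 <- aa_one_to_three(strsplit(sequence, "")[[1]])
  if (anyNA(aa3)) stop("sequence contains a non-standard amino-acid code")
  xyz <- helix_ca_coords(n)
  write_fixture_pdb(path, xyz, resno = seq_len(n) + as.integer(offset),
                    resid = aa3, chain = chain)
}

fibonacci_sphere <- function(n, radius, center) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = center[1] + radius * cos(theta) * sin(phi),
        y = center[2] + radius * sin(theta) * sin(phi),
        z = center[3] + radius * cos(phi))
}

#' Spherical cavity-shell fixture
#'
#' Pseudo-atoms (written as alanine C-alpha carbons so the structure module
#' accepts them as protein) on a Fibonacci sphere. The interior is a perfect
#' cavity whose geometric center is `center`, exactly — the ground truth for
#' pocket-recovery tests.
#'
#' @param n_atoms number of shell atoms (at least 30).
#' @param radius shell radius in Angstrom (4 to 10).
#' @param center cavity center coordinate.
#' @param path output PDB path.
#' @param chain chain identifier.
#' @param start_resno author number of the first shell residue.
#' @return `path`, invisibly.
#' @export
make_cavity_shell <- function(n_atoms = 92L, radius = 6,
                              center = c(0, 0, 0),
                              path = tempfile(fileext = ".pdb"),
                              chain = "A", start_resno = 1L) {
  if (n_atoms < 30L) stop("a cavity shell needs at least 30 atoms")
  if (radius < 4 || radius > 10) stop("shell radius must be in [4, 10] Angstrom")
  xyz <- fibonacci_sphere(n_atoms, radius, center)
  write_fixture_pdb(path, xyz, resno = seq_len(n_atoms) + start_resno - 1L,
                    resid = "ALA", chain = chain)
}

#' Two-cavity fixture
#'
#' Two cavity shells with centers `separation` Angstrom apart (chains A and
#' B); the pocket detector must report exactly one pocket per cavity.
#'
#' @param n_atoms shell atoms per cavity.
#' @param radius shell radius, Angstrom.
#' @param separation center-to-center distance, Angstrom.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
make_two_cavities <- function(n_atoms = 92L, radius = 6, separation = 40,
                              path = tempfile(fileext = ".pdb")) {
  a <- fibonacci_sphere(n_atoms, radius, c(0, 0, 0))
  b <- fibonacci_sphere(n_atoms, radius, c(separation, 0, 0))
  xyz <- rbind(a, b)
  write_fixture_pdb(path, xyz,
                    resno = c(seq_len(n_atoms), seq_len(n_atoms)),
                    resid = "ALA",
                    chain = rep(c("A", "B"), each = n_atoms))
}

#' Convex (pocket-free) fixture
#'
#' Four atoms at the vertices of a regular tetrahedron with 30 A edges: no
#' placement can reach the burial threshold, so the pocket detector must
#' return nothing.
#'
#' @param edge tetrahedron edge length, Angstrom.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
make_convex <- function(edge = 30, path = tempfile(fileext = ".pdb")) {
  s <- edge / sqrt(2)
  xyz <- s * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(2)
  write_fixture_pdb(path, xyz, resno = 1:4, resid = "ALA", chain = "A")
}

#' Dispatch a named fixture kind
#'
#' @param kind one of `"helix"`, `"renumbered_helix"`, `"cavity_shell"`,
#'   `"two_cavities"`, `"convex"`.
#' @param path output PDB path.
#' @param ... forwarded to the specific generator.
#' @return `path`, invisibly.
#' @export
make_fixture <- function(kind, path = tempfile(fileext = ".pdb"), ...) {
  switch(kind,
    helix = make_helix(path = path, ...),
    renumbered_helix = make_helix(path = path, ...),
    cavity_shell = make_cavity_shell(path = path, ...),
    two_cavities = make_two_cavities(path = path, ...),
    convex = make_convex(path = path, ...),
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
}

#' Toy variant TSV fixture
#'
#' @param path output path.
#' @param rows data.frame with columns `gene` and `protein_change` (and
#'   optionally `chrom`, `pos`, `ref`, `alt`, `pdb`); written verbatim.
#' @return `path`, invisibly.
#' @export
make_variant_tsv <- function(path, rows) {
  cols <- colnames(rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# toy variant table", con)
  writeLines(paste(cols, collapse = "\t"), con)
  for (i in seq_len(nrow(rows))) {
    writeLines(paste(as.character(unlist(rows[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Toy HUMSAVAR snapshot fixture
#'
#' @param path output path.
#' @param rows data.frame with `gene`, `acc`, `ftid`, `change` (HGVS `p.`),
#'   `category`, `dbsnp`, `disease`.
#' @return `path`, invisibly.
#' @export
make_humsavar_snippet <- function(path, rows) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("Index of protein altering variants (toy snapshot)",
               "",
               "Main  Swiss-Prot  FTId        AA change      Category  dbSNP        Disease",
               "_________________________________________________________________________"),
             con)
  for (i in seq_len(nrow(rows))) {
    writeLines(sprintf("%-9s %-10s %-11s %-14s %-9s %-12s %s",
                       rows$gene[i], rows$acc[i], rows$ftid[i], rows$change[i],
                       rows$category[i], rows$dbsnp[i], rows$disease[i]), con)
  }
  invisible(path)
}

#' Toy ClinVar variant-summary fixture
#'
#' @param path output path.
#' @param rows data.frame with `gene`, `significance`, `assembly`, `chrom`,
#'   `pos`, `ref`, `alt`, `name`.
#' @return `path`, invisibly.
#' @export
make_clinvar_snippet <- function(path, rows) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("GeneSymbol", "ClinicalSignificance", "Assembly",
                     "Chromosome", "PositionVCF", "ReferenceAlleleVCF",
                     "AlternateAlleleVCF", "Name"), collapse = "\t"), con)
  for (i in seq_len(nrow(rows))) {
    writeLines(paste(c(rows$gene[i], rows$significance[i], rows$assembly[i],
                       rows$chrom[i], rows$pos[i], rows$ref[i], rows$alt[i],
                       rows$name[i]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Toy ANNOVAR exonic table fixture
#'
#' @param path output path.
#' @param rows data.frame with `class` (functional class), `annotation`
#'   (the gene:transcript:...:p. string), `chrom`, `start`, `end`, `ref`,
#'   `alt`.
#' @return `path`, invisibly.
#' @export
make_annovar_table <- function(path, rows) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(rows))) {
    writeLines(paste(c(sprintf("line%d", i), rows$class[i], rows$annotation[i],
                       rows$chrom[i], rows$start[i], rows$end[i], rows$ref[i],
                       rows$alt[i]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Toy minimal VCF fixture
#'
#' @param path output path.
#' @param rows data.frame with `chrom`, `pos`, `ref`, `alt` (comma-joined for
#'   multi-allelic sites) and `ann` (the INFO value, `NA` to omit the key).
#' @param info_key INFO field name used for the annotation.
#' @return `path`, invisibly.
#' @export
make_minimal_vcf <- function(path, rows, info_key = "PCH") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"GENE|PROTEIN_CHANGE per ALT\">",
                       info_key),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(rows))) {
    info <- if (is.na(rows$ann[i])) "." else sprintf("%s=%s", info_key, rows$ann[i])
    writeLines(paste(c(rows$chrom[i], rows$pos[i], ".", rows$ref[i],
                       rows$alt[i], ".", "PASS", info), collapse = "\t"), con)
  }
  invisible(path)
}
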
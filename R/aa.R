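# Amino-acid code tables shared across modules.

#' @keywords internal
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = unname(AA_THREE_TO_ONE))

#' The 20 standard one-letter amino-acid codes
#'
#' @return Character vector of the 20 one-letter codes.
#' @export
aa_codes <- function() unname(AA_THREE_TO_ONE)

#' Convert a three-letter residue name to its one-letter code
#'
#' Case-insensitive; returns `NA` for non-standard residue names (selenomethionine
#' and other modified residues are deliberately not folded into standard codes,
#' so mapping against them fails loudly rather than silently).
#'
#' @param x character vector of three-letter residue names.
#' @return character vector of one-letter codes, `NA` where unknown.
#' @export
aa_three_to_one <- function(x) {
  out <- AA_THREE_TO_ONE[toupper(x)]
  unname(out)
}

#' Convert a one-letter amino-acid code to its three-letter residue name
#'
#' @param x character vector of one-letter codes.
#' @return character vector of three-letter names, `NA` where unknown.
#' @export
aa_one_to_three <- function(x) {
  unname(AA_ONE_TO_THREE[toupper(x)])
}

#' @keywords internal
is_standard_aa1 <- function(x) toupper(x) %in% unname(AA_THREE_TO_ONE)

# Kyte-Doolittle hydropathy and residue volumes, loaded from the shipped table.
aa_properties <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "aa_properties.tsv", package = "structvar")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' @keywords internal
vdw_radii_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "vdw_radii.tsv", package = "structvar")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})
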
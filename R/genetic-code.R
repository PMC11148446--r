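# Standard genetic code bookkeeping shared by all codon statistics.
# Codons are DNA-alphabet (T, not U) internally; RNA spelling is display-only.

.codonfam_cache <- new.env(parent = emptyenv())

#' Standard genetic code table
#'
#' Builds the lookup structure used by every codon statistic: the codon to
#' amino-acid map of the standard genetic code, the per-amino-acid synonymous
#' codon families, their degeneracy classes, the stop codons and the
#' single-codon amino acids (Met, Trp).
#'
#' The 61 sense codons partition into 9 two-fold, 1 three-fold (Ile),
#' 5 four-fold and 3 six-fold (Leu, Ser, Arg) families plus Met and Trp.
#'
#' @return An object of class `genetic_code_table`: a list with elements
#'   `aa` (named character, codon -> one-letter amino acid, stops as `"*"`),
#'   `sense_codons`, `stop_codons`, `families` (list, amino acid -> codon
#'   vector), `degeneracy` (named integer per amino acid), `single_aa`
#'   (amino acids with one codon) and `synonymous_aa` (amino acids with
#'   two or more codons).
#' @examples
#' gc <- genetic_code_table()
#' gc$degeneracy[["L"]] # Leu is six-fold degenerate
#' @export
genetic_code_table <- function() {
  if (!is.null(.codonfam_cache$code)) {
    return(.codonfam_cache$code)
  }
  map <- Biostrings::GENETIC_CODE
  aa <- stats::setNames(unname(map), names(map))
  stop_codons <- sort(names(aa)[aa == "*"])
  sense <- names(aa)[aa != "*"]
  families <- split(sense, aa[sense])
  families <- lapply(families, sort)
  degeneracy <- vapply(families, length, integer(1))
  code <- structure(
    list(
      aa = aa,
      sense_codons = sort(sense),
      stop_codons = stop_codons,
      families = families,
      degeneracy = degeneracy,
      single_aa = names(degeneracy)[degeneracy == 1L],
      synonymous_aa = names(degeneracy)[degeneracy > 1L]
    ),
    class = "genetic_code_table"
  )
  .codonfam_cache$code <- code
  code
}

#' @export
print.genetic_code_table <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons\n")
  cat("Degeneracy classes:",
      paste(sprintf("%d-fold x%d", sort(unique(x$degeneracy)),
                    tabulate(factor(x$degeneracy))[order(unique(x$degeneracy))]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Convert codon spelling between DNA and RNA alphabets
#'
#' @param codons Character vector of codons.
#' @return `to_rna()` replaces T with U; `to_dna()` replaces U with T.
#' @examples
#' to_rna("AAG") # "AAG"
#' to_rna("TTC") # "UUC"
#' @export
to_rna <- function(codons) chartr("T", "U", toupper(codons))

#' @rdname to_rna
#' @export
to_dna <- function(codons) chartr("U", "T", toupper(codons))
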
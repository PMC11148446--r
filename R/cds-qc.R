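# CDS screening: read coding sequences and apply the quality filters that
# precede any codon statistic. A record passes iff
#   (a) length >= min_length (default 300 bp),
#   (b) length is a multiple of 3,
#   (c) the first codon is ATG,
#   (d) the last codon is TAA, TAG or TGA,
#   (e) the sequence contains only A, C, G, T.
# U is normalized to T and case is folded at read time so DNA and mRNA FASTA
# dialects both work.

#' Construct a set of CDS records
#'
#' @param id Character vector of sequence identifiers.
#' @param sequence Character vector of nucleotide sequences. `U` is
#'   normalized to `T` and lower case is folded to upper case.
#' @return A data frame of class `cds_set` with columns `id`, `sequence`,
#'   `length` (bases).
#' @examples
#' cds_set("g1", "ATGGCTTAA")
#' @export
cds_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) {
    stop("duplicate CDS identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sequence <- chartr("u", "t", toupper(as.character(sequence)))
  sequence <- chartr("U", "T", sequence)
  out <- data.frame(
    id = as.character(id),
    sequence = sequence,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Read CDS records from a (multi-)FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Wrapped and single-line FASTA are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `cds_set` data frame (see [cds_set()]).
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(seqs), "[ \t]+"), `[[`, character(1), 1L)
  cds_set(ids, as.character(seqs))
}

#' Write CDS records to FASTA
#'
#' @param records A `cds_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.qc_predicates <- c("min_length", "frame", "start_codon", "stop_codon",
                    "alphabet", "internal_stop")

#' Screen CDS records before codon analysis
#'
#' Applies the screening filters listed above. Divisibility by 3 is checked
#' in addition to the minimum length because codon statistics are undefined
#' on partial codons; records failing it are reported distinctly. Only the
#' terminal codon is checked against the stop set by default; internal stop
#' codons can additionally be screened with `internal_stops = TRUE`.
#'
#' @param records A `cds_set` data frame (or anything [cds_set()] accepts via
#'   its two columns `id` and `sequence`).
#' @param min_length Minimum sequence length in bases (default 300).
#' @param internal_stops If `TRUE`, a record also fails when a stop codon
#'   occurs before the final codon (off by default).
#' @return A list with elements
#'   \describe{
#'     \item{passing}{`cds_set` of passing records, input order preserved.}
#'     \item{report}{object of class `cds_qc_report`: a data frame with
#'       columns `id`, `length`, `pass`, `failed_predicates` (comma-separated)
#'       plus attributes `n_pass`, `n_fail` and `predicate_failures` (named
#'       integer, failures per predicate).}
#'   }
#' @examples
#' recs <- cds_set(c("ok", "short"),
#'                 c(paste0("ATG", strrep("GCT", 98), "TAA"), "ATGTAA"))
#' screen_cds(recs)$report
#' @export
screen_cds <- function(records, min_length = 300, internal_stops = FALSE) {
  records <- as_cds_set(records)
  code <- genetic_code_table()
  n <- nrow(records)
  failed <- vector("list", n)
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    len <- records$length[i]
    f <- character(0)
    if (len < min_length) f <- c(f, "min_length")
    if (len %% 3L != 0L) f <- c(f, "frame")
    if (len < 3L || substr(s, 1L, 3L) != "ATG") f <- c(f, "start_codon")
    if (len < 3L ||
        !(substr(s, len - 2L, len) %in% code$stop_codons)) {
      f <- c(f, "stop_codon")
    }
    if (grepl("[^ACGT]", s)) f <- c(f, "alphabet")
    if (internal_stops && len >= 6L && len %% 3L == 0L) {
      # all codons but the last
      body <- substring(s, seq(1L, len - 3L, by = 3L), seq(3L, len - 3L, by = 3L))
      if (any(body %in% code$stop_codons)) f <- c(f, "internal_stop")
    }
    failed[[i]] <- f
  }
  pass <- lengths(failed) == 0L
  report <- data.frame(
    id = records$id,
    length = records$length,
    pass = pass,
    failed_predicates = vapply(failed, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  per_pred <- vapply(.qc_predicates, function(p) {
    sum(vapply(failed, function(f) p %in% f, logical(1)))
  }, integer(1))
  attr(report, "n_pass") <- sum(pass)
  attr(report, "n_fail") <- sum(!pass)
  attr(report, "predicate_failures") <- per_pred
  class(report) <- c("cds_qc_report", "data.frame")
  passing <- records[pass, , drop = FALSE]
  class(passing) <- c("cds_set", "data.frame")
  list(passing = passing, report = report)
}

as_cds_set <- function(records) {
  if (inherits(records, "cds_set")) return(records)
  if (is.data.frame(records) && all(c("id", "sequence") %in% names(records))) {
    return(cds_set(records$id, records$sequence))
  }
  stop("`records` must be a cds_set or a data frame with columns id, sequence")
}

#' Write a QC report as TSV
#'
#' Columns: `id`, `length`, `pass`, `failed_predicates`.
#'
#' @param report A `cds_qc_report` from [screen_cds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a CDS into codons
#'
#' @param sequence A single nucleotide string (or a one-row `cds_set`).
#' @return Character vector of `length/3` non-overlapping triplets in
#'   5' to 3' order; their concatenation reproduces the sequence.
#' @examples
#' split_codons("ATGGCTGCCTAA")
#' @export
split_codons <- function(sequence) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  len <- nchar(sequence)
  if (len %% 3L != 0L) {
    stop("malformed CDS: length ", len, " is not a multiple of 3")
  }
  if (len == 0L) return(character(0))
  substring(sequence, seq(1L, len - 2L, by = 3L), seq(3L, len, by = 3L))
}
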
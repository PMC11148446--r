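# Optimal-codon determination: partition genes into putative high/low
# expression tails by ENC (lower ENC = stronger bias = putative higher
# expression), compute delta-RSCU between pooled tail counts, and intersect
# the delta-RSCU selected codons with the per-amino-acid RSCU maxima of the
# whole set.

#' Partition genes into ENC tails
#'
#' Genes are sorted by ENC ascending; the tail size is
#' `max(1, round-half-up(fraction * n))`. The low-ENC tail is labelled
#' high-expression (stronger bias as the standard expression proxy) and the
#' high-ENC tail low-expression. ENC ties are broken by gene id
#' (lexicographic), so the partition is deterministic under permutation of
#' input order.
#'
#' @param stats A `gene_codon_stats` table (columns `gene`, `ENC`).
#' @param fraction Tail fraction (default 0.10).
#' @return List of class `expression_partition` with `high` and `low`
#'   (gene id vectors), `tail_size`, `fraction` and `enc` (named ENC values
#'   in sort order).
#' @examples
#' df <- data.frame(gene = letters[1:7], ENC = c(50, 55, 52, 58, 45, 60, 53))
#' partition_by_enc(df) # 1 gene per tail
#' @export
partition_by_enc <- function(stats, fraction = 0.10) {
  stopifnot(is.data.frame(stats), all(c("gene", "ENC") %in% names(stats)),
            fraction > 0, fraction <= 0.5)
  ok <- !is.na(stats$ENC)
  stats <- stats[ok, , drop = FALSE]
  n <- nrow(stats)
  if (n < 2L) stop("need at least 2 genes with computable ENC")
  ord <- order(stats$ENC, stats$gene)
  genes <- stats$gene[ord]
  enc_sorted <- stats::setNames(stats$ENC[ord], genes)
  k <- max(1L, as.integer(floor(fraction * n + 0.5)))
  structure(
    list(
      high = genes[seq_len(k)],
      low = genes[seq.int(n - k + 1L, n)],
      tail_size = k,
      fraction = fraction,
      enc = enc_sorted
    ),
    class = "expression_partition"
  )
}

#' @export
print.expression_partition <- function(x, ...) {
  cat("expression_partition:", length(x$enc), "genes,",
      x$tail_size, "per tail\n")
  cat("  high-expression (low ENC):", paste(x$high, collapse = ", "), "\n")
  cat("  low-expression (high ENC):", paste(x$low, collapse = ", "), "\n")
  invisible(x)
}

#' Delta-RSCU between high- and low-expression gene sets
#'
#' RSCU is computed on pooled codon counts of each set and subtracted
#' (high minus low). Codons whose amino acid is absent from either set get
#' a missing delta.
#'
#' @param high,low `rscu_table`s of the two tails (pooled counts), e.g.
#'   `rscu(pool_codon_counts(records[ids, ]))`.
#' @return Data frame with columns `codon`, `amino_acid`, `rscu_high`,
#'   `rscu_low`, `delta`, one row per sense codon of a multi-codon amino
#'   acid.
#' @export
delta_rscu <- function(high, low) {
  stopifnot(inherits(high, "rscu_table"), inherits(low, "rscu_table"))
  stopifnot(identical(high$codon, low$codon))
  out <- data.frame(
    codon = high$codon,
    amino_acid = high$amino_acid,
    rscu_high = high$rscu,
    rscu_low = low$rscu,
    delta = high$rscu - low$rscu,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Determine optimal codons
#'
#' Implements the stepwise rule: codons with `delta > threshold` (strict)
#' are high-expression superior; per amino acid the codon maximizing RSCU in
#' the full pooled set, kept only when that RSCU exceeds 1 (strict), is the
#' high-frequency superior codon (ties broken lexicographically and
#' flagged); the optimal set is the intersection.
#'
#' @param rscu_all `rscu_table` over the full gene set (pooled counts).
#' @param delta Output of [delta_rscu()].
#' @param threshold Strict delta-RSCU cutoff (default 0.08).
#' @param label Species label carried into the result.
#' @return List of class `optimal_codon_set`: `label`,
#'   `high_expression` (codons with delta above threshold),
#'   `high_frequency` (per-amino-acid RSCU maxima above 1),
#'   `optimal` (intersection), `tied_aa` (amino acids whose maximum was
#'   tied) and `ending_base` (named counts of optimal codons ending A/T vs
#'   G/C). Codons are DNA-spelled; use [to_rna()] for presentation.
#' @export
determine_optimal <- function(rscu_all, delta, threshold = 0.08,
                              label = "set") {
  stopifnot(inherits(rscu_all, "rscu_table"), is.data.frame(delta))
  high_expr <- delta$codon[!is.na(delta$delta) & delta$delta > threshold]
  high_freq <- character(0)
  tied <- character(0)
  for (a in unique(rscu_all$amino_acid)) {
    rows <- rscu_all[rscu_all$amino_acid == a, ]
    if (all(is.na(rows$rscu))) next
    mx <- max(rows$rscu, na.rm = TRUE)
    if (mx <= 1) next
    best <- sort(rows$codon[!is.na(rows$rscu) & rows$rscu == mx])
    if (length(best) > 1L) tied <- c(tied, a)
    high_freq <- c(high_freq, best[1L])
  }
  optimal <- sort(intersect(high_expr, high_freq))
  third <- substr(optimal, 3L, 3L)
  structure(
    list(
      label = label,
      high_expression = sort(high_expr),
      high_frequency = sort(high_freq),
      optimal = optimal,
      tied_aa = tied,
      ending_base = c(AT = sum(third %in% c("A", "T")),
                      GC = sum(third %in% c("G", "C")))
    ),
    class = "optimal_codon_set"
  )
}

#' @export
print.optimal_codon_set <- function(x, ...) {
  cat("optimal_codon_set [", x$label, "]\n", sep = "")
  cat("  high-expression superior:", length(x$high_expression), "codons\n")
  cat("  high-frequency superior: ", length(x$high_frequency), "codons\n")
  cat("  optimal:", paste(to_rna(x$optimal), collapse = ", "),
      sprintf("(%d ending A/U, %d ending G/C)\n",
              x$ending_base[["AT"]], x$ending_base[["GC"]]))
  invisible(x)
}

#' Full optimal-codon procedure for one species
#'
#' Convenience wrapper chaining [partition_by_enc()], pooled [rscu()],
#' [delta_rscu()] and [determine_optimal()].
#'
#' @param records A screened `cds_set`.
#' @param stats Matching `gene_codon_stats` (defaults to
#'   `usage_table(records)`).
#' @param fraction Tail fraction for the ENC partition.
#' @param threshold Strict delta-RSCU cutoff.
#' @param label Species label.
#' @return List with `partition`, `delta` (the delta-RSCU table with a
#'   `selected` column) and `set` (the `optimal_codon_set`).
#' @export
optimal_codon_analysis <- function(records, stats = usage_table(records),
                                   fraction = 0.10, threshold = 0.08,
                                   label = "set") {
  records <- as_cds_set(records)
  part <- partition_by_enc(stats, fraction)
  sub <- function(ids) records[records$id %in% ids, , drop = FALSE]
  rscu_high <- rscu(pool_codon_counts(sub(part$high)))
  rscu_low <- rscu(pool_codon_counts(sub(part$low)))
  rscu_all <- rscu(pool_codon_counts(records))
  d <- delta_rscu(rscu_high, rscu_low)
  set <- determine_optimal(rscu_all, d, threshold, label)
  d$selected <- d$codon %in% set$high_expression
  list(partition = part, delta = d, set = set)
}

#' Cross-species optimal-codon comparison
#'
#' @param sets List of `optimal_codon_set` objects with distinct labels.
#' @return List with `membership` (data frame: `codon` in RNA spelling, one
#'   logical column per species, `n_species`) and `regions` (named integer:
#'   counts of codons per exact species combination, the Venn regions).
#' @examples
#' a <- structure(list(label = "A", optimal = c("AAG", "TTC", "CCA")),
#'                class = "optimal_codon_set")
#' b <- structure(list(label = "B", optimal = c("AAG", "TTC", "CTG")),
#'                class = "optimal_codon_set")
#' compare_species(list(a, b))$regions
#' @export
compare_species <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  labels <- vapply(sets, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate species labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  all_codons <- sort(unique(unlist(lapply(sets, function(s) s$optimal))))
  member <- vapply(sets, function(s) all_codons %in% s$optimal,
                   logical(length(all_codons)))
  member <- matrix(member, nrow = length(all_codons),
                   dimnames = list(NULL, labels))
  membership <- data.frame(codon = to_rna(all_codons), member,
                           n_species = rowSums(member),
                           stringsAsFactors = FALSE)
  combo <- apply(member, 1L, function(m) paste(labels[m], collapse = "&"))
  regions <- table(factor(combo))
  list(membership = membership,
       regions = stats::setNames(as.integer(regions), names(regions)))
}
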
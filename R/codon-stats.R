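# Per-gene codon-usage bias statistics, following CodonW's conventions:
# RSCU, Wright's effective number of codons (ENC), the codon adaptation
# index (CAI), codon bias index (CBI), frequency of optimal codons (Fop),
# and silent third-position base composition (T3s/C3s/A3s/G3s, GC3s) plus
# whole-sequence GC.

#' Tally codon usage of a gene
#'
#' @param codons Ordered codon vector, e.g. from [split_codons()]. All
#'   entries must be triplets over A, C, G, T.
#' @return An object of class `codon_count`: a list with `counts` (named
#'   integer over all 64 codons), `sense_total` (stop codons excluded),
#'   `stop_total` and `aa_totals` (named integer per amino acid).
#' @examples
#' count_codons(c("ATG", "TTT", "TTT", "TTC", "TAA"))
#' @export
count_codons <- function(codons) {
  code <- genetic_code_table()
  codons <- toupper(codons)
  bad <- which(!codons %in% names(code$aa))
  if (length(bad) > 0L) {
    stop("invalid codon '", codons[bad[1]], "' at position ", bad[1])
  }
  counts <- stats::setNames(integer(64), names(code$aa))
  tab <- table(codons)
  counts[names(tab)] <- as.integer(tab)
  aa_totals <- vapply(code$families, function(f) sum(counts[f]), integer(1))
  structure(
    list(
      counts = counts,
      sense_total = sum(counts[code$sense_codons]),
      stop_total = sum(counts[code$stop_codons]),
      aa_totals = aa_totals
    ),
    class = "codon_count"
  )
}

#' @export
print.codon_count <- function(x, ...) {
  cat("codon_count:", x$sense_total, "sense codons,",
      x$stop_total, "stop codons\n")
  invisible(x)
}

# Pool several codon_count objects (or count a whole cds_set) into one tally.

#' Pooled codon counts over a gene set
#'
#' @param records A `cds_set` data frame whose records passed [screen_cds()].
#' @return A single `codon_count` over the concatenated codons of all genes.
#' @export
pool_codon_counts <- function(records) {
  records <- as_cds_set(records)
  codons <- unlist(lapply(records$sequence, split_codons), use.names = FALSE)
  count_codons(codons)
}

#' Relative synonymous codon usage
#'
#' For codon j of an amino acid with degeneracy k and total count N,
#' RSCU = count_j / (N / k): the observed count divided by the expected
#' count under uniform synonymous usage. Values above 1 mark codons used
#' more often than expected. Stop codons and the single-codon amino acids
#' Met and Trp are excluded. Codons of an amino acid that is absent from
#' the gene get `NA` (absent amino acid), distinct from 0 (unused codon of
#' an observed amino acid).
#'
#' @param counts A `codon_count`.
#' @return A data frame of class `rscu_table` with columns `codon`,
#'   `amino_acid`, `count`, `rscu`, one row per sense codon of each
#'   multi-codon amino acid (59 rows).
#' @examples
#' cc <- count_codons(c("TTT", "TTT", "TTT", "TTC"))
#' subset(rscu(cc), amino_acid == "F") # 1.5 and 0.5
#' @export
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_count"))
  code <- genetic_code_table()
  rows <- lapply(code$synonymous_aa, function(a) {
    fam <- code$families[[a]]
    k <- length(fam)
    n_a <- counts$aa_totals[[a]]
    val <- if (n_a == 0L) rep(NA_real_, k) else counts$counts[fam] / (n_a / k)
    data.frame(codon = fam, amino_acid = a,
               count = as.integer(counts$counts[fam]),
               rscu = unname(val), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}

# Wright's per-amino-acid homozygosity estimate
#   F = (n * sum(p^2) - 1) / (n - 1),  defined for n >= 2,
# where n is the amino acid's codon count and p its usage fractions.
.homozygosity <- function(counts) {
  code <- genetic_code_table()
  vapply(code$synonymous_aa, function(a) {
    fam <- code$families[[a]]
    n <- counts$aa_totals[[a]]
    if (n < 2L) return(NA_real_)
    p <- counts$counts[fam] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's estimator with CodonW's conventions. Per amino acid with at
#' least two codon observations the homozygosity F is estimated as
#' `(n * sum(p^2) - 1) / (n - 1)`; F values are averaged within each
#' degeneracy class and
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`
#' with Fk the mean homozygosity of the k-fold class.
#' If the three-fold class (Ile) mean is undefined it is
#' imputed as the mean of the 2-fold and 4-fold class means. If any other
#' class mean is undefined or non-positive the statistic is flagged
#' not-computable. The reported value is capped at 61; the theoretical range
#' is 20 (one codon per amino acid) to 61 (uniform usage).
#'
#' @param counts A `codon_count`.
#' @return An object of class `enc_estimate`: list with `value` (capped, or
#'   `NA` when not computable), `raw` (uncapped), `computable` (logical),
#'   `class_means` (named numeric: F2, F3, F4, F6) and `homozygosity`
#'   (per-amino-acid F).
#' @examples
#' # every sense codon twice: raw value 102, reported 61
#' cc <- count_codons(rep(genetic_code_table()$sense_codons, 2))
#' enc(cc)$value
#' @export
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_count"))
  code <- genetic_code_table()
  fhat <- .homozygosity(counts)
  deg <- code$degeneracy[code$synonymous_aa]
  class_mean <- function(k) {
    v <- fhat[deg == k]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- class_mean(2L); f3 <- class_mean(3L)
  f4 <- class_mean(4L); f6 <- class_mean(6L)
  if (is.na(f3)) {
    f3 <- if (!is.na(f2) && !is.na(f4)) (f2 + f4) / 2 else NA_real_
  }
  means <- c(F2 = f2, F3 = f3, F4 = f4, F6 = f6)
  computable <- !anyNA(means) && all(means > 0)
  raw <- if (computable) 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6 else NA_real_
  structure(
    list(
      value = if (computable) min(raw, 61) else NA_real_,
      raw = raw,
      computable = computable,
      class_means = means,
      homozygosity = fhat
    ),
    class = "enc_estimate"
  )
}

#' @export
print.enc_estimate <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("ENC = %.4f (raw %.4f)\n", x$value, x$raw))
  } else {
    cat("ENC not computable (too few codon observations)\n")
  }
  invisible(x)
}

#' Relative adaptiveness weights for CAI
#'
#' Weights are `w = RSCU / max(RSCU)` within each amino acid of a reference
#' gene set of highly expressed genes, so each amino acid has at least one
#' codon with w = 1. `cai_weights()` returns the built-in reference;
#' `reference_weights()` derives weights from any reference gene set;
#' `read_weights_tsv()` loads a two-column (codon, value) TSV.
#'
#' The built-in `"ecoli"` table carries the classic Escherichia coli
#' relative-adaptiveness values of Sharp & Li (1987), the reference CodonW
#' ships as its default. Reference codons with w = 0 are floored at 0.01
#' when used, so the geometric mean stays finite.
#'
#' @param set Name of a built-in reference set (currently `"ecoli"`).
#' @return Named numeric vector over the 61 sense codons, values in (0, 1].
#' @export
cai_weights <- function(set = "ecoli") {
  set <- match.arg(set, "ecoli")
  w <- c(
    TTT = 0.296, TTC = 1.000, TTA = 0.020, TTG = 0.020,
    CTT = 0.042, CTC = 0.037, CTA = 0.007, CTG = 1.000,
    ATT = 0.185, ATC = 1.000, ATA = 0.003, ATG = 1.000,
    GTT = 1.000, GTC = 0.066, GTA = 0.495, GTG = 0.221,
    TCT = 1.000, TCC = 0.744, TCA = 0.077, TCG = 0.017,
    AGT = 0.085, AGC = 0.410,
    CCT = 0.070, CCC = 0.012, CCA = 0.135, CCG = 1.000,
    ACT = 0.965, ACC = 1.000, ACA = 0.076, ACG = 0.099,
    GCT = 1.000, GCC = 0.122, GCA = 0.586, GCG = 0.424,
    TAT = 0.239, TAC = 1.000, CAT = 0.291, CAC = 1.000,
    CAA = 0.124, CAG = 1.000, AAT = 0.051, AAC = 1.000,
    AAA = 1.000, AAG = 0.253, GAT = 0.434, GAC = 1.000,
    GAA = 1.000, GAG = 0.259, TGT = 0.500, TGC = 1.000,
    TGG = 1.000,
    CGT = 1.000, CGC = 0.356, CGA = 0.004, CGG = 0.004,
    AGA = 0.004, AGG = 0.002,
    GGT = 1.000, GGC = 0.724, GGA = 0.010, GGG = 0.019
  )
  validate_weights(w)
}

#' @rdname cai_weights
#' @param records A `cds_set` of reference (highly expressed) genes.
#' @export
reference_weights <- function(records) {
  counts <- pool_codon_counts(records)
  rs <- rscu(counts)
  code <- genetic_code_table()
  w <- stats::setNames(rep(1, length(code$sense_codons)), code$sense_codons)
  for (a in code$synonymous_aa) {
    rows <- rs[rs$amino_acid == a, ]
    if (anyNA(rows$rscu)) next # amino acid absent from reference: keep w = 1
    w[rows$codon] <- rows$rscu / max(rows$rscu)
  }
  validate_weights(w)
}

#' @rdname cai_weights
#' @param path Path to a two-column TSV (codon, value) with a header line.
#' @export
read_weights_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("weight TSV needs two columns: codon, value")
  validate_weights(stats::setNames(as.numeric(df[[2]]), to_dna(df[[1]])))
}

validate_weights <- function(w) {
  code <- genetic_code_table()
  missing <- setdiff(code$sense_codons, names(w))
  if (length(missing) > 0L) {
    stop("weights missing for codons: ", paste(missing, collapse = ", "))
  }
  w <- w[code$sense_codons]
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("weights must be finite and in [0, 1]")
  }
  for (a in code$synonymous_aa) {
    if (max(w[code$families[[a]]]) < 1) {
      stop("amino acid ", a, " has no codon with weight 1")
    }
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness w of every counted codon,
#' excluding stop codons and the single-codon amino acids Met and Trp.
#' Reference weights of 0 are floored at 0.01 before taking logs.
#'
#' @param counts A `codon_count`.
#' @param weights Named numeric weight vector (see [cai_weights()]).
#' @param floor Minimum weight substituted for zero reference weights.
#' @return CAI in (0, 1], or `NA` when the gene has no eligible codons.
#' @examples
#' w <- cai_weights()
#' cai(count_codons(c("TTC", "AAA")), w) # both w = 1 -> CAI = 1
#' @export
cai <- function(counts, weights = cai_weights(), floor = 0.01) {
  stopifnot(inherits(counts, "codon_count"))
  code <- genetic_code_table()
  weights <- validate_weights(weights)
  eligible <- setdiff(code$sense_codons,
                      unlist(code$families[code$single_aa], use.names = FALSE))
  n <- counts$counts[eligible]
  if (sum(n) == 0L) return(NA_real_)
  w <- pmax(weights[eligible], floor)
  exp(sum(n * log(w)) / sum(n))
}

#' Codon bias index and frequency of optimal codons
#'
#' Over the amino acids that possess at least one optimal codon, with
#' `N_opt` the number of optimal codons used, `N_tot` the total codons and
#' `N_ran` the expected optimal count under uniform synonymous usage:
#' `CBI = (N_opt - N_ran) / (N_tot - N_ran)` and `Fop = N_opt / N_tot`.
#' CBI ranges from -1 (optimal codons avoided entirely) through 0 (random
#' usage) to 1 (only optimal codons); Fop is the plain usage fraction.
#'
#' @param counts A `codon_count`.
#' @param optimal Character vector of optimal codons (DNA or RNA spelling);
#'   default: the codons with weight 1 in the built-in CAI reference.
#' @return List with `cbi` (`NA` when `N_tot == N_ran`, degenerate) and
#'   `fop` (`NA` only when no contributing amino acid is observed).
#' @examples
#' cc <- count_codons(rep("TTC", 10)) # Phe, optimal codon only
#' cbi_fop(cc, optimal = "TTC")
#' @export
cbi_fop <- function(counts, optimal = optimal_codons_default()) {
  stopifnot(inherits(counts, "codon_count"))
  code <- genetic_code_table()
  optimal <- to_dna(optimal)
  if (length(optimal) == 0L) stop("`optimal` must contain at least one codon")
  unknown <- setdiff(optimal, code$sense_codons)
  if (length(unknown) > 0L) {
    stop("unknown optimal codons: ", paste(unknown, collapse = ", "))
  }
  n_opt <- 0; n_tot <- 0; n_ran <- 0
  for (a in code$synonymous_aa) {
    fam <- code$families[[a]]
    opt <- intersect(fam, optimal)
    if (length(opt) == 0L) next
    n_a <- counts$aa_totals[[a]]
    n_opt <- n_opt + sum(counts$counts[opt])
    n_tot <- n_tot + n_a
    n_ran <- n_ran + n_a * length(opt) / length(fam)
  }
  if (n_tot == 0) return(list(cbi = NA_real_, fop = NA_real_))
  list(
    cbi = if (n_tot == n_ran) NA_real_ else (n_opt - n_ran) / (n_tot - n_ran),
    fop = n_opt / n_tot
  )
}

#' Default optimal-codon set
#'
#' The codons carrying weight 1 in a CAI reference-weight vector (one or
#' more per amino acid): a deterministic stand-in until a species-specific
#' set has been derived with [determine_optimal()].
#'
#' @param weights Named weight vector (see [cai_weights()]).
#' @return Character vector of codons (DNA spelling), Met/Trp excluded.
#' @export
optimal_codons_default <- function(weights = cai_weights()) {
  code <- genetic_code_table()
  weights <- validate_weights(weights)
  w <- weights[setdiff(code$sense_codons,
                       unlist(code$families[code$single_aa], use.names = FALSE))]
  names(w)[w == 1]
}

# Codons eligible for "silent" third-position statistics: sense codons of
# multi-codon amino acids. CodonW's X3s convention: the frequency of base X
# at synonymous third positions, among codons whose amino acid can accept X
# at position 3.
.silent_third <- function() {
  code <- genetic_code_table()
  fams <- code$families[code$synonymous_aa]
  codons <- unlist(fams, use.names = FALSE)
  third <- substr(codons, 3L, 3L)
  aa <- rep(names(fams), lengths(fams))
  reachable <- lapply(fams, function(f) unique(substr(f, 3L, 3L)))
  list(codons = codons, third = third, aa = aa, reachable = reachable)
}

#' Third-position base composition
#'
#' Computes GC3s (fraction of synonymous third positions carrying G or C;
#' stop, Met and Trp codons excluded), the silent base frequencies T3s, C3s,
#' A3s, G3s (frequency of base X at synonymous third positions among codons
#' whose amino acid can accept X at position 3 -- CodonW's convention), and
#' whole-sequence GC.
#'
#' @param counts A `codon_count`.
#' @param sequence The full nucleotide sequence the counts came from (used
#'   only for GC); omit to get `NA` GC.
#' @return Named list `t3s`, `c3s`, `a3s`, `g3s`, `gc3s`, `gc`; silent
#'   statistics are `NA` when the gene has no synonymous codons.
#' @examples
#' s <- strrep("GCC", 10)
#' third_position_composition(count_codons(split_codons(s)), s)$gc3s # 1
#' @export
third_position_composition <- function(counts, sequence = NULL) {
  stopifnot(inherits(counts, "codon_count"))
  st <- .silent_third()
  n <- counts$counts[st$codons]
  total <- sum(n)
  if (total == 0L) {
    comp <- list(t3s = NA_real_, c3s = NA_real_, a3s = NA_real_,
                 g3s = NA_real_, gc3s = NA_real_)
  } else {
    x3s <- function(base) {
      ok_aa <- names(st$reachable)[vapply(st$reachable, function(r)
        base %in% r, logical(1))]
      denom <- sum(n[st$aa %in% ok_aa])
      if (denom == 0L) return(NA_real_)
      sum(n[st$third == base]) / denom
    }
    comp <- list(
      t3s = x3s("T"), c3s = x3s("C"), a3s = x3s("A"), g3s = x3s("G"),
      gc3s = sum(n[st$third %in% c("G", "C")]) / total
    )
  }
  gc <- NA_real_
  if (!is.null(sequence)) {
    bases <- strsplit(toupper(sequence), "")[[1]]
    gc <- mean(bases %in% c("G", "C"))
  }
  c(comp, list(gc = gc))
}

#' Per-gene codon bias parameter table
#'
#' One row per gene with the classic CodonW output columns, in the order
#' `gene, T3s, C3s, A3s, G3s, CAI, CBI, Fop, ENC, GC3s, GC`.
#'
#' @param records A `cds_set` whose records passed [screen_cds()].
#' @param weights CAI reference weights (see [cai_weights()]).
#' @param optimal Optimal-codon set for CBI/Fop
#'   (default [optimal_codons_default()]).
#' @return A data frame of class `gene_codon_stats`; not-computable
#'   statistics appear as `NA`. The attribute `summary` holds the per-set
#'   `range` and `average` rows (arithmetic means over genes, `NA` excluded).
#' @examples
#' set.seed(1)
#' recs <- generate_cds_set(simulation_config(n_genes = 3, seed = 7))
#' usage_table(recs)
#' @export
usage_table <- function(records, weights = cai_weights(),
                        optimal = optimal_codons_default(weights)) {
  records <- as_cds_set(records)
  cols <- c("T3s", "C3s", "A3s", "G3s", "CAI", "CBI", "Fop",
            "ENC", "GC3s", "GC")
  if (nrow(records) == 0L) {
    out <- data.frame(gene = character(0))
    for (cl in cols) out[[cl]] <- numeric(0)
    class(out) <- c("gene_codon_stats", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    codons <- split_codons(records$sequence[i])
    cc <- count_codons(codons)
    comp <- third_position_composition(cc, records$sequence[i])
    cf <- cbi_fop(cc, optimal)
    data.frame(
      gene = records$id[i],
      T3s = comp$t3s, C3s = comp$c3s, A3s = comp$a3s, G3s = comp$g3s,
      CAI = cai(cc, weights), CBI = cf$cbi, Fop = cf$fop,
      ENC = enc(cc)$value, GC3s = comp$gc3s, GC = comp$gc,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  rng <- vapply(cols, function(cl) {
    v <- out[[cl]][!is.na(out[[cl]])]
    if (length(v) == 0L) return(NA_character_)
    sprintf("%.4g-%.4g", min(v), max(v))
  }, character(1))
  avg <- vapply(cols, function(cl) mean(out[[cl]], na.rm = TRUE), numeric(1))
  attr(out, "summary") <- list(range = rng, average = avg)
  class(out) <- c("gene_codon_stats", "data.frame")
  out
}

#' Write per-gene codon statistics as TSV
#'
#' @param stats A `gene_codon_stats` table from [usage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_usage_tsv <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-codon RSCU table as TSV
#'
#' Columns: codon (RNA spelling), amino_acid, count, RSCU.
#'
#' @param rscu_table An `rscu_table` from [rscu()].
#' @param path Output path.
#' @param alphabet `"rna"` (default, matching conventional presentation)
#'   or `"dna"`.
#' @return `path`, invisibly.
#' @export
write_rscu_tsv <- function(rscu_table, path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  df <- as.data.frame(rscu_table)
  if (alphabet == "rna") df$codon <- to_rna(df$codon)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
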
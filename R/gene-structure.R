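# GFF3 utilities: strand-aware upstream (promoter) sequence extraction and
# exon-intron-UTR structure summaries. Coordinates are GFF3-native
# throughout: 1-based, inclusive on both ends.

#' Construct a genome annotation from a feature table
#'
#' @param features Data frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent` (NA for top-level features). Coordinates are
#'   1-based inclusive and must satisfy `start <= end`.
#' @return The validated data frame, classed `genome_annotation`.
#' @export
genome_annotation <- function(features) {
  need <- c("seqid", "type", "start", "end", "strand", "ID", "Parent")
  missing <- setdiff(need, names(features))
  if (length(missing) > 0L) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  features <- as.data.frame(features)[, need]
  for (col in c("seqid", "type", "strand", "ID", "Parent")) {
    features[[col]] <- as.character(features[[col]])
  }
  bad <- which(features$start > features$end)
  if (length(bad) > 0L) {
    stop("feature with start > end at row ", bad[1L])
  }
  class(features) <- c("genome_annotation", "data.frame")
  features
}

#' Read a GFF3 file
#'
#' Parses with `rtracklayer::readGFF()`; features with multiple parents are
#' expanded to one row per parent.
#'
#' @param path Path to a GFF3 file.
#' @return A `genome_annotation` data frame.
#' @export
read_annotation <- function(path) {
  gff <- as.data.frame(rtracklayer::readGFF(path))
  if (!"ID" %in% names(gff)) gff$ID <- NA_character_
  if (!"Parent" %in% names(gff)) gff$Parent <- NA_character_
  parents <- gff$Parent
  if (is.list(parents)) {
    n_par <- pmax(1L, lengths(parents))
    idx <- rep(seq_len(nrow(gff)), n_par)
    parent_chr <- unlist(lapply(parents, function(p) {
      if (length(p) == 0L) NA_character_ else as.character(p)
    }), use.names = FALSE)
    gff <- gff[idx, ]
    gff$Parent <- parent_chr
  }
  genome_annotation(gff)
}

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    x <- genome
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    x <- Biostrings::DNAStringSet(genome)
  } else {
    stop("`genome` must be a DNAStringSet, a named character vector, ",
         "or a FASTA path")
  }
  names(x) <- vapply(strsplit(names(x), "[ \t]+"), `[[`, character(1), 1L)
  x
}

#' Extract upstream (promoter) sequences
#'
#' For a plus-strand gene starting at position p, returns the bases
#' `[max(1, p - upstream), p - 1]`; for a minus-strand gene ending at q, the
#' reverse complement of `[q + 1, min(L, q + upstream)]` with L the contig
#' length. The extracted window abuts the gene's 5' end with no gap and no
#' overlap. Windows clipped at a contig boundary are flagged truncated,
#' never padded. Unknown gene ids or missing contigs give per-gene error
#' notes; the run continues.
#'
#' @param annotation A `genome_annotation`.
#' @param genome Genome sequence: `DNAStringSet`, named character vector or
#'   FASTA path.
#' @param gene_ids Gene feature IDs to extract.
#' @param upstream Window size in bases (default 2000).
#' @param feature_type Feature type holding the gene coordinates
#'   (default `"gene"`; use `"mRNA"` for annotations whose gene and mRNA
#'   5' ends differ).
#' @return Data frame of class `promoter_set`: `gene`, `seqid`, `start`,
#'   `end` (1-based inclusive; `NA` with zero-width windows), `strand`,
#'   `length`, `truncated`, `note`, `sequence`.
#' @export
extract_promoters <- function(annotation, genome, gene_ids, upstream = 2000,
                              feature_type = "gene") {
  stopifnot(inherits(annotation, "genome_annotation"), upstream >= 1)
  genome <- .as_genome(genome)
  feats <- annotation[annotation$type == feature_type, , drop = FALSE]
  rows <- lapply(gene_ids, function(g) {
    out <- data.frame(gene = g, seqid = NA_character_, start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      length = 0L, truncated = NA, note = "",
                      sequence = NA_character_, stringsAsFactors = FALSE)
    i <- which(feats$ID == g)
    if (length(i) == 0L) {
      out$note <- "gene not found in annotation"
      return(out)
    }
    f <- feats[i[1L], ]
    out$seqid <- f$seqid
    out$strand <- f$strand
    if (!f$seqid %in% names(genome)) {
      out$note <- "seqid absent from genome FASTA"
      return(out)
    }
    contig_len <- Biostrings::width(genome[f$seqid])
    if (f$strand == "-") {
      s <- f$end + 1L
      e <- min(contig_len, f$end + upstream)
    } else {
      if (f$strand != "+") out$note <- "unknown strand, treated as +"
      e <- f$start - 1L
      s <- max(1L, f$start - upstream)
    }
    if (s > e) { # gene starts at the contig edge: empty window
      out$truncated <- TRUE
      out$sequence <- ""
      return(out)
    }
    seq <- Biostrings::subseq(genome[[f$seqid]], s, e)
    if (f$strand == "-") seq <- Biostrings::reverseComplement(seq)
    out$start <- s
    out$end <- e
    out$length <- e - s + 1L
    out$truncated <- out$length < upstream
    out$sequence <- as.character(seq)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Write promoter sequences to FASTA
#'
#' Genes with error notes (no sequence) are omitted.
#'
#' @param promoters A `promoter_set` from [extract_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  ok <- !is.na(promoters$sequence)
  x <- Biostrings::BStringSet(
    stats::setNames(promoters$sequence[ok], promoters$gene[ok]))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# subtract intervals b from intervals a (all 1-based inclusive); returns a
# data.frame(start, end) of the remaining segments
.interval_subtract <- function(a, b) {
  segs <- list()
  if (nrow(a) > 0L) a <- a[order(a$start), , drop = FALSE]
  if (nrow(b) > 0L) b <- b[order(b$start), , drop = FALSE]
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    cur_s <- s
    for (j in seq_len(nrow(b))) {
      bs <- b$start[j]; be <- b$end[j]
      if (be < cur_s || bs > e) next
      if (bs > cur_s) segs[[length(segs) + 1L]] <- c(cur_s, bs - 1L)
      cur_s <- max(cur_s, be + 1L)
      if (cur_s > e) break
    }
    if (cur_s <= e) segs[[length(segs) + 1L]] <- c(cur_s, e)
  }
  if (length(segs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2])
}

.transcript_children <- function(annotation, transcript_id, types) {
  annotation[annotation$Parent %in% transcript_id &
               annotation$type %in% types, , drop = FALSE]
}

#' Exon-intron-UTR structure summary per transcript
#'
#' For each transcript: `length` is the parent gene's span (end - start + 1;
#' the transcript's own span when no gene parent exists), `cds_segments`
#' the number of CDS features, `introns` the number of gaps between
#' consecutive exons (between CDS segments when the annotation has no
#' exons), and `utr_segments` the number of annotated five_prime_UTR /
#' three_prime_UTR features -- derived as the exon-minus-CDS interval
#' segments when UTR features are absent (`utr_source` records which).
#'
#' @param annotation A `genome_annotation`.
#' @param transcript_ids Transcript (mRNA) IDs to summarize; default: the
#'   first mRNA of every gene, one row per gene.
#' @return Data frame with columns `transcript`, `length`, `introns`,
#'   `cds_segments`, `utr_segments`, `utr_source`
#'   (`"annotated"`/`"derived"`/`"none"`) and `note` (flags transcripts with
#'   neither exons nor CDS). Rows follow the requested order.
#' @export
structure_summary <- function(annotation, transcript_ids = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  tx_types <- c("mRNA", "transcript")
  tx <- annotation[annotation$type %in% tx_types, , drop = FALSE]
  if (is.null(transcript_ids)) {
    transcript_ids <- tx$ID[!duplicated(tx$Parent) | is.na(tx$Parent)]
  }
  rows <- lapply(transcript_ids, function(t) {
    out <- data.frame(transcript = t, length = NA_integer_,
                      introns = NA_integer_, cds_segments = NA_integer_,
                      utr_segments = NA_integer_, utr_source = "none",
                      note = "", stringsAsFactors = FALSE)
    ti <- which(tx$ID == t)
    if (length(ti) == 0L) {
      out$note <- "transcript not found"
      return(out)
    }
    trow <- tx[ti[1L], ]
    gene <- annotation[annotation$type == "gene" &
                         annotation$ID %in% trow$Parent, , drop = FALSE]
    span <- if (nrow(gene) > 0L) gene[1L, ] else trow
    out$length <- span$end - span$start + 1L
    exons <- .transcript_children(annotation, t, "exon")
    cds <- .transcript_children(annotation, t, "CDS")
    utr <- .transcript_children(annotation, t,
                                c("five_prime_UTR", "three_prime_UTR"))
    if (nrow(exons) == 0L && nrow(cds) == 0L) {
      out$note <- "no exon or CDS features"
      return(out)
    }
    intron_base <- if (nrow(exons) > 0L) exons else cds
    intron_base <- intron_base[order(intron_base$start), , drop = FALSE]
    gaps <- 0L
    if (nrow(intron_base) > 1L) {
      gaps <- sum(intron_base$start[-1L] >
                    intron_base$end[-nrow(intron_base)] + 1L)
    }
    out$introns <- gaps
    out$cds_segments <- nrow(cds)
    if (nrow(utr) > 0L) {
      out$utr_segments <- nrow(utr)
      out$utr_source <- "annotated"
    } else if (nrow(exons) > 0L && nrow(cds) > 0L) {
      derived <- .interval_subtract(exons[, c("start", "end")],
                                    cds[, c("start", "end")])
      out$utr_segments <- nrow(derived)
      out$utr_source <- if (nrow(derived) > 0L) "derived" else "none"
      if (nrow(derived) == 0L) out$utr_segments <- 0L
    } else {
      out$utr_segments <- 0L
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment-level intervals of transcripts, BED-style
#'
#' @param annotation A `genome_annotation`.
#' @param transcript_ids Transcript IDs.
#' @return Data frame in BED spirit (`seqid`, `start` 0-based, `end`
#'   exclusive, `name` = `type:transcript`, `strand`), one row per exon,
#'   CDS and UTR segment.
#' @export
structure_segments <- function(annotation, transcript_ids) {
  segs <- .transcript_children(
    annotation, transcript_ids,
    c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"))
  data.frame(
    seqid = segs$seqid,
    start = segs$start - 1L,
    end = segs$end,
    name = paste0(segs$type, ":", segs$Parent),
    strand = segs$strand,
    stringsAsFactors = FALSE
  )
}

#' Write a structure summary (or BED segments) as TSV
#'
#' @param x Output of [structure_summary()] or [structure_segments()].
#' @param path Output path.
#' @param col.names Write a header line (default `TRUE`; use `FALSE` for
#'   BED).
#' @return `path`, invisibly.
#' @export
write_structure_tsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  invisible(path)
}
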
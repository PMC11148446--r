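# Independent brute-force oracles, written directly from the defining
# formulas and kept free of the package's internal code paths.

# --- codon bias oracles ------------------------------------------------

oracle_code <- local({
  map <- Biostrings::GENETIC_CODE
  aa <- unname(map)
  list(
    aa = stats::setNames(aa, names(map)),
    sense = names(map)[aa != "*"],
    stops = names(map)[aa == "*"]
  )
})

# RSCU by direct per-codon loop over the definition
oracle_rscu <- function(codons) {
  oc <- oracle_code
  multi_aa <- names(which(table(oc$aa[oc$sense]) > 1))
  out <- list()
  for (codon in sort(oc$sense)) {
    a <- oc$aa[[codon]]
    if (!a %in% multi_aa) next
    syn <- oc$sense[oc$aa[oc$sense] == a]
    n_a <- sum(codons %in% syn)
    k <- length(syn)
    val <- if (n_a == 0) NA_real_ else sum(codons == codon) / (n_a / k)
    out[[codon]] <- val
  }
  unlist(out)
}

# Wright's ENC by direct formula, independently structured
oracle_enc <- function(codons) {
  oc <- oracle_code
  fam <- split(oc$sense, oc$aa[oc$sense])
  fam <- fam[lengths(fam) > 1]
  fhat <- list()
  for (a in names(fam)) {
    n <- sum(codons %in% fam[[a]])
    if (n < 2) next
    psq <- 0
    for (codon in fam[[a]]) psq <- psq + (sum(codons == codon) / n)^2
    fhat[[a]] <- (n * psq - 1) / (n - 1)
  }
  deg <- lengths(fam)
  mean_k <- function(k) {
    vals <- unlist(fhat[names(fam)[deg == k]])
    if (is.null(vals) || length(vals) == 0) NA_real_ else mean(vals)
  }
  f2 <- mean_k(2); f3 <- mean_k(3); f4 <- mean_k(4); f6 <- mean_k(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6)) || any(c(f2, f3, f4, f6) <= 0)) {
    return(NA_real_)
  }
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# random sense-codon gene of n codons
random_codons <- function(n) {
  sample(oracle_code$sense, n, replace = TRUE)
}

# --- reconciliation oracle ---------------------------------------------

# minimal rooted-binary tree index computed from scratch
oracle_tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_all)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2]] <- tree$edge[i, 1]
  root <- which(is.na(parent))
  depth <- integer(n_all)
  for (v in seq_len(n_all)) {
    p <- v
    while (!is.na(parent[p])) {
      depth[v] <- depth[v] + 1L
      p <- parent[p]
    }
  }
  ancestors <- lapply(seq_len(n_all), function(v) {
    out <- v
    while (!is.na(parent[out[length(out)]])) out <- c(out, parent[out[length(out)]])
    out
  })
  list(n_tip = n_tip, n_all = n_all, root = root, parent = parent,
       depth = depth, ancestors = ancestors)
}

oracle_lca <- function(idx, u, v) {
  common <- intersect(idx$ancestors[[u]], idx$ancestors[[v]])
  common[which.max(idx$depth[common])]
}

oracle_dist <- function(idx, anc, desc) idx$depth[desc] - idx$depth[anc]

# minimum duplication+loss cost over ALL feasible gene-node-to-species-node
# mappings, by exhaustive enumeration (gene trees with few leaves only)
oracle_min_dl_cost <- function(gene, species, mapping) {
  sidx <- oracle_tree_index(species)
  gidx <- oracle_tree_index(gene)
  gmap_leaf <- match(mapping[gene$tip.label], species$tip.label)
  internal <- which(seq_len(gidx$n_all) > gidx$n_tip)
  kids <- lapply(seq_len(gidx$n_all), function(v) gene$edge[gene$edge[, 1] == v, 2])
  post <- internal[order(gidx$depth[internal], decreasing = TRUE)]
  cost_of <- function(assign) {
    gamma <- c(gmap_leaf, rep(NA_integer_, gidx$n_all - gidx$n_tip))
    gamma[internal] <- assign
    total <- 0
    for (v in post) {
      c1 <- kids[[v]][1]; c2 <- kids[[v]][2]
      lca <- oracle_lca(sidx, gamma[c1], gamma[c2])
      # gamma(v) must be an ancestor (weak) of the children's LCA
      if (!gamma[v] %in% sidx$ancestors[[lca]]) return(Inf)
      dup <- gamma[v] != lca || gamma[v] == gamma[c1] || gamma[v] == gamma[c2]
      total <- total + as.integer(dup)
      for (c in c(c1, c2)) {
        # losses on the edge: one per skipped species edge, plus one if dup
        d <- oracle_dist(sidx, gamma[v], gamma[c])
        total <- total + d - 1 + as.integer(dup)
      }
    }
    groot <- internal[which.min(gidx$depth[internal])]
    total + oracle_dist(sidx, sidx$root, gamma[groot])
  }
  grid <- expand.grid(rep(list(seq_len(sidx$n_all)), length(internal)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    best <- min(best, cost_of(as.integer(grid[i, ])))
  }
  best
}

# --- gene structure oracle ----------------------------------------------

# per-base interval arithmetic: counts from coverage vectors
oracle_structure_counts <- function(exons, cds) {
  lo <- min(exons$start); hi <- max(exons$end)
  pos <- lo:hi
  in_exon <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(exons))) {
    in_exon[pos >= exons$start[i] & pos <= exons$end[i]] <- TRUE
  }
  in_cds <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(cds))) {
    in_cds[pos >= cds$start[i] & pos <= cds$end[i]] <- TRUE
  }
  runs <- function(x) sum(diff(c(FALSE, x)) == 1)
  list(
    introns = runs(!in_exon),
    utr_segments = runs(in_exon & !in_cds)
  )
}

# --- random fixtures -----------------------------------------------------

# random gene model on a random contig: non-overlapping exons with gaps,
# CDS spanning an interior window of the exon chain
random_gene_model <- function(gene_id = "g1", contig = "chr1") {
  n_exon <- sample(1:6, 1)
  widths <- sample(50:300, n_exon, replace = TRUE)
  gaps <- if (n_exon > 1) sample(20:500, n_exon - 1, replace = TRUE) else integer(0)
  gene_start <- sample(1:5000, 1)
  starts <- gene_start + cumsum(c(0, widths[-n_exon] + gaps))
  ends <- starts + widths - 1
  strand <- sample(c("+", "-"), 1)
  # CDS window strictly inside the exon span so UTRs exist at both ends
  cds_lo <- starts[1] + sample(5:30, 1)
  cds_hi <- ends[n_exon] - sample(5:30, 1)
  cds <- data.frame(start = pmax(starts, cds_lo), end = pmin(ends, cds_hi))
  cds <- cds[cds$start <= cds$end, , drop = FALSE]
  tid <- paste0(gene_id, ".t1")
  feats <- rbind(
    data.frame(seqid = contig, type = "gene", start = gene_start,
               end = ends[n_exon], strand = strand, ID = gene_id,
               Parent = NA_character_),
    data.frame(seqid = contig, type = "mRNA", start = gene_start,
               end = ends[n_exon], strand = strand, ID = tid,
               Parent = gene_id),
    data.frame(seqid = contig, type = "exon", start = starts, end = ends,
               strand = strand, ID = NA_character_, Parent = tid),
    data.frame(seqid = contig, type = "CDS", start = cds$start,
               end = cds$end, strand = strand, ID = NA_character_,
               Parent = tid)
  )
  list(annotation = genome_annotation(feats), gene_id = gene_id,
       transcript_id = tid, exons = data.frame(start = starts, end = ends),
       cds = cds, strand = strand, gene_start = gene_start,
       gene_end = ends[n_exon])
}

random_contig <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reverse complement without Biostrings, for the involution property
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
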
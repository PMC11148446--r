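# Seeded generators for every pipeline stage: codon-usage profiles with a
# tunable bias parameter and GC3s target, CDS sets built codon by codon so
# they pass screening by construction, and gene-family histories on a
# species tree with a known duplication/loss ledger that the reconciliation
# can be audited against.

#' Default amino-acid frequency vector
#'
#' Uniform weight over the 18 multi-codon amino acids, with Met and Trp at
#' one tenth of that weight so every degeneracy class is exercised without
#' the single-codon amino acids dominating anything.
#'
#' @return Named numeric vector over the 20 amino acids, summing to 1.
#' @export
default_aa_freq <- function() {
  code <- genetic_code_table()
  w <- stats::setNames(rep(1, length(code$families)), names(code$families))
  w[code$single_aa] <- 0.1
  w / sum(w)
}

#' Build a codon-usage profile
#'
#' Per amino acid with degeneracy k, the preferred codon gets probability
#' `beta + (1 - beta)/k` and every other synonym `(1 - beta)/k`: `beta = 0`
#' is uniform usage, `beta = 1` a single codon per amino acid. When
#' `target_gc3s` is set, probabilities are tilted by a common third-position
#' G/C factor, solved numerically so the expected GC3s under `aa_freq`
#' equals the target to within 1e-6.
#'
#' @param beta Bias parameter in \[0, 1\].
#' @param preferred Optional named character vector (amino acid -> codon)
#'   overriding the default preferred codon (the alphabetically first
#'   synonym).
#' @param target_gc3s Optional GC3s target in (0, 1).
#' @param aa_freq Amino-acid frequencies used for the GC3s expectation
#'   (default [default_aa_freq()]).
#' @return Object of class `codon_profile`: list with `prob` (per amino
#'   acid, a named probability vector over its codons), `beta`, `preferred`
#'   and `aa_freq`.
#' @examples
#' p <- make_profile(beta = 0.5)
#' p$prob[["F"]] # two-fold family: 0.75 / 0.25
#' @export
make_profile <- function(beta = 0, preferred = NULL, target_gc3s = NULL,
                         aa_freq = default_aa_freq()) {
  stopifnot(beta >= 0, beta <= 1)
  code <- genetic_code_table()
  pref <- vapply(code$families, `[[`, character(1), 1L)
  if (!is.null(preferred)) {
    for (a in names(preferred)) {
      if (!a %in% names(code$families)) stop("unknown amino acid: ", a)
      if (!preferred[[a]] %in% code$families[[a]]) {
        stop("codon ", preferred[[a]], " is not a synonym for ", a)
      }
      pref[[a]] <- preferred[[a]]
    }
  }
  prob <- lapply(names(code$families), function(a) {
    fam <- code$families[[a]]
    k <- length(fam)
    p <- stats::setNames(rep((1 - beta) / k, k), fam)
    p[pref[[a]]] <- p[pref[[a]]] + beta
    p
  })
  names(prob) <- names(code$families)
  profile <- structure(
    list(prob = prob, beta = beta, preferred = pref, aa_freq = aa_freq),
    class = "codon_profile"
  )
  if (!is.null(target_gc3s)) {
    profile <- .tilt_gc3s(profile, target_gc3s)
  }
  profile
}

# Expected GC3s of a profile: the probability that a synonymous codon drawn
# under aa_freq ends in G or C (Met/Trp excluded, as in the statistic).
#' Expected GC3s of a codon profile
#'
#' @param profile A `codon_profile`.
#' @return Expected GC3s in \[0, 1\].
#' @export
expected_gc3s <- function(profile) {
  stopifnot(inherits(profile, "codon_profile"))
  code <- genetic_code_table()
  f <- profile$aa_freq[code$synonymous_aa]
  f <- f / sum(f)
  share <- vapply(code$synonymous_aa, function(a) {
    p <- profile$prob[[a]]
    sum(p[substr(names(p), 3L, 3L) %in% c("G", "C")])
  }, numeric(1))
  sum(f * share)
}

.tilt_gc3s <- function(profile, target) {
  stopifnot(target > 0, target < 1)
  code <- genetic_code_table()
  f <- profile$aa_freq[code$synonymous_aa]
  f <- f / sum(f)
  gc_at <- function(log_t) {
    t <- exp(log_t)
    share <- vapply(code$synonymous_aa, function(a) {
      p <- profile$prob[[a]]
      gc <- substr(names(p), 3L, 3L) %in% c("G", "C")
      q <- p * ifelse(gc, t, 1)
      sum(q[gc]) / sum(q)
    }, numeric(1))
    sum(f * share)
  }
  lo <- gc_at(-60); hi <- gc_at(60)
  if (target < lo || target > hi) {
    stop(sprintf(
      "target GC3s %.4f is unattainable for this profile; attainable range is [%.6f, %.6f]",
      target, lo, hi))
  }
  root <- stats::uniroot(function(x) gc_at(x) - target, c(-60, 60),
                         tol = 1e-12)
  t <- exp(root$root)
  for (a in code$synonymous_aa) {
    p <- profile$prob[[a]]
    gc <- substr(names(p), 3L, 3L) %in% c("G", "C")
    q <- p * ifelse(gc, t, 1)
    profile$prob[[a]] <- q / sum(q)
  }
  profile
}

#' Simulation configuration for CDS generation
#'
#' @param n_genes Number of genes.
#' @param length_range Integer range of gene lengths in codons, start and
#'   stop included (default 100-400, i.e. 300-1200 bp, so every gene clears
#'   the 300 bp screening floor).
#' @param aa_freq Amino-acid frequencies for the coding body.
#' @param profile `codon_profile` the codons are drawn from.
#' @param seed Random seed; the seed fully determines the output.
#' @param prefix Gene id prefix.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 50, length_range = c(100L, 400L),
                              aa_freq = default_aa_freq(),
                              profile = make_profile(aa_freq = aa_freq),
                              seed = NULL, prefix = "gene") {
  stopifnot(n_genes >= 0, length(length_range) == 2L,
            length_range[1] >= 3, length_range[1] <= length_range[2],
            inherits(profile, "codon_profile"))
  structure(
    list(n_genes = as.integer(n_genes),
         length_range = as.integer(length_range),
         aa_freq = aa_freq, profile = profile, seed = seed, prefix = prefix),
    class = "simulation_config"
  )
}

#' Generate a synthetic CDS set
#'
#' Each gene is framed as ATG + body + one stop codon (drawn uniformly from
#' TAA/TAG/TGA); body amino acids are i.i.d. from `aa_freq` and codons from
#' the profile. With the default length range every emitted record passes
#' [screen_cds()] by construction. The same seed gives byte-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return A `cds_set` data frame.
#' @examples
#' recs <- generate_cds_set(simulation_config(n_genes = 2, seed = 1))
#' screen_cds(recs)$report$pass
#' @export
generate_cds_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  code <- genetic_code_table()
  aa_pool <- names(config$aa_freq)
  seqs <- character(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    len <- if (config$length_range[1] == config$length_range[2]) {
      config$length_range[1]
    } else {
      sample(seq.int(config$length_range[1], config$length_range[2]), 1L)
    }
    n_body <- len - 2L
    aas <- sample(aa_pool, n_body, replace = TRUE, prob = config$aa_freq)
    codons <- character(n_body)
    for (a in unique(aas)) {
      pos <- which(aas == a)
      p <- config$profile$prob[[a]]
      codons[pos] <- sample(names(p), length(pos), replace = TRUE, prob = p)
    }
    stop_codon <- sample(code$stop_codons, 1L)
    seqs[i] <- paste0("ATG", paste(codons, collapse = ""), stop_codon)
  }
  cds_set(sprintf("%s_%03d", config$prefix, seq_len(config$n_genes)), seqs)
}

#' Simulate a gene-family history on a species tree
#'
#' Starting from a single lineage at the species root, each species-tree
#' branch receives Poisson-distributed duplication and loss events
#' (`dup_rate`, `loss_rate` expected events per branch) applied in random
#' order: a duplication copies a uniformly chosen surviving lineage, a loss
#' removes one. Events drawn on a branch with no surviving lineages have no
#' effect and are not recorded. Histories with fewer than two surviving
#' genes are rejected and resampled (a one-gene family has no gene tree);
#' the rejection count is reported.
#'
#' @param species Rooted binary species tree (`phylo`).
#' @param dup_rate,loss_rate Expected events per branch (>= 0). The defaults
#'   (0.2 duplications, 0.1 losses) describe a family in the expansion
#'   regime, with duplications outnumbering losses.
#' @param seed Random seed.
#' @param max_tries Maximum resampling attempts before giving up.
#' @return Object of class `family_history`: list with `species_tree`,
#'   `gene_tree` (`phylo`), `mapping` (gene leaf -> species), `events`
#'   (data frame: `branch`, `duplications`, `losses` -- realized events per
#'   species branch), `counts` (data frame: `node`, `count` -- lineages
#'   surviving at each species node), `genes_per_species` (named integer)
#'   and `rejected` (number of resampled extinct/singleton histories).
#' @examples
#' sp <- read_newick("((A,B),C);")
#' h <- generate_family_history(sp, dup_rate = 0.3, loss_rate = 0.1, seed = 1)
#' reconcile(h$gene_tree, h$species_tree, h$mapping)
#' @export
generate_family_history <- function(species, dup_rate = 0.2, loss_rate = 0.1,
                                    seed = NULL, max_tries = 100L) {
  validate_tree(species, "species tree")
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  sp <- .tree_index(species)
  rejected <- 0L
  for (try in seq_len(max_tries)) {
    h <- .simulate_history_once(species, sp, dup_rate, loss_rate)
    if (!is.null(h)) {
      h$rejected <- rejected
      return(h)
    }
    rejected <- rejected + 1L
  }
  stop("family died out (or left < 2 genes) in all ", max_tries,
       " attempts; lower loss_rate")
}

.simulate_history_once <- function(species, sp, dup_rate, loss_rate) {
  children <- vector("list", 0)
  labels <- character(0)
  new_node <- function() {
    children[[length(children) + 1L]] <<- integer(0)
    labels[length(labels) + 1L] <<- NA_character_
    length(children)
  }
  dup_real <- integer(sp$n_all)
  loss_real <- integer(sp$n_all)
  counts <- integer(sp$n_all)
  active_at <- vector("list", sp$n_all)
  root_l <- new_node()
  active_at[[sp$root]] <- root_l
  counts[sp$root] <- 1L
  leaf_counter <- stats::setNames(integer(sp$n_tip), species$tip.label)
  pre <- order(sp$depth, seq_len(sp$n_all))
  for (v in pre) {
    if (v <= sp$n_tip) {
      # label surviving lineages as sampled genes of this species
      for (x in active_at[[v]]) {
        leaf_counter[v] <- leaf_counter[v] + 1L
        labels[x] <- paste0(species$tip.label[v], "_g", leaf_counter[v])
      }
      next
    }
    # speciation: every lineage at v branches into both children
    branch_start <- lapply(sp$children[[v]], function(c) integer(0))
    names(branch_start) <- as.character(sp$children[[v]])
    for (x in active_at[[v]]) {
      kids <- c(new_node(), new_node())
      children[[x]] <- kids
      for (j in seq_along(sp$children[[v]])) {
        cb <- as.character(sp$children[[v]][j])
        branch_start[[cb]] <- c(branch_start[[cb]], kids[j])
      }
    }
    for (c in sp$children[[v]]) {
      act <- branch_start[[as.character(c)]]
      n_d <- stats::rpois(1L, dup_rate)
      n_l <- stats::rpois(1L, loss_rate)
      ev <- sample(rep(c("D", "L"), c(n_d, n_l)))
      for (e in ev) {
        if (length(act) == 0L) next # event with no lineage to act on
        pick <- act[sample.int(length(act), 1L)]
        if (e == "D") {
          kids <- c(new_node(), new_node())
          children[[pick]] <- kids
          act <- c(act[act != pick], kids)
          dup_real[c] <- dup_real[c] + 1L
        } else {
          act <- act[act != pick]
          loss_real[c] <- loss_real[c] + 1L
        }
      }
      active_at[[c]] <- act
      counts[c] <- length(act)
    }
  }
  if (sum(leaf_counter) < 2L) return(NULL)
  # prune extinct lineages / suppress unary nodes, emit Newick
  render <- function(id) {
    kids <- children[[id]]
    if (length(kids) == 0L) {
      if (is.na(labels[id])) return(NULL) # extinct, unlabelled
      return(labels[id])
    }
    parts <- Filter(Negate(is.null), lapply(kids, render))
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) return(parts[[1L]])
    paste0("(", parts[[1L]], ",", parts[[2L]], ")")
  }
  nwk <- render(root_l)
  if (is.null(nwk) || !grepl(",", nwk)) return(NULL)
  gene_tree <- read_newick(paste0(nwk, ";"))
  mapping <- stats::setNames(sub("_g[0-9]+$", "", gene_tree$tip.label),
                             gene_tree$tip.label)
  structure(
    list(
      species_tree = species,
      gene_tree = gene_tree,
      mapping = mapping,
      events = data.frame(branch = sp$label, duplications = dup_real,
                          losses = loss_real,
                          is_root = seq_len(sp$n_all) == sp$root,
                          stringsAsFactors = FALSE),
      counts = data.frame(node = sp$label, count = counts,
                          stringsAsFactors = FALSE),
      genes_per_species = leaf_counter,
      rejected = 0L
    ),
    class = "family_history"
  )
}

#' @export
print.family_history <- function(x, ...) {
  cat("family_history:", sum(x$genes_per_species), "genes in",
      sum(x$genes_per_species > 0), "species;",
      sum(x$events$duplications), "duplications,",
      sum(x$events$losses), "losses\n")
  invisible(x)
}
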
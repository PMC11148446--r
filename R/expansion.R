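# Parsimony duplication-loss reconciliation of a rooted binary gene tree
# against a rooted binary species tree (LCA mapping, unit costs). Produces
# per-gene-node event labels, per-species-branch duplication/loss tallies
# ("d:l" pairs) and ancestral family sizes at every species-tree node.

#' Read and validate a rooted binary Newick tree
#'
#' Accepts a Newick string (must contain parentheses or end with `;`) or a
#' file path. Branch lengths are accepted and ignored downstream.
#' Multifurcations, unrooted trees and duplicate leaf labels are rejected
#' with a clear message.
#'
#' @param x Newick text or a path to a Newick file.
#' @return An `ape` `phylo` object, rooted and binary.
#' @examples
#' read_newick("((A,B),C);")
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_text <- grepl("[();]", x)
  tree <- tryCatch(
    if (is_text) ape::read.tree(text = x) else ape::read.tree(x),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("Newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected exactly one tree")
    tree <- tree[[1L]]
  }
  validate_tree(tree)
  tree
}

validate_tree <- function(tree, what = "tree") {
  if (!inherits(tree, "phylo")) stop(what, " is not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop(what, " has duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  tab <- tabulate(tree$edge[, 1], nbins = max(tree$edge))
  multi <- which(tab > 2L)
  if (length(multi) > 0L) {
    stop(what, " has a multifurcation at internal node ", multi[1L],
         " (", tab[multi[1L]], " children); a rooted binary tree is required")
  }
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  invisible(tree)
}

# Parent/children/depth index of a rooted binary phylo.
.tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  parent <- integer(n_all)
  children <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- n_tip + 1L
  depth <- integer(n_all)
  # preorder by increasing depth
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[1L]; stack <- stack[-1L]
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      stack <- c(stack, c)
    }
  }
  # clade tips, for labelling internal nodes without node.label
  clade <- vector("list", n_all)
  for (v in seq_len(n_tip)) clade[[v]] <- tree$tip.label[v]
  post <- rev(order(depth, seq_len(n_all)))
  for (v in post) {
    if (v > n_tip) {
      clade[[v]] <- sort(unlist(lapply(children[[v]], function(c) clade[[c]])))
    }
  }
  label <- character(n_all)
  label[seq_len(n_tip)] <- tree$tip.label
  for (v in seq.int(n_tip + 1L, n_all)) {
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - n_tip] else ""
    label[v] <- if (!is.na(lab) && nzchar(lab)) lab
                else paste(clade[[v]], collapse = "+")
  }
  list(n_tip = n_tip, n_all = n_all, root = root, parent = parent,
       children = children, depth = depth, label = label)
}

# LCA in a rooted tree via parent pointers.
.lca <- function(idx, u, v) {
  while (u != v) {
    if (idx$depth[u] < idx$depth[v]) v <- idx$parent[v] else u <- idx$parent[u]
  }
  u
}

.sibling <- function(idx, v) {
  setdiff(idx$children[[idx$parent[v]]], v)
}

#' Map gene ids to species by identifier prefix
#'
#' Convenience for gene ids that carry the species label as a prefix
#' (longest match wins).
#'
#' @param gene_ids Character vector of gene-tree leaf labels.
#' @param species_labels Character vector of species-tree leaf labels.
#' @return Named character vector (gene id -> species label).
#' @examples
#' map_by_prefix(c("Si_1", "Os_1"), c("Si", "Os"))
#' @export
map_by_prefix <- function(gene_ids, species_labels) {
  out <- vapply(gene_ids, function(g) {
    hits <- species_labels[startsWith(g, species_labels)]
    if (length(hits) == 0L) {
      stop("no species label is a prefix of gene id '", g, "'")
    }
    hits[which.max(nchar(hits))]
  }, character(1))
  stats::setNames(out, gene_ids)
}

#' Reconcile a gene tree with a species tree (duplication-loss parsimony)
#'
#' Standard LCA-mapping reconciliation with unit costs: every gene-tree
#' node maps to the species-tree LCA of its children's images; a node is a
#' duplication iff it maps to the same species node as at least one child;
#' each gene edge implies one loss per species-tree edge it skips (plus one
#' when the parent is a duplication). Duplications are attributed to the
#' species-tree branch ending at the mapped node; each loss to the branch of
#' the species lineage in which the gene lineage disappeared. A single
#' ancestral gene is assumed at the species root, so losses are also charged
#' along the path from the species root to the gene-tree root's image.
#'
#' @param gene Rooted binary gene tree (`phylo`, see [read_newick()]).
#' @param species Rooted binary species tree (`phylo`).
#' @param mapping Named character vector, gene leaf label -> species leaf
#'   label. Default maps by identifier prefix ([map_by_prefix()]).
#' @return Object of class `reconciliation`: list with
#'   \describe{
#'     \item{events}{data frame, one row per internal gene node: `gene_node`
#'       (clade label), `event` (`"speciation"`/`"duplication"`), `species`
#'       (mapped species node label).}
#'     \item{branches}{data frame, one row per species node: `branch`,
#'       `duplications`, `losses`, `dl` (the `"d:l"` pair), `count`
#'       (ancestral family size at the node), `is_root`, `is_tip`.}
#'     \item{total_duplications, total_losses, root_count}{scalars; the root
#'       count is the family size after stem duplications above the species
#'       root.}
#'   }
#' @examples
#' sp <- read_newick("(A,B);")
#' gt <- read_newick("((A_1,A_2),B_1);")
#' reconcile(gt, sp) # one duplication on A's terminal branch
#' @export
reconcile <- function(gene, species,
                      mapping = map_by_prefix(gene$tip.label,
                                              species$tip.label)) {
  validate_tree(gene, "gene tree")
  validate_tree(species, "species tree")
  if (!all(gene$tip.label %in% names(mapping))) {
    stop("mapping missing for gene leaves: ",
         paste(setdiff(gene$tip.label, names(mapping)), collapse = ", "))
  }
  bad <- setdiff(unname(mapping[gene$tip.label]), species$tip.label)
  if (length(bad) > 0L) {
    stop("gene leaves map to unknown species: ", paste(bad, collapse = ", "))
  }
  sp <- .tree_index(species)
  gt <- .tree_index(gene)

  # LCA mapping M, gene postorder
  M <- integer(gt$n_all)
  is_dup <- logical(gt$n_all)
  post <- order(gt$depth, seq_len(gt$n_all), decreasing = TRUE)
  for (v in post) {
    if (v <= gt$n_tip) {
      M[v] <- match(mapping[[gene$tip.label[v]]], species$tip.label)
    } else {
      kids <- gt$children[[v]]
      M[v] <- .lca(sp, M[kids[1]], M[kids[2]])
      is_dup[v] <- any(M[kids] == M[v])
    }
  }

  dup_br <- integer(sp$n_all)
  loss_br <- integer(sp$n_all)
  # losses on a gene edge mapping from species node `from` down to `to`:
  # one at the sibling of every node on the path strictly below `from`,
  # except the first path node when the parent event is a speciation
  charge_losses <- function(from, to, parent_is_dup) {
    chain <- integer(0)
    p <- to
    while (p != from) {
      chain <- c(chain, p)
      p <- sp$parent[p]
    }
    # chain = s_m, ..., s_1 (top of path is last)
    if (!parent_is_dup && length(chain) > 0L) {
      chain <- chain[-length(chain)]
    }
    for (x in chain) {
      s <- .sibling(sp, x)
      loss_br[s] <<- loss_br[s] + 1L
    }
  }
  for (v in seq_len(gt$n_all)) {
    if (v > gt$n_tip) dup_br[M[v]] <- dup_br[M[v]] + as.integer(is_dup[v])
  }
  for (v in seq_len(gt$n_all)) {
    if (v <= gt$n_tip) next
    for (c in gt$children[[v]]) {
      charge_losses(M[v], M[c], is_dup[v])
    }
  }
  # origin: one ancestral gene entering at the species root
  charge_losses(sp$root, M[gt$root], parent_is_dup = TRUE)

  # ancestral counts by the conservation identity, preorder
  count <- integer(sp$n_all)
  count[sp$root] <- 1L + dup_br[sp$root]
  pre <- order(sp$depth, seq_len(sp$n_all))
  for (v in pre) {
    if (v == sp$root) next
    count[v] <- count[sp$parent[v]] + dup_br[v] - loss_br[v]
  }

  events <- data.frame(
    gene_node = gt$label[seq.int(gt$n_tip + 1L, gt$n_all)],
    event = ifelse(is_dup[seq.int(gt$n_tip + 1L, gt$n_all)],
                   "duplication", "speciation"),
    species = sp$label[M[seq.int(gt$n_tip + 1L, gt$n_all)]],
    stringsAsFactors = FALSE
  )
  branches <- data.frame(
    branch = sp$label,
    duplications = dup_br,
    losses = loss_br,
    dl = sprintf("%d:%d", dup_br, loss_br),
    count = count,
    is_root = seq_len(sp$n_all) == sp$root,
    is_tip = seq_len(sp$n_all) <= sp$n_tip,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      events = events,
      branches = branches,
      total_duplications = sum(dup_br),
      total_losses = sum(loss_br),
      root_count = count[sp$root],
      species_tree = species,
      gene_tree = gene,
      mapping = mapping
    ),
    class = "reconciliation"
  )
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation:", x$total_duplications, "duplications,",
      x$total_losses, "losses; root family size", x$root_count, "\n")
  invisible(x)
}

#' Branch-annotated family expansion summary
#'
#' @param rec A `reconciliation` from [reconcile()].
#' @return List with `table` (the per-branch data frame plus a `status`
#'   column: `"expansion"` when duplications exceed losses, `"contraction"`
#'   when losses exceed duplications, else `"stable"`) and `newick` (the
#'   species tree with every node relabelled `label_d<dup>_l<loss>_n<count>`).
#' @export
expansion_report <- function(rec) {
  stopifnot(inherits(rec, "reconciliation"))
  tab <- rec$branches
  tab$status <- ifelse(tab$duplications > tab$losses, "expansion",
                       ifelse(tab$losses > tab$duplications,
                              "contraction", "stable"))
  sp <- .tree_index(rec$species_tree)
  ann <- function(v) {
    base <- gsub("[^A-Za-z0-9.+-]", "_", sp$label[v])
    sprintf("%s_d%d_l%d_n%d", base, tab$duplications[v], tab$losses[v],
            tab$count[v])
  }
  render <- function(v) {
    if (v <= sp$n_tip) return(ann(v))
    kids <- sp$children[[v]]
    paste0("(", render(kids[1]), ",", render(kids[2]), ")", ann(v))
  }
  list(table = tab, newick = paste0(render(sp$root), ";"))
}

#' Write reconciliation outputs
#'
#' Writes the per-branch events TSV (`branch, duplications, losses, dl,
#' count, status`), the ancestral-counts TSV (`node, count`) and the
#' annotated Newick.
#'
#' @param rec A `reconciliation`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_reconciliation <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- expansion_report(rec)
  events_path <- file.path(dir, "events.tsv")
  counts_path <- file.path(dir, "ancestral_counts.tsv")
  nwk_path <- file.path(dir, "annotated.nwk")
  utils::write.table(rep$table[, c("branch", "duplications", "losses",
                                   "dl", "count", "status")],
                     events_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(rep$table[, c("branch", "count")], counts_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("node", "count"))
  writeLines(rep$newick, nwk_path)
  invisible(c(events = events_path, counts = counts_path, newick = nwk_path))
}
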
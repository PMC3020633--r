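## Gene-tree / species-tree reconciliation by minimum deep coalescence.
##
## The statistic is purely topological: for every species-tree edge --
## identified with the species cluster C below it -- k(C) is the number of
## maximal gene-tree clades whose tips map entirely into C, and the edge
## contributes max(0, k(C) - 1) extra lineages.  Tip edges are included,
## so multiple alleles of one species count.  Branch lengths are ignored;
## polytomies in either tree are treated as hard.

# accept a named character vector or a two-column table
as_taxon_map <- function(map) {
  if (is.data.frame(map)) {
    if (!all(c("tip_label", "deme") %in% names(map)))
      abort("taxon map table needs columns 'tip_label' and 'deme'")
    map <- setNames(as.character(map$deme), as.character(map$tip_label))
  }
  if (is.null(names(map)) || any(names(map) == ""))
    abort("taxon map must be named by tip label")
  if (anyDuplicated(names(map)))
    abort("duplicate tip label in taxon map")
  map
}

# cluster matrix of a rooted species tree: one row per node except the
# root (i.e. one per edge), columns ordered by `species`
species_cluster_matrix <- function(species_tree, species = NULL) {
  if (!ape::is.rooted(species_tree))
    abort("species tree must be rooted")
  if (is.null(species)) species <- species_tree$tip.label
  n <- length(species_tree$tip.label)
  root <- n + 1L
  n_nodes <- n + species_tree$Nnode
  m <- matrix(FALSE, n_nodes, length(species),
              dimnames = list(NULL, species))
  sp_idx <- match(species_tree$tip.label, species)
  if (anyNA(sp_idx)) abort("species tree tips missing from species set")
  m[cbind(seq_len(n), sp_idx)] <- TRUE
  po <- ape::reorder.phylo(species_tree, "postorder")
  for (i in seq_len(nrow(po$edge)))
    m[po$edge[i, 1], ] <- m[po$edge[i, 1], ] | m[po$edge[i, 2], ]
  m[-root, , drop = FALSE]
}

# phylo -> parent array (0-based, -1 at root) for the C++ counter
phylo_parent <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  parent <- rep(-1L, n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1] - 1L
  parent
}

#' Minimum number of deep coalescences
#'
#' Fits a rooted gene tree (multiple alleles per species allowed, species
#' may be missing) into a rooted species tree and returns the minimum
#' number of extra lineages over all valid coalescent histories.
#'
#' @param gene_tree rooted `phylo`; polytomies allowed.
#' @param species_tree rooted `phylo` over species (deme) names; branch
#'   lengths ignored; polytomies allowed.
#' @param map taxon map: named character vector `tip_label -> deme`, or a
#'   tibble with columns `tip_label`, `deme`.
#' @param assume_rooted treat the tree as rooted as written even when its
#'   root is a polytomy (which `ape` flags as unrooted).  Collapsed
#'   consensus trees legitimately carry hard root polytomies; a genuinely
#'   unrooted tree should instead be rooted with [root_with_outgroup()].
#' @return non-negative integer.
#' @export
count_deep_coalescences <- function(gene_tree, species_tree, map,
                                    assume_rooted = FALSE) {
  map <- as_taxon_map(map)
  if (!inherits(gene_tree, "phylo")) abort("gene_tree must be a phylo")
  if (is.null(gene_tree$tip.label) || !length(gene_tree$tip.label))
    abort("gene tree has no tip labels")
  if (!assume_rooted && !ape::is.rooted(gene_tree))
    abort("gene tree must be rooted")
  species <- species_tree$tip.label
  deme <- map[gene_tree$tip.label]
  if (anyNA(deme))
    abort(paste("gene-tree tips missing from taxon map:",
                paste(setdiff(gene_tree$tip.label, names(map)),
                      collapse = ", ")))
  sp <- match(deme, species)
  if (anyNA(sp))
    abort(paste("mapped demes absent from species tree:",
                paste(setdiff(deme, species), collapse = ", ")))
  clusters <- species_cluster_matrix(species_tree, species)
  .dc_count_cpp(phylo_parent(gene_tree), length(gene_tree$tip.label),
                sp - 1L, clusters)
}

#' Brute-force deep-coalescence oracle
#'
#' Exhaustively enumerates every valid assignment of gene-tree
#' coalescences to species-tree branches (each coalescence placed at or
#' above the LCA of its descendants' species, never above its parent's
#' placement), counts the extra lineages of each history directly, and
#' returns the minimum.  Exponential in gene-tree size; intended as an
#' independent check of [count_deep_coalescences()] on small instances.
#'
#' @inheritParams count_deep_coalescences
#' @param max_tips refuse instances larger than this (default 8).
#' @return non-negative integer.
#' @export
brute_force_deep_coalescences <- function(gene_tree, species_tree, map,
                                          max_tips = 8) {
  map <- as_taxon_map(map)
  n <- length(gene_tree$tip.label)
  if (n > max_tips) abort("instance too large for the brute-force oracle")
  if (!ape::is.rooted(gene_tree)) abort("gene tree must be rooted")

  ns <- length(species_tree$tip.label)
  s_nodes <- ns + species_tree$Nnode
  s_root <- ns + 1L
  s_parent <- rep(NA_integer_, s_nodes)
  s_parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  anc_path <- lapply(seq_len(s_nodes), function(v) {
    path <- v
    while (!is.na(s_parent[v])) { v <- s_parent[v]; path <- c(path, v) }
    path
  })

  deme <- map[gene_tree$tip.label]
  tip_pop <- match(deme, species_tree$tip.label)
  if (anyNA(tip_pop)) abort("unmapped tip label or deme not in species tree")

  g_nodes <- n + gene_tree$Nnode
  g_parent <- rep(NA_integer_, g_nodes)
  g_parent[gene_tree$edge[, 2]] <- gene_tree$edge[, 1]

  # species LCA below each gene node: ascend via shared ancestor paths
  lca2 <- function(u, v) {
    common <- intersect(anc_path[[u]], anc_path[[v]])
    common[1]
  }
  po <- ape::reorder.phylo(gene_tree, "postorder")
  g_lca <- rep(NA_integer_, g_nodes)
  g_lca[seq_len(n)] <- tip_pop
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    g_lca[p] <- if (is.na(g_lca[p])) g_lca[ch] else lca2(g_lca[p], g_lca[ch])
  }

  internal <- (n + 1L):g_nodes
  allowed <- lapply(internal, function(v) anc_path[[g_lca[v]]])
  grid <- expand.grid(allowed, KEEP.OUT.ATTRS = FALSE)

  non_root_g <- which(!is.na(g_parent))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    pop <- c(tip_pop, as.integer(grid[r, ]))
    ok <- TRUE
    exits <- integer(s_nodes)
    for (v in non_root_g) {
      path <- anc_path[[pop[v]]]
      stop_at <- match(pop[g_parent[v]], path)
      if (is.na(stop_at)) { ok <- FALSE; break }   # non-monotone placement
      if (stop_at > 1) {
        seg <- path[seq_len(stop_at - 1L)]
        exits[seg] <- exits[seg] + 1L
      }
    }
    if (!ok) next
    cnt <- sum(pmax(0L, exits[-s_root] - 1L))
    if (cnt < best) best <- cnt
    if (best == 0) break
  }
  as.integer(best)
}

## ---- I/O --------------------------------------------------------------

#' Read gene trees from newick
#'
#' Accepts one or more newick trees per file (one per line or separated
#' by semicolons); quoted labels are supported by the underlying parser.
#' @param path newick file.
#' @return list of `phylo`.
#' @export
read_gene_trees <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) abort(paste("could not parse newick in", path))
  if (inherits(trees, "phylo")) trees <- list(trees)
  unclass(trees)
}

#' Read / write a taxon map
#'
#' Two-column TSV `tip_label <TAB> deme`; a header line naming the two
#' columns is accepted and written.
#' @param path TSV file.
#' @return named character vector `tip_label -> deme`.
#' @export
read_taxon_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character",
                         col.names = c("tip_label", "deme"))
  if (nrow(x) && identical(unlist(x[1, ], use.names = FALSE),
                           c("tip_label", "deme")))
    x <- x[-1, , drop = FALSE]
  if (anyDuplicated(x$tip_label))
    abort("duplicate tip label in taxon map file")
  setNames(x$deme, x$tip_label)
}

#' @rdname read_taxon_map
#' @param map named character vector or `tip_label`/`deme` table.
#' @export
write_taxon_map <- function(map, path) {
  map <- as_taxon_map(map)
  utils::write.table(
    data.frame(tip_label = names(map), deme = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup tips from the rest.
#' @param tree a `phylo`.
#' @param outgroup character vector of outgroup tip labels.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    abort(paste("outgroup tips absent from tree:",
                paste(missing, collapse = ", ")))
  out <- tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                  error = function(e)
                    abort(paste("outgroup not separable:",
                                conditionMessage(e))))
  out
}
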
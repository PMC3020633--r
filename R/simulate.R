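## Gene-tree simulation under a scaled demographic model.
##
## All randomness flows through R's RNG (Mersenne-Twister via set.seed),
## so a seed fully determines the output.  Per-locus substreams are
## derived from a replicate seed by locus index with a small LCG step, so
## loci can be regenerated independently.

# deterministic substream derivation; stays inside 32-bit integer range
seed_stream <- function(seed, k) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(k) * 12347
  as.integer(x %% m)
}

# flatten a scaled model for the C++ core: name -> 0-based index
scaled_model_args <- function(scaled) {
  demes <- scaled$demes$name
  idx <- function(x) match(x, demes) - 1L
  list(n_demes = length(demes),
       deme_size = scaled$demes$rel_size,
       split_time = scaled$splits$time,
       split_derived = idx(scaled$splits$derived),
       split_ancestral = idx(scaled$splits$ancestral),
       mig_start = scaled$migrations$start,
       mig_end = scaled$migrations$end,
       mig_from = idx(scaled$migrations$from),
       mig_to = idx(scaled$migrations$to),
       mig_rate = scaled$migrations$rate,
       demes = demes)
}

# counts: named vector over demes -> full count vector in model deme order
full_counts <- function(counts, scaled) {
  out <- setNames(integer(length(scaled$demes$name)), scaled$demes$name)
  bad <- setdiff(names(counts), scaled$contemporary)
  if (length(bad))
    abort(paste("samples requested in non-contemporary demes:",
                paste(bad, collapse = ", ")))
  out[names(counts)] <- as.integer(counts)
  out
}

# raw simulated tree: parent/time arrays straight from the core
sim_raw <- function(scaled, counts, args = scaled_model_args(scaled)) {
  cnt <- full_counts(counts, scaled)
  if (sum(cnt) < 2) abort("at least 2 total samples are required")
  res <- .sim_tree_cpp(args$n_demes, args$deme_size,
                       args$split_time, args$split_derived,
                       args$split_ancestral,
                       args$mig_start, args$mig_end,
                       args$mig_from, args$mig_to, args$mig_rate,
                       unname(cnt))
  res$deme_names <- args$demes
  res
}

# raw -> ape phylo with tip labels "deme|i" and ultrametric branch lengths
raw_to_phylo <- function(raw, units = c("coalescent", "years"),
                         scaled = NULL) {
  units <- match.arg(units)
  n <- raw$n_tips
  n_nodes <- 2L * n - 1L
  tm <- raw$node_time
  if (units == "years") {
    if (is.null(scaled)) abort("units = 'years' needs the scaled model")
    tm <- tm * 4 * scaled$reference_size / scaled$gens_per_year
  }
  # internal node j (0-based, increasing time) -> ape id; root gets n+1
  ape_id <- integer(n_nodes)
  ape_id[seq_len(n)] <- seq_len(n)
  ape_id[(n + 1):n_nodes] <- (2L * n - 1L):(n + 1L)
  parent <- raw$parent + 1L
  child <- which(parent > 0L)             # all but the root
  edge <- cbind(ape_id[parent[child]], ape_id[child])
  elen <- tm[parent[child]] - tm[child]
  deme <- raw$deme_names[raw$tip_deme + 1L]
  allele <- stats::ave(seq_along(deme), deme, FUN = seq_along)
  tr <- structure(list(edge = edge,
                       edge.length = elen,
                       tip.label = paste0(deme, "|", allele),
                       Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate one gene tree under a scaled demographic model
#'
#' Runs the event-driven structured coalescent: within each deme of
#' relative size x, each lineage pair coalesces at rate 2/x per scaled
#' time unit (units of 4 * reference_size generations); lineages migrate
#' backward along active migration phases at their scaled per-lineage
#' rates; at each split time all lineages of the derived deme transfer to
#' the ancestral deme.  Simulation ends at the grand MRCA.
#'
#' @param scaled a `scaled_demographic_model` (see [to_coalescent_scale()]),
#'   or a `demographic_model` which is scaled first.
#' @param counts named integer vector: samples per contemporary deme.
#' @param seed optional integer; when given, `set.seed(seed)` is applied
#'   so the tree is reproducible.
#' @param units branch-length units of the returned tree: `"coalescent"`
#'   (default) or `"years"`.
#' @return rooted ultrametric `phylo`; tips labeled `deme|allele`.
#' @export
simulate_gene_tree <- function(scaled, counts, seed = NULL,
                               units = c("coalescent", "years")) {
  if (inherits(scaled, "demographic_model"))
    scaled <- to_coalescent_scale(scaled)
  if (!is.null(seed)) set.seed(seed)
  raw <- sim_raw(scaled, counts)
  raw_to_phylo(raw, units = units, scaled = scaled)
}

#' Simulate a multi-locus replicate
#'
#' One independent gene tree per locus of the sampling scheme, each with
#' that locus's per-deme sample counts; demes with zero samples are absent
#' from that locus's tree.  Per-locus seeds are derived from `seed` by
#' locus index, so the same seed always yields the same eight trees.
#'
#' @param model a `demographic_model` or `scaled_demographic_model`.
#' @param sampling sampling-scheme tibble (see [limenitis_sampling()]).
#' @param seed optional integer replicate seed.
#' @inheritParams simulate_gene_tree
#' @return named list of `phylo`, one per locus.
#' @export
simulate_replicate <- function(model, sampling = limenitis_sampling(),
                               seed = NULL,
                               units = c("coalescent", "years")) {
  scaled <- if (inherits(model, "demographic_model"))
    to_coalescent_scale(model) else model
  validate_sampling(sampling)
  raws <- simulate_replicate_raw(scaled, sampling, seed)
  lapply(raws, raw_to_phylo, units = match.arg(units), scaled = scaled)
}

# fast path used by the bootstrap: returns raw structures, no phylo
simulate_replicate_raw <- function(scaled, sampling, seed = NULL,
                                   args = scaled_model_args(scaled)) {
  deme_cols <- setdiff(names(sampling), "locus")
  out <- vector("list", nrow(sampling))
  names(out) <- sampling$locus
  for (i in seq_len(nrow(sampling))) {
    counts <- unlist(sampling[i, deme_cols])
    counts <- counts[counts > 0]
    if (sum(counts) < 2)
      abort(paste0("locus '", sampling$locus[i],
                   "' has fewer than 2 total samples"))
    if (!is.null(seed)) set.seed(seed_stream(seed, i))
    out[[i]] <- sim_raw(scaled, counts, args)
  }
  out
}

#' Mean pairwise cross-deme coalescence diagnostics
#'
#' For two focal demes, the fraction of gene-tree coalescences joining a
#' clade containing only deme-A tips with one containing only deme-B tips
#' that occur more recently than a reference time.  Used to verify that
#' stronger migration moves cross-deme coalescences below the species
#' split.
#'
#' @param raws list of raw simulated trees (internal structure).
#' @param deme_a,deme_b focal deme names.
#' @param before scaled time threshold.
#' @keywords internal
cross_coal_fraction <- function(raws, deme_a, deme_b, before) {
  frac_one <- function(raw) {
    n <- raw$n_tips
    n_nodes <- 2L * n - 1L
    a <- integer(n_nodes); b <- integer(n_nodes); tot <- integer(n_nodes)
    deme <- raw$deme_names[raw$tip_deme + 1L]
    a[seq_len(n)] <- as.integer(deme == deme_a)
    b[seq_len(n)] <- as.integer(deme == deme_b)
    tot[seq_len(n)] <- 1L
    parent <- raw$parent + 1L
    for (v in seq_len(n_nodes)) {         # children precede parents
      p <- parent[v]
      if (p > 0) { a[p] <- a[p] + a[v]; b[p] <- b[p] + b[v]
                   tot[p] <- tot[p] + tot[v] }
    }
    # internal node joins two clades; cross if one is pure-A, other pure-B
    cross <- logical(n_nodes); early <- logical(n_nodes)
    for (v in which(parent > 0)) {
      p <- parent[v]
      # sibling totals via parent minus child (binary trees)
      sa <- a[p] - a[v]; sb <- b[p] - b[v]; st <- tot[p] - tot[v]
      pureA_v <- a[v] == tot[v] && a[v] > 0
      pureB_v <- b[v] == tot[v] && b[v] > 0
      pureA_s <- sa == st && sa > 0
      pureB_s <- sb == st && sb > 0
      if ((pureA_v && pureB_s) || (pureB_v && pureA_s)) {
        cross[p] <- TRUE
        early[p] <- raw$node_time[p] < before
      }
    }
    if (!any(cross)) return(NA_real_)
    sum(early[cross]) / sum(cross)
  }
  mean(vapply(raws, frac_one, numeric(1)), na.rm = TRUE)
}

#' Write gene trees to a multi-tree newick file
#'
#' One tree per line, tip labels `deme|allele_index`.
#' @param trees list of `phylo` (or a single `phylo`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, ape::write.tree, character(1))
  writeLines(txt, path)
  invisible(path)
}
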
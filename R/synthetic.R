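## Pseudo-observed data sets: one simulated replicate written in exactly
## the observed-data input format (per-locus newick + taxon-map TSV), so
## the whole pipeline is exercisable without any external data.  The
## generator reuses the simulator; independence for validation comes from
## the brute-force reconciliation oracle and the closed-form coalescent
## checks.

# tiny 32-bit FNV-1a over a character scalar; stable provenance
# fingerprint.  Arithmetic in doubles, xor on 16-bit halves (bitwXor is
# limited to values below 2^31).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    hi <- h %/% 65536; lo <- h %% 65536
    h <- bitwXor(hi, b %/% 65536) * 65536 + bitwXor(lo, b %% 65536)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((lo * p) %% 4294967296 + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

model_fingerprint <- function(model) {
  fnv1a_hash(paste(
    model$model_id, model$hypothesis, model$reference_size,
    paste(model$demes$name, model$demes$size, model$demes$gens_per_year,
          collapse = ";"),
    paste(model$splits$time_years, model$splits$derived,
          model$splits$ancestral, collapse = ";"),
    paste(model$migrations$start_years, model$migrations$end_years,
          model$migrations$source, model$migrations$dest,
          model$migrations$rate_migrants_per_gen, collapse = ";"),
    sep = "|"))
}

#' Generate a pseudo-observed data set
#'
#' Simulates one multi-locus replicate under a demographic model and
#' writes it in the observed-data input format: one newick file per locus
#' (tips `deme|allele`), a two-column taxon-map TSV, and a JSON manifest
#' recording provenance.  The same `(model, seed)` always regenerates
#' byte-identical files.
#'
#' @param model a `demographic_model`, or the id of a builtin model.
#' @param sampling sampling-scheme tibble.
#' @param seed integer seed.
#' @param dir output directory, created if needed.
#' @return object of class `pseudo_observed_set`: file paths plus the
#'   manifest, invisibly usable with [read_gene_trees()] /
#'   [read_taxon_map()].
#' @export
generate_pseudo_observed <- function(model, sampling = limenitis_sampling(),
                                     seed, dir) {
  if (is.character(model)) model <- limenitis_model(model)
  validate_sampling(sampling, model)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste("cannot create directory", dir))

  trees <- simulate_replicate(model, sampling, seed = seed)
  tree_files <- file.path(dir, paste0(names(trees), ".nwk"))
  for (i in seq_along(trees)) write_gene_trees(trees[[i]], tree_files[i])

  labels <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  map <- setNames(sub("\\|.*$", "", labels), labels)
  map_file <- file.path(dir, "taxon_map.tsv")
  write_taxon_map(map, map_file)

  manifest <- list(
    generator = "dcboot::generate_pseudo_observed",
    package_version = as.character(utils::packageVersion("dcboot")),
    model_id = model$model_id,
    hypothesis = model$hypothesis,
    model_fingerprint = model_fingerprint(model),
    seed = seed,
    loci = as.list(setNames(lapply(trees, function(t)
      length(t$tip.label)), names(trees))),
    synthetic = TRUE)
  manifest_file <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)

  structure(list(dir = dir,
                 tree_files = setNames(tree_files, names(trees)),
                 map_file = map_file,
                 manifest_file = manifest_file,
                 manifest = manifest),
            class = "pseudo_observed_set")
}

#' @export
print.pseudo_observed_set <- function(x, ...) {
  cat("<pseudo_observed_set> model ", x$manifest$model_id,
      ", seed ", x$manifest$seed, "\n", sep = "")
  cat("  dir:", x$dir, "\n")
  cat("  loci:", paste(names(x$tree_files), collapse = ", "), "\n")
  invisible(x)
}

#' Read a pseudo-observed set back as gene trees + map
#'
#' @param x a `pseudo_observed_set` or a directory written by
#'   [generate_pseudo_observed()].
#' @return list with elements `gene_trees` (list of `phylo`) and `map`.
#' @export
read_pseudo_observed <- function(x) {
  dir <- if (inherits(x, "pseudo_observed_set")) x$dir else x
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  files <- file.path(dir, paste0(names(manifest$loci), ".nwk"))
  trees <- lapply(files, function(f) read_gene_trees(f)[[1]])
  names(trees) <- names(manifest$loci)
  list(gene_trees = trees,
       map = read_taxon_map(file.path(dir, "taxon_map.tsv")),
       manifest = manifest)
}

#' Collapse short branches into polytomies
#'
#' Emulates the loss of resolution of consensus trees: the given fraction
#' of the shortest internal branches is collapsed (`ceiling(fraction *
#' n_internal_edges)` of them).  Exact-length ties are broken by seeded
#' random permutation when `seed` is given, otherwise by edge index.
#'
#' @param tree a `phylo` with branch lengths.
#' @param collapse_fraction fraction in `[0, 1]` of internal branches to
#'   collapse.
#' @param seed optional integer for tie-breaking.
#' @return a `phylo`, possibly with polytomies.
#' @export
degrade_to_consensus <- function(tree, collapse_fraction, seed = NULL) {
  stopifnot(collapse_fraction >= 0, collapse_fraction <= 1)
  if (collapse_fraction == 0) return(tree)
  if (is.null(tree$edge.length))
    abort("degrade_to_consensus needs branch lengths")
  n <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > n)
  if (!length(internal)) return(tree)
  k <- ceiling(collapse_fraction * length(internal))
  if (!is.null(seed)) set.seed(seed)
  tiebreak <- if (is.null(seed)) seq_along(internal)
              else sample(seq_along(internal))
  sel <- internal[order(tree$edge.length[internal], tiebreak)[seq_len(k)]]
  tree$edge.length[sel] <- -1          # sentinel: guaranteed below tol
  out <- ape::di2multi(tree, tol = 0)
  out$edge.length[out$edge.length < 0] <- 0   # safety: none should remain
  out
}
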
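# shared fixtures: tiny demographic models and tree helpers, all built in
# code at test time

rt <- function(x) ape::read.tree(text = x)

sp3 <- function() rt("((A,B),C);")
sp4_ladder <- function() rt("(((A,B),C),D);")
sp4_balanced <- function() rt("((A,B),(C,D));")

# map tip labels like "a1", "b2" to species "A", "B", ...
auto_map <- function(tree) {
  labs <- tree$tip.label
  setNames(toupper(substr(labs, 1, 1)), labs)
}

# single panmictic deme, reference size = deme size
single_deme_model <- function(size = 1e6) {
  demographic_model(
    "one", "custom",
    demes = tibble::tibble(name = "A", size = size, gens_per_year = 1),
    splits = tibble::tibble(time_years = double(), derived = character(),
                            ancestral = character()),
    reference_size = size)
}

# two demes joining at `tau` scaled units, optional migration phase
two_deme_model <- function(tau = 0.3, mig_rate = 0, mig_end = 0.1) {
  size <- 1e6
  unit_years <- 4 * size            # 1 generation per year
  migrations <- if (mig_rate > 0) {
    tibble::tibble(start_years = 0, end_years = mig_end * unit_years,
                   source = "A", dest = "B",
                   rate_migrants_per_gen = mig_rate)
  } else NULL
  args <- list(
    model_id = "two", hypothesis = "custom",
    demes = tibble::tibble(name = c("A", "B", "AB"), size = size,
                           gens_per_year = 1),
    splits = tibble::tibble(time_years = rep(tau * unit_years, 2),
                            derived = c("A", "B"),
                            ancestral = c("AB", "AB")),
    reference_size = size)
  if (!is.null(migrations)) args$migrations <- migrations
  do.call(demographic_model, args)
}

# small three-deme sampling scheme for fast bootstrap tests
tiny_sampling <- function() {
  tibble::tibble(locus = c("L1", "L2"),
                 arthemis = c(3, 4), astyanax = c(3, 2),
                 arizonensis = c(2, 2))
}

# random reconciliation instance: rooted binary gene tree over n tips
# mapped uniformly onto the species of a given species tree
random_instance <- function(n_tips, species_tree) {
  sp <- species_tree$tip.label
  labs <- paste0(tolower(sample(sp, n_tips, replace = TRUE)), seq_len(n_tips))
  g <- ape::rtree(n_tips, tip.label = labs)
  list(gene = g, species = species_tree,
       map = setNames(toupper(substr(labs, 1, 1)), labs))
}
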
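#' @useDynLib dcboot, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
"_PACKAGE"

#' The six contemporary Limenitis lineages
#'
#' Deme labels used throughout the builtin models and sampling scheme, in
#' the column order of the sampling table.
#' @export
limenitis_lineages <- c("archippus", "arizonensis", "arthemis", "astyanax",
                        "lorquini", "weidemeyerii")

#' Construct a demographic model
#'
#' A demographic model is a set of demes (each with a diploid effective
#' size and a number of generations per year), a list of population splits
#' (backward in time, all lineages of the derived deme join the ancestral
#' deme at the split time), and a list of migration phases (forward-time
#' direction, expected migrants per generation, active over a half-open
#' interval of years before present).
#'
#' @param model_id label for the model.
#' @param hypothesis short label for the species-tree hypothesis the model
#'   embodies (e.g. `"MM"`, `"R"`, or `"custom"`).
#' @param demes tibble with columns `name`, `size` (diploid individuals),
#'   `gens_per_year`.
#' @param splits tibble with columns `time_years`, `derived`, `ancestral`.
#' @param migrations tibble with columns `start_years`, `end_years`,
#'   `source`, `dest` (forward-time direction of movement),
#'   `rate_migrants_per_gen`; may have zero rows.
#' @param reference_size diploid size used for coalescent scaling.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(model_id, hypothesis, demes, splits,
                              migrations = empty_migrations(),
                              reference_size) {
  m <- structure(
    list(model_id = model_id,
         hypothesis = hypothesis,
         demes = as_tibble(demes),
         splits = dplyr::arrange(as_tibble(splits), .data$time_years),
         migrations = as_tibble(migrations),
         reference_size = reference_size),
    class = "demographic_model")
  validate_demographic_model(m)
  m
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> ", x$model_id,
      " (hypothesis ", x$hypothesis, ")\n", sep = "")
  cat("  demes:      ", nrow(x$demes),
      " (", sum(!x$demes$name %in% x$splits$ancestral), " contemporary)\n",
      sep = "")
  cat("  splits:     ", nrow(x$splits), "\n", sep = "")
  cat("  migrations: ", nrow(x$migrations), "\n", sep = "")
  cat("  reference_size: ", format(x$reference_size, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

empty_migrations <- function() {
  tibble(start_years = double(), end_years = double(),
         source = character(), dest = character(),
         rate_migrants_per_gen = double())
}

#' Contemporary (tip) demes of a model
#'
#' Demes not created by any split, i.e. those extant at the present and
#' available for sampling.
#' @param model a `demographic_model`.
#' @return character vector of deme names.
#' @export
contemporary_demes <- function(model) {
  setdiff(model$demes$name, model$splits$ancestral)
}

#' Validate a demographic model
#'
#' Checks the structural invariants: positive sizes and generation counts,
#' unique deme names, split times positive and forming a single rooted
#' history (every deme except one root is eventually absorbed), migration
#' intervals well-formed with both demes extant throughout.
#'
#' @param model a `demographic_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_demographic_model <- function(model) {
  d <- model$demes
  if (anyDuplicated(d$name)) abort("deme names must be unique")
  if (any(d$size <= 0)) abort("deme effective sizes must be positive")
  if (any(d$gens_per_year <= 0)) abort("generations per year must be positive")
  if (model$reference_size <= 0) abort("reference_size must be positive")

  s <- model$splits
  if (any(s$time_years <= 0)) abort("split times must be positive")
  unknown <- setdiff(c(s$derived, s$ancestral), d$name)
  if (length(unknown))
    abort(paste("splits reference unknown demes:",
                paste(unknown, collapse = ", ")))
  if (anyDuplicated(s$derived))
    abort("a deme may be absorbed by at most one split")
  # exactly one root: one deme never derived
  roots <- setdiff(d$name, s$derived)
  if (length(roots) != 1)
    abort(paste("model must have exactly one root deme; found",
                length(roots)))
  # every ancestral deme must exist by the time it receives lineages:
  # its own absorption (if any) must be later than all splits feeding it
  for (i in seq_len(nrow(s))) {
    anc <- s$ancestral[i]
    j <- which(s$derived == anc)
    if (length(j) && s$time_years[j] < s$time_years[i])
      abort(paste0("deme '", anc, "' is absorbed at ", s$time_years[j],
                   " years but receives lineages at ", s$time_years[i]))
  }
  # derived demes must not receive lineages after their own absorption
  m <- model$migrations
  if (nrow(m)) {
    if (any(m$rate_migrants_per_gen < 0)) abort("migration rates must be >= 0")
    if (any(m$start_years < 0) || any(m$start_years >= m$end_years))
      abort("migration intervals must satisfy 0 <= start < end")
    if (any(m$source == m$dest)) abort("migration source and dest must differ")
    unknown <- setdiff(c(m$source, m$dest), d$name)
    if (length(unknown))
      abort(paste("migrations reference unknown demes:",
                  paste(unknown, collapse = ", ")))
    end_time <- setNames(rep(Inf, nrow(d)), d$name)
    end_time[s$derived] <- s$time_years
    bad <- m$end_years > pmin(end_time[m$source], end_time[m$dest])
    if (any(bad))
      abort("migration phase extends past the lifetime of one of its demes")
  }
  invisible(model)
}

## ---- builtin Limenitis suite -----------------------------------------

# Table of split times (years) for the fifteen builtin models.  T1 is the
# younger ingroup divergence (astyanax/arizonensis under MM,
# arthemis/astyanax under R); T2 is the older one joining the third
# arthemis-complex lineage.
limenitis_model_table <- function() {
  tibble(
    model_id  = c(paste0("MM", 1:12), paste0("R", 1:3)),
    hypothesis = c(rep("MM", 12), rep("R", 3)),
    migration = c(rep("moderate", 6), rep("high", 6), rep("moderate", 3)),
    T1 = c(117500, 211500, 327500, 589500, 537000, 966600,
           117500, 211500, 327500, 589500, 537000, 966600,
           235000, 655000, 1075000),
    T2 = c(235000, 235000, 655000, 655000, 1075000, 1075000,
           235000, 235000, 655000, 655000, 1075000, 1075000,
           1095000, 1095000, 1095000))
}

# migration tiers: expected migrants per generation, forward-time
# astyanax -> arthemis and arthemis -> astyanax, active since the
# postglacial onset of hybridization
limenitis_migration_rates <- list(
  moderate = c(astyanax_to_arthemis = 3.2,  arthemis_to_astyanax = 0.14),
  high     = c(astyanax_to_arthemis = 17.71, arthemis_to_astyanax = 15.53))

limenitis_hybridization_start <- 12000  # years before present

#' Default outgroup divergence times
#'
#' Successive joins of the outgroup species onto the arthemis-complex stem,
#' outgroup-ward: L. lorquini, then L. weidemeyerii, then L. archippus.
#' These divergences are shared by all builtin models and are older than
#' every ingroup divergence; they are exposed as configuration because
#' absolute deep-coalescence counts are sensitive to them.
#' @export
default_outgroup_times <- c(lorquini = 1.5e6, weidemeyerii = 2.5e6,
                            archippus = 3.5e6)

#' Build one Limenitis demographic model
#'
#' @param model_id one of MM1--MM12, R1--R3.
#' @param outgroup_times named vector of join times (years) for
#'   `lorquini`, `weidemeyerii`, `archippus`, in increasing order of age.
#' @param lineage_size diploid effective size of each contemporary lineage.
#' @param stem_size diploid effective size of the arthemis-complex
#'   ancestral stem (from the older ingroup split back to the lorquini
#'   join).
#' @param gens_per_year generations per year, shared by all demes.
#' @param migration_unit how the published migration-rate values are
#'   interpreted.  `"scaled_4Nm"` (default): the values are already
#'   coalescent-scaled rates in the `ms` convention (`4*N0*m`), so the
#'   stored migrants-per-generation field is `value * N_dest / (4 *
#'   N_ref)`; this is the reading under which the simulated distributions
#'   reproduce the published per-model means.  `"migrants_per_gen"`: the
#'   values are expected migrant individuals per generation (`N*m`) and
#'   are stored as-is.
#' @return a `demographic_model`.
#' @export
limenitis_model <- function(model_id,
                            outgroup_times = default_outgroup_times,
                            lineage_size = 2.5e6,
                            stem_size = 3.5e5,
                            gens_per_year = 2,
                            migration_unit = c("scaled_4Nm",
                                               "migrants_per_gen")) {
  migration_unit <- match.arg(migration_unit)
  tab <- limenitis_model_table()
  row <- tab[tab$model_id == model_id, ]
  if (nrow(row) != 1)
    abort(paste0("unknown builtin model '", model_id, "'"))
  stopifnot(all(c("lorquini", "weidemeyerii", "archippus") %in%
                  names(outgroup_times)))
  og <- outgroup_times[c("lorquini", "weidemeyerii", "archippus")]
  if (any(og <= row$T2) || is.unsorted(og, strictly = TRUE))
    abort("outgroup times must be strictly increasing and older than T2")

  anc <- c("anc_pair", "arthemis_stem", "anc_lorquini", "anc_weidemeyerii",
           "root")
  demes <- tibble(
    name = c(limenitis_lineages, anc),
    size = c(rep(lineage_size, 6),
             lineage_size,          # ancestor of the T1 pair
             stem_size,             # arthemis-complex stem
             rep(lineage_size, 3)),
    gens_per_year = gens_per_year)

  pair <- if (row$hypothesis == "MM") c("astyanax", "arizonensis")
          else c("arthemis", "astyanax")
  third <- setdiff(c("arthemis", "astyanax", "arizonensis"), pair)
  splits <- tibble(
    time_years = c(row$T1, row$T1, row$T2, row$T2,
                   og[["lorquini"]], og[["lorquini"]],
                   og[["weidemeyerii"]], og[["weidemeyerii"]],
                   og[["archippus"]], og[["archippus"]]),
    derived   = c(pair[1], pair[2], "anc_pair", third,
                  "arthemis_stem", "lorquini",
                  "anc_lorquini", "weidemeyerii",
                  "anc_weidemeyerii", "archippus"),
    ancestral = c("anc_pair", "anc_pair", "arthemis_stem", "arthemis_stem",
                  "anc_lorquini", "anc_lorquini",
                  "anc_weidemeyerii", "anc_weidemeyerii",
                  "root", "root"))

  r <- limenitis_migration_rates[[row$migration]]
  rate <- c(r[["astyanax_to_arthemis"]], r[["arthemis_to_astyanax"]])
  if (migration_unit == "scaled_4Nm") {
    # published values are ms-style 4*N0*m; store as migrants/generation
    # so the simulator's backward scaling recovers the published rate
    rate <- rate * lineage_size / (4 * lineage_size)
  }
  migrations <- tibble(
    start_years = 0,
    end_years = limenitis_hybridization_start,
    source = c("astyanax", "arthemis"),
    dest   = c("arthemis", "astyanax"),
    rate_migrants_per_gen = rate)

  demographic_model(model_id = model_id, hypothesis = row$hypothesis,
                    demes = demes, splits = splits, migrations = migrations,
                    reference_size = lineage_size)
}

#' The fifteen builtin Limenitis models
#'
#' Twelve monophyletic-mimic models (MM1--MM12: astyanax and arizonensis
#' sister; MM1--MM6 moderate migration, MM7--MM12 high migration) and
#' three reversion models (R1--R3: arthemis and astyanax sister, moderate
#' migration), each defined by its two ingroup divergence times.
#'
#' @inheritParams limenitis_model
#' @return named list of 15 `demographic_model` objects.
#' @export
limenitis_models <- function(outgroup_times = default_outgroup_times,
                             lineage_size = 2.5e6,
                             stem_size = 3.5e5,
                             gens_per_year = 2,
                             migration_unit = c("scaled_4Nm",
                                                "migrants_per_gen")) {
  migration_unit <- match.arg(migration_unit)
  ids <- limenitis_model_table()$model_id
  setNames(lapply(ids, limenitis_model, outgroup_times = outgroup_times,
                  lineage_size = lineage_size, stem_size = stem_size,
                  gens_per_year = gens_per_year,
                  migration_unit = migration_unit),
           ids)
}

#' Per-locus, per-lineage sample counts of the Limenitis data set
#'
#' The sampling scheme of the eight nuclear loci: four protein-coding
#' (EF1a, wg, kettin, Ldh) and four anonymous (Anon06, Anon10, Anon15,
#' Anon17), with the number of sampled alleles per lineage.
#'
#' @return tibble with a `locus` column and one count column per lineage.
#' @export
limenitis_sampling <- function() {
  tibble(
    locus        = c("Anon06", "Anon10", "Anon15", "Anon17",
                     "EF1a", "kettin", "Ldh", "wg"),
    archippus    = c(1, 1, 1, 0, 22, 1, 1, 7),
    arizonensis  = c(2, 2, 1, 2, 12, 4, 3, 2),
    arthemis     = c(11, 11, 11, 13, 14, 11, 11, 16),
    astyanax     = c(7, 8, 9, 8, 16, 9, 9, 4),
    lorquini     = c(1, 1, 0, 1, 17, 1, 1, 1),
    weidemeyerii = c(1, 1, 1, 1, 15, 1, 1, 4))
}

#' Validate a sampling scheme against a model
#' @param sampling tibble as returned by [limenitis_sampling()].
#' @param model optional `demographic_model`; when given, count columns
#'   must be contemporary demes of the model.
#' @return the sampling tibble, invisibly.
#' @export
validate_sampling <- function(sampling, model = NULL) {
  if (!"locus" %in% names(sampling)) abort("sampling needs a 'locus' column")
  if (anyDuplicated(sampling$locus)) abort("locus names must be unique")
  counts <- as.matrix(sampling[setdiff(names(sampling), "locus")])
  if (any(counts < 0) || any(counts != round(counts)))
    abort("sample counts must be non-negative integers")
  if (!any(rowSums(counts) >= 2))
    abort("at least one locus needs >= 2 total samples")
  if (!is.null(model)) {
    extra <- setdiff(colnames(counts), contemporary_demes(model))
    if (length(extra))
      abort(paste("sampling includes non-contemporary demes:",
                  paste(extra, collapse = ", ")))
  }
  invisible(sampling)
}

## ---- coalescent scaling ----------------------------------------------

#' Convert a demographic model to coalescent scale
#'
#' Times are re-expressed in units of `4 * reference_size` generations,
#' deme sizes as ratios to the reference size, and forward-time migration
#' (M migrants per generation from `source` into `dest`) as the backward
#' per-lineage rate experienced by a lineage sampled in `dest`:
#' `4 * reference_size * M / N_dest` per scaled time unit.  All demes must
#' share one `gens_per_year`.
#'
#' @param model a `demographic_model`.
#' @return an object of class `scaled_demographic_model`.
#' @export
to_coalescent_scale <- function(model) {
  validate_demographic_model(model)
  g <- unique(model$demes$gens_per_year)
  if (length(g) != 1)
    abort("all demes must share one generations-per-year value")
  N0 <- model$reference_size
  if (N0 <= 0) abort("reference_size must be positive")
  unit_gens <- 4 * N0
  sizes <- setNames(model$demes$size, model$demes$name)

  splits <- model$splits |>
    mutate(time = .data$time_years * g / unit_gens) |>
    select("time", "derived", "ancestral")

  migrations <- model$migrations |>
    mutate(start = .data$start_years * g / unit_gens,
           end = .data$end_years * g / unit_gens,
           # backward in time a lineage in `dest` jumps to `source`
           from = .data$dest, to = .data$source,
           rate = unname(unit_gens * .data$rate_migrants_per_gen /
                           sizes[.data$dest])) |>
    select("start", "end", "from", "to", "rate")

  structure(
    list(model_id = model$model_id,
         hypothesis = model$hypothesis,
         demes = tibble(name = model$demes$name,
                        rel_size = model$demes$size / N0),
         splits = splits,
         migrations = migrations,
         contemporary = contemporary_demes(model),
         gens_per_year = g,
         reference_size = N0),
    class = "scaled_demographic_model")
}

#' Invert coalescent scaling
#'
#' Recovers the natural-unit `demographic_model` from a scaled one.
#' @param scaled a `scaled_demographic_model`.
#' @return a `demographic_model`.
#' @export
from_coalescent_scale <- function(scaled) {
  N0 <- scaled$reference_size
  g <- scaled$gens_per_year
  unit_gens <- 4 * N0
  sizes <- setNames(scaled$demes$rel_size * N0, scaled$demes$name)
  demographic_model(
    model_id = scaled$model_id,
    hypothesis = scaled$hypothesis,
    demes = tibble(name = scaled$demes$name, size = unname(sizes),
                   gens_per_year = g),
    splits = tibble(time_years = scaled$splits$time * unit_gens / g,
                    derived = scaled$splits$derived,
                    ancestral = scaled$splits$ancestral),
    migrations = tibble(
      start_years = scaled$migrations$start * unit_gens / g,
      end_years = scaled$migrations$end * unit_gens / g,
      source = scaled$migrations$to,
      dest = scaled$migrations$from,
      rate_migrants_per_gen = unname(scaled$migrations$rate *
        sizes[scaled$migrations$from] / unit_gens)),
    reference_size = N0)
}

## ---- config serialization --------------------------------------------

#' Write / read a demographic model configuration
#'
#' Models serialize to YAML or JSON with their demes, splits, migration
#' phases and reference size, so a full parameterization can be archived
#' alongside results or supplied by users.
#'
#' @param model a `demographic_model`.
#' @param path output file; extension `.yml`/`.yaml` or `.json` selects
#'   the format.
#' @return `path`, invisibly (write) or a `demographic_model` (read).
#' @export
write_model_config <- function(model, path) {
  x <- list(model_id = model$model_id,
            hypothesis = model$hypothesis,
            reference_size = model$reference_size,
            demes = lapply(seq_len(nrow(model$demes)), function(i)
              as.list(model$demes[i, ])),
            splits = lapply(seq_len(nrow(model$splits)), function(i)
              as.list(model$splits[i, ])),
            migrations = lapply(seq_len(nrow(model$migrations)), function(i)
              as.list(model$migrations[i, ])))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
       else yaml::read_yaml(path)
  bind_rows2 <- function(lst) dplyr::bind_rows(lapply(lst, as_tibble))
  mig <- if (length(x$migrations)) bind_rows2(x$migrations)
         else empty_migrations()
  demographic_model(model_id = x$model_id, hypothesis = x$hypothesis,
                    demes = bind_rows2(x$demes),
                    splits = bind_rows2(x$splits),
                    migrations = mig,
                    reference_size = x$reference_size)
}

#' Export the builtin parameter tables as TSV
#'
#' Writes the sampling table (per-locus, per-lineage counts) and the model
#' table (model, hypothesis, migration tier, T1, T2) to `dir`.
#' @param dir output directory, created if needed.
#' @return paths of the two files, invisibly.
#' @export
export_builtin_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "sampling_scheme.tsv")
  p2 <- file.path(dir, "model_parameters.tsv")
  utils::write.table(limenitis_sampling(), p1, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(limenitis_model_table(), p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(sampling = p1, models = p2))
}
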
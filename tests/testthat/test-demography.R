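test_that("the builtin suite has the published structure and times", {
  models <- limenitis_models()
  expect_length(models, 15)
  expect_named(models, c(paste0("MM", 1:12), paste0("R", 1:3)))

  tab <- dcboot:::limenitis_model_table()
  expect_true(all(tab$T1 < tab$T2))

  # spot checks against the published parameter table
  t1 <- function(m) min(m$splits$time_years)
  t2 <- function(m) sort(unique(m$splits$time_years))[2]
  expect_equal(t1(models$MM1), 117500)
  expect_equal(t2(models$MM1), 235000)
  expect_equal(t1(models$MM7), 117500)
  expect_equal(t2(models$MM7), 235000)
  expect_equal(t1(models$R2), 655000)
  expect_equal(t2(models$R2), 1095000)

  for (m in models) {
    expect_silent(validate_demographic_model(m))
    expect_setequal(contemporary_demes(m), limenitis_lineages)
    expect_equal(m$demes$size[m$demes$name == "arthemis_stem"], 3.5e5)
    expect_true(all(m$demes$size[m$demes$name %in% limenitis_lineages] ==
                      2.5e6))
    expect_true(all(m$demes$gens_per_year == 2))
  }

  # migration tiers: MM7-12 high, everything else moderate; the builtin
  # default reads the published values as ms-scaled 4Nm rates
  scaled_rates <- function(m) sort(to_coalescent_scale(m)$migrations$rate)
  expect_equal(scaled_rates(models$MM1), c(0.14, 3.2))
  expect_equal(scaled_rates(models$R3), c(0.14, 3.2))
  expect_equal(scaled_rates(models$MM7), c(15.53, 17.71))
  expect_equal(scaled_rates(models$MM12), c(15.53, 17.71))

  # under the literal migrants-per-generation reading the same numbers
  # appear in the natural-unit field instead
  m_nat <- limenitis_model("MM1", migration_unit = "migrants_per_gen")
  expect_setequal(m_nat$migrations$rate_migrants_per_gen, c(3.2, 0.14))
  expect_equal(sort(to_coalescent_scale(m_nat)$migrations$rate),
               c(0.56, 12.8))
})

test_that("MM and R models differ only in the arthemis-complex history", {
  mm <- limenitis_model("MM1")
  r <- limenitis_model("R1")
  expect_identical(mm$demes, r$demes)
  expect_identical(mm$migrations, r$migrations)
  outgroup <- function(m)
    m$splits[m$splits$time_years > 1.4e6, c("derived", "ancestral")]
  expect_identical(outgroup(mm), outgroup(r))
  # ingroup sister pair differs
  pair_members <- function(m)
    sort(m$splits$derived[m$splits$ancestral == "anc_pair"])
  expect_equal(pair_members(mm), c("arizonensis", "astyanax"))
  expect_equal(pair_members(r), c("arthemis", "astyanax"))
})

test_that("the sampling scheme matches the published counts", {
  s <- limenitis_sampling()
  expect_equal(nrow(s), 8)
  ef1a <- s[s$locus == "EF1a", ]
  expect_equal(unlist(ef1a[limenitis_lineages], use.names = FALSE),
               c(22, 12, 14, 16, 17, 15))
  expect_equal(sum(ef1a[limenitis_lineages]), 96)
  expect_equal(s$lorquini[s$locus == "Anon15"], 0)
  expect_equal(s$archippus[s$locus == "Anon17"], 0)
  expect_silent(validate_sampling(s, limenitis_model("MM1")))

  bad <- s; bad$arthemis[1] <- -1
  expect_error(validate_sampling(bad), "non-negative")
  dup <- s; dup$locus[2] <- dup$locus[1]
  expect_error(validate_sampling(dup), "unique")
})

test_that("coalescent scaling follows the ms conventions", {
  m <- demographic_model(
    "toy", "custom",
    demes = tibble::tibble(name = c("X", "Y", "XY"), size = 2.5e6,
                           gens_per_year = 2),
    splits = tibble::tibble(time_years = c(235000, 235000),
                            derived = c("X", "Y"),
                            ancestral = c("XY", "XY")),
    migrations = tibble::tibble(start_years = 0, end_years = 12000,
                                source = "X", dest = "Y",
                                rate_migrants_per_gen = 3.2),
    reference_size = 2.5e6)
  s <- to_coalescent_scale(m)
  expect_equal(s$splits$time, c(0.047, 0.047))
  expect_equal(s$migrations$rate, 12.8)       # 4 * Nref * M / N_dest
  expect_equal(s$migrations$start, 0)         # zero maps to zero
  expect_equal(s$migrations$end, 12000 * 2 / 1e7)
  expect_equal(s$demes$rel_size, rep(1, 3))
})

test_that("scaling round-trips every builtin model", {
  for (m in limenitis_models()) {
    back <- from_coalescent_scale(to_coalescent_scale(m))
    expect_equal(back$splits$time_years, m$splits$time_years,
                 tolerance = 1e-12)
    expect_equal(back$migrations$rate_migrants_per_gen,
                 m$migrations$rate_migrants_per_gen, tolerance = 1e-12)
    expect_equal(back$demes$size, m$demes$size, tolerance = 1e-12)
  }
})

test_that("model validation rejects malformed histories", {
  demes <- tibble::tibble(name = c("A", "B", "AB"), size = 1e5,
                          gens_per_year = 1)
  splits <- tibble::tibble(time_years = c(10000, 10000),
                           derived = c("A", "B"),
                           ancestral = c("AB", "AB"))
  ok <- demographic_model("ok", "custom", demes, splits,
                          reference_size = 1e5)
  expect_s3_class(ok, "demographic_model")

  expect_error(demographic_model("bad", "custom",
    dplyr::mutate(demes, name = c("A", "A", "AB")), splits,
    reference_size = 1e5), "unique")
  expect_error(demographic_model("bad", "custom",
    dplyr::mutate(demes, size = c(-1, 1e5, 1e5)), splits,
    reference_size = 1e5), "positive")
  expect_error(demographic_model("bad", "custom", demes,
    splits[1, ], reference_size = 1e5), "root")
  # migration within the demes' lifetimes is fine; outliving one is not
  expect_no_error(demographic_model("ok2", "custom", demes, splits,
    migrations = tibble::tibble(start_years = 0, end_years = 5000,
                                source = "A", dest = "B",
                                rate_migrants_per_gen = 1),
    reference_size = 1e5))
  expect_error(demographic_model("bad", "custom", demes, splits,
    migrations = tibble::tibble(start_years = 0, end_years = 20000,
                                source = "A", dest = "B",
                                rate_migrants_per_gen = 1),
    reference_size = 1e5), "lifetime")
})

test_that("model configs round-trip through YAML and JSON", {
  m <- limenitis_model("R2")
  for (ext in c(".yml", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_model_config(m, p)
    back <- read_model_config(p)
    expect_equal(back$splits, m$splits)
    expect_equal(back$migrations, m$migrations)
    expect_equal(back$demes, m$demes)
    expect_equal(back$reference_size, m$reference_size)
  }
})

test_that("builtin tables export in the published layout", {
  d <- withr::local_tempdir()
  paths <- export_builtin_tables(d)
  s <- utils::read.table(paths[["sampling"]], sep = "\t", header = TRUE)
  expect_equal(dim(s), c(8, 7))
  tab <- utils::read.table(paths[["models"]], sep = "\t", header = TRUE)
  expect_equal(nrow(tab), 15)
  expect_true(all(c("model_id", "T1", "T2") %in% names(tab)))
})
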
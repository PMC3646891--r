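# MS1 precursor search: adduct arithmetic, tolerance matching, filters.

test_that("adduct arithmetic converts m/z to neutral mass and back", {
  expect_equal(neutral_mass_from_mz(760.5851, "[M+H]+"), 759.5778,
               tolerance = 1e-3)
  expect_equal(neutral_mass_from_mz(758.5705, "[M-H]-"), 759.5778,
               tolerance = 1e-3)
  expect_identical(neutral_mass_from_mz(500, "neutral"), 500)
  set.seed(3)
  for (a in default_adducts()$name) {
    m <- stats::runif(5, 300, 900)
    expect_equal(neutral_mass_from_mz(mz_from_neutral_mass(m, a), a), m,
                 tolerance = 1e-9, label = a)
  }
  expect_error(neutral_mass_from_mz(500, "[M+X]+"), "available")
  adt <- default_adducts()
  expect_identical(adt$charge[adt$name == "neutral"], 0L)
  expect_identical(adt$mass_delta[adt$name == "neutral"], 0)
  expect_true(all(abs(adt$charge[adt$name != "neutral"]) == 1L))
})

test_that("the worked precursor example resolves to its isobaric species", {
  hits05 <- ms1_search(759.58, tolerance = 0.05, adducts = "neutral")
  expect_true(all(c("PC 34:1", "PC O-35:1") %in% hits05$species_name))
  hits01 <- ms1_search(759.58, tolerance = 0.01, adducts = "neutral")
  expect_true("PC 34:1" %in% hits01$species_name)
  expect_false("PC O-35:1" %in% hits01$species_name)
  # category filter removes the PC hits
  filtered <- ms1_search(759.58, tolerance = 0.05, adducts = "neutral",
                         exclude = list(categories = "glycerophospholipids"))
  expect_false(any(grepl("^PC", filtered$species_name)))
  # empty query list is an empty result
  expect_identical(nrow(ms1_search(numeric(0), tolerance = 0.05,
                                   adducts = "neutral")), 0L)
})

test_that("input validation rejects degenerate searches", {
  expect_error(ms1_search(700, tolerance = 0, adducts = "neutral"), "positive")
  expect_error(ms1_search(700, tolerance = -1, adducts = "neutral"), "positive")
  expect_error(ms1_search(700, tolerance = 0.01, adducts = character(0)),
               "at least one")
  expect_error(parse_tolerance("fast"), "cannot parse")
  expect_identical(parse_tolerance("5ppm"), list(value = 5, mode = "ppm"))
  expect_identical(parse_tolerance("0.01 Da"), list(value = 0.01, mode = "da"))
})

test_that("hits equal a naive linear scan for random queries", {
  tbl <- species_table(default_subclasses, rules_c8)
  adducts <- c("[M+H]+", "[M-H]-", "neutral")
  adt <- default_adducts()
  set.seed(101)
  queries <- stats::runif(100, 200, 900)
  got <- ms1_search(queries, tolerance = 0.02, adducts = adducts,
                    species = tbl)
  # oracle: triple loop over (query, adduct, species)
  oracle <- character(0)
  for (q in queries) {
    for (a in adducts) {
      row <- adt[adt$name == a, ]
      neutral <- if (row$charge == 0L) q else abs(row$charge) * q - row$mass_delta
      sel <- abs(neutral - tbl$neutral_mass) <= 0.02
      if (any(sel)) oracle <- c(oracle, paste(q, a, tbl$name[sel]))
    }
  }
  expect_setequal(paste(got$query_mz, got$adduct, got$species_name), oracle)
})

test_that("widening tolerance, adding adducts or removing filters keeps hits", {
  tbl <- species_table(default_subclasses, rules_c8)
  set.seed(202)
  queries <- stats::runif(30, 300, 800)
  key <- function(h) paste(h$query_mz, h$adduct, h$species_name)
  narrow <- ms1_search(queries, tolerance = 0.01, adducts = "[M+H]+",
                       species = tbl)
  wide <- ms1_search(queries, tolerance = 0.05, adducts = "[M+H]+",
                     species = tbl)
  expect_true(all(key(narrow) %in% key(wide)))
  more_adducts <- ms1_search(queries, tolerance = 0.01,
                             adducts = c("[M+H]+", "[M+Na]+"), species = tbl)
  expect_true(all(key(narrow) %in% key(more_adducts)))
  filtered <- ms1_search(queries, tolerance = 0.01, adducts = "[M+H]+",
                         species = tbl,
                         exclude = list(main_classes = c("PE", "TG")))
  expect_true(all(key(filtered) %in% key(narrow)))
  expect_false(any(grepl("^PE |^TG ", filtered$species_name)))
})

test_that("Da and ppm tolerances admit the same boundary hit", {
  tbl <- species_table(default_subclasses, rules_c8)
  target <- tbl[tbl$name == "PC 16:1", ]
  t_da <- 0.02
  q <- target$neutral_mass + t_da * (1 - 1e-9)  # just inside the Da boundary
  hit_da <- ms1_search(q, tolerance = t_da, adducts = "neutral", species = tbl)
  t_ppm <- t_da / target$neutral_mass * 1e6
  hit_ppm <- ms1_search(q, tolerance = list(value = t_ppm, mode = "ppm"),
                        adducts = "neutral", species = tbl)
  expect_true("PC 16:1" %in% hit_da$species_name)
  expect_true("PC 16:1" %in% hit_ppm$species_name)
})

test_that("hits are grouped by query and sorted by absolute error then name", {
  h <- ms1_search(c(759.58, 495.33), tolerance = 0.05, adducts = "neutral")
  expect_identical(unique(h$query_mz), c(759.58, 495.33))
  for (q in unique(h$query_mz)) {
    block <- h[h$query_mz == q, ]
    expect_false(is.unsorted(abs(block$delta_mda)))
  }
  expect_identical(h$species_name[h$query_mz == 759.58][1], "PC 34:1")
})

test_that("mass lists are read with comments and blanks ignored", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# precursor masses", "759.58", "", "  495.33  ",
               "760.5851 # protonated"), path)
  expect_identical(read_mass_list(path), c(759.58, 495.33, 760.5851))
  writeLines(c("759.58", "oops"), path)
  expect_error(read_mass_list(path), "non-numeric")
})
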
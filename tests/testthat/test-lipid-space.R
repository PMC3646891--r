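# Sub-class construction, the four-level hierarchy, and combinatorial counts.

test_that("the Cartesian cross yields one sub-class per linkage multiset", {
  pc <- Filter(function(s) s$main_class == "PC" && s$slot_count == 2,
               default_subclasses)
  expect_length(pc, 3)  # {acyl,acyl}, {acyl,alkyl}, {alkyl,alkyl}
  expect_setequal(vapply(pc, function(s) sum(s$linkage == "alkyl"), integer(1)),
                  0:2)
  tg <- Filter(function(s) s$main_class == "TG", default_subclasses)
  expect_length(tg, 4)  # multisets of size 3 over two linkages
  mg <- Filter(function(s) s$main_class == "MG", default_subclasses)
  expect_length(mg, 2)
  expect_length(default_subclasses, 39)
  # collapsed naming: a single mixed sub-class, alkyl listed first
  mixed <- find_subclass(default_subclasses, "PC", n_alkyl = 1)
  expect_identical(mixed$display_name, "monoalkyl,monoacylglycerophosphocholines")
  expect_identical(mixed$linkage, c("alkyl", "acyl"))
  expect_error(lipid_subclass("XX", "acyl"), "unknown main-class")
  expect_error(lipid_subclass("PC", c("acyl", "acyl", "acyl")), "at most two")
})

test_that("species enumeration covers exactly the realizable totals", {
  sc <- find_subclass(default_subclasses, "PC")
  reduced <- enumerate_species(sc, chain_rules(max_carbons = 4))
  expect_identical(
    vapply(reduced, function(r) c(r$total_carbons, r$total_double_bonds),
           integer(2)),
    matrix(as.integer(c(4,0, 5,0, 5,1, 6,0, 6,1, 6,2, 7,0, 7,1, 7,2,
                        8,0, 8,1, 8,2)), nrow = 2))
  full <- record_names(enumerate_species(sc))
  expect_true("PC 34:1" %in% full)
  ether <- record_names(enumerate_species(
    find_subclass(default_subclasses, "PC", n_alkyl = 1)))
  expect_true("PC O-35:1" %in% ether)
})

test_that("species children are the chain multisets matching the totals", {
  kids <- record_names(species_children(parse_name("PC 34:1")))
  expect_true("PC 16:0_18:1" %in% kids)
  expect_identical(anyDuplicated(kids), 0L)
  # unique split under reduced rules
  r4 <- chain_rules(max_carbons = 4)
  cfg <- default_config()
  sp40 <- enumerate_species(find_subclass(default_subclasses, "PC"), r4)[[1]]
  expect_identical(sp40$name, "PC 4:0")
  expect_identical(record_names(species_children(sp40, r4)), "PC 2:0_2:0")
  # brute-force verified pair count for PC 8:2 at max_carbons = 4
  sp82 <- parse_name("PC 8:2")
  expect_identical(record_names(species_children(sp82, r4)),
                   c("PC 4:1_4:1"))
})

test_that("sn assignment respects collapsing and symmetric multisets", {
  expect_setequal(record_names(fas_children(parse_name("PC 16:0_18:1"))),
                  c("PC 16:0/18:1", "PC 18:1/16:0"))
  expect_identical(record_names(fas_children(parse_name("PC 16:0_16:0"))),
                   "PC 16:0/16:0")
  # mixed linkage: the alkyl chain is canonically at sn1
  expect_identical(record_names(fas_children(parse_name("PC O-16:0_18:1"))),
                   "PC O-16:0/18:1")
})

test_that("isomer children are the Cartesian product of position sets", {
  iso <- subspecies_children(parse_name("PC 18:1/16:0"))
  expect_length(iso, 16)
  expect_identical(iso[[1]]$name, "PC 18:1(2)/16:0")
  sat <- subspecies_children(parse_name("PC 16:0/18:0"))
  expect_length(sat, 1)
  expect_identical(sat[[1]]$name, "PC 16:0/18:0")
  tri <- record_names(subspecies_children(parse_name("PC 18:3/16:0")))
  expect_true("PC 18:3(9,12,15)/16:0" %in% tri)
})

test_that("parent inverts every children operation", {
  expect_identical(parent_record(parse_name("PC 18:1/16:0"))$name,
                   "PC 16:0_18:1")
  expect_identical(parent_record(parse_name("PC 16:0_18:1"))$name, "PC 34:1")
  expect_error(parent_record(parse_name("PC 34:1")), "no parent")
  set.seed(42)
  for (sc in default_subclasses[sample(seq_along(default_subclasses), 6)]) {
    for (sp in sample(enumerate_species(sc, rules_c6), 2)) {
      for (fas in species_children(sp, rules_c6)) {
        expect_identical(parent_record(fas)$name, sp$name)
        for (ss in fas_children(fas, rules_c6)) {
          expect_identical(parent_record(ss)$name, fas$name)
          for (iso in subspecies_children(ss, rules_c6)) {
            expect_identical(parent_record(iso)$name, ss$name)
          }
        }
      }
    }
  }
})

test_that("combinatorial counts equal enumeration lengths at every level", {
  cfg <- default_config()
  cases <- list(
    list(sc = find_subclass(default_subclasses, "PC"), rules = rules_c8),
    list(sc = find_subclass(default_subclasses, "PC", n_alkyl = 1), rules = rules_c8),
    list(sc = find_subclass(default_subclasses, "LPC"), rules = rules_c8),
    list(sc = find_subclass(default_subclasses, "MG"), rules = rules_c8),
    list(sc = find_subclass(default_subclasses, "DG", n_alkyl = 2), rules = rules_c6),
    list(sc = find_subclass(default_subclasses, "TG"), rules = rules_c6),
    list(sc = find_subclass(default_subclasses, "TG", n_alkyl = 1), rules = rules_c6),
    list(sc = find_subclass(default_subclasses, "PC"),
         rules = chain_rules(max_carbons = 10))
  )
  for (case in cases) {
    sc <- case$sc; rules <- case$rules
    sp <- enumerate_species(sc, rules)
    expect_equal(count_records(sc, "Species", rules), length(sp), label = sc$display_name)
    fas <- all_fas(sc, rules)
    expect_equal(count_records(sc, "FasSpecies", rules), length(fas),
                 label = sc$display_name)
    ss <- unlist(lapply(fas, fas_children, rules = rules), recursive = FALSE)
    expect_equal(count_records(sc, "SubSpecies", rules), length(ss),
                 label = sc$display_name)
    iso <- unlist(lapply(ss, subspecies_children, rules = rules),
                  recursive = FALSE)
    expect_equal(count_records(sc, "Isomer", rules), length(iso),
                 label = sc$display_name)
  }
})

test_that("diacyl sub-species count under defaults is the squared type count", {
  sc <- find_subclass(default_subclasses, "PC")
  expect_equal(count_records(sc, "SubSpecies"), 30276)  # 174^2
  # all-saturated sub-space: isomer count equals sub-species count
  rules_sat <- chain_rules(max_carbons = 8, max_double_bonds = 0)
  expect_equal(count_records(sc, "Isomer", rules_sat),
               count_records(sc, "SubSpecies", rules_sat))
})

test_that("children of distinct parents partition the next level", {
  for (sc in list(find_subclass(default_subclasses, "PC", n_alkyl = 1),
                  find_subclass(default_subclasses, "TG"))) {
    fas <- all_fas(sc, rules_c6)
    nm <- record_names(fas)
    expect_identical(anyDuplicated(nm), 0L)          # disjoint children
    expect_equal(length(fas), count_records(sc, "FasSpecies", rules_c6))
    ss_names <- record_names(unlist(lapply(fas, fas_children, rules = rules_c6),
                                    recursive = FALSE))
    expect_identical(anyDuplicated(ss_names), 0L)
  }
})

test_that("formula and mass are invariant down each descendant set", {
  for (sc in list(find_subclass(default_subclasses, "PC"),
                  find_subclass(default_subclasses, "DG", n_alkyl = 1))) {
    for (sp in enumerate_species(sc, rules_c6)) {
      for (fas in species_children(sp, rules_c6)) {
        expect_identical(fas$formula, sp$formula)
        for (ss in fas_children(fas, rules_c6)) {
          expect_identical(ss$formula, sp$formula)
          for (iso in subspecies_children(ss, rules_c6)) {
            expect_identical(iso$formula, sp$formula)
            expect_equal(iso$neutral_mass, sp$neutral_mass, tolerance = 1e-12)
          }
        }
      }
    }
  }
})

test_that("the flat species table agrees with record enumeration", {
  tbl <- species_table(default_subclasses, rules_c8)
  recs <- unlist(lapply(default_subclasses, enumerate_species, rules = rules_c8),
                 recursive = FALSE)
  expect_identical(nrow(tbl), length(recs))
  expect_setequal(tbl$name, record_names(recs))
  by_name <- stats::setNames(vapply(recs, function(r) r$neutral_mass, numeric(1)),
                             record_names(recs))
  expect_equal(tbl$neutral_mass, unname(by_name[tbl$name]), tolerance = 1e-12)
  by_formula <- stats::setNames(vapply(recs, function(r) formula_string(r$formula),
                                       character(1)), record_names(recs))
  expect_identical(tbl$formula, unname(by_formula[tbl$name]))
})
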
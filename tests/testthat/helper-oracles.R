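# Independent brute-force oracles and small shared fixtures.

# Brute-force double-bond position sets: filter every subset of the
# admissible positions by the spacing predicate. Independent of the
# recursive enumerator and of the closed-form count.
brute_force_db_sets <- function(carbons, n_db, rules = chain_rules()) {
  first <- rules$first_db_position
  last <- carbons - 1L - if (rules$allow_terminal_db) 0L else 1L
  if (n_db == 0L) return(list(integer(0)))
  if (last < first || n_db > (last - first + 1L)) return(list())
  pool <- seq.int(first, last)
  if (n_db > length(pool)) return(list())
  # combn(x, m) treats scalar x as seq_len(x); index the pool instead
  sets <- lapply(utils::combn(seq_along(pool), n_db, simplify = FALSE),
                 function(i) pool[i])
  ok <- vapply(sets, function(s) {
    if (length(s) > 1L) {
      gaps <- diff(s)
      if (any(gaps %% rules$db_position_step != 0L)) return(FALSE)
    }
    length(s) <= rules$max_double_bonds
  }, logical(1))
  sets[ok]
}

# full enumerations by walking the hierarchy (test-side convenience)
all_fas <- function(subclass, rules, config = default_config()) {
  unlist(lapply(enumerate_species(subclass, rules, config),
                species_children, rules = rules, config = config),
         recursive = FALSE)
}

all_subspecies <- function(subclass, rules, config = default_config()) {
  unlist(lapply(all_fas(subclass, rules, config),
                fas_children, rules = rules, config = config),
         recursive = FALSE)
}

all_isomers <- function(subclass, rules, config = default_config()) {
  unlist(lapply(all_subspecies(subclass, rules, config),
                subspecies_children, rules = rules, config = config),
         recursive = FALSE)
}

record_names <- function(records) {
  vapply(records, function(r) r$name, character(1))
}

# shared reduced spaces
rules_c6 <- chain_rules(max_carbons = 6)
rules_c8 <- chain_rules(max_carbons = 8)
default_subclasses <- build_subclasses()
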
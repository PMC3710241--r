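# Shared fixtures, built in code.

# Small handmade knowledge base exercising every predicate.
make_tiny_kb <- function() {
  knowledge_base(list(
    category = data.frame(
      drug = c("d1", "d2", "d3"),
      category = c("Serotonin Uptake Inhibitors", "Antacids", "Antacids")),
    drug_cluster = data.frame(
      drug = c("d1", "d2"), cluster = c("17_quinine", "2_estazolam"),
      source = c("hpcc", "hpcc")),
    drug_has_target = data.frame(
      drug = c("d1", "d1", "d2", "d3"),
      protein = c("p1", "p2", "p2", "p3"),
      action = c("inhibitor", "activator", "inhibitor", "other")),
    goterm = data.frame(
      protein = c("p1", "p2", "p4"),
      go_term = c("translation", "mitosis", "translation")),
    go_relation = data.frame(
      go_term = c("g1", "g2"), relation = c("is_a", "part_of"),
      go_parent = c("g2", "g3")),
    interact = data.frame(protein = c("p1", "p2"),
                          protein2 = c("p4", "p4")),
    pathway = data.frame(
      protein = c("p1", "p4"), pathway = c("Endocytosis", "Endocytosis"),
      source = c("kegg", "kegg")),
    domain = data.frame(protein = "p2", domain = "Kinase")
  ))
}

# Chain hierarchy root -> x -> y plus a sibling branch.
make_chain_hierarchy <- function() {
  term_hierarchy(child = c("x", "y", "z"),
                 parent = c("root", "x", "root"))
}

# Two disjoint subtrees under a shared root.
make_two_subtree_hierarchy <- function() {
  term_hierarchy(
    child = c("L", "R", "l1", "l2", "l3", "r1", "r2", "r3"),
    parent = c("root", "root", "L", "L", "L", "R", "R", "R"))
}

# Random DAG hierarchy for property tests.
random_hierarchy <- function(n_terms, seed) {
  set.seed(seed)
  child <- parent <- relation <- character(0)
  ids <- sprintf("t%02d", seq_len(n_terms))
  for (i in 2:n_terms) {
    child <- c(child, ids[i])
    parent <- c(parent, ids[sample.int(i - 1L, 1L)])
    relation <- c(relation, sample(c("is_a", "part_of"), 1L))
    if (i > 2L && stats::runif(1L) < 0.15) {
      p2 <- setdiff(ids[seq_len(i - 1L)], parent[length(parent)])
      child <- c(child, ids[i])
      parent <- c(parent, p2[sample.int(length(p2), 1L)])
      relation <- c(relation, "part_of")
    }
  }
  term_hierarchy(child, parent, relation)
}

# Standard planted rules used by the synthetic end-to-end fixtures.
planted_rule_inhibitor_pathway <- function(frac = 0.25) {
  planted_rule(list(lit("drug_has_target", "?A", "?B", "inhibitor"),
                    lit("pathway", "?B", "PW_planted_1", "kegg")),
               tcs = c(1L, 2L), carrier_fraction = frac)
}
planted_rule_activator_goterm <- function(frac = 0.25) {
  planted_rule(list(lit("drug_has_target", "?A", "?B", "activator"),
                    lit("goterm", "?B", "GO_planted_2")),
               tcs = c(1L, 2L), carrier_fraction = frac)
}
planted_rule_category <- function(frac = 0.2) {
  planted_rule(list(lit("category", "?A", "CAT_planted")),
               tcs = NULL, carrier_fraction = frac)
}

# The reference study scenario: 300 drugs, two relational rules feeding
# one profile and a category rule feeding another.  Built once per test
# run (the relational induction on it is exercised by the acceptance
# suite).
.scenario_cache <- new.env(parent = emptyenv())
study_scenario <- function() {
  if (is.null(.scenario_cache$sc)) {
    cfg <- synth_config(
      planted_rules = list(planted_rule_inhibitor_pathway(),
                           planted_rule_activator_goterm(),
                           planted_rule_category()),
      seed = 42L)
    .scenario_cache$sc <- synth_scenario(cfg)
  }
  .scenario_cache$sc
}

# Smaller, faster scenario for module-level tests.
small_scenario <- function(seed = 7L, fn = 0, fp = 0) {
  cfg <- synth_config(
    n_drugs = 80L, n_targets = 100L, n_go_terms = 60L,
    n_pathways = 20L, n_domains = 20L, n_categories = 10L,
    planted_rules = list(planted_rule_inhibitor_pathway(0.3),
                         planted_rule_category(0.25)),
    fn = fn, fp = fp, seed = seed)
  synth_scenario(cfg)
}

sep_key <- function(s) paste(s$tcs, collapse = ",")
sep_keys <- function(seps) vapply(seps, sep_key, "")

expect_same_seps <- function(a, b) {
  expect_identical(sep_keys(a), sep_keys(b))
  expect_identical(vapply(a, `[[`, 0L, "support"),
                   vapply(b, `[[`, 0L, "support"))
  for (i in seq_along(a)) {
    expect_setequal(a[[i]]$covered, b[[i]]$covered)
  }
}

random_binary_table <- function(nrow, ncol, density, seed) {
  set.seed(seed)
  matrix(rbinom(nrow * ncol, 1L, density), nrow = nrow)
}
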
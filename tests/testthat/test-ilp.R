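test_that("saturation lifts the seed's facts into typed literals", {
  kb1 <- knowledge_base(list(category = data.frame(d = "d1", c = "X")))
  bt <- saturate("d1", kb1)
  expect_length(bt$literals, 1L)
  expect_identical(format(bt$literals[[1L]]$lit), "category(A,'X')")

  kb2 <- knowledge_base(list(
    drug_has_target = data.frame(d = "d1", p = "p1", a = "inhibitor"),
    goterm = data.frame(p = "p1", g = "translation")))
  bt2 <- saturate("d1", kb2)
  lits <- vapply(bt2$literals, function(e) format(e$lit), "")
  expect_true("drug_has_target(A,B,inhibitor)" %in% lits)
  # the goterm annotation chains off the target variable, as a constant
  # (mode #) and as an output variable (mode -)
  expect_true("goterm(B,translation)" %in% lits)
  expect_true(any(grepl("^goterm\\(B,[A-Z]\\)$", lits)))

  # a drug with no facts has an empty bottom clause
  kb3 <- knowledge_base(list(category = data.frame(d = "d9", c = "X")),
                        side_effects = list(d0 = character(0)))
  expect_length(saturate("d0", kb3)$literals, 0L)
})

test_that("the chain-depth cap stops saturation at the target level", {
  kb <- knowledge_base(list(
    drug_has_target = data.frame(d = "d1", p = "p1", a = "other"),
    interact = data.frame(p = "p1", q = "p2"),
    goterm = data.frame(p = c("p1", "p2"), g = c("g1", "g2"))))
  bt1 <- saturate("d1", kb, cfg = ilp_config(max_chain_depth = 1L))
  lits1 <- vapply(bt1$literals, function(e) e$lit$predicate, "")
  # no literal mentions an interactant-of-target at depth cap 1
  expect_false("interact" %in% lits1)
  expect_true("goterm" %in% lits1)

  bt3 <- saturate("d1", kb, cfg = ilp_config(max_chain_depth = 3L))
  lits3 <- vapply(bt3$literals, function(e) e$lit$predicate, "")
  expect_true("interact" %in% lits3)
})

test_that("rule coverage follows the fact chains", {
  kb <- make_tiny_kb()
  # an empty body covers every drug
  expect_true(covers(list(), "d3", kb))
  body <- list(lit("drug_has_target", "?A", "?B", "inhibitor"),
               lit("pathway", "?B", "Endocytosis", "kegg"))
  expect_true(covers(body, "d1", kb))
  expect_false(covers(body, "d2", kb))   # p2 lacks the pathway link

  # a 2-step relation chain agrees with exhaustive binding enumeration
  kbg <- knowledge_base(list(
    drug_has_target = data.frame(d = c("da", "db"), p = c("q1", "q2"),
                                 a = "inhibitor"),
    goterm = data.frame(p = c("q1", "q2"), g = c("g1", "g4")),
    go_relation = data.frame(g = c("g1", "g2", "g4"),
                             r = c("is_a", "is_a", "part_of"),
                             h = c("g2", "g3", "g3"))))
  chain <- list(lit("drug_has_target", "?A", "?B", "inhibitor"),
                lit("goterm", "?B", "?C"),
                lit("go_relation", "?C", "is_a", "?D"),
                lit("go_relation", "?D", "is_a", "g3"))
  for (d in kbg$drugs) {
    expect_identical(covers(chain, d, kbg),
                     length(kb_match(kbg, chain, c(A = d))) > 0L,
                     label = d)
  }
  expect_true(covers(chain, "da", kbg))
  expect_false(covers(chain, "db", kbg))
})

test_that("search_rule finds a shared-category separation", {
  facts <- list(
    category = data.frame(
      d = c(sprintf("p%d", 1:6), sprintf("n%d", 1:6)),
      c = c(rep("X", 6L), rep("Y", 6L))))
  kb <- knowledge_base(facts)
  pos <- sprintf("p%d", 1:6)
  neg <- sprintf("n%d", 1:6)
  rule <- search_rule(pos[1L], pos, neg, kb, ilp_config(min_pos = 5L))
  expect_identical(rule$P, 6L)
  expect_identical(rule$N, 0L)
  expect_identical(format(rule$body[[1L]]), "category(A,'X')")

  # a seed with an empty bottom clause yields no rule
  kb0 <- knowledge_base(
    list(category = data.frame(d = neg, c = "Y")),
    side_effects = stats::setNames(
      rep(list(character(0)), 6L), pos))
  expect_null(search_rule(pos[1L], pos, neg, kb0))
})

test_that("accepted rules respect min_pos and noise on the full sets", {
  sc <- small_scenario()
  fp <- filter_prevalent(sc$fingerprints)
  seps <- mine_mfis(fp)
  sep <- Filter(function(s) setequal(s$tcs, c(1L, 2L)), seps)[[1L]]
  ls <- build_learning_set(fp, sep)
  cfg <- ilp_config()
  th <- induce_cover(ls$positives, ls$negatives, sc$kb, cfg)
  expect_gt(length(th$rules), 0L)
  for (r in th$rules) {
    P <- sum(vapply(ls$positives, function(d) covers(r, d, sc$kb), TRUE))
    N <- sum(vapply(ls$negatives, function(d) covers(r, d, sc$kb), TRUE))
    expect_identical(P, r$P)
    expect_identical(N, r$N)
    expect_gte(P, cfg$min_pos)
    expect_lte(N, cfg$noise)
    # body variables chain back to the head variable
    bound <- "A"
    for (l in r$body) {
      vars <- l$vars[l$is_var]
      expect_true(any(vars %in% bound))
      bound <- union(bound, vars)
    }
  }
})

test_that("induce_cover retains overlapping rules", {
  # d4, d5 satisfy both planted bodies; the two sub-populations are
  # only covered jointly by two overlapping rules
  n_pos <- sprintf("d%d", 1:7)
  n_neg <- sprintf("n%d", 1:6)
  facts <- list(
    category = data.frame(
      d = c(n_pos[1:5], n_pos[4:7], n_neg),
      c = c(rep("CX", 5L), rep("CY", 4L), rep("CZ", 6L))))
  kb <- knowledge_base(facts)
  th <- induce_cover(n_pos, n_neg, kb, ilp_config(min_pos = 4L))
  expect_length(th$rules, 2L)
  both <- Reduce(intersect, lapply(th$rules, `[[`, "covered_pos"))
  expect_setequal(both, c("d4", "d5"))
  expect_length(th$uncovered, 0L)

  # predictions are the disjunction over rules
  pred <- predict_theory(th, c(n_pos, n_neg), kb)
  expect_identical(unname(pred), c(rep(TRUE, 7L), rep(FALSE, 6L)))

  empty <- structure(list(rules = list(), uncovered = character(0)),
                     class = "sep_theory")
  expect_false(any(predict_theory(empty, n_pos, kb)))
})

test_that("min_pos above the positive count yields an empty theory", {
  kb <- make_tiny_kb()
  th <- induce_cover(c("d1", "d2"), "d3", kb,
                     ilp_config(min_pos = 5L))
  expect_length(th$rules, 0L)
  expect_setequal(th$uncovered, c("d1", "d2"))
  expect_error(induce_cover("d1", "d1", kb), "disjoint")
})

test_that("mode declarations validate their shape", {
  expect_error(mode_decl("category", "#drug"), "arity")
  expect_error(mode_decl("goterm", "#protein", "#go_term"), "input")
  expect_error(mode_decl("frob", "+drug"), "unknown predicate")
  m <- mode_decl("pathway", "+protein", "#pathway", "#source")
  expect_identical(m$marks, c("+", "#", "#"))
})
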
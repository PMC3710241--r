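test_that("generated hierarchies have the configured tree shape", {
  cfg <- synth_config(hierarchy_branching = 3L, hierarchy_depth = 2L,
                      second_parent_fraction = 0, seed = 1L)
  h <- generate_hierarchy(cfg)
  expect_length(h$terms, 13L)            # 1 root + 3 internal + 9 leaves
  expect_length(h$roots, 1L)
  expect_identical(sum(h$depth == 2L), 9L)
  expect_identical(sum(h$depth == 1L), 3L)
  expect_identical(nrow(h$edges), 12L)

  # same seed, same edges; different seed may differ via extra parents
  cfg2 <- synth_config(second_parent_fraction = 0.3, seed = 8L)
  e1 <- generate_hierarchy(cfg2)$edges
  e2 <- generate_hierarchy(cfg2)$edges
  expect_identical(e1, e2)
})

test_that("random hierarchy configs always produce connected DAGs", {
  set.seed(202)
  for (i in 1:100) {
    cfg <- synth_config(hierarchy_branching = sample(2:4, 1L),
                        hierarchy_depth = sample(2:4, 1L),
                        second_parent_fraction = runif(1L, 0, 0.3),
                        seed = i)
    h <- generate_hierarchy(cfg)    # term_hierarchy() rejects cycles
    expect_true(all(is.finite(h$depth)))
  }
})

test_that("planted bodies are satisfied by exactly the carriers", {
  cfg <- synth_config(
    n_drugs = 60L, n_targets = 80L,
    planted_rules = list(planted_rule_inhibitor_pathway(0.3)),
    seed = 5L)
  gen <- generate_kb(cfg)
  carriers <- gen$truth[[1L]]$carriers
  drugs <- sprintf("D%04d", 1:60)
  sat <- drugs[vapply(drugs, function(d) {
    covers(gen$truth[[1L]]$body, d, gen$kb)
  }, TRUE)]
  expect_setequal(sat, carriers)

  # carrier fraction 0: nobody satisfies the body
  cfg0 <- synth_config(
    n_drugs = 40L,
    planted_rules = list(planted_rule_inhibitor_pathway(0)),
    seed = 5L)
  gen0 <- generate_kb(cfg0)
  expect_length(gen0$truth[[1L]]$carriers, 0L)
  expect_false(any(vapply(sprintf("D%04d", 1:40), function(d) {
    covers(gen0$truth[[1L]]$body, d, gen0$kb)
  }, TRUE)))
})

test_that("the target multiplicity matches the configured mean", {
  cfg <- synth_config(n_drugs = 500L, n_targets = 600L,
                      targets_per_drug = 4, seed = 11L)
  gen <- generate_kb(cfg)
  dht <- gen$kb$facts$drug_has_target
  mean_t <- nrow(dht) / 500
  expect_lt(abs(mean_t - 4) / 4, 0.1)
})

test_that("noise-free annotations make fingerprints match carriers", {
  sc <- small_scenario(seed = 19L)
  fp <- sc$fingerprints
  for (tr in sc$truth) {
    cols <- match(tr$tcs, attr(fp, "tc_index"))
    pos <- rownames(fp)[rowSums(fp[, cols, drop = FALSE]) ==
                          length(cols)]
    expect_setequal(pos, tr$carriers)
  }
})

test_that("fp = 1 marks every drug positive for the planted profile", {
  sc <- small_scenario(seed = 23L, fp = 1)
  fp <- sc$fingerprints
  tr <- sc$truth[[1L]]
  cols <- match(tr$tcs, attr(fp, "tc_index"))
  expect_true(all(rowSums(fp[, cols, drop = FALSE]) == length(cols)))
})

test_that("no rules and zero background give empty annotations", {
  cfg <- synth_config(n_drugs = 20L, background_rate = 0, seed = 2L)
  sc <- synth_scenario(cfg)
  expect_identical(sum(lengths(sc$side_effects)), 0L)
})

test_that("report generation feeds the checking procedure", {
  sc <- small_scenario(seed = 29L)
  tr <- sc$truth[[1L]]
  sep <- structure(list(id = "S", tcs = tr$tcs,
                        tc_names = tc_names(sc$clustering)[tr$tcs],
                        support = length(tr$carriers),
                        covered = tr$carriers),
                   class = "sep_profile")
  # full reporting: every carrier confirmable
  confirmed <- faers_check(tr$carriers, sep, sc$reports, sc$clustering)
  expect_setequal(confirmed, tr$carriers)

  # no reports, or decoys only: no confirmations
  cfg0 <- sc$config
  cfg0$faers_fraction <- 0
  rep0 <- generate_faers(sc$kb, sc$truth, sc$clustering, cfg0)
  expect_true(all(rep0$role != "primary_suspect"))
  expect_length(faers_check(tr$carriers, sep, rep0, sc$clustering), 0L)
})

test_that("identical configurations export byte-identical scenarios", {
  cfg <- synth_config(n_drugs = 30L, n_targets = 40L, seed = 77L,
                      planted_rules = list(planted_rule_category(0.3)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(synth_scenario(cfg), d1)
  write_scenario(synth_scenario(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true("ground_truth.json" %in% list.files(d1))
})

test_that("label noise degrades but does not destroy rule recovery", {
  sc <- small_scenario(seed = 31L, fn = 0.2)
  fp <- filter_prevalent(sc$fingerprints)
  tr <- sc$truth[[1L]]
  cols <- match(tr$tcs, attr(fp, "tc_index"))
  pos <- rownames(fp)[rowSums(fp[, cols, drop = FALSE]) == length(cols)]
  neg <- rownames(fp)[rowSums(fp[, cols, drop = FALSE]) == 0L]
  # annotation noise relabels some true carriers as negatives, so the
  # noise budget must absorb them for any rule to be acceptable
  th <- induce_cover(pos, neg, sc$kb,
                     ilp_config(noise = ceiling(0.25 * length(pos))))
  pred <- predict_theory(th, pos, sc$kb)
  sens <- mean(pred)
  prevalence <- length(pos) / (length(pos) + length(neg))
  expect_gt(sens, prevalence)
})
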
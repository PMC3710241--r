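make_ls_table <- function() {
  m <- rbind(d1 = c(1L, 1L, 0L), d2 = c(1L, 0L, 0L),
             d3 = c(0L, 0L, 0L), d4 = c(1L, 1L, 1L))
  colnames(m) <- c("1_a", "2_b", "3_c")
  structure(m, tc_index = 1:3,
            class = c("sep_fingerprints", "matrix", "array"))
}

test_that("learning sets split into positives, negatives, excluded", {
  tab <- make_ls_table()
  sep <- structure(list(id = "SEP_1", tcs = c(1L, 2L),
                        tc_names = c("1_a", "2_b"), support = 2L,
                        covered = c("d1", "d4")),
                   class = "sep_profile")
  ls <- build_learning_set(tab, sep)
  expect_setequal(ls$positives, c("d1", "d4"))  # all profile TCs
  expect_identical(ls$negatives, "d3")          # none of them
  expect_identical(ls$excluded, "d2")           # partial match
  expect_setequal(c(ls$positives, ls$negatives, ls$excluded),
                  rownames(tab))
  sep$tcs <- c(1L, 9L)
  expect_error(build_learning_set(tab, sep), "not present")
})

test_that("metrics implement the confusion-matrix formulas", {
  m <- metrics(confusion(tp = 5L, fn = 5L, tn = 3L, fp = 1L))
  expect_equal(unname(m), c(8 / 14, 0.75, 0.5))

  perfect <- metrics(confusion(4L, 0L, 6L, 0L))
  expect_equal(unname(perfect), c(1, 1, 1))

  wrong <- metrics(confusion(0L, 3L, 0L, 3L))
  expect_identical(unname(wrong["Acc"]), 0)

  # zero denominators are reported as absent, not zero
  no_neg <- metrics(confusion(2L, 0L, 0L, 1L))
  expect_true(is.na(no_neg["Spec"]))
  expect_error(confusion(-1L, 0L, 0L, 0L), "non-negative")
})

test_that("stratified folds stay within one of the class targets", {
  ls <- structure(list(positives = sprintf("p%02d", 1:50),
                       negatives = sprintf("n%02d", 1:75)),
                  class = "sep_learning_set")
  seen_folds <- new.env()
  trainer <- function(train_pos, train_neg) {
    # record held-out sizes through the training complement
    seen_folds$pos <- c(seen_folds$pos, 50L - length(train_pos))
    seen_folds$neg <- c(seen_folds$neg, 75L - length(train_neg))
    function(drugs) rep(FALSE, length(drugs))
  }
  cv <- stratified_cv(ls, trainer, folds = 10L, runs = 2L, seed = 5L)
  expect_identical(nrow(cv), 20L)
  expect_true(all(seen_folds$pos == 5L))
  expect_true(all(seen_folds$neg %in% c(7L, 8L)))
  # assay totals equal the held-out fold size; per-run totals restore
  # the learning set
  expect_identical(cv$TP + cv$FP + cv$TN + cv$FN,
                   seen_folds$pos[1:20] + seen_folds$neg[1:20])
  for (r in unique(cv$run)) {
    expect_identical(sum(cv[cv$run == r, c("TP", "FP", "TN", "FN")]),
                     125L)
  }
  # the always-negative model: Sens 0, Spec 1 in every assay
  expect_true(all(cv$Sens == 0))
  expect_true(all(cv$Spec == 1))
  expect_equal(cv_summary(cv)$Spec, 1)
})

test_that("cross-validation is seeded and reproducible", {
  ls <- structure(list(positives = sprintf("p%02d", 1:20),
                       negatives = sprintf("n%02d", 1:30)),
                  class = "sep_learning_set")
  trainer <- function(tp, tn) {
    function(drugs) grepl("^p", drugs) & substr(drugs, 2L, 3L) < "15"
  }
  cv1 <- stratified_cv(ls, trainer, folds = 10L, runs = 10L, seed = 9L)
  cv2 <- stratified_cv(ls, trainer, folds = 10L, runs = 10L, seed = 9L)
  expect_identical(cv1, cv2)
  expect_identical(nrow(cv1), 100L)
  cv3 <- stratified_cv(ls, trainer, folds = 10L, runs = 1L, seed = 10L)
  expect_false(identical(cv1[cv1$run == 1L, -(1:2)],
                         cv3[, -(1:2)]) &&
                 identical(cv1$TP[1:10], cv3$TP))
  expect_error(stratified_cv(
    structure(list(positives = "p1", negatives = sprintf("n%d", 1:20)),
              class = "sep_learning_set"), trainer),
    "folds")
})

test_that("direct testing labels drugs by the learning-set rule", {
  tab <- make_ls_table()
  sep <- structure(list(id = "SEP_1", tcs = c(1L, 2L),
                        tc_names = c("1_a", "2_b"), support = 2L,
                        covered = c("d1", "d4")),
                   class = "sep_profile")
  # empty test set -> zero matrix
  empty <- tab[0L, , drop = FALSE]
  attr(empty, "tc_index") <- 1:3
  dt0 <- direct_test(function(d) logical(0), empty, sep)
  expect_identical(unlist(dt0$cm), c(TP = 0L, FP = 0L, TN = 0L, FN = 0L))

  # a predictor that flags d3 and d4: one TP (d4), one FP (d3);
  # excluded d2 is skipped entirely
  pred <- function(drugs) drugs %in% c("d3", "d4")
  dt <- direct_test(pred, tab, sep)
  expect_identical(dt$cm$TP, 1L)
  expect_identical(dt$cm$FP, 1L)
  expect_identical(dt$cm$FN, 1L)
  expect_identical(dt$fp_drugs, "d3")
})

test_that("report checking requires a primary-suspect hit in every TC", {
  h <- make_two_subtree_hierarchy()
  tc <- build_term_clusters(c("l1", "l2", "l3", "r1", "r2", "r3"), h,
                            k = 2L)
  sep <- structure(list(id = "S", tcs = c(1L, 2L),
                        tc_names = tc_names(tc), support = 1L,
                        covered = NULL),
                   class = "sep_profile")
  t1 <- tc$clusters[[1L]]$members[1L]
  t2 <- tc$clusters[[2L]]$members[1L]
  reports <- faers_reports(
    drug_id = c("dA", "dA", "dB", "dC", "dC"),
    term_id = c(t1, t2, t1, t1, t2),
    role = c("primary_suspect", "primary_suspect", "primary_suspect",
             "concomitant", "concomitant"))
  confirmed <- faers_check(c("dA", "dB", "dC", "dD"), sep, reports, tc)
  expect_identical(confirmed, "dA")    # dB hits one TC, dC not primary
  expect_identical(faers_check(character(0), sep, reports, tc),
                   character(0))
})
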
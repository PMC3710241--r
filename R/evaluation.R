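#' Build the learning set of a side-effect profile
#'
#' Positives are the drugs whose fingerprint contains every TC of the
#' profile; negatives are the drugs associated with none of the
#' profile's TCs; drugs matching only part of the profile are excluded
#' from both classes.
#'
#' @param table A `sep_fingerprints` matrix.
#' @param sep A `sep_profile`.
#' @return An object of class `sep_learning_set` with `sep_id`,
#'   `positives`, `negatives`, `excluded`.
#' @export
build_learning_set <- function(table, sep) {
  tc_index <- attr(table, "tc_index")
  if (is.null(tc_index)) tc_index <- seq_len(ncol(table))
  cols <- match(sep$tcs, tc_index)
  if (anyNA(cols)) {
    stop("SEP TC(s) not present in the fingerprint table: ",
         paste(sep$tcs[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  sub <- table[, cols, drop = FALSE]
  hits <- rowSums(sub)
  drugs <- rownames(table)
  structure(list(sep_id = sep$id,
                 positives = drugs[hits == length(cols)],
                 negatives = drugs[hits == 0L],
                 excluded = drugs[hits > 0L & hits < length(cols)]),
            class = "sep_learning_set")
}

#' @export
print.sep_learning_set <- function(x, ...) {
  cat("Learning set", if (!is.na(x$sep_id)) paste0("(", x$sep_id, ")"),
      ":", length(x$positives), "positives,", length(x$negatives),
      "negatives,", length(x$excluded), "excluded\n")
  invisible(x)
}

#' Confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return An object of class `sep_confusion`.
#' @export
confusion <- function(tp, fp, tn, fn) {
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(lapply(counts, as.integer), class = "sep_confusion")
}

#' Accuracy, specificity and sensitivity of a confusion matrix
#'
#' `Acc = (TP + TN) / total`, `Spec = TN / (TN + FP)` (true negative
#' rate), `Sens = TP / (TP + FN)` (true positive rate).  A ratio with a
#' zero denominator is reported as `NA`, not as zero.
#'
#' @param cm A [confusion()] matrix (or list with TP/FP/TN/FN).
#' @return Named numeric vector `c(Acc, Spec, Sens)`.
#' @export
metrics <- function(cm) {
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  c(Acc = if (total > 0L) (cm$TP + cm$TN) / total else NA_real_,
    Spec = if (cm$TN + cm$FP > 0L) cm$TN / (cm$TN + cm$FP) else NA_real_,
    Sens = if (cm$TP + cm$FN > 0L) cm$TP / (cm$TP + cm$FN) else NA_real_)
}

#' @export
print.sep_confusion <- function(x, ...) {
  cat("TP =", x$TP, " FP =", x$FP, " TN =", x$TN, " FN =", x$FN, "\n")
  m <- metrics(x)
  cat("Acc =", signif(m["Acc"], 3L), " Spec =", signif(m["Spec"], 3L),
      " Sens =", signif(m["Sens"], 3L), "\n")
  invisible(x)
}

.confusion_from_pred <- function(pred, truth) {
  confusion(tp = sum(pred & truth), fp = sum(pred & !truth),
            tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Repeated stratified cross-validation
#'
#' Runs `runs` repetitions of `folds`-fold stratified cross-validation.
#' Per run, each class is shuffled with a run-specific seed and dealt
#' round-robin into folds, so fold class sizes stay within one of the
#' class-proportional target; the model is retrained on each training
#' split and each assay's confusion matrix is computed from held-out
#' predictions only.
#'
#' @param learning_set A `sep_learning_set`.
#' @param model_trainer `function(train_pos, train_neg)` returning a
#'   predictor `function(drugs)` that yields a logical vector (e.g.
#'   [dt_trainer()] or [ilp_trainer()]).
#' @param folds Folds per run (default 10); each class must have at
#'   least this many members.
#' @param runs Repetitions (default 10).
#' @param seed Base random seed; run `r` uses `seed + r - 1`.
#' @return A data frame of class `sep_cv` with one row per assay
#'   (`run`, `fold`, `TP`, `FP`, `TN`, `FN`, `Acc`, `Spec`, `Sens`).
#' @export
stratified_cv <- function(learning_set, model_trainer, folds = 10L,
                          runs = 10L, seed = 1L) {
  pos <- learning_set$positives
  neg <- learning_set$negatives
  small <- min(length(pos), length(neg))
  if (small < folds) {
    stop("smallest class has ", small, " members; use at most ", small,
         " folds", call. = FALSE)
  }
  rows <- vector("list", folds * runs)
  i <- 0L
  for (run in seq_len(runs)) {
    set.seed(seed + run - 1L)
    pos_sh <- pos[sample.int(length(pos))]
    neg_sh <- neg[sample.int(length(neg))]
    pos_fold <- rep_len(seq_len(folds), length(pos_sh))
    neg_fold <- rep_len(seq_len(folds), length(neg_sh))
    for (f in seq_len(folds)) {
      train_pos <- pos_sh[pos_fold != f]
      train_neg <- neg_sh[neg_fold != f]
      test_pos <- pos_sh[pos_fold == f]
      test_neg <- neg_sh[neg_fold == f]
      predictor <- model_trainer(train_pos, train_neg)
      pred <- predictor(c(test_pos, test_neg))
      truth <- c(rep(TRUE, length(test_pos)), rep(FALSE, length(test_neg)))
      cm <- .confusion_from_pred(as.logical(pred), truth)
      m <- metrics(cm)
      i <- i + 1L
      rows[[i]] <- data.frame(run = run, fold = f, TP = cm$TP,
                              FP = cm$FP, TN = cm$TN, FN = cm$FN,
                              Acc = m[["Acc"]], Spec = m[["Spec"]],
                              Sens = m[["Sens"]])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sep_cv", "data.frame")
  out
}

#' Aggregate cross-validation assays
#'
#' @param cv A `sep_cv` data frame from [stratified_cv()].
#' @return Named list with the mean and standard deviation of accuracy,
#'   specificity and sensitivity over all assays (`NA` assays dropped).
#' @export
cv_summary <- function(cv) {
  list(Acc = mean(cv$Acc, na.rm = TRUE),
       Spec = mean(cv$Spec, na.rm = TRUE),
       Sens = mean(cv$Sens, na.rm = TRUE),
       Acc_sd = stats::sd(cv$Acc, na.rm = TRUE),
       Spec_sd = stats::sd(cv$Spec, na.rm = TRUE),
       Sens_sd = stats::sd(cv$Sens, na.rm = TRUE),
       n_assays = nrow(cv))
}

#' Decision-tree trainer for cross-validation
#'
#' @param kb A `sep_kb` supplying the attributes.
#' @param min_leaf,cf,prune Passed to [learn_tree()].
#' @return `function(train_pos, train_neg)` returning a predictor
#'   usable by [stratified_cv()] and [direct_test()].
#' @export
dt_trainer <- function(kb, min_leaf = 5L, cf = 0.25, prune = TRUE) {
  force(kb)
  function(train_pos, train_neg) {
    tab <- build_attribute_table(
      kb, list(positives = train_pos, negatives = train_neg))
    tree <- learn_tree(tab, min_leaf = min_leaf, cf = cf, prune = prune)
    function(drugs) {
      x <- build_attribute_table(
        kb, list(positives = drugs, negatives = character(0)))
      predict_tree(tree, x) == "pos"
    }
  }
}

#' Relational-rule trainer for cross-validation
#'
#' @param kb A `sep_kb`.
#' @param cfg An [ilp_config()].
#' @param modes Mode declarations.
#' @return `function(train_pos, train_neg)` returning a predictor.
#' @export
ilp_trainer <- function(kb, cfg = ilp_config(), modes = default_modes()) {
  force(kb); force(cfg); force(modes)
  function(train_pos, train_neg) {
    theory <- induce_cover(train_pos, train_neg, kb, cfg, modes)
    function(drugs) unname(predict_theory(theory, drugs, kb))
  }
}

#' Direct test of a model on held-out drugs
#'
#' Ground-truth labels are derived from the test drugs' fingerprints by
#' the learning-set rule (all profile TCs present = positive, none =
#' negative, partial = excluded and skipped); test drugs absent from
#' the knowledge base are skipped with a message.  Returns the
#' confusion matrix plus the list of false-positive drugs, the input of
#' the report-based checking procedure.
#'
#' @param model A `sep_theory`, `sep_dtree`, or a predictor
#'   `function(drugs) -> logical`.
#' @param test_table Fingerprint table of the test drugs (ground truth).
#' @param sep The `sep_profile` under test.
#' @param kb A `sep_kb` holding the test drugs' descriptors (required
#'   for theory/tree models).
#' @return List of class `sep_direct_test`: `cm` ([confusion()]),
#'   `fp_drugs`, `tp_drugs`, `skipped`.
#' @export
direct_test <- function(model, test_table, sep, kb = NULL) {
  ls <- build_learning_set(test_table, sep)
  drugs <- c(ls$positives, ls$negatives)
  truth <- c(rep(TRUE, length(ls$positives)),
             rep(FALSE, length(ls$negatives)))
  skipped <- character(0)
  if (!is.null(kb)) {
    known <- drugs %in% kb$drugs
    skipped <- drugs[!known]
    if (length(skipped)) {
      message("skipping ", length(skipped),
              " test drug(s) absent from the knowledge base")
    }
    truth <- truth[known]
    drugs <- drugs[known]
  }
  if (!length(drugs)) {
    return(structure(list(cm = confusion(0L, 0L, 0L, 0L),
                          fp_drugs = character(0),
                          tp_drugs = character(0), skipped = skipped),
                     class = "sep_direct_test"))
  }
  pred <- if (inherits(model, "sep_theory")) {
    unname(predict_theory(model, drugs, kb))
  } else if (inherits(model, "sep_dtree")) {
    x <- build_attribute_table(
      kb, list(positives = drugs, negatives = character(0)))
    predict_tree(model, x) == "pos"
  } else {
    as.logical(model(drugs))
  }
  structure(list(cm = .confusion_from_pred(pred, truth),
                 fp_drugs = drugs[pred & !truth],
                 tp_drugs = drugs[pred & truth],
                 skipped = skipped),
            class = "sep_direct_test")
}

#' @export
print.sep_direct_test <- function(x, ...) {
  print(x$cm)
  cat("false-positive drugs:",
      if (length(x$fp_drugs)) paste(x$fp_drugs, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Construct a spontaneous-report set
#'
#' A FAERS-style table of (drug, side-effect term, role) records; the
#' role flag distinguishes reports naming the drug as primary suspect
#' from other involvements.
#'
#' @param drug_id,term_id,role Equal-length character vectors; `role`
#'   is `"primary_suspect"` or any other involvement label.
#' @return A data frame of class `sep_reports`.
#' @export
faers_reports <- function(drug_id, term_id, role) {
  out <- data.frame(drug_id = as.character(drug_id),
                    term_id = as.character(term_id),
                    role = as.character(role),
                    stringsAsFactors = FALSE)
  class(out) <- c("sep_reports", "data.frame")
  out
}

#' Read a report table from TSV
#'
#' Columns `drug_id`, `term_id`, `role`.
#'
#' @param path TSV file.
#' @return A `sep_reports` data frame.
#' @export
read_faers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  faers_reports(df$drug_id, df$term_id, df$role)
}

#' Check predicted false positives against spontaneous reports
#'
#' A drug is confirmed for a profile when, for every TC of the profile,
#' at least one report names the drug as primary suspect of a
#' side-effect term belonging to that TC's members.  Reports with any
#' other role flag never confirm.
#'
#' @param fp_drugs Drugs flagged false positive by a model.
#' @param sep The `sep_profile`.
#' @param reports A [faers_reports()] table.
#' @param clustering The `sep_tc` clustering defining TC membership.
#' @return The confirmed subset of `fp_drugs`.
#' @export
faers_check <- function(fp_drugs, sep, reports, clustering) {
  if (!length(fp_drugs)) return(character(0))
  primary <- reports[reports$role == "primary_suspect", , drop = FALSE]
  members <- lapply(sep$tcs, function(i) {
    if (i < 1L || i > length(clustering$clusters)) {
      stop("SEP TC index ", i, " outside the clustering", call. = FALSE)
    }
    clustering$clusters[[i]]$members
  })
  ok <- vapply(fp_drugs, function(d) {
    terms <- primary$term_id[primary$drug_id == d]
    all(vapply(members, function(mem) any(terms %in% mem), TRUE))
  }, TRUE)
  fp_drugs[ok]
}
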
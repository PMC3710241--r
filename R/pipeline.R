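#' Run the full profile-mining pipeline on a knowledge base
#'
#' Chains the analysis stages: term clustering of the annotated
#' side-effect vocabulary, fingerprint construction, prevalence
#' filtering, profile mining, and per-profile characterization
#' (decision tree and/or relational theory on the full learning set,
#' with optional repeated stratified cross-validation).
#'
#' @param kb A `sep_kb` with side effects and a term hierarchy attached
#'   (e.g. from [load_kb()] or [synth_scenario()]).
#' @param k Term-cluster count override; `NULL` selects it by the
#'   Kelley-Gardner-Sutcliffe penalty.
#' @param clustering An existing `sep_tc` term clustering to use as-is
#'   (e.g. an expert-validated one); when supplied, `k` is ignored and
#'   the annotated terms are not re-clustered.
#' @param assoc An [assoc_config()].
#' @param miner A [miner_config()].
#' @param learners Character subset of `c("dt", "ilp")`.
#' @param dt_min_leaf,dt_cf Decision-tree parameters.
#' @param ilp An [ilp_config()].
#' @param modes Mode declarations for the relational learner.
#' @param cv Run cross-validation per profile (default `FALSE`; the
#'   full-set models are always built).
#' @param folds,runs,seed Cross-validation parameters.
#' @param max_seps Characterize at most this many profiles (by mining
#'   order); `NULL` for all.
#' @param verbose Log stage progress to standard error.
#' @return List of class `sep_pipeline`: `clustering`, `fingerprints`
#'   (filtered), `seps`, `stats`, and per-profile `models` (each with
#'   `learning_set`, `tree`, `theory`, `cv_dt`, `cv_ilp` as requested).
#' @export
run_pipeline <- function(kb, k = NULL, clustering = NULL,
                         assoc = assoc_config(),
                         miner = miner_config(),
                         learners = c("dt", "ilp"),
                         dt_min_leaf = 5L, dt_cf = 0.25,
                         ilp = ilp_config(), modes = default_modes(),
                         cv = FALSE, folds = 10L, runs = 10L, seed = 1L,
                         max_seps = NULL, verbose = FALSE) {
  if (is.null(kb$hierarchy)) {
    stop("knowledge base has no term hierarchy attached", call. = FALSE)
  }
  if (!length(kb$side_effects)) {
    stop("knowledge base has no side-effect annotations", call. = FALSE)
  }
  say <- function(...) if (verbose) message("[pipeline] ", ...)

  if (is.null(clustering)) {
    terms <- intersect(
      unique(unlist(kb$side_effects, use.names = FALSE)),
      kb$hierarchy$terms)
    say("clustering ", length(terms), " side-effect terms")
    clustering <- build_term_clusters(terms, kb$hierarchy, k = k)
  }
  say(clustering$k, " term clusters")

  fp <- build_fingerprints(kb$side_effects, clustering, assoc)
  fp <- filter_prevalent(fp, miner$prevalence_cutoff)
  say("fingerprints: ", nrow(fp), " drugs x ", ncol(fp),
      " TCs after prevalence filter")

  seps <- mine_mfis(fp, miner)
  say(length(seps), " side-effect profiles mined")
  stats <- sep_statistics(seps)

  todo <- if (is.null(max_seps)) seps else utils::head(seps, max_seps)
  models <- lapply(todo, function(sep) {
    say("characterizing ", sep$id)
    ls <- build_learning_set(fp, sep)
    out <- list(sep = sep, learning_set = ls, tree = NULL,
                theory = NULL, cv_dt = NULL, cv_ilp = NULL)
    if ("dt" %in% learners) {
      tab <- build_attribute_table(kb, ls)
      out$tree <- learn_tree(tab, min_leaf = dt_min_leaf, cf = dt_cf)
      if (cv) {
        out$cv_dt <- stratified_cv(
          ls, dt_trainer(kb, dt_min_leaf, dt_cf),
          folds = folds, runs = runs, seed = seed)
      }
    }
    if ("ilp" %in% learners) {
      out$theory <- induce_cover(ls$positives, ls$negatives, kb, ilp,
                                 modes, sep_id = sep$id)
      if (cv) {
        out$cv_ilp <- stratified_cv(
          ls, ilp_trainer(kb, ilp, modes),
          folds = folds, runs = runs, seed = seed)
      }
    }
    out
  })
  structure(list(clustering = clustering, fingerprints = fp,
                 seps = seps, stats = stats, models = models),
            class = "sep_pipeline")
}

#' @export
print.sep_pipeline <- function(x, ...) {
  cat("Side-effect profile pipeline\n")
  cat("  ", x$clustering$k, " term clusters; ", nrow(x$fingerprints),
      " drugs x ", ncol(x$fingerprints), " TCs\n", sep = "")
  cat("  ", length(x$seps), " profiles; ", length(x$models),
      " characterized\n", sep = "")
  invisible(x)
}
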
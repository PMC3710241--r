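#' Ward agglomeration of a distance matrix
#'
#' Runs Ward's minimum-variance agglomeration via the Lance-Williams
#' recurrence applied to squared distances (the `ward.D` update on
#' `d^2`), the linkage used to group side-effect terms into term
#' clusters.
#'
#' @param dist Square symmetric numeric matrix with zero diagonal, or a
#'   `dist` object.
#' @return An [stats::hclust] tree (`n - 1` merges with non-decreasing
#'   heights).
#' @export
ward_cluster <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop("dist must be a square matrix", call. = FALSE)
  }
  if (max(abs(dist - t(dist))) > 1e-8) {
    stop("dist must be symmetric", call. = FALSE)
  }
  if (any(diag(dist) != 0)) {
    stop("dist must have a zero diagonal", call. = FALSE)
  }
  if (nrow(dist) < 2L) stop("need at least two points", call. = FALSE)
  stats::hclust(stats::as.dist(dist^2), method = "ward.D")
}

#' Select the number of clusters by the Kelley-Gardner-Sutcliffe penalty
#'
#' At every cut level with `k` clusters (`k = 2, ..., n - 1`) the
#' average spread is the mean, over clusters of two or more members, of
#' the mean within-cluster pairwise distance.  The spreads are min-max
#' normalized onto `[1, n - 2]` (all mapped to 1 when they are all
#' equal) and `k` is added; the level minimizing this penalty is
#' returned, ties resolved toward the smaller `k` (coarser clustering).
#'
#' @param hc An [stats::hclust] tree from [ward_cluster()].
#' @param dist The distance matrix the tree was built from (original,
#'   unsquared distances).
#' @return The selected cluster count, with the full penalty profile in
#'   attribute `"penalty"`.
#' @export
select_k <- function(hc, dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  n <- nrow(dist)
  if (n < 3L) stop("need at least 3 points to select a cut", call. = FALSE)
  ks <- 2:(n - 1L)
  spread <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    per <- vapply(split(seq_len(n), cl), function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      sub <- dist[idx, idx, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, 0)
    mean(per, na.rm = TRUE)
  }, 0)
  rng <- range(spread)
  norm <- if (diff(rng) == 0) {
    rep(1, length(spread))
  } else {
    1 + (n - 3) * (spread - rng[1L]) / diff(rng)
  }
  penalty <- norm + ks
  k <- ks[which.min(penalty)]  # which.min takes the first, i.e. smaller k
  attr(k, "penalty") <- stats::setNames(penalty, ks)
  k
}

#' Group side-effect terms into named term clusters
#'
#' The core grouping step: pairwise semantic similarities are turned
#' into distances (`1 - sim`), Ward-agglomerated, and cut either at a
#' user-supplied `k` or at the Kelley-Gardner-Sutcliffe optimum.  Each
#' term cluster (TC) is indexed in dendrogram order and named
#' `"<index>_<representative>"`, the representative being the cluster
#' medoid (maximum average similarity to co-members; ties broken by the
#' lexicographically smallest label).
#'
#' @param terms Term ids to cluster (subset of `h$terms`).
#' @param h A [term_hierarchy()].
#' @param k Optional cluster-count override (`2 <= k <= length(terms)`;
#'   `k = length(terms)` puts every term in its own cluster).
#' @return An object of class `sep_tc` (a term clustering): a list with
#'   `clusters` (each with `index`, `representative`, `name`, `members`,
#'   `size`), the selected `k`, and the source term set.
#' @export
build_term_clusters <- function(terms, h, k = NULL) {
  missing <- setdiff(terms, h$terms)
  if (length(missing)) {
    stop("term(s) not in hierarchy: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  terms <- unique(as.character(terms))
  n <- length(terms)
  if (n < 2L) stop("need at least two terms to cluster", call. = FALSE)
  if (!is.null(k) && (k > n || k < 1L)) {
    stop("k must be between 1 and the number of terms (", n, ")",
         call. = FALSE)
  }
  sim <- similarity_matrix(h, terms)
  d <- 1 - sim
  hc <- ward_cluster(d)
  if (is.null(k)) k <- as.integer(select_k(hc, d))
  assign <- stats::cutree(hc, k = k)

  ## index clusters 1..k by first appearance in dendrogram leaf order
  leaf_order <- hc$order
  first_seen <- unique(assign[leaf_order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  assign <- relabel[as.character(assign)]

  clusters <- lapply(seq_len(k), function(i) {
    members <- terms[assign == i]
    if (length(members) == 1L) {
      rep_term <- members
    } else {
      avg_sim <- rowMeans(sim[members, members, drop = FALSE])
      best <- avg_sim == max(avg_sim)
      cand <- members[best]
      rep_term <- cand[order(h$labels[cand], cand)][1L]
    }
    rep_label <- gsub("[ \t]", "_", h$labels[[rep_term]])
    list(index = i, representative = rep_term,
         name = paste0(i, "_", rep_label),
         members = members, size = length(members))
  })
  structure(list(clusters = clusters, k = k, terms = terms),
            class = "sep_tc")
}

#' @export
print.sep_tc <- function(x, ...) {
  cat("Term clustering:", x$k, "term clusters over", length(x$terms),
      "terms\n")
  sizes <- vapply(x$clusters, `[[`, 0L, "size")
  cat("  sizes:", paste(range(sizes), collapse = "-"), "(min-max)\n")
  for (cl in utils::head(x$clusters, 8L)) {
    cat("  ", cl$name, " (k=", cl$size, ")\n", sep = "")
  }
  if (x$k > 8L) cat("  ...\n")
  invisible(x)
}

#' Term-cluster display names
#'
#' @param tc A `sep_tc` clustering.
#' @return Character vector `"<index>_<representative label>"`.
#' @export
tc_names <- function(tc) {
  vapply(tc$clusters, `[[`, "", "name")
}

#' Term-cluster sizes `k_i`
#'
#' @param tc A `sep_tc` clustering.
#' @return Integer vector of member counts, one per cluster.
#' @export
tc_sizes <- function(tc) {
  vapply(tc$clusters, `[[`, 0L, "size")
}

#' Export a term clustering as TSV
#'
#' Columns: `tc_index`, `representative`, `member_term`.
#'
#' @param tc A `sep_tc`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_term_clusters <- function(tc, path) {
  rows <- do.call(rbind, lapply(tc$clusters, function(cl) {
    data.frame(tc_index = cl$index, representative = cl$representative,
               member_term = cl$members, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
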
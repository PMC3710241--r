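#' Association heuristic configuration
#'
#' Controls the size-dependent threshold that associates a drug with a
#' term cluster: cluster sizes `k_i` are grouped into intervals of
#' `interval_width` terms and the required number of annotating
#' side-effect terms `n_i` grows by one per interval, capped at
#' `n_max`.  With the defaults (width 5, cap 5) sizes 1-5 require one
#' term, 6-10 two, ..., and 21 or more require five.
#'
#' @param interval_width Terms per interval (default 5).
#' @param n_max Cap on the required count (default 5).
#' @return An object of class `sep_assoc_config`.
#' @export
assoc_config <- function(interval_width = 5L, n_max = 5L) {
  if (interval_width < 1L || n_max < 1L) {
    stop("interval_width and n_max must be >= 1", call. = FALSE)
  }
  structure(list(interval_width = as.integer(interval_width),
                 n_max = as.integer(n_max)),
            class = "sep_assoc_config")
}

#' Minimal side-effect count required to assign a term cluster
#'
#' `n_i = min(n_max, ceiling(k_i / interval_width))`.
#'
#' @param k_i Term-cluster size(s), `>= 1` (vectorized).
#' @param cfg An [assoc_config()].
#' @return Integer vector of required counts `n_i`.
#' @examples
#' min_se_count(c(2, 7, 20, 21, 59))  # 1 2 4 5 5
#' @export
min_se_count <- function(k_i, cfg = assoc_config()) {
  if (any(k_i < 1L)) stop("k_i must be >= 1", call. = FALSE)
  pmin(cfg$n_max, as.integer(ceiling(k_i / cfg$interval_width)))
}

#' Build the binary drug x term-cluster fingerprint table
#'
#' A drug is associated with term cluster `TC_i` (cell set to 1) when at
#' least `n_i` of its annotated side-effect terms fall inside the
#' cluster, `n_i` given by [min_se_count()].  Annotation terms missing
#' from the clustering's term universe are ignored; their count is kept
#' in the `"skipped_terms"` attribute.
#'
#' @param side_effects Named list mapping drug id to a character vector
#'   of side-effect term ids.
#' @param clustering A `sep_tc` term clustering.
#' @param cfg An [assoc_config()].
#' @return A binary integer matrix of class `sep_fingerprints` (rows =
#'   drugs, columns = term clusters, column names from [tc_names()]),
#'   with attributes `tc_index` and `skipped_terms`.
#' @export
build_fingerprints <- function(side_effects, clustering,
                               cfg = assoc_config()) {
  if (!inherits(clustering, "sep_tc") || !length(clustering$clusters)) {
    stop("empty or invalid clustering", call. = FALSE)
  }
  drugs <- names(side_effects)
  universe <- clustering$terms
  skipped <- 0L
  k <- clustering$k
  n_req <- min_se_count(tc_sizes(clustering), cfg)
  members <- lapply(clustering$clusters, `[[`, "members")
  m <- matrix(0L, nrow = length(drugs), ncol = k,
              dimnames = list(drugs, tc_names(clustering)))
  for (d in seq_along(drugs)) {
    terms <- unique(side_effects[[d]])
    known <- terms[terms %in% universe]
    skipped <- skipped + (length(terms) - length(known))
    if (!length(known)) next
    hits <- vapply(members, function(mem) sum(known %in% mem), 0L)
    m[d, ] <- as.integer(hits >= n_req)
  }
  structure(m, tc_index = seq_len(k), skipped_terms = skipped,
            class = c("sep_fingerprints", "matrix", "array"))
}

#' Drop term clusters covering more than a fraction of the drugs
#'
#' Columns whose coverage is strictly greater than
#' `fraction * nrow(table)` are removed before profile mining; ties at
#' exactly the fraction are kept.  The operation is idempotent.
#'
#' @param table A `sep_fingerprints` binary matrix.
#' @param fraction Coverage cutoff in `(0, 1)` (default 0.5).
#' @return The filtered table (rows unchanged).
#' @export
filter_prevalent <- function(table, fraction = 0.5) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  keep <- colSums(table) <= fraction * nrow(table)
  out <- table[, keep, drop = FALSE]
  structure(out, tc_index = attr(table, "tc_index")[keep],
            skipped_terms = attr(table, "skipped_terms"),
            class = class(table))
}

#' @export
print.sep_fingerprints <- function(x, ...) {
  cat("Drug x TC fingerprint table:", nrow(x), "drugs x", ncol(x),
      "term clusters; density",
      signif(mean(x), 3L), "\n")
  invisible(x)
}

#' Export a fingerprint table as TSV
#'
#' First column `drug_id`, then one 0/1 column per term cluster.
#'
#' @param table A `sep_fingerprints` matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(table, path) {
  df <- data.frame(drug_id = rownames(table),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
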
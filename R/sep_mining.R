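#' Miner configuration for side-effect profiles
#'
#' A side-effect profile (SEP) is a maximal frequent itemset (MFI) of
#' term clusters: a TC combination shared by at least `min_support`
#' drugs, none of whose proper supersets is also frequent.  The support
#' threshold is given either as an absolute drug count or as a fraction
#' of the drug set (default 20%), resolved per table as
#' `ceiling(fraction * n_drugs)`.
#'
#' @param min_support Optional absolute support threshold (overrides the
#'   fraction).
#' @param support_fraction Fraction of drugs an itemset must cover
#'   (default 0.2).
#' @param prevalence_cutoff Fraction passed to [filter_prevalent()] by
#'   pipeline drivers (default 0.5).
#' @return An object of class `sep_miner_config`.
#' @export
miner_config <- function(min_support = NULL, support_fraction = 0.2,
                         prevalence_cutoff = 0.5) {
  if (!is.null(min_support) && min_support < 1L) {
    stop("min_support must be >= 1", call. = FALSE)
  }
  structure(list(min_support = min_support,
                 support_fraction = support_fraction,
                 prevalence_cutoff = prevalence_cutoff),
            class = "sep_miner_config")
}

.resolve_min_support <- function(table, cfg) {
  ms <- if (!is.null(cfg$min_support)) {
    as.integer(cfg$min_support)
  } else {
    as.integer(ceiling(cfg$support_fraction * nrow(table)))
  }
  if (ms > nrow(table)) {
    stop("min_support (", ms, ") exceeds drug count (", nrow(table), ")",
         call. = FALSE)
  }
  max(1L, ms)
}

.new_sep <- function(tcs, tc_labels, support, covered, id = NA_character_) {
  structure(list(id = id, tcs = tcs, tc_names = tc_labels,
                 support = support, covered = covered),
            class = "sep_profile")
}

#' @export
format.sep_profile <- function(x, ...) {
  paste0(if (!is.na(x$id)) paste0(x$id, ": ") else "",
         paste(x$tc_names, collapse = ", "),
         " (support ", x$support, ")")
}

#' @export
print.sep_profile <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## order: support descending, then lexicographic on the TC index vector
.order_seps <- function(seps) {
  if (!length(seps)) return(seps)
  sup <- vapply(seps, `[[`, 0L, "support")
  key <- vapply(seps, function(s) {
    paste(sprintf("%08d", s$tcs), collapse = ",")
  }, "")
  seps <- seps[order(-sup, key)]
  for (i in seq_along(seps)) seps[[i]]$id <- paste0("SEP_", i)
  seps
}

.sep_from_cols <- function(cols, tids, table) {
  tc_index <- attr(table, "tc_index")
  if (is.null(tc_index)) tc_index <- seq_len(ncol(table))
  cols <- sort(cols)
  labels <- colnames(table)
  if (is.null(labels)) labels <- paste0("TC", seq_len(ncol(table)))
  covered <- if (is.null(rownames(table))) tids else rownames(table)[tids]
  .new_sep(tcs = tc_index[cols], tc_labels = labels[cols],
           support = length(tids), covered = covered)
}

#' Mine side-effect profiles as maximal frequent itemsets
#'
#' Depth-first search over the itemset lattice with tidset (row-set)
#' intersection for support counting, support-based pruning, and a
#' superset check against already-found MFIs for maximality.  The empty
#' itemset is never reported.  Output order is deterministic: support
#' descending, then lexicographic on the TC index sets; ids `SEP_1`,
#' `SEP_2`, ... follow that order.
#'
#' @param table A binary `sep_fingerprints` matrix (drugs x TCs),
#'   typically after [filter_prevalent()].
#' @param cfg A [miner_config()].
#' @return List of `sep_profile` objects (`id`, `tcs`, `tc_names`,
#'   `support`, `covered`).
#' @export
mine_mfis <- function(table, cfg = miner_config()) {
  if (nrow(table) == 0L || ncol(table) == 0L) return(list())
  minsup <- .resolve_min_support(table, cfg)
  ncols <- ncol(table)
  tids <- lapply(seq_len(ncols), function(j) which(table[, j] == 1L))
  sup <- lengths(tids)
  items <- order(sup, seq_len(ncols))
  items <- items[sup[items] >= minsup]
  if (!length(items)) return(list())

  mfis <- list()
  subset_of_found <- function(set) {
    for (m in mfis) if (all(set %in% m$items)) return(TRUE)
    FALSE
  }
  dfs <- function(head, htids, tail) {
    keep <- integer(0)
    exts <- list()
    for (e in tail) {
      t2 <- if (is.null(htids)) tids[[e]] else intersect(htids, tids[[e]])
      if (length(t2) >= minsup) {
        keep[length(keep) + 1L] <- e
        exts[[length(exts) + 1L]] <- t2
      }
    }
    if (!length(keep)) {
      if (length(head) && !subset_of_found(head)) {
        mfis[[length(mfis) + 1L]] <<- list(items = sort(head),
                                           tids = htids)
      }
      return(invisible(NULL))
    }
    for (i in seq_along(keep)) {
      dfs(c(head, keep[i]), exts[[i]],
          if (i < length(keep)) keep[seq.int(i + 1L, length(keep))]
          else integer(0))
    }
    invisible(NULL)
  }
  dfs(integer(0), NULL, items)

  .order_seps(lapply(mfis, function(m) {
    .sep_from_cols(m$items, m$tids, table)
  }))
}

#' Exhaustive maximal-frequent-itemset oracle
#'
#' Enumerates every non-empty itemset over the table's columns, keeps
#' the frequent ones, and discards any with a frequent proper superset.
#' Intended as an independent correctness oracle for [mine_mfis()] on
#' small tables.
#'
#' @param table Binary matrix with at most 20 columns.
#' @param cfg A [miner_config()].
#' @return List of `sep_profile` objects in the same deterministic order
#'   as [mine_mfis()].
#' @export
brute_force_mfis <- function(table, cfg = miner_config()) {
  if (ncol(table) > 20L) {
    stop("brute_force_mfis refuses tables with more than 20 columns",
         call. = FALSE)
  }
  if (nrow(table) == 0L || ncol(table) == 0L) return(list())
  minsup <- .resolve_min_support(table, cfg)
  m <- ncol(table)
  rowmask <- as.integer(table %*% (2^(seq_len(m) - 1L)))
  masks <- seq_len(2^m - 1L)
  support <- vapply(masks, function(mask) {
    sum(bitwAnd(rowmask, mask) == mask)
  }, 0L)
  freq <- masks[support >= minsup]
  if (!length(freq)) return(list())
  maximal <- vapply(freq, function(mask) {
    sup_sets <- freq[bitwAnd(freq, mask) == mask]
    all(sup_sets == mask)
  }, TRUE)
  .order_seps(lapply(freq[maximal], function(mask) {
    cols <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    tids_ <- which(bitwAnd(rowmask, mask) == mask)
    .sep_from_cols(cols, tids_, table)
  }))
}

#' Summary statistics of a set of side-effect profiles
#'
#' @param seps List of `sep_profile` objects (e.g. from [mine_mfis()] or
#'   [read_sep_table()]).
#' @return A list of class `sep_stats`: profile count, number of
#'   distinct TCs involved, profile-length histogram, per-TC frequency
#'   (how many profiles each TC appears in), support range, and -- when
#'   the profiles carry covered drug sets -- the maximum number of drugs
#'   jointly covered by any two distinct profiles (drugs containing the
#'   union of both TC sets).
#' @export
sep_statistics <- function(seps) {
  if (!length(seps)) {
    return(structure(list(n_seps = 0L, n_distinct_tcs = 0L,
                          length_histogram = integer(0),
                          tc_frequency = integer(0),
                          min_support = NA_integer_,
                          max_support = NA_integer_,
                          max_joint_coverage = NA_integer_),
                     class = "sep_stats"))
  }
  lens <- vapply(seps, function(s) length(s$tcs), 0L)
  all_names <- unlist(lapply(seps, `[[`, "tc_names"), use.names = FALSE)
  freq <- sort(table(all_names), decreasing = TRUE)
  sup <- vapply(seps, `[[`, 0L, "support")
  covered <- lapply(seps, `[[`, "covered")
  max_joint <- NA_integer_
  if (length(seps) >= 2L && !any(vapply(covered, is.null, TRUE))) {
    max_joint <- 0L
    for (i in seq_len(length(seps) - 1L)) {
      for (j in seq.int(i + 1L, length(seps))) {
        max_joint <- max(max_joint,
                         length(intersect(covered[[i]], covered[[j]])))
      }
    }
  }
  structure(list(
    n_seps = length(seps),
    n_distinct_tcs = length(unique(all_names)),
    length_histogram = table(factor(lens, levels = seq_len(max(lens)))),
    tc_frequency = freq,
    min_support = min(sup),
    max_support = max(sup),
    max_joint_coverage = max_joint
  ), class = "sep_stats")
}

#' @export
print.sep_stats <- function(x, ...) {
  cat("Side-effect profile statistics\n")
  cat("  profiles:", x$n_seps, " distinct TCs:", x$n_distinct_tcs, "\n")
  if (x$n_seps > 0L) {
    hist <- x$length_histogram[x$length_histogram > 0L]
    cat("  length histogram:",
        paste(names(hist), hist, sep = ":", collapse = "  "), "\n")
    cat("  support:", x$min_support, "-", x$max_support, "\n")
    cat("  most frequent TCs:",
        paste(utils::head(names(x$tc_frequency), 3L),
              utils::head(x$tc_frequency, 3L), sep = " x",
              collapse = ", "), "\n")
    if (!is.na(x$max_joint_coverage)) {
      cat("  max pairwise joint coverage:", x$max_joint_coverage, "\n")
    }
  }
  invisible(x)
}

#' Read a side-effect profile table from TSV
#'
#' Expects columns `sep` (id), `composition` (comma-separated TC names
#' of the form `<index>_<representative>`), `support`, and optionally
#' `avg_overlap` (parsed into the `avg_overlap` field but not
#' recomputed by any operation).  The packaged fixture
#' `system.file("extdata", "table1_seps.tsv", package = "sepminer")`
#' transcribes the 26 reference profiles.
#'
#' @param path TSV file.
#' @return List of `sep_profile` objects (no covered drug sets).
#' @export
read_sep_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  lapply(seq_len(nrow(df)), function(i) {
    parts <- trimws(strsplit(df$composition[i], ",")[[1L]])
    idx <- as.integer(sub("_.*$", "", parts))
    sep <- .new_sep(tcs = idx, tc_labels = parts,
                    support = as.integer(df$support[i]),
                    covered = NULL, id = df$sep[i])
    if (!is.null(df$avg_overlap)) {
      sep$avg_overlap <- as.integer(df$avg_overlap[i])
    }
    sep
  })
}

#' Export side-effect profiles as TSV
#'
#' Columns `sep`, `composition`, `support` (the reference-table layout).
#'
#' @param seps List of `sep_profile` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sep_table <- function(seps, path) {
  df <- data.frame(
    sep = vapply(seps, `[[`, "", "id"),
    composition = vapply(seps, function(s) {
      paste(s$tc_names, collapse = ", ")
    }, ""),
    support = vapply(seps, `[[`, 0L, "support")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
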
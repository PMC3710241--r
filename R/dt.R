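#' Build the single-table attribute representation of a learning set
#'
#' Encodes each drug of a learning set as a binary attribute-value
#' vector derived from the knowledge base: one indicator per drug
#' category, three per known drug target (activation, inhibition,
#' other), and one per structural-cluster membership (method-tagged),
#' plus the class column (`pos` / `neg`) in first position.  A drug
#' with no facts yields an all-zero feature row.
#'
#' @param kb A `sep_kb`.
#' @param learning_set A `sep_learning_set` from [build_learning_set()],
#'   or any list with `positives` and `negatives` character vectors.
#' @return A data frame of class `sep_attr_table`: `class` factor with
#'   levels `c("neg", "pos")` followed by 0/1 integer attributes.
#' @export
build_attribute_table <- function(kb, learning_set) {
  drugs <- c(learning_set$positives, learning_set$negatives)
  labels <- factor(rep(c("pos", "neg"),
                       c(length(learning_set$positives),
                         length(learning_set$negatives))),
                   levels = c("neg", "pos"))
  absent <- setdiff(drugs, kb$drugs)
  if (length(absent)) {
    stop("drug(s) absent from knowledge base: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  safe <- function(x) gsub("[^A-Za-z0-9_]", ".", x)

  dht <- kb$facts$drug_has_target
  targets <- sort(unique(dht[, 2L]))
  cat_facts <- kb$facts$category
  clu <- kb$facts$drug_cluster
  clu_keys <- character(0)
  if (nrow(clu)) {
    clu_keys <- sort(unique(paste(clu[, 3L], clu[, 2L], sep = "\r")))
  }

  n <- length(drugs)
  cols <- list(class = labels)
  for (categ in kb$categories) {
    has <- cat_facts[cat_facts[, 2L] == categ, 1L]
    cols[[paste0("cat_", safe(categ))]] <- as.integer(drugs %in% has)
  }
  action_suffix <- c(activator = "activation", inhibitor = "inhibition",
                     other = "other")
  for (tgt in targets) {
    sub <- dht[dht[, 2L] == tgt, , drop = FALSE]
    for (act in names(action_suffix)) {
      has <- sub[sub[, 3L] == act, 1L]
      cols[[paste0("tgt_", safe(tgt), "_", action_suffix[[act]])]] <-
        as.integer(drugs %in% has)
    }
  }
  for (key in clu_keys) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    has <- clu[clu[, 3L] == parts[1L] & clu[, 2L] == parts[2L], 1L]
    cols[[paste0("clu_", safe(parts[1L]), "_", safe(parts[2L]))]] <-
      as.integer(drugs %in% has)
  }
  out <- data.frame(cols, check.names = FALSE,
                    row.names = make.unique(drugs))
  attr(out, "drug_ids") <- drugs
  class(out) <- c("sep_attr_table", "data.frame")
  out
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

## candidate binary splits (attribute == value vs rest) scored by gain
## ratio; both children must hold >= min_leaf rows
.best_split <- function(x, cls, min_leaf) {
  n <- nrow(x)
  h <- .entropy(table(cls))
  best <- NULL
  for (j in seq_along(x)) {
    vals <- sort(unique(as.character(x[[j]])))
    if (length(vals) < 2L) next
    ## for two-valued attributes both splits are equivalent: test the
    ## larger value so 0/1 attributes read "attr == 1"
    if (length(vals) == 2L) vals <- vals[2L]
    for (v in vals) {
      eq <- as.character(x[[j]]) == v
      n1 <- sum(eq)
      if (n1 < min_leaf || n - n1 < min_leaf) next
      h1 <- .entropy(table(cls[eq]))
      h0 <- .entropy(table(cls[!eq]))
      gain <- h - (n1 * h1 + (n - n1) * h0) / n
      if (gain <= 1e-12) next
      p1 <- n1 / n
      split_info <- -(p1 * log2(p1) + (1 - p1) * log2(1 - p1))
      gr <- gain / split_info
      if (is.null(best) || gr > best$gr + 1e-12) {
        best <- list(j = j, value = v, gr = gr, eq = eq)
      }
    }
  }
  best
}

## C4.5 pessimistic upper bound on the error rate of a leaf
.ucf <- function(errors, n, cf) {
  if (n == 0L) return(0)
  stats::qbeta(1 - cf, errors + 1, n - errors)
}

.grow_tree <- function(x, cls, min_leaf) {
  counts <- table(cls)
  majority <- names(counts)[which.max(counts)]
  if (length(unique(cls)) == 1L || nrow(x) < 2L * min_leaf) {
    return(list(kind = "leaf", class = majority,
                counts = as.integer(counts),
                count_names = names(counts)))
  }
  best <- .best_split(x, cls, min_leaf)
  if (is.null(best)) {
    return(list(kind = "leaf", class = majority,
                counts = as.integer(counts),
                count_names = names(counts)))
  }
  list(kind = "split", attr = names(x)[best$j], value = best$value,
       counts = as.integer(counts), count_names = names(counts),
       majority = majority,
       eq = .grow_tree(x[best$eq, , drop = FALSE], cls[best$eq], min_leaf),
       ne = .grow_tree(x[!best$eq, , drop = FALSE], cls[!best$eq],
                       min_leaf))
}

.prune_tree <- function(node, cf) {
  if (node$kind == "leaf") {
    n <- sum(node$counts)
    e <- n - max(node$counts)
    node$est_errors <- n * .ucf(e, n, cf)
    return(node)
  }
  node$eq <- .prune_tree(node$eq, cf)
  node$ne <- .prune_tree(node$ne, cf)
  subtree_est <- node$eq$est_errors + node$ne$est_errors
  n <- sum(node$counts)
  e <- n - max(node$counts)
  leaf_est <- n * .ucf(e, n, cf)
  if (leaf_est <= subtree_est + 1e-8) {
    return(list(kind = "leaf", class = node$majority,
                counts = node$counts, count_names = node$count_names,
                est_errors = leaf_est))
  }
  node$est_errors <- subtree_est
  node
}

#' Learn a binary-split decision tree
#'
#' Greedy top-down induction in the C4.5 style restricted to binary
#' (value-vs-rest) tests on nominal attributes: at each node the test
#' maximizing the gain ratio is chosen among splits leaving at least
#' `min_leaf` rows in each child; ties go to the earliest column (then
#' earliest value).  A constant-class table yields a single leaf.
#' Optional bottom-up pessimistic-error pruning uses the C4.5 binomial
#' upper confidence bound at confidence `cf`.
#'
#' @param table A `sep_attr_table` (or any data frame whose first/`class`
#'   column is the class factor).
#' @param min_leaf Minimum rows per child (default 5).
#' @param cf Pruning confidence (default 0.25).
#' @param prune Apply pessimistic pruning (default `TRUE`).
#' @return An object of class `sep_dtree`.
#' @export
learn_tree <- function(table, min_leaf = 5L, cf = 0.25, prune = TRUE) {
  cls_col <- if ("class" %in% names(table)) "class" else names(table)[1L]
  cls <- factor(table[[cls_col]])
  x <- table[setdiff(names(table), cls_col)]
  if (nrow(x) < 1L) stop("empty table", call. = FALSE)
  root <- .grow_tree(x, cls, as.integer(min_leaf))
  if (prune) root <- .prune_tree(root, cf)
  structure(list(root = root, min_leaf = as.integer(min_leaf), cf = cf,
                 pruned = prune, class_levels = levels(cls)),
            class = "sep_dtree")
}

#' Classify rows with a decision tree
#'
#' Each row is routed down the tree; a missing tested attribute sends
#' the row to the not-equals branch.
#'
#' @param tree A `sep_dtree`.
#' @param newdata Data frame of attribute values (a `class` column, if
#'   present, is ignored).
#' @return Character vector of predicted classes, one per row.
#' @export
predict_tree <- function(tree, newdata) {
  walk <- function(node, row) {
    if (node$kind == "leaf") return(node$class)
    v <- row[[node$attr]]
    if (is.null(v) || is.na(v)) return(walk(node$ne, row))
    if (as.character(v) == node$value) walk(node$eq, row)
    else walk(node$ne, row)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    walk(tree$root, newdata[i, , drop = FALSE])
  }, "")
}

.format_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$kind == "leaf") {
    return(paste0(pad, "-> ", node$class, " (",
                  paste(node$count_names, node$counts, sep = "=",
                        collapse = ", "), ")"))
  }
  c(paste0(pad, node$attr, " == ", node$value, ":"),
    .format_node(node$eq, indent + 1L),
    paste0(pad, node$attr, " != ", node$value, ":"),
    .format_node(node$ne, indent + 1L))
}

#' @export
format.sep_dtree <- function(x, ...) {
  paste(.format_node(x$root, 0L), collapse = "\n")
}

#' @export
print.sep_dtree <- function(x, ...) {
  cat("Binary-split decision tree (min_leaf=", x$min_leaf,
      if (x$pruned) ", pruned" else ", unpruned", ")\n", sep = "")
  cat(format(x), "\n")
  invisible(x)
}

#' Number of nodes in a decision tree
#' @param tree A `sep_dtree`.
#' @return Integer node count (internal nodes plus leaves).
#' @export
tree_size <- function(tree) {
  count <- function(node) {
    if (node$kind == "leaf") return(1L)
    1L + count(node$eq) + count(node$ne)
  }
  count(tree$root)
}

#' Export an attribute table in ARFF format
#'
#' Writes the Weka-style ARFF representation of a [build_attribute_table()]
#' result (all attributes nominal).  Requires the `foreign` package.
#'
#' @param table A `sep_attr_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_attr_arff <- function(table, path) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("the 'foreign' package is required for ARFF export",
         call. = FALSE)
  }
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    if (!is.factor(df[[j]])) df[[j]] <- factor(df[[j]], levels = c(0L, 1L))
  }
  foreign::write.arff(df, path)
  invisible(path)
}

#' Serialize a decision tree to JSON
#'
#' @param tree A `sep_dtree`.
#' @return A JSON string (nested nodes with attribute, test value,
#'   branches, class counts).
#' @export
tree_to_json <- function(tree) {
  strip <- function(node) {
    node$est_errors <- NULL
    if (node$kind == "split") {
      node$eq <- strip(node$eq)
      node$ne <- strip(node$ne)
    }
    node
  }
  jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, pretty = TRUE)
}
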
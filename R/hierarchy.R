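#' Build a side-effect term hierarchy
#'
#' The hierarchy is a rooted directed acyclic graph of side-effect terms
#' (child -> parent edges tagged `is_a` or `part_of`), the structure a
#' MedDRA-style vocabulary exposes.  Terms may have several parents;
#' roots are the terms with no parent.
#'
#' @param child,parent Character vectors of term ids (edge list).
#' @param relation Relation types, each `"is_a"` or `"part_of"`
#'   (recycled if scalar).
#' @param labels Optional named character vector mapping term id to a
#'   human-readable label; unnamed terms use their id as label.
#' @return An object of class `sep_hierarchy` with elements `terms`,
#'   `labels`, `edges`, `roots`, and precomputed `depth` (shortest edge
#'   count to the nearest root) and `ancestors` (each term's ancestor
#'   set, itself included).
#' @export
term_hierarchy <- function(child, parent, relation = "is_a",
                           labels = NULL) {
  child <- as.character(child)
  parent <- as.character(parent)
  relation <- rep_len(as.character(relation), length(child))
  bad <- setdiff(unique(relation), .valid_go_relations)
  if (length(child) && length(bad)) {
    stop("invalid relation type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  edges <- data.frame(child = child, parent = parent, relation = relation,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges), , drop = FALSE]
  terms <- sort(unique(c(edges$child, edges$parent, names(labels))))
  if (!length(terms)) stop("empty hierarchy", call. = FALSE)

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = data.frame(name = terms)
  )
  if (!igraph::is_dag(g)) {
    stop("term hierarchy contains a cycle", call. = FALSE)
  }
  roots <- terms[igraph::degree(g, mode = "out") == 0L]

  ## depth: shortest child->parent path to any root
  d <- igraph::distances(g, v = terms, to = roots, mode = "out")
  depth <- apply(d, 1L, min)
  if (any(!is.finite(depth))) {
    stop("term(s) not connected to a root: ",
         paste(utils::head(terms[!is.finite(depth)], 5L), collapse = ", "),
         call. = FALSE)
  }
  names(depth) <- terms

  anc <- lapply(igraph::ego(g, order = length(terms), nodes = terms,
                            mode = "out"),
                function(v) v$name)
  names(anc) <- terms

  lab <- stats::setNames(terms, terms)
  if (!is.null(labels)) lab[names(labels)] <- labels

  structure(
    list(terms = terms, labels = lab, edges = edges, roots = roots,
         depth = depth, ancestors = anc),
    class = "sep_hierarchy"
  )
}

#' @export
print.sep_hierarchy <- function(x, ...) {
  cat("Side-effect term hierarchy:", length(x$terms), "terms,",
      nrow(x$edges), "edges,", length(x$roots), "root(s), max depth",
      max(x$depth), "\n")
  invisible(x)
}

#' Read a term hierarchy from an OBO file
#'
#' Minimal stanza reader covering `[Term]` blocks with `id`, `name`,
#' `is_a` and `relationship: part_of` lines; an alternative to the
#' `hierarchy.tsv` edge-list input.
#'
#' @param path Path to an OBO file.
#' @return A `sep_hierarchy`.
#' @export
read_obo_hierarchy <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  child <- parent <- relation <- character(0)
  labels <- character(0)
  id <- NULL
  in_term <- FALSE
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; id <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^name:", ln) && !is.null(id)) {
      labels[id] <- trimws(sub("^name:", "", ln))
    } else if (grepl("^is_a:", ln) && !is.null(id)) {
      child <- c(child, id)
      parent <- c(parent, trimws(sub("^is_a:", "", ln)))
      relation <- c(relation, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln) && !is.null(id)) {
      child <- c(child, id)
      parent <- c(parent, trimws(sub("^relationship:\\s*part_of", "", ln)))
      relation <- c(relation, "part_of")
    }
  }
  term_hierarchy(child, parent, relation, labels = labels)
}

#' Hierarchy-based semantic similarity between two terms
#'
#' Wu-Palmer similarity generalized to a DAG:
#' \deqn{sim(a, b) = \max_{c \in anc(a) \cap anc(b)}
#'       \frac{2\,depth(c)}{depth(a) + depth(b)}}
#' where ancestors include the terms themselves, both `is_a` and
#' `part_of` edges count as hierarchy edges, and depth is the shortest
#' edge count from the nearest root.  `sim(a, a) = 1` (by convention
#' also for roots); two terms whose only common ancestor is a root score
#' 0.
#'
#' @param h A [term_hierarchy()].
#' @param a,b Term ids.
#' @return Similarity in `[0, 1]`, symmetric in `a` and `b`.
#' @export
semantic_similarity <- function(h, a, b) {
  for (t in c(a, b)) {
    if (!t %in% h$terms) stop("unknown term '", t, "'", call. = FALSE)
  }
  if (a == b) return(1)
  common <- intersect(h$ancestors[[a]], h$ancestors[[b]])
  if (!length(common)) return(0)
  denom <- h$depth[[a]] + h$depth[[b]]
  if (denom == 0) return(1)  # two roots can only share themselves
  max(2 * h$depth[common] / denom)
}

#' Pairwise semantic similarity matrix
#'
#' @param h A [term_hierarchy()].
#' @param terms Terms to compare (default: all terms of the hierarchy).
#' @return Symmetric matrix of [semantic_similarity()] values with unit
#'   diagonal.
#' @export
similarity_matrix <- function(h, terms = h$terms) {
  missing <- setdiff(terms, h$terms)
  if (length(missing)) {
    stop("unknown term(s): ", paste(utils::head(missing, 5L),
                                    collapse = ", "), call. = FALSE)
  }
  n <- length(terms)
  m <- diag(1, n)
  dimnames(m) <- list(terms, terms)
  if (n < 2L) return(m)
  depth <- h$depth[terms]
  anc <- h$ancestors[terms]
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      common <- intersect(anc[[i]], anc[[j]])
      s <- if (!length(common)) 0 else {
        denom <- depth[[i]] + depth[[j]]
        if (denom == 0) 1 else max(2 * h$depth[common] / denom)
      }
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}
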
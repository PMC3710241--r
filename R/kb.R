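## Fixed predicate vocabulary of the drug/target knowledge base.
## Argument names double as entity roles used for registration.
.pred_spec <- list(
  category        = c("drug", "category"),
  drug_cluster    = c("drug", "cluster", "source"),
  drug_has_target = c("drug", "protein", "action"),
  goterm          = c("protein", "go_term"),
  go_relation     = c("go_term", "relation", "go_parent"),
  interact        = c("protein", "protein2"),
  pathway         = c("protein", "pathway", "source"),
  domain          = c("protein", "domain")
)

.valid_actions <- c("activator", "inhibitor", "other")
.valid_go_relations <- c("is_a", "part_of")

#' Construct a ground atom or query literal
#'
#' A literal is a predicate name applied to constants and/or variables.
#' Variables are written with a leading question mark (`"?A"`); any other
#' string is a constant.  Ground atoms (no variables) are the facts stored
#' in a [knowledge_base()]; literals with variables form conjunctive
#' queries for [kb_match()] and rule bodies for the relational learner.
#'
#' @param predicate Predicate name; must belong to the fixed vocabulary
#'   (`category/2`, `drug_cluster/3`, `drug_has_target/3`, `goterm/2`,
#'   `go_relation/3`, `interact/2`, `pathway/3`, `domain/2`).
#' @param ... Argument strings, one per predicate argument.
#' @return An object of class `sep_literal`.
#' @examples
#' lit("drug_has_target", "?A", "?B", "inhibitor")
#' lit("pathway", "?B", "Endocytosis", "kegg")
#' @export
lit <- function(predicate, ...) {
  args <- as.character(unlist(list(...), use.names = FALSE))
  spec <- .pred_spec[[predicate]]
  if (is.null(spec)) {
    stop("unknown predicate '", predicate, "'", call. = FALSE)
  }
  if (length(args) != length(spec)) {
    stop("predicate '", predicate, "' has arity ", length(spec),
         ", got ", length(args), " arguments", call. = FALSE)
  }
  is_var <- startsWith(args, "?")
  structure(
    list(predicate = predicate, args = args, is_var = is_var,
         vars = ifelse(is_var, substring(args, 2L), NA_character_)),
    class = "sep_literal"
  )
}

#' @export
format.sep_literal <- function(x, ...) {
  args <- ifelse(x$is_var, sub("^\\?", "", x$args),
                 ifelse(grepl("^[A-Za-z0-9_:.]+$", x$args) &
                          !grepl("^[A-Z]", x$args),
                        x$args, paste0("'", x$args, "'")))
  paste0(x$predicate, "(", paste(args, collapse = ","), ")")
}

#' @export
print.sep_literal <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

.lit_vars <- function(l) sub("^\\?", "", l$args[l$is_var])

.validate_fact_values <- function(pred, mat) {
  if (pred == "drug_has_target") {
    bad <- setdiff(unique(mat[, 3L]), .valid_actions)
    if (length(bad)) {
      stop("invalid drug_has_target action(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (pred == "go_relation") {
    bad <- setdiff(unique(mat[, 2L]), .valid_go_relations)
    if (length(bad)) {
      stop("invalid go_relation type(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(NULL)
}

## registry role -> which predicate argument positions feed it
.registry_map <- list(
  drugs      = list(category = 1L, drug_cluster = 1L, drug_has_target = 1L),
  proteins   = list(drug_has_target = 2L, goterm = 1L, interact = c(1L, 2L),
                    pathway = 1L, domain = 1L),
  go_terms   = list(goterm = 2L, go_relation = c(1L, 3L)),
  pathways   = list(pathway = 2L),
  domains    = list(domain = 2L),
  clusters   = list(drug_cluster = 2L),
  categories = list(category = 2L)
)

#' Build a relational knowledge base from ground facts
#'
#' Assembles the indexed fact store consumed by the conjunctive-query
#' engine, the attribute-table builder and the relational rule learner.
#' Facts are deduplicated; `interact/2` is stored symmetrically so that
#' protein-protein interactions can be traversed in either direction;
#' entity registries (drugs, proteins, GO terms, pathways, domains,
#' structural clusters, categories) are derived from the facts.  The GO
#' relation graph is checked for acyclicity within each relation type.
#'
#' @param facts Named list, one element per predicate, each a data frame
#'   or character matrix whose columns are the predicate arguments in
#'   order.  Missing predicates are treated as empty.
#' @param side_effects Optional named list mapping drug id to a character
#'   vector of side-effect term ids.
#' @param hierarchy Optional [term_hierarchy()] the side-effect terms are
#'   drawn from; when supplied, annotation terms absent from it are
#'   rejected.
#' @return An object of class `sep_kb`.
#' @seealso [load_kb()], [kb_match()]
#' @export
knowledge_base <- function(facts = list(), side_effects = NULL,
                           hierarchy = NULL) {
  unknown <- setdiff(names(facts), names(.pred_spec))
  if (length(unknown)) {
    stop("unknown predicate(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  store <- list()
  for (pred in names(.pred_spec)) {
    spec <- .pred_spec[[pred]]
    f <- facts[[pred]]
    if (is.null(f) || NROW(f) == 0L) {
      mat <- matrix(character(0), ncol = length(spec),
                    dimnames = list(NULL, spec))
    } else {
      mat <- as.matrix(as.data.frame(f, stringsAsFactors = FALSE))
      mode(mat) <- "character"
      if (ncol(mat) != length(spec)) {
        stop("predicate '", pred, "' expects ", length(spec),
             " columns, got ", ncol(mat), call. = FALSE)
      }
      colnames(mat) <- spec
      .validate_fact_values(pred, mat)
      if (pred == "interact") {
        mat <- rbind(mat, mat[, c(2L, 1L), drop = FALSE])
        colnames(mat) <- spec
      }
      mat <- mat[!duplicated(apply(mat, 1L, paste, collapse = "\r")), ,
                 drop = FALSE]
    }
    store[[pred]] <- mat
  }

  ## acyclicity of each go_relation type
  gr <- store$go_relation
  for (ty in .valid_go_relations) {
    sub <- gr[gr[, 2L] == ty, , drop = FALSE]
    if (nrow(sub) > 0L) {
      g <- igraph::graph_from_edgelist(sub[, c(1L, 3L), drop = FALSE])
      if (!igraph::is_dag(g)) {
        stop("go_relation graph for type '", ty, "' contains a cycle",
             call. = FALSE)
      }
    }
  }

  registries <- lapply(.registry_map, function(srcs) {
    vals <- unlist(lapply(names(srcs), function(pred) {
      store[[pred]][, srcs[[pred]], drop = TRUE]
    }), use.names = FALSE)
    sort(unique(as.character(vals)))
  })

  if (!is.null(side_effects)) {
    side_effects <- lapply(side_effects, function(x) unique(as.character(x)))
    if (!is.null(hierarchy)) {
      bad <- setdiff(unique(unlist(side_effects, use.names = FALSE)),
                     hierarchy$terms)
      if (length(bad)) {
        stop("side-effect term(s) not in hierarchy: ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      }
    }
    registries$drugs <- sort(unique(c(registries$drugs, names(side_effects))))
  } else {
    side_effects <- list()
  }

  index <- lapply(store, function(mat) {
    if (nrow(mat) == 0L) list() else split(seq_len(nrow(mat)), mat[, 1L])
  })
  cols <- lapply(store, function(mat) {
    lapply(seq_len(ncol(mat)), function(j) mat[, j])
  })

  structure(
    c(list(facts = store, index = index, cols = cols,
           side_effects = side_effects, hierarchy = hierarchy),
      registries),
    class = "sep_kb"
  )
}

#' Number of ground facts in a knowledge base
#'
#' Symmetrized `interact` orientations count once.
#' @param kb A `sep_kb`.
#' @return Integer fact count.
#' @export
kb_n_facts <- function(kb) {
  n <- sum(vapply(kb$facts, nrow, 0L))
  n - nrow(kb$facts$interact) %/% 2L
}

#' @export
print.sep_kb <- function(x, ...) {
  cat("Relational knowledge base\n")
  cat("  drugs:", length(x$drugs), " proteins:", length(x$proteins),
      " GO terms:", length(x$go_terms), "\n")
  cat("  pathways:", length(x$pathways), " domains:", length(x$domains),
      " clusters:", length(x$clusters),
      " categories:", length(x$categories), "\n")
  cat("  facts:", kb_n_facts(x),
      " drugs with side effects:", length(x$side_effects), "\n")
  invisible(x)
}

#' Load a knowledge base from a directory of predicate TSV files
#'
#' Reads one UTF-8 TSV per predicate (`category.tsv`,
#' `drug_has_target.tsv`, `interact.tsv`, `goterm.tsv`,
#' `go_relation.tsv`, `pathway.tsv`, `domain.tsv`, `drug_cluster.tsv`;
#' absent files mean no facts), plus optional `side_effects.tsv`
#' (columns `drug_id`, `term_id`) and `hierarchy.tsv` (columns
#' `child_id`, `parent_id`, `relation_type`).  Every file carries a
#' header row naming the argument roles.
#'
#' @param dir Directory containing the fact files.
#' @return A `sep_kb`; the term hierarchy, when present, is attached.
#' @seealso [write_kb()] for the inverse (round-trip safe) export.
#' @export
load_kb <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  read_tsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", quote = "",
                      fileEncoding = "UTF-8", check.names = FALSE)
  }
  tsvs <- list.files(dir, pattern = "\\.tsv$")
  known <- c(paste0(names(.pred_spec), ".tsv"),
             "side_effects.tsv", "hierarchy.tsv")
  stray <- setdiff(tsvs, known)
  if (length(stray)) {
    stop("unknown predicate file(s) in ", dir, ": ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  facts <- list()
  for (pred in names(.pred_spec)) {
    path <- file.path(dir, paste0(pred, ".tsv"))
    if (file.exists(path)) facts[[pred]] <- read_tsv(path)
  }
  hierarchy <- NULL
  hpath <- file.path(dir, "hierarchy.tsv")
  if (file.exists(hpath)) {
    h <- read_tsv(hpath)
    hierarchy <- term_hierarchy(h[[1L]], h[[2L]], h[[3L]])
  }
  side_effects <- NULL
  spath <- file.path(dir, "side_effects.tsv")
  if (file.exists(spath)) {
    se <- read_tsv(spath)
    side_effects <- split(se[[2L]], se[[1L]])
  }
  knowledge_base(facts, side_effects = side_effects, hierarchy = hierarchy)
}

#' Export a knowledge base as predicate TSV files
#'
#' Writes the same dialect [load_kb()] reads, so that a written knowledge
#' base reloads identically.  Only one orientation of each symmetric
#' `interact` fact is written.
#'
#' @param kb A `sep_kb`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  for (pred in names(.pred_spec)) {
    mat <- kb$facts[[pred]]
    if (nrow(mat) == 0L) next
    if (pred == "interact") {
      keep <- mat[, 1L] <= mat[, 2L]
      ## self-interactions appear once already; dedupe orientation
      mat <- mat[keep | !(paste(mat[, 2L], mat[, 1L]) %in%
                            paste(mat[keep, 1L], mat[keep, 2L])), ,
                 drop = FALSE]
    }
    write_tsv(as.data.frame(mat), file.path(dir, paste0(pred, ".tsv")))
  }
  if (length(kb$side_effects)) {
    se <- data.frame(
      drug_id = rep(names(kb$side_effects),
                    lengths(kb$side_effects)),
      term_id = unlist(kb$side_effects, use.names = FALSE)
    )
    write_tsv(se, file.path(dir, "side_effects.tsv"))
  }
  if (!is.null(kb$hierarchy)) {
    h <- kb$hierarchy
    write_tsv(data.frame(child_id = h$edges$child, parent_id = h$edges$parent,
                         relation_type = h$edges$relation),
              file.path(dir, "hierarchy.tsv"))
  }
  invisible(dir)
}

#' Evaluate a conjunctive query against a knowledge base
#'
#' Depth-first backtracking join with first-argument indexing: literals
#' are evaluated left to right and candidate facts are enumerated in
#' insertion order, so the binding stream is deterministic.  The rule
#' bodies produced by the relational learner are evaluated with this
#' engine.
#'
#' @param kb A `sep_kb`.
#' @param query List of [lit()] literals (an empty list yields exactly
#'   one empty binding).
#' @param bindings Named character vector of seed bindings (variable
#'   name, without the `?` prefix, to constant).
#' @param limit Stop after this many complete bindings (e.g. `1` for an
#'   existence check).
#' @param cap Guard against unbound-variable explosion: error if more
#'   than `cap` bindings would be produced.
#' @return List of named character vectors, one per complete binding.
#' @examples
#' kb <- knowledge_base(list(
#'   drug_has_target = data.frame(d = "d1", p = "p1", a = "inhibitor"),
#'   pathway = data.frame(p = "p1", pw = "Endocytosis", s = "kegg")))
#' kb_match(kb, list(lit("drug_has_target", "?A", "?B", "inhibitor"),
#'                   lit("pathway", "?B", "Endocytosis", "kegg")))
#' @export
kb_match <- function(kb, query, bindings = character(0), limit = Inf,
                     cap = 1e6) {
  for (l in query) {
    if (!inherits(l, "sep_literal")) {
      stop("query must be a list of literals built with lit()",
           call. = FALSE)
    }
  }
  results <- vector("list", 64L)
  n_res <- 0L
  bind0 <- as.character(bindings)
  names(bind0) <- names(bindings)

  emit <- function(b) {
    n_res <<- n_res + 1L
    if (n_res > cap) {
      stop("result cap (", cap, ") exceeded while evaluating query ",
           paste(vapply(query, format, ""), collapse = ", "),
           call. = FALSE)
    }
    if (n_res > length(results)) {
      length(results) <<- 2L * length(results)
    }
    results[[n_res]] <<- b
  }

  recurse <- function(i, b) {
    if (n_res >= limit) return(invisible(NULL))
    if (i > length(query)) {
      emit(b)
      return(invisible(NULL))
    }
    l <- query[[i]]
    mat <- kb$facts[[l$predicate]]
    vars <- ifelse(l$is_var, sub("^\\?", "", l$args), NA_character_)
    vals <- ifelse(l$is_var, unname(b[vars]), l$args)
    bound <- !is.na(vals)
    if (nrow(mat) == 0L) return(invisible(NULL))
    if (bound[1L]) {
      rows <- kb$index[[l$predicate]][[vals[1L]]]
      if (is.null(rows)) return(invisible(NULL))
    } else {
      rows <- seq_len(nrow(mat))
    }
    for (j in seq_along(vals)[-1L]) {
      if (bound[j]) {
        rows <- rows[mat[rows, j] == vals[j]]
        if (!length(rows)) return(invisible(NULL))
      }
    }
    free <- which(!bound)
    if (!length(free)) {
      recurse(i + 1L, b)
      return(invisible(NULL))
    }
    for (r in rows) {
      if (n_res >= limit) break
      b2 <- b
      ok <- TRUE
      for (j in free) {
        v <- vars[j]
        val <- mat[r, j]
        if (v %in% names(b2)) {
          if (!identical(unname(b2[v]), val)) { ok <- FALSE; break }
        } else {
          b2[v] <- val
        }
      }
      if (ok) recurse(i + 1L, b2)
    }
    invisible(NULL)
  }

  recurse(1L, bind0)
  length(results) <- n_res
  results
}

#' Does a conjunctive query have at least one solution?
#'
#' @inheritParams kb_match
#' @return Logical scalar.
#' @export
kb_exists <- function(kb, query, bindings = character(0)) {
  cb <- .compile_body(query)
  bind <- rep(NA_character_, cb$n_vars)
  if (length(bindings)) {
    slots <- match(names(bindings), cb$vars)
    known <- !is.na(slots)
    bind[slots[known]] <- as.character(bindings)[known]
  }
  .cexists(kb$facts, kb$index, cb$lits, 1L, bind)
}

## Compile a literal list for the fast existence engine: variables are
## mapped to integer slots (in order of first occurrence, after any
## `vars` given up front), so bindings become plain unnamed character
## vectors indexed by position.
.compile_body <- function(body, vars = "A") {
  lits <- vector("list", length(body))
  for (i in seq_along(body)) {
    l <- body[[i]]
    slots <- integer(length(l$args))
    consts <- l$args
    for (j in seq_along(l$args)) {
      if (l$is_var[j]) {
        v <- l$vars[j]
        s <- match(v, vars)
        if (is.na(s)) {
          vars <- c(vars, v)
          s <- length(vars)
        }
        slots[j] <- s
        consts[j] <- NA_character_
      }
    }
    lits[[i]] <- list(pred = l$predicate, slots = slots, consts = consts)
  }
  list(lits = lits, vars = vars, n_vars = length(vars))
}

## allocation-light existence check used heavily by the rule learner;
## same evaluation order as kb_match, early exit on the first solution
.cexists <- function(facts, index, lits, i, bind) {
  if (i > length(lits)) return(TRUE)
  el <- lits[[i]]
  mat <- facts[[el$pred]]
  if (nrow(mat) == 0L) return(FALSE)
  slots <- el$slots
  vals <- el$consts
  for (j in seq_along(slots)) {
    if (slots[j] > 0L) vals[j] <- bind[slots[j]]
  }
  if (!is.na(vals[1L])) {
    rows <- index[[el$pred]][[vals[1L]]]
    if (is.null(rows)) return(FALSE)
  } else {
    rows <- seq_len(nrow(mat))
  }
  free <- which(is.na(vals))
  n_arg <- length(vals)
  if (n_arg > 1L) {
    for (j in 2:n_arg) {
      if (!is.na(vals[j])) {
        rows <- rows[mat[rows, j] == vals[j]]
        if (!length(rows)) return(FALSE)
      }
    }
  }
  if (!length(free)) {
    return(.cexists(facts, index, lits, i + 1L, bind))
  }
  fslots <- slots[free]
  for (r in rows) {
    b2 <- bind
    ok <- TRUE
    for (k in seq_along(free)) {
      val <- mat[r, free[k]]
      s <- fslots[k]
      cur <- b2[s]
      if (is.na(cur)) {
        b2[s] <- val
      } else if (cur != val) {
        ok <- FALSE
        break
      }
    }
    if (ok && .cexists(facts, index, lits, i + 1L, b2)) return(TRUE)
  }
  FALSE
}
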
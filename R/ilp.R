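#' Mode declaration for the relational learner
#'
#' A mode states, for each argument of a predicate, whether the rule
#' language treats it as an input variable (`"+type"`), an output
#' variable (`"-type"`), or a ground constant (`"#type"`), and what
#' entity type it carries.  Modes drive saturation: the bottom clause of
#' a seed drug is assembled by instantiating modes against the seed's
#' facts.
#'
#' @param predicate Predicate name from the fixed vocabulary.
#' @param ... One role string per argument, e.g.
#'   `mode_decl("drug_has_target", "+drug", "-protein", "#action")`.
#' @return An object of class `sep_mode`.
#' @export
mode_decl <- function(predicate, ...) {
  roles <- as.character(unlist(list(...), use.names = FALSE))
  spec <- .pred_spec[[predicate]]
  if (is.null(spec)) {
    stop("unknown predicate '", predicate, "'", call. = FALSE)
  }
  if (length(roles) != length(spec)) {
    stop("predicate '", predicate, "' has arity ", length(spec),
         call. = FALSE)
  }
  marks <- substr(roles, 1L, 1L)
  if (!all(marks %in% c("+", "-", "#"))) {
    stop("each role must start with '+', '-' or '#'", call. = FALSE)
  }
  if (!any(marks == "+")) {
    stop("a body-literal mode needs at least one input ('+') argument",
         call. = FALSE)
  }
  structure(list(predicate = predicate, marks = marks,
                 types = substring(roles, 2L)),
            class = "sep_mode")
}

#' Default mode declarations
#'
#' The rule language of the drug/target knowledge base: drugs chain to
#' targets, targets to interactants, and proteins to their GO, pathway
#' and domain annotations; GO terms chain along `is_a`/`part_of` edges.
#' Action types, sources, relation types, category, cluster, pathway,
#' domain and GO labels may appear as constants; drug and protein
#' arguments are always variablized.
#'
#' @return List of [mode_decl()] objects.
#' @export
default_modes <- function() {
  list(
    mode_decl("category", "+drug", "#category"),
    mode_decl("drug_cluster", "+drug", "#cluster", "#source"),
    mode_decl("drug_has_target", "+drug", "-protein", "#action"),
    mode_decl("goterm", "+protein", "#go_term"),
    mode_decl("goterm", "+protein", "-go_term"),
    mode_decl("go_relation", "+go_term", "#relation", "#go_term"),
    mode_decl("go_relation", "+go_term", "#relation", "-go_term"),
    mode_decl("interact", "+protein", "-protein"),
    mode_decl("pathway", "+protein", "#pathway", "#source"),
    mode_decl("domain", "+protein", "#domain")
  )
}

#' Read mode declarations from a JSON file
#'
#' Expects an array of objects with fields `predicate` and `roles`.
#'
#' @param path JSON file.
#' @return List of [mode_decl()] objects.
#' @export
read_modes <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(spec, function(m) {
    do.call(mode_decl, c(list(m$predicate), as.list(m$roles)))
  })
}

#' Relational learner configuration
#'
#' @param min_pos Minimum positives an acceptable rule must cover
#'   (default 5).
#' @param noise Maximum negatives an acceptable rule may cover
#'   (default 1; one is never sure a drug truly lacks a side effect).
#' @param induce_type Induction regime; only `"induce_cover"`
#'   (overlapping rules, quality measured on the full example sets) is
#'   implemented.
#' @param max_body_literals Longest rule body searched (default 6).
#' @param max_chain_depth Longest entity chain from the drug variable
#'   (default 3: drug, target, interactant, annotation).
#' @param beam_width Beam width of the refinement search (default 20).
#' @param saturation_cap Most bottom-clause literals kept per predicate
#'   (default 50).
#' @return An object of class `sep_ilp_config`.
#' @export
ilp_config <- function(min_pos = 5L, noise = 1L,
                       induce_type = "induce_cover",
                       max_body_literals = 6L, max_chain_depth = 3L,
                       beam_width = 20L, saturation_cap = 50L) {
  if (min_pos < 1L) stop("min_pos must be >= 1", call. = FALSE)
  if (noise < 0L) stop("noise must be >= 0", call. = FALSE)
  if (!identical(induce_type, "induce_cover")) {
    stop("only induce_type = 'induce_cover' is supported", call. = FALSE)
  }
  structure(list(min_pos = as.integer(min_pos), noise = as.integer(noise),
                 induce_type = induce_type,
                 max_body_literals = as.integer(max_body_literals),
                 max_chain_depth = as.integer(max_chain_depth),
                 beam_width = as.integer(beam_width),
                 saturation_cap = as.integer(saturation_cap)),
            class = "sep_ilp_config")
}

.var_name <- function(i) {
  if (i <= 26L) LETTERS[i] else paste0("V", i)
}

#' Saturate a seed drug into its bottom clause
#'
#' Breadth-first instantiation of the mode declarations from the seed's
#' ground facts: starting at the drug variable `A` (depth 0), each mode
#' applied to a reachable entity produces literals whose constants are
#' lifted to typed variables except at constant (`#`) positions.  New
#' entity variables deepen the chain by one; chains stop at
#' `max_chain_depth`.  Each predicate contributes at most
#' `saturation_cap` literals, in fact insertion order.
#'
#' @param seed Drug id (a positive example).
#' @param kb A `sep_kb`.
#' @param modes List of [mode_decl()]s (default [default_modes()]).
#' @param cfg An [ilp_config()].
#' @return An object of class `sep_bottom`: literal entries (`lit`,
#'   `in_vars`, `out_vars`) plus the variable table.  Empty when the
#'   seed has no facts.
#' @export
saturate <- function(seed, kb, modes = default_modes(),
                     cfg = ilp_config()) {
  var_of <- new.env(parent = emptyenv())   # "<type>\r<const>" -> var
  depth_of <- list()
  n_vars <- 1L
  assign(paste0("drug\r", seed), "A", envir = var_of)
  depth_of[["A"]] <- 0L

  queue <- list(list(const = seed, type = "drug", var = "A", depth = 0L))
  qi <- 1L
  literals <- list()
  lit_keys <- character(0)
  pred_count <- stats::setNames(integer(length(.pred_spec)),
                                names(.pred_spec))

  while (qi <= length(queue)) {
    entry <- queue[[qi]]
    qi <- qi + 1L
    for (m in modes) {
      in_pos <- which(m$marks == "+")
      if (length(in_pos) != 1L || m$types[in_pos] != entry$type) next
      mat <- kb$facts[[m$predicate]]
      if (nrow(mat) == 0L) next
      rows <- if (in_pos == 1L) {
        kb$index[[m$predicate]][[entry$const]]
      } else {
        which(mat[, in_pos] == entry$const)
      }
      if (is.null(rows) || !length(rows)) next
      for (r in rows) {
        if (pred_count[[m$predicate]] >= cfg$saturation_cap) break
        args <- character(length(m$marks))
        out_vars <- character(0)
        new_entries <- list()
        ok <- TRUE
        for (j in seq_along(m$marks)) {
          cst <- mat[r, j]
          if (m$marks[j] == "+") {
            args[j] <- paste0("?", entry$var)
          } else if (m$marks[j] == "#") {
            args[j] <- cst
          } else {
            key <- paste0(m$types[j], "\r", cst)
            v <- if (exists(key, envir = var_of, inherits = FALSE)) {
              get(key, envir = var_of)
            } else NA_character_
            if (is.na(v)) {
              if (entry$depth + 1L > cfg$max_chain_depth) {
                ok <- FALSE
                break
              }
              n_vars <- n_vars + 1L
              v <- .var_name(n_vars)
              assign(key, v, envir = var_of)
              depth_of[[v]] <- entry$depth + 1L
              new_entries[[length(new_entries) + 1L]] <-
                list(const = cst, type = m$types[j], var = v,
                     depth = entry$depth + 1L)
            }
            args[j] <- paste0("?", v)
            out_vars <- c(out_vars, v)
          }
        }
        if (!ok) next
        l <- do.call(lit, c(list(m$predicate), as.list(args)))
        key <- paste(m$predicate, paste(args, collapse = "\r"))
        if (key %in% lit_keys) next
        lit_keys <- c(lit_keys, key)
        pred_count[[m$predicate]] <- pred_count[[m$predicate]] + 1L
        literals[[length(literals) + 1L]] <-
          list(lit = l, in_vars = entry$var, out_vars = out_vars)
        for (ne in new_entries) queue[[length(queue) + 1L]] <- ne
      }
    }
  }
  structure(list(literals = literals, seed = seed,
                 depth_of = depth_of),
            class = "sep_bottom")
}

#' @export
print.sep_bottom <- function(x, ...) {
  cat("Bottom clause for seed", x$seed, "-", length(x$literals),
      "literals\n")
  for (e in utils::head(x$literals, 12L)) cat(" ", format(e$lit), "\n")
  if (length(x$literals) > 12L) cat("  ...\n")
  invisible(x)
}

.new_rule <- function(body, p, n, covered_pos, covered_neg) {
  structure(list(head = "sep(A)", body = body, P = p, N = n,
                 covered_pos = covered_pos, covered_neg = covered_neg),
            class = "sep_rule")
}

#' @export
format.sep_rule <- function(x, ...) {
  paste0("sep(A) :- ",
         paste(vapply(x$body, format, ""), collapse = ", "),
         "  [P=", x$P, ", N=", x$N, "]")
}

#' @export
print.sep_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Does a rule cover a drug?
#'
#' True iff the rule body, with the head variable `A` bound to the drug,
#' has at least one solution in the knowledge base.  A rule with an
#' empty body covers every drug.
#'
#' @param rule A `sep_rule` (or a bare list of [lit()] literals).
#' @param drug Drug id.
#' @param kb A `sep_kb`.
#' @return Logical scalar.
#' @export
covers <- function(rule, drug, kb) {
  body <- if (inherits(rule, "sep_rule")) rule$body else rule
  kb_exists(kb, body, c(A = drug))
}

## Which of `drugs` satisfy `body`?  Evaluated as a relational
## semi-join: literals are inner-joined left to right on their shared
## variables, projecting after each join onto the head variable plus
## the variables still needed downstream.  Vectorized, so the cost is
## driven by fact-table sizes, not by the number of candidate drugs.
.cover_set <- function(body, drugs, kb) {
  if (!length(body)) return(drugs)
  nlit <- length(body)
  later <- vector("list", nlit)
  acc <- "A"
  for (i in rev(seq_len(nlit))) {
    later[[i]] <- acc
    acc <- union(acc, body[[i]]$vars[body[[i]]$is_var])
  }
  df <- data.frame(A = unique(drugs), stringsAsFactors = FALSE)
  for (i in seq_len(nlit)) {
    l <- body[[i]]
    cols <- kb$cols[[l$predicate]]
    if (!length(cols[[1L]])) return(character(0))
    rows <- seq_along(cols[[1L]])
    for (j in seq_along(l$args)) {
      if (!l$is_var[j]) {
        rows <- rows[cols[[j]][rows] == l$args[j]]
        if (!length(rows)) return(character(0))
      }
    }
    vpos <- which(l$is_var)
    vnames <- l$vars[vpos]
    first_pos <- vpos[!duplicated(vnames)]
    ## a variable repeated inside one literal constrains rows directly
    if (anyDuplicated(vnames)) {
      for (k in which(duplicated(vnames))) {
        k0 <- first_pos[match(vnames[k], vnames[!duplicated(vnames)])]
        rows <- rows[cols[[vpos[k]]][rows] == cols[[k0]][rows]]
      }
      if (!length(rows)) return(character(0))
    }
    tab <- stats::setNames(
      lapply(first_pos, function(j) cols[[j]][rows]),
      vnames[!duplicated(vnames)])
    tab <- unique(as.data.frame(tab, stringsAsFactors = FALSE,
                                check.names = FALSE))
    keys <- intersect(names(df), names(tab))
    df <- if (length(keys)) {
      merge(df, tab, by = keys)
    } else {
      merge(df, tab, by = NULL)  # disconnected literal: product
    }
    if (!nrow(df)) return(character(0))
    need <- intersect(names(df), later[[i]])
    df <- unique(df[need])
  }
  drugs[drugs %in% df$A]
}

#' Search for one acceptable rule from a seed example
#'
#' Beam search over bodies drawn from the seed's bottom clause, grown
#' one connected literal at a time (a literal is addable when its input
#' variable is already bound by the head or an earlier literal).  A body
#' is acceptable when it covers at least `min_pos` positives and at most
#' `noise` negatives of the full example sets; among acceptable bodies
#' the one maximizing P is returned, ties resolved toward fewer literals
#' and then discovery order.
#'
#' @param seed Drug id, a member of `pos`.
#' @param pos,neg Character vectors of positive / negative example drug
#'   ids.
#' @param kb A `sep_kb`.
#' @param cfg An [ilp_config()].
#' @param modes List of [mode_decl()]s.
#' @param bottom Optional precomputed [saturate()] result for `seed`.
#' @return A `sep_rule`, or `NULL` when no acceptable rule exists.
#' @export
search_rule <- function(seed, pos, neg, kb, cfg = ilp_config(),
                        modes = default_modes(), bottom = NULL) {
  stopifnot(seed %in% pos)
  if (is.null(bottom)) bottom <- saturate(seed, kb, modes, cfg)
  lits <- bottom$literals
  if (!length(lits)) return(NULL)

  best <- NULL
  init <- list(idx = integer(0), bound = "A", pos_cov = pos,
               neg_cov = neg, P = length(pos), N = length(neg))
  beam <- list(init)
  seen <- new.env(hash = TRUE, parent = emptyenv())

  for (level in seq_len(cfg$max_body_literals)) {
    cand <- list()
    for (state in beam) {
      for (i in seq_along(lits)) {
        if (i %in% state$idx) next
        if (!all(lits[[i]]$in_vars %in% state$bound)) next
        idx2 <- c(state$idx, i)
        sig <- paste(sort(idx2), collapse = ",")
        if (!is.null(seen[[sig]])) next
        seen[[sig]] <- TRUE
        body <- lapply(idx2, function(k) lits[[k]]$lit)
        pos_cov <- .cover_set(body, state$pos_cov, kb)
        ## positive coverage is anti-monotone: refinements below
        ## min_pos, or that cannot beat the best accepted rule (longer
        ## bodies lose P-ties), are dead ends
        if (length(pos_cov) < cfg$min_pos) next
        if (!is.null(best) && length(pos_cov) <= best$P) next
        neg_cov <- .cover_set(body, state$neg_cov, kb)
        st <- list(idx = idx2,
                   bound = c(state$bound, lits[[i]]$out_vars),
                   pos_cov = pos_cov, neg_cov = neg_cov,
                   P = length(pos_cov), N = length(neg_cov))
        if (st$N <= cfg$noise && (is.null(best) || st$P > best$P)) {
          best <- st
        }
        cand[[length(cand) + 1L]] <- st
      }
    }
    if (!length(cand)) break
    ## beam priority is the coverage score P - N, so restrictive bodies
    ## that separate the classes displace vacuous high-P refinements
    score <- vapply(cand, function(s) s$P - s$N, 0L)
    ord <- order(-score, seq_along(cand))
    beam <- cand[utils::head(ord, cfg$beam_width)]
    if (!is.null(best) &&
        max(vapply(beam, `[[`, 0L, "P")) <= best$P) {
      break
    }
  }
  if (is.null(best)) return(NULL)
  body <- lapply(best$idx, function(k) lits[[k]]$lit)
  .new_rule(body, best$P, best$N, best$pos_cov, best$neg_cov)
}

#' Induce a theory of overlapping rules
#'
#' The induce-cover loop: seeds are taken in the fixed input order of
#' the positives; each accepted rule's P and N are measured against the
#' full example sets, and positives covered by an accepted rule are only
#' removed from seed selection (rules may overlap in coverage).  The
#' loop stops when every positive is covered or no remaining seed yields
#' an acceptable rule.
#'
#' @param pos,neg Disjoint character vectors of example drug ids.
#' @param kb A `sep_kb`.
#' @param cfg An [ilp_config()].
#' @param modes List of [mode_decl()]s.
#' @param sep_id Optional profile id recorded on the theory.
#' @return An object of class `sep_theory`: `rules`, `uncovered`
#'   (positives no accepted rule covers), `config`, `sep_id`.
#' @export
induce_cover <- function(pos, neg, kb, cfg = ilp_config(),
                         modes = default_modes(), sep_id = NULL) {
  if (length(intersect(pos, neg))) {
    stop("pos and neg must be disjoint", call. = FALSE)
  }
  rules <- list()
  covered <- character(0)
  exhausted <- character(0)
  repeat {
    seeds <- setdiff(pos, c(covered, exhausted))
    if (!length(seeds)) break
    seed <- seeds[1L]
    rule <- search_rule(seed, pos, neg, kb, cfg, modes)
    if (is.null(rule)) {
      exhausted <- c(exhausted, seed)
      next
    }
    rules[[length(rules) + 1L]] <- rule
    newly <- rule$covered_pos
    if (!seed %in% newly) exhausted <- c(exhausted, seed)
    covered <- union(covered, newly)
  }
  structure(list(rules = rules, uncovered = setdiff(pos, covered),
                 config = cfg, sep_id = sep_id),
            class = "sep_theory")
}

#' @export
print.sep_theory <- function(x, ...) {
  cat("Theory", if (!is.null(x$sep_id)) paste0("for ", x$sep_id) else "",
      "-", length(x$rules), "rule(s),", length(x$uncovered),
      "uncovered positive(s)\n")
  for (r in x$rules) cat(" ", format(r), "\n")
  invisible(x)
}

#' Predict with a theory
#'
#' A drug is predicted positive when at least one rule of the theory
#' covers it; an empty theory predicts every drug negative.
#'
#' @param theory A `sep_theory`.
#' @param drugs Character vector of drug ids.
#' @param kb A `sep_kb`.
#' @return Named logical vector of predictions.
#' @export
predict_theory <- function(theory, drugs, kb) {
  out <- vapply(drugs, function(d) {
    for (r in theory$rules) {
      if (covers(r, d, kb)) return(TRUE)
    }
    FALSE
  }, TRUE)
  stats::setNames(out, drugs)
}

#' Serialize a theory to JSON
#'
#' Rules are emitted with their surface-syntax body, literal structure
#' and P/N coverage counts.
#'
#' @param theory A `sep_theory`.
#' @return A JSON string.
#' @export
theory_to_json <- function(theory) {
  rules <- lapply(theory$rules, function(r) {
    list(head = r$head,
         body = vapply(r$body, format, ""),
         literals = lapply(r$body, function(l) {
           list(predicate = l$predicate, args = l$args)
         }),
         P = r$P, N = r$N)
  })
  jsonlite::toJSON(list(sep_id = theory$sep_id, rules = rules,
                        uncovered = theory$uncovered),
                   auto_unbox = TRUE, pretty = TRUE, null = "null")
}
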
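#' Configuration of the synthetic relational knowledge base
#'
#' Describes the generated study population: a MedDRA-style term
#' hierarchy, drugs annotated with side-effect terms, multi-target
#' drugs (about four targets per drug on average, the density of the
#' curated drug/target resource the generator emulates), and
#' annotation-rich targets.  Planted rules give every pipeline stage a
#' ground truth: each rule's relational body is instantiated so that
#' exactly its carrier drugs satisfy it, and carriers receive the
#' side-effect terms of the rule's target profile.
#'
#' @param n_drugs,n_targets Entity counts (defaults 300 / 400).
#' @param n_go_terms,n_pathways,n_domains,n_categories Annotation pool
#'   sizes.
#' @param n_clusters Structural clusters per clustering method.
#' @param cluster_methods Method labels for drug_cluster facts.
#' @param targets_per_drug Mean targets per drug (default 4).
#' @param hierarchy_branching,hierarchy_depth Shape of the term
#'   hierarchy (a full b-ary tree of the given edge depth).
#' @param second_parent_fraction Fraction of non-root terms given a
#'   second (`part_of`) parent, exercising DAG handling (default 0.1).
#' @param n_term_clusters Cut level used by [synth_scenario()] when
#'   clustering the generated terms.
#' @param planted_rules List of [planted_rule()] objects.
#' @param fn,fp Label-noise rates: probability that a carrier misses its
#'   profile terms / that a non-carrier receives them (defaults 0).
#' @param background_rate Per-term probability of a background
#'   side-effect annotation (default 0.02).
#' @param faers_fraction Fraction of carriers that get primary-suspect
#'   reports across all profile TCs (default 1).
#' @param faers_decoys Number of non-primary decoy reports (default 50).
#' @param seed Master random seed; every generator operation derives its
#'   stream from it.
#' @return An object of class `sep_synth_config`.
#' @export
synth_config <- function(n_drugs = 300L, n_targets = 400L,
                         n_go_terms = 150L, n_pathways = 40L,
                         n_domains = 60L, n_categories = 25L,
                         n_clusters = 12L,
                         cluster_methods = c("tanimoto", "hpcc"),
                         targets_per_drug = 4,
                         hierarchy_branching = 3L, hierarchy_depth = 4L,
                         second_parent_fraction = 0.1,
                         n_term_clusters = 20L,
                         planted_rules = list(),
                         fn = 0, fp = 0, background_rate = 0.02,
                         faers_fraction = 1, faers_decoys = 50L,
                         seed = 1L) {
  counts <- c(n_drugs, n_targets, n_go_terms, n_pathways, n_domains,
              n_categories, n_clusters)
  if (any(counts < 1L)) stop("entity counts must be >= 1", call. = FALSE)
  rates <- c(fn, fp, background_rate, second_parent_fraction,
             faers_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (hierarchy_depth < 2L) {
    stop("hierarchy_depth must be >= 2", call. = FALSE)
  }
  structure(as.list(environment()), class = "sep_synth_config")
}

#' Declare a planted relational rule
#'
#' @param body List of [lit()] literals with head variable `?A`;
#'   include at least one constant that the background generator cannot
#'   emit (any label outside the generated `P/go:/PW/DM/CAT/..` pools,
#'   e.g. `"PW_planted_1"`), so that only carriers can satisfy the
#'   body.  [generate_kb()] verifies this and fails otherwise.
#' @param tcs Integer TC indices of the rule's target side-effect
#'   profile, or `NULL` to let [synth_scenario()] assign a free pair.
#' @param carrier_fraction Fraction of drugs carrying the rule
#'   (default 0.25).
#' @return An object of class `sep_planted_rule`.
#' @export
planted_rule <- function(body, tcs = NULL, carrier_fraction = 0.25) {
  for (l in body) {
    if (!inherits(l, "sep_literal")) {
      stop("body must be a list of lit() literals", call. = FALSE)
    }
  }
  if (carrier_fraction < 0 || carrier_fraction > 1) {
    stop("carrier_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(body = body, tcs = tcs,
                 carrier_fraction = carrier_fraction),
            class = "sep_planted_rule")
}

#' Generate a rooted DAG-shaped term hierarchy
#'
#' A full b-ary `is_a` tree of the configured edge depth; a configured
#' fraction of non-root terms additionally receives a second
#' (`part_of`) parent picked from the level above, so downstream code
#' is exercised on a true DAG.
#'
#' @param cfg A [synth_config()].
#' @return A [term_hierarchy()].
#' @export
generate_hierarchy <- function(cfg) {
  set.seed(cfg$seed + 101L)
  b <- cfg$hierarchy_branching
  d <- cfg$hierarchy_depth
  n_per_level <- b^(0:d)
  ids <- sprintf("SE%04d", seq_len(sum(n_per_level)))
  level <- rep(0:d, n_per_level)
  child <- parent <- relation <- character(0)
  offset <- cumsum(c(0, n_per_level))
  for (l in seq_len(d)) {
    kids <- ids[level == l]
    pars <- ids[level == l - 1L]
    child <- c(child, kids)
    parent <- c(parent, pars[((seq_along(kids) - 1L) %/% b) + 1L])
    relation <- c(relation, rep("is_a", length(kids)))
  }
  extra <- which(level > 0L)
  extra <- extra[stats::runif(length(extra)) < cfg$second_parent_fraction]
  for (i in extra) {
    pool <- setdiff(ids[level == level[i] - 1L],
                    parent[child == ids[i]])
    if (!length(pool)) next
    child <- c(child, ids[i])
    parent <- c(parent, pool[sample.int(length(pool), 1L)])
    relation <- c(relation, "part_of")
  }
  term_hierarchy(child, parent, relation,
                 labels = stats::setNames(ids, ids))
}

## entity type of each predicate argument, for fresh-entity invention
.arg_entity <- c(drug = "drug", protein = "protein", protein2 = "protein",
                 go_term = "go_term", go_parent = "go_term",
                 category = "category", cluster = "cluster",
                 source = "source", action = "action",
                 relation = "relation", pathway = "pathway",
                 domain = "domain")

#' Generate a knowledge base with planted relational rules
#'
#' Draws background facts (drug categories, structural clusters,
#' drug-target actions, protein-protein interactions, GO annotations
#' and relations, pathways, domains) from uniform pools, then
#' instantiates every planted rule body once per carrier: unbound body
#' variables become fresh dedicated entities, so carriers satisfy the
#' body while non-carrier drugs are verified not to.
#'
#' @param cfg A [synth_config()].
#' @return List with `kb` (a `sep_kb`, without side effects) and
#'   `truth` (class `sep_truth`: per rule the body, carrier set and
#'   target TC set).
#' @export
generate_kb <- function(cfg) {
  set.seed(cfg$seed + 202L)
  drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))
  proteins <- sprintf("P%04d", seq_len(cfg$n_targets))
  go_pool <- sprintf("go:%04d", seq_len(cfg$n_go_terms))
  pw_pool <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  dm_pool <- sprintf("DM%03d", seq_len(cfg$n_domains))
  cat_pool <- sprintf("CAT%02d", seq_len(cfg$n_categories))
  clu_pool <- sprintf("%d_clu", seq_len(cfg$n_clusters))
  sources <- c("kegg", "pid")

  facts <- list(category = NULL, drug_cluster = NULL,
                drug_has_target = NULL, goterm = NULL,
                go_relation = NULL, interact = NULL, pathway = NULL,
                domain = NULL)
  add <- function(pred, ...) {
    facts[[pred]] <<- rbind(facts[[pred]], cbind(...))
  }

  ## drug-side facts
  for (d in drugs) {
    n_cat <- sample.int(3L, 1L)
    add("category", d, sample(cat_pool, n_cat))
    for (m in cfg$cluster_methods) {
      add("drug_cluster", d, sample(clu_pool, 1L), m)
    }
    n_t <- 1L + stats::rpois(1L, cfg$targets_per_drug - 1)
    n_t <- min(n_t, length(proteins))
    tgt <- sample(proteins, n_t)
    add("drug_has_target", d, tgt,
        sample(.valid_actions, n_t, replace = TRUE))
  }

  ## protein-side facts for every protein in the pool
  for (p in proteins) {
    add("goterm", p, sample(go_pool, sample.int(4L, 1L)))
    add("pathway", p, sample(pw_pool, sample.int(3L, 1L)),
        sample(sources, 1L))
    add("domain", p, sample(dm_pool, sample.int(2L, 1L)))
    n_int <- sample.int(3L, 1L) - 1L
    if (n_int > 0L) {
      add("interact", p, sample(setdiff(proteins, p), n_int))
    }
  }

  ## GO DAG: every term after the first gets one earlier parent
  if (cfg$n_go_terms > 1L) {
    for (i in 2:cfg$n_go_terms) {
      add("go_relation", go_pool[i],
          sample(.valid_go_relations, 1L),
          go_pool[sample.int(i - 1L, 1L)])
    }
  }

  ## plant rules: dedicated fresh entities per carrier
  truth <- list()
  unassigned <- drugs
  fresh_id <- 0L
  for (ri in seq_along(cfg$planted_rules)) {
    pr <- cfg$planted_rules[[ri]]
    n_car <- floor(pr$carrier_fraction * cfg$n_drugs)
    if (n_car > length(unassigned)) {
      stop("planted carrier fractions exceed the drug set", call. = FALSE)
    }
    carriers <- sort(sample(unassigned, n_car))
    unassigned <- setdiff(unassigned, carriers)
    for (d in carriers) {
      bind <- c(A = d)
      for (l in pr$body) {
        args <- character(length(l$args))
        spec <- .pred_spec[[l$predicate]]
        for (j in seq_along(l$args)) {
          if (l$is_var[j]) {
            v <- sub("^\\?", "", l$args[j])
            if (is.na(bind[v])) {
              fresh_id <- fresh_id + 1L
              ent <- .arg_entity[[spec[j]]]
              bind[v] <- sprintf("X%s%05d", substr(ent, 1L, 2L),
                                 fresh_id)
            }
            args[j] <- bind[v]
          } else {
            args[j] <- l$args[j]
          }
        }
        add(l$predicate, matrix(args, nrow = 1L))
      }
    }
    truth[[ri]] <- list(rule = ri, body = pr$body, carriers = carriers,
                        tcs = pr$tcs,
                        carrier_fraction = pr$carrier_fraction)
  }

  kb <- knowledge_base(facts)

  ## soundness: exactly the carriers satisfy each planted body
  for (tr in truth) {
    sat <- drugs[vapply(drugs, function(d) {
      kb_exists(kb, tr$body, c(A = d))
    }, TRUE)]
    if (!setequal(sat, tr$carriers)) {
      stop("planted rule ", tr$rule, " is satisfied by ",
           length(setdiff(sat, tr$carriers)), " non-carrier drug(s); ",
           "use reserved constants in the body", call. = FALSE)
    }
  }

  structure(list(kb = kb,
                 truth = structure(truth, class = "sep_truth")),
            class = "sep_synth_kb")
}

#' Generate side-effect annotations with planted profiles
#'
#' Carriers of each planted rule receive, with probability `1 - fn`,
#' the minimal required number of member terms of every TC of the
#' rule's profile (so their fingerprint is positive for the profile);
#' non-carriers receive the same terms with probability `fp`.
#' Background terms are drawn uniformly at `background_rate` from the
#' terms outside all planted profiles, so that with `fn = fp = 0` the
#' fingerprint positives of a planted profile are exactly its carriers.
#'
#' @param kb A `sep_kb` from [generate_kb()] (supplies the drug set).
#' @param truth The matching `sep_truth`.
#' @param clustering A `sep_tc` over the generated hierarchy; each
#'   planted rule's `tcs` must be valid cluster indices.
#' @param cfg The [synth_config()].
#' @return Named list drug id -> character vector of term ids (empty
#'   vectors kept, so every drug appears as a fingerprint row).
#' @export
generate_side_effects <- function(kb, truth, clustering, cfg) {
  set.seed(cfg$seed + 303L)
  drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))
  k_sizes <- tc_sizes(clustering)
  n_req <- min_se_count(k_sizes)
  members <- lapply(clustering$clusters, `[[`, "members")
  planted_terms <- unique(unlist(lapply(truth, function(tr) {
    unlist(members[tr$tcs], use.names = FALSE)
  }), use.names = FALSE))
  background_pool <- setdiff(clustering$terms, planted_terms)

  se <- stats::setNames(
    lapply(drugs, function(d) {
      if (!length(background_pool)) return(character(0))
      hit <- stats::runif(length(background_pool)) < cfg$background_rate
      background_pool[hit]
    }),
    drugs)

  for (tr in truth) {
    if (is.null(tr$tcs)) {
      stop("planted rule ", tr$rule, " has no assigned TC set",
           call. = FALSE)
    }
    for (d in drugs) {
      is_carrier <- d %in% tr$carriers
      p_receive <- if (is_carrier) 1 - cfg$fn else cfg$fp
      if (stats::runif(1L) < p_receive) {
        extra <- unlist(lapply(tr$tcs, function(i) {
          sample(members[[i]], n_req[i])
        }), use.names = FALSE)
        se[[d]] <- unique(c(se[[d]], extra))
      }
    }
  }
  se
}

#' Generate a spontaneous-report table for the planted profiles
#'
#' For a configured fraction of each rule's carriers, one
#' primary-suspect report is emitted per TC of the rule's profile (a
#' random member term); decoy reports with a non-primary role are added
#' on random drugs and terms.
#'
#' @inheritParams generate_side_effects
#' @return A [faers_reports()] data frame.
#' @export
generate_faers <- function(kb, truth, clustering, cfg) {
  set.seed(cfg$seed + 404L)
  drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))
  members <- lapply(clustering$clusters, `[[`, "members")
  drug_id <- term_id <- role <- character(0)
  for (tr in truth) {
    n_rep <- round(cfg$faers_fraction * length(tr$carriers))
    if (n_rep < 1L) next
    reported <- sort(sample(tr$carriers, n_rep))
    for (d in reported) {
      for (i in tr$tcs) {
        drug_id <- c(drug_id, d)
        term_id <- c(term_id, sample(members[[i]], 1L))
        role <- c(role, "primary_suspect")
      }
    }
  }
  if (cfg$faers_decoys > 0L) {
    drug_id <- c(drug_id, sample(drugs, cfg$faers_decoys, replace = TRUE))
    term_id <- c(term_id, sample(clustering$terms, cfg$faers_decoys,
                                 replace = TRUE))
    role <- c(role, rep("concomitant", cfg$faers_decoys))
  }
  faers_reports(drug_id, term_id, role)
}

#' Generate a complete synthetic study
#'
#' Convenience driver chaining the generator: hierarchy, term
#' clustering (at the configured cut), knowledge base with planted
#' rules (free TC pairs are assigned to rules declared with
#' `tcs = NULL`), side-effect annotations, and reports.  The returned
#' knowledge base has the side effects and hierarchy attached.
#'
#' @param cfg A [synth_config()].
#' @return List of class `sep_scenario`: `config`, `hierarchy`,
#'   `clustering`, `kb`, `truth`, `side_effects`, `reports`,
#'   `fingerprints` (the [build_fingerprints()] table).
#' @export
synth_scenario <- function(cfg = synth_config()) {
  h <- generate_hierarchy(cfg)
  leaves <- setdiff(h$terms, h$edges$parent)
  clustering <- build_term_clusters(leaves, h, k = cfg$n_term_clusters)

  ## assign free TC pairs to rules that did not fix their profile
  used <- unlist(lapply(cfg$planted_rules, `[[`, "tcs"))
  free <- setdiff(seq_len(clustering$k), used)
  for (i in seq_along(cfg$planted_rules)) {
    if (is.null(cfg$planted_rules[[i]]$tcs)) {
      if (length(free) < 2L) {
        stop("not enough free TCs to assign to planted rules",
             call. = FALSE)
      }
      cfg$planted_rules[[i]]$tcs <- free[1:2]
      free <- free[-(1:2)]
    }
  }

  gen <- generate_kb(cfg)
  truth <- gen$truth
  se <- generate_side_effects(gen$kb, truth, clustering, cfg)
  reports <- generate_faers(gen$kb, truth, clustering, cfg)
  kb <- knowledge_base(gen$kb$facts, side_effects = se, hierarchy = h)
  fingerprints <- build_fingerprints(se, clustering)
  structure(list(config = cfg, hierarchy = h, clustering = clustering,
                 kb = kb, truth = truth, side_effects = se,
                 reports = reports, fingerprints = fingerprints),
            class = "sep_scenario")
}

#' Export a synthetic scenario as plain-text files
#'
#' Writes the knowledge-base TSV dialect ([write_kb()]), the term
#' clustering, the fingerprint table, the report table and
#' `ground_truth.json` into a directory.
#'
#' @param scenario A `sep_scenario`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_kb(scenario$kb, dir)
  write_term_clusters(scenario$clustering,
                      file.path(dir, "term_clusters.tsv"))
  write_fingerprints(scenario$fingerprints,
                     file.path(dir, "fingerprints.tsv"))
  utils::write.table(scenario$reports,
                     file.path(dir, "faers_reports.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  gt <- lapply(scenario$truth, function(tr) {
    list(rule = tr$rule,
         body = vapply(tr$body, format, ""),
         tcs = tr$tcs, carriers = tr$carriers)
  })
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}
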
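# Synthetic heterogeneous knowledge graphs with planted low-rank complex
# latent structure.  The generator draws true complex embeddings at a
# small rank, scores every type-compatible pair with the ComplEx form,
# and emits the top-scoring pairs per relation as edges.  Because the
# planted structure lives in the same functional family the model fits,
# link recovery on these graphs is a meaningful benchmark; a structure-
# free "random" mode is included as a negative control.

#' Default 5-type / 11-relation schema
#'
#' The canonical connection set of a biomedical knowledge graph:
#' GeneProtein, Disease, GOProcess, Pathway and Compound entities, linked
#' by protein-protein interaction, therapeutic-relationship (the
#' benchmark), biological-association, therapeutic-link, experimental-
#' evidence and mechanistic-connection relations.
#'
#' @return data.frame with columns name, subject_type, object_type (11
#'   rows)
#' @export
default_relation_schema <- function() {
  data.frame(
    name = c("PPI", "TherapeuticRelationship",
             "BiologicalAssociation_GP_D", "BiologicalAssociation_GP_P",
             "BiologicalAssociation_GP_GO", "TherapeuticLink_GP_GO",
             "TherapeuticLink_C_D", "ExperimentalEvidence_GP_C",
             "MechanisticConnection_D_P", "MechanisticConnection_D_GO",
             "BiologicalAssociation_GO_GO"),
    subject_type = c("GeneProtein", "Disease", "GeneProtein", "GeneProtein",
                     "GeneProtein", "GeneProtein", "Compound", "GeneProtein",
                     "Disease", "Disease", "GOProcess"),
    object_type = c("GeneProtein", "GeneProtein", "Disease", "Pathway",
                    "GOProcess", "GOProcess", "Disease", "Compound",
                    "Pathway", "GOProcess", "GOProcess"),
    stringsAsFactors = FALSE)
}

#' Synthetic-graph configuration
#'
#' Defaults describe the desk-scale study substrate: 500 entities over
#' the 5 canonical types with a GeneProtein pool large enough for ranking
#' metrics to have dynamic range, 11 relations, planted complex rank 8,
#' roughly 20 benchmark positives per disease, no label noise, year tags
#' spanning 1990-2015.
#'
#' @param entities_per_type named integer vector of entity counts by type
#' @param relation_schema data.frame as in [default_relation_schema()]
#' @param true_dim rank of the planted complex embeddings
#' @param entity_scale_sd standard deviation (log scale) of the lognormal
#'   per-entity strength factor multiplying the planted embeddings.
#'   Heterogeneous entity strengths reproduce the hub-dominated,
#'   heavy-tailed degree structure of real curated graphs; 0 gives
#'   homogeneous norms
#' @param edge_density expected positive fraction of each relation's
#'   type-compatible pair pool; scalar, or a named vector with a
#'   `default` entry plus per-relation overrides
#' @param noise_rate probability that any pair's label is flipped
#' @param year_range inclusive (first, last) calendar-year pair
#' @param structure `"planted"` (low-rank ComplEx scores) or `"random"`
#'   (uniform edges, no structure; negative control)
#' @param seed integer seed
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(entities_per_type = c(GeneProtein = 300L,
                                                   Disease = 40L,
                                                   GOProcess = 70L,
                                                   Pathway = 20L,
                                                   Compound = 70L),
                             relation_schema = default_relation_schema(),
                             true_dim = 8L,
                             entity_scale_sd = 0.8,
                             edge_density = c(default = 0.02,
                                              TherapeuticRelationship = 1 / 15),
                             noise_rate = 0, year_range = c(1990L, 2015L),
                             structure = c("planted", "random"),
                             seed = 1L) {
  structure_mode <- match.arg(structure)
  if (any(entities_per_type < 1L)) stopf("entity counts must be positive")
  if (true_dim < 1L) stopf("true_dim must be positive")
  if (noise_rate < 0 || noise_rate > 1) stopf("noise_rate must be in [0, 1]")
  if (any(edge_density < 0) || any(edge_density > 1))
    stopf("edge_density must be in [0, 1]")
  if (length(edge_density) > 1L && !"default" %in% names(edge_density))
    stopf("a multi-valued edge_density needs a 'default' entry")
  if (year_range[1] > year_range[2]) stopf("invalid year_range")
  missing_types <- setdiff(unique(c(relation_schema$subject_type,
                                    relation_schema$object_type)),
                           names(entities_per_type))
  if (length(missing_types))
    stopf("entities_per_type lacks counts for: %s",
          paste(missing_types, collapse = ", "))
  if (entity_scale_sd < 0) stopf("entity_scale_sd must be >= 0")
  out <- list(entities_per_type = entities_per_type,
              relation_schema = relation_schema,
              true_dim = as.integer(true_dim),
              entity_scale_sd = entity_scale_sd,
              edge_density = edge_density, noise_rate = noise_rate,
              year_range = as.integer(year_range),
              structure = structure_mode, seed = as.integer(seed))
  class(out) <- "synthetic_config"
  out
}

density_for <- function(config, relation) {
  d <- config$edge_density
  if (is.null(names(d))) return(unname(d[1]))
  if (relation %in% names(d)) unname(d[[relation]]) else unname(d[["default"]])
}

type_prefix <- function(type) {
  p <- c(GeneProtein = "GP", Disease = "D", GOProcess = "GO", Pathway = "P",
         Compound = "C")[type]
  if (is.na(p)) toupper(substr(type, 1, 2)) else unname(p)
}

#' Generate a synthetic knowledge graph with planted structure
#'
#' Draws planted complex entity and relation embeddings at
#' `config$true_dim`, scores every type-compatible (subject, object) pair
#' of each relation with the ComplEx form, and emits as positive the
#' pairs whose score exceeds the per-relation threshold chosen so the
#' expected positive count equals `edge_density` times the pair-pool
#' size.  Labels are then flipped independently at `noise_rate`.
#' Self-pairs of within-type relations are excluded (a self-edge carries
#' no ranking information).  In `"random"` mode edges are drawn uniformly
#' instead, so no latent structure exists to recover.
#'
#' @param config a [synthetic_config()]
#' @return list with elements `kg` (a [knowledge_graph()]) and `truth`
#'   (class `planted_truth`: planted embeddings, per-relation thresholds,
#'   and the config) — regenerating edges from `truth` at the stored
#'   thresholds reproduces the noise-free graph exactly
#' @export
generate_synthetic_kg <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  types <- names(config$entities_per_type)
  ids_by_type <- lapply(types, function(tp) {
    sprintf("%s%04d", type_prefix(tp), seq_len(config$entities_per_type[[tp]]))
  })
  names(ids_by_type) <- types
  entities <- data.frame(
    id = unlist(ids_by_type, use.names = FALSE),
    type_label = rep(types, lengths(ids_by_type)),
    stringsAsFactors = FALSE)
  n <- nrow(entities)
  k <- nrow(config$relation_schema)
  td <- config$true_dim

  with_seed(config$seed, {
    # lognormal per-entity strength: hub entities dominate the top-scoring
    # pairs, as in real curated graphs
    scl <- exp(stats::rnorm(n, 0, config$entity_scale_sd %||% 0))
    ent_re <- matrix(stats::rnorm(n * td, sd = 1 / sqrt(td)), n, td,
                     dimnames = list(entities$id, NULL)) * scl
    ent_im <- matrix(stats::rnorm(n * td, sd = 1 / sqrt(td)), n, td,
                     dimnames = list(entities$id, NULL)) * scl
    rel_re <- matrix(stats::rnorm(k * td, sd = 1 / sqrt(td)), k, td,
                     dimnames = list(config$relation_schema$name, NULL))
    rel_im <- matrix(stats::rnorm(k * td, sd = 1 / sqrt(td)), k, td,
                     dimnames = list(config$relation_schema$name, NULL))

    thresholds <- stats::setNames(numeric(k), config$relation_schema$name)
    triples <- vector("list", k)
    for (i in seq_len(k)) {
      rel <- config$relation_schema[i, ]
      subj_ids <- ids_by_type[[rel$subject_type]]
      obj_ids <- ids_by_type[[rel$object_type]]
      # full Ns x No ComplEx score matrix for this relation
      Sa <- ent_re[subj_ids, , drop = FALSE]
      Sb <- ent_im[subj_ids, , drop = FALSE]
      Oa <- ent_re[obj_ids, , drop = FALSE]
      Ob <- ent_im[obj_ids, , drop = FALSE]
      la <- rel_re[i, ]; lb <- rel_im[i, ]
      Phi <- tcrossprod(sweep(Sa, 2, la, `*`), Oa) +
        tcrossprod(sweep(Sb, 2, la, `*`), Ob) +
        tcrossprod(sweep(Sa, 2, lb, `*`), Ob) -
        tcrossprod(sweep(Sb, 2, lb, `*`), Oa)
      self <- rel$subject_type == rel$object_type
      if (self) diag(Phi) <- NA # exclude self-loops from the pair pool
      pair_ok <- !is.na(Phi)
      pool_size <- sum(pair_ok)
      dens <- density_for(config, rel$name)
      n_pos <- round(dens * pool_size)
      if (n_pos < 1L || n_pos >= pool_size)
        stopf("edge_density %.3g unachievable for relation %s (pool %d)",
              dens, rel$name, pool_size)
      if (config$structure == "planted") {
        thr <- sort(Phi[pair_ok], decreasing = TRUE)[n_pos]
        thresholds[[rel$name]] <- thr
        positive <- pair_ok & Phi >= thr
      } else {
        # structure-free control: uniformly random edge set of equal size
        thresholds[[rel$name]] <- NA_real_
        pick <- sample(which(pair_ok), n_pos)
        positive <- matrix(FALSE, nrow(Phi), ncol(Phi))
        positive[pick] <- TRUE
      }
      if (config$noise_rate > 0) {
        flip <- matrix(stats::runif(length(Phi)) < config$noise_rate,
                       nrow(Phi))
        positive <- xor(positive, flip) & pair_ok
      }
      idx <- which(positive, arr.ind = TRUE)
      triples[[i]] <- data.frame(subject = subj_ids[idx[, 1]],
                                 relation = rel$name,
                                 object = obj_ids[idx[, 2]],
                                 year = NA_integer_,
                                 stringsAsFactors = FALSE)
    }
    kg <- knowledge_graph(entities, config$relation_schema,
                          do.call(rbind, triples))
    truth <- structure(list(entity_real = ent_re, entity_imag = ent_im,
                            relation_real = rel_re, relation_imag = rel_im,
                            thresholds = thresholds, config = config),
                       class = "planted_truth")
    list(kg = kg, truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> true_dim=%d, %d entities, %d relations (%s)\n",
              x$config$true_dim, nrow(x$entity_real),
              nrow(x$relation_real), x$config$structure))
  invisible(x)
}

# planted ComplEx score of (subject ids, relation name, object ids)
planted_scores <- function(truth, subjects, relation, objects) {
  la <- truth$relation_real[relation, ]
  lb <- truth$relation_imag[relation, ]
  Sa <- truth$entity_real[subjects, , drop = FALSE]
  Sb <- truth$entity_imag[subjects, , drop = FALSE]
  Oa <- truth$entity_real[objects, , drop = FALSE]
  Ob <- truth$entity_imag[objects, , drop = FALSE]
  rowSums(sweep(Sa * Oa + Sb * Ob, 2, la, `*`)) +
    rowSums(sweep(Sa * Ob - Sb * Oa, 2, lb, `*`))
}

#' Assign years to synthetic edges
#'
#' Tags every triple of the designated relations with a calendar year in
#' `year_range`.  `"uniform"` draws years i.i.d.; `"score_ordered"`
#' assigns earlier years to higher planted scores (emulating strong
#' relationships being discovered first), with tied scores ordered
#' randomly.
#'
#' @param kg a `knowledge_graph`
#' @param year_range inclusive (first, last) year pair
#' @param mode `"uniform"` or `"score_ordered"`
#' @param truth a `planted_truth` (required for `"score_ordered"`)
#' @param relations relation names to tag; default all relations present
#' @param seed optional seed
#' @return the graph with year-tagged triples
#' @export
assign_synthetic_years <- function(kg, year_range, mode = c("uniform",
                                                            "score_ordered"),
                                   truth = NULL, relations = NULL,
                                   seed = NULL) {
  mode <- match.arg(mode)
  year_range <- as.integer(year_range)
  if (length(year_range) != 2L || year_range[1] > year_range[2])
    stopf("year_range must be an inclusive (first, last) pair")
  relations <- relations %||% unique(kg$triples$relation)
  years <- year_range[1]:year_range[2]
  with_seed(seed, {
    for (rel in relations) {
      rows <- which(kg$triples$relation == rel)
      if (!length(rows)) next
      if (mode == "uniform") {
        kg$triples$year[rows] <- sample(years, length(rows), replace = TRUE)
      } else {
        if (is.null(truth)) stopf("score_ordered mode needs `truth`")
        sc <- planted_scores(truth, kg$triples$subject[rows], rel,
                             kg$triples$object[rows])
        ord <- order(-sc, stats::runif(length(sc)))
        # descending score -> ascending year, spread evenly over the range
        yr <- years[ceiling(seq_along(rows) / length(rows) * length(years))]
        kg$triples$year[rows[ord]] <- yr
      }
    }
    kg
  })
}

#' Bayes-optimal ranking from the planted truth
#'
#' Ranks candidates by their planted ComplEx score — the optimal ranking
#' for the noise-free graph, used as the reference ("perfect model") in
#' evaluator tests and as an upper baseline for trained models.
#'
#' @param truth a `planted_truth`
#' @param subject subject entity id
#' @param relation relation name
#' @param candidates character vector of candidate entity ids
#' @param filter_set optional data.frame of triples to filter
#' @return a `ranked_list`
#' @export
oracle_ranking <- function(truth, subject, relation, candidates,
                           filter_set = NULL) {
  if (!subject %in% rownames(truth$entity_real))
    stopf("unknown subject '%s'", subject)
  if (!relation %in% rownames(truth$relation_real))
    stopf("unknown relation '%s'", relation)
  candidates <- unique(candidates)
  unknown <- setdiff(candidates, rownames(truth$entity_real))
  if (length(unknown)) stopf("unknown candidate '%s'", unknown[1])
  filtered_out <- character()
  if (!is.null(filter_set) && nrow(filter_set)) {
    hit <- filter_set$subject == subject & filter_set$relation == relation
    filtered_out <- intersect(candidates, unique(filter_set$object[hit]))
    candidates <- setdiff(candidates, filtered_out)
  }
  sc <- planted_scores(truth, rep(subject, length(candidates)), relation,
                       candidates)
  ord <- order(-sc, candidates)
  structure(list(subject = subject, relation = relation,
                 candidates = candidates[ord], scores = sc[ord],
                 filtered_out = filtered_out),
            class = "ranked_list")
}

#' Write a synthetic graph with its manifest
#'
#' Emits `edges.tsv`, `entities.tsv` and `manifest.json` (config echo,
#' per-relation edge counts, planted thresholds) into `dir`.
#'
#' @param kg a `knowledge_graph`
#' @param truth the matching `planted_truth`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_synthetic_kg <- function(kg, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(kg, file.path(dir, "edges.tsv"),
                  entity_dict = file.path(dir, "entities.tsv"))
  counts <- as.list(table(kg$triples$relation))
  cfg <- truth$config
  jsonlite::write_json(
    list(entities_per_type = as.list(cfg$entities_per_type),
         true_dim = cfg$true_dim,
         entity_scale_sd = cfg$entity_scale_sd,
         edge_density = as.list(cfg$edge_density),
         noise_rate = cfg$noise_rate,
         year_range = cfg$year_range,
         structure = cfg$structure,
         seed = cfg$seed,
         per_relation_counts = counts,
         thresholds = as.list(truth$thresholds)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
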
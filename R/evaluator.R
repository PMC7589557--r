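# Filtered per-disease ranking evaluation: recall@k, average precision,
# mAP, recall-vs-rank curves, and Mann-Whitney-Wilcoxon score-distribution
# comparisons with Bonferroni correction.
#
# Recall (not AUROC/AUPR) is the headline metric because knowledge-graph
# edges are positive-unlabelled: absent edges may simply be undiscovered,
# so only positive-based metrics are trustworthy.

#' Rank candidate objects for a (subject, relation) query
#'
#' Scores every candidate with the model's decoder, removes candidates
#' that form a known edge with this subject and relation in `filter_set`
#' (so train/validation facts do not crowd out test items), and sorts by
#' descending score.  Ties are broken by ascending entity id, making the
#' ranking deterministic.
#'
#' @param model an [embedding_set()] with entity/relation rownames
#' @param subject subject entity id (e.g. a disease)
#' @param relation relation name
#' @param candidate_pool nonempty character vector of candidate entity ids
#' @param filter_set data.frame of known triples to filter, or `NULL`
#' @return object of class `ranked_list`: `subject`, `relation`,
#'   `candidates` (descending score order), `scores`, `filtered_out`
#' @export
rank_objects <- function(model, subject, relation, candidate_pool,
                         filter_set = NULL) {
  if (!length(candidate_pool)) stopf("candidate_pool must be nonempty")
  ids <- rownames(model$entity_real)
  rels <- rownames(model$relation_real)
  s <- match(subject, ids)
  r <- match(relation, rels)
  if (is.na(s)) stopf("unknown subject '%s'", subject)
  if (is.na(r)) stopf("unknown relation '%s'", relation)
  candidate_pool <- unique(candidate_pool)
  c_idx <- match(candidate_pool, ids)
  if (anyNA(c_idx))
    stopf("unknown candidate '%s'", candidate_pool[which(is.na(c_idx))[1]])

  filtered_out <- character()
  if (!is.null(filter_set) && nrow(filter_set)) {
    hit <- filter_set$subject == subject & filter_set$relation == relation
    filtered_out <- intersect(candidate_pool,
                              unique(filter_set$object[hit]))
  }
  keep <- !candidate_pool %in% filtered_out
  cand <- candidate_pool[keep]
  scores <- score_candidates(model, s, r, c_idx[keep])
  ord <- order(-scores, cand)
  structure(list(subject = subject, relation = relation,
                 candidates = cand[ord], scores = scores[ord],
                 filtered_out = filtered_out),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("<ranked_list> (%s, %s): %d candidates, %d filtered\n",
              x$subject, x$relation, length(x$candidates),
              length(x$filtered_out)))
  invisible(x)
}

ranked_candidates <- function(ranked) {
  if (inherits(ranked, "ranked_list")) ranked$candidates
  else as.character(ranked)
}

#' Recall at rank k
#'
#' Fraction of a query's ground-truth positives found in the top `k`
#' ranked candidates.
#'
#' @param ranked a [rank_objects()] result (or a character vector already
#'   in rank order)
#' @param positives nonempty character vector of ground-truth positive ids
#' @param k maximum rank of interest (>= 1)
#' @return recall in \[0, 1\]
#' @export
recall_at_k <- function(ranked, positives, k) {
  if (!length(positives)) stopf("recall is undefined with no positives")
  if (k < 1L) stopf("k must be >= 1")
  cand <- ranked_candidates(ranked)
  top <- cand[seq_len(min(k, length(cand)))]
  length(intersect(positives, top)) / length(unique(positives))
}

#' Average precision of a ranked list
#'
#' \deqn{AP = \frac{\sum_{k=1}^{N} P(k)\,rel(k)}{GTP}} where `rel(k)`
#' indicates a positive at rank k, `P(k)` is precision over the top k, `N`
#' the rank cutoff, and GTP the *total* number of ground-truth positives
#' for the query (not capped at N), so truncated lists are penalized.
#'
#' @param ranked a [rank_objects()] result or ordered id vector
#' @param positives nonempty character vector of positive ids
#' @param N rank cutoff; default the full list length
#' @return average precision in \[0, 1\]
#' @export
average_precision <- function(ranked, positives, N = NULL) {
  if (!length(positives)) stopf("AP is undefined with no positives")
  cand <- ranked_candidates(ranked)
  N <- min(N %||% length(cand), length(cand))
  if (N < 1L) stopf("N must be >= 1")
  rel <- as.integer(cand[seq_len(N)] %in% positives)
  gtp <- length(unique(positives))
  prec_at_k <- cumsum(rel) / seq_len(N)
  sum(prec_at_k * rel) / gtp
}

#' Mean average precision over diseases
#'
#' @param per_disease_ap nonempty numeric vector (or named map) of
#'   per-disease AP values
#' @return unweighted mean AP
#' @export
mean_average_precision <- function(per_disease_ap) {
  ap <- unlist(per_disease_ap, use.names = FALSE)
  if (!length(ap)) stopf("empty AP map")
  mean(ap)
}

#' Averaged recall-vs-rank curve
#'
#' For each k in `k_grid`, the simple mean over queries of recall@k.  The
#' curve is non-decreasing in k by construction.
#'
#' @param ranked_lists list of [rank_objects()] results (or ordered id
#'   vectors), one per disease
#' @param positives_list parallel list of positive id vectors
#' @param k_grid ascending integer vector of rank cutoffs
#' @return named numeric vector, one averaged recall per k
#' @export
recall_curve <- function(ranked_lists, positives_list, k_grid) {
  if (!length(ranked_lists) || length(ranked_lists) != length(positives_list))
    stopf("ranked_lists and positives_list must be nonempty and parallel")
  if (is.unsorted(k_grid)) stopf("k_grid must be sorted ascending")
  out <- vapply(k_grid, function(k) {
    mean(mapply(function(rl, pos) recall_at_k(rl, pos, k),
                ranked_lists, positives_list))
  }, numeric(1))
  stats::setNames(out, paste0("recall@", k_grid))
}

# ---------------------------------------------------------------------------
# Whole-benchmark evaluation

# Build per-disease filtered rankings for the triples in eval_triples.
# Candidate pool = every entity of the benchmark relation's object type.
per_disease_rankings <- function(model, kg, eval_triples, filter_triples,
                                 benchmark_relation, diseases = NULL) {
  rel <- kg$relations[kg$relations$name == benchmark_relation, ]
  if (nrow(rel) != 1L) stopf("unknown relation '%s'", benchmark_relation)
  pool <- kg$entities$id[kg$entities$type_label == rel$object_type]
  bench <- eval_triples[eval_triples$relation == benchmark_relation, ,
                        drop = FALSE]
  subjects <- sort(unique(bench$subject))
  if (!is.null(diseases)) subjects <- intersect(subjects, diseases)
  out <- lapply(subjects, function(dz) {
    pos <- unique(bench$object[bench$subject == dz])
    ranked <- rank_objects(model, dz, benchmark_relation, pool,
                           filter_set = filter_triples)
    # positives entirely filtered out leave recall undefined
    pos <- setdiff(pos, ranked$filtered_out)
    if (!length(pos)) return(NULL)
    list(disease = dz, ranked = ranked, positives = pos)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Evaluate a trained model on a benchmark split
#'
#' For every disease with at least one test positive, ranks the full
#' candidate pool (all entities of the benchmark relation's object type),
#' filters train and validation edges from the list, and computes AP and
#' recall@k over `k_grid`.  Diseases whose test positives were all
#' filtered (recall undefined) are excluded from the averages, with a
#' logged count.
#'
#' @param model an [embedding_set()]
#' @param kg the underlying `knowledge_graph`
#' @param split the `data_split` whose test set is evaluated
#' @param k_grid rank cutoffs for the recall curve
#' @param ap_cutoff rank cutoff N for AP (`NULL` = full list)
#' @param diseases optional disease-id restriction (e.g. the output of
#'   [filter_benchmark_diseases()])
#' @return object of class `eval_report`: `per_disease` data.frame
#'   (disease, GTP, AP, recall@k columns), `aggregate` (mAP and averaged
#'   recall@k), `D`, `k_grid`
#' @export
evaluate_model <- function(model, kg, split, k_grid = c(50, 100, 200, 500),
                           ap_cutoff = NULL, diseases = NULL) {
  filter_triples <- rbind(split$train, split$valid)
  rl <- per_disease_rankings(model, kg, split$test, filter_triples,
                             split$benchmark_relation, diseases = diseases)
  n_dropped <- length(setdiff(unique(
    split$test$subject[split$test$relation == split$benchmark_relation]),
    vapply(rl, `[[`, character(1), "disease")))
  if (n_dropped > 0L)
    kg_log(sprintf("%d disease(s) excluded from averages (no scoreable test positives)",
                   n_dropped))
  if (!length(rl)) stopf("no disease has scoreable test positives")

  per <- do.call(rbind, lapply(rl, function(x) {
    rec <- vapply(k_grid, function(k) recall_at_k(x$ranked, x$positives, k),
                  numeric(1))
    row <- data.frame(disease = x$disease, GTP = length(x$positives),
                      AP = average_precision(x$ranked, x$positives,
                                             N = ap_cutoff),
                      stringsAsFactors = FALSE)
    row[paste0("recall@", k_grid)] <- as.list(rec)
    row
  }))
  rownames(per) <- NULL
  agg <- c(mAP = mean(per$AP),
           colMeans(per[paste0("recall@", k_grid)]))
  structure(list(per_disease = per, aggregate = agg, D = nrow(per),
                 k_grid = k_grid),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d disease(s)\n", x$D))
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.tsv` (one row per disease: disease, GTP, AP, recall@k
#' columns) and `aggregate.json` (mAP, averaged recall@k, disease count).
#'
#' @param report an [evaluate_model()] result
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_disease, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(D = report$D, k_grid = report$k_grid,
         aggregate = as.list(report$aggregate)),
    file.path(dir, "aggregate.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write per-disease ranked predictions
#'
#' One TSV per disease: rank, entity_id, raw_score, normalized_score.
#'
#' @param ranked a [rank_objects()] result
#' @param path output TSV path
#' @param normalization score normalization mode, see [normalize_score()]
#' @return `path`, invisibly
#' @export
write_ranked_list <- function(ranked, path, normalization = "sigmoid") {
  df <- data.frame(rank = seq_along(ranked$candidates),
                   entity_id = ranked$candidates,
                   raw_score = ranked$scores,
                   normalized_score = normalize_score(ranked$scores,
                                                      normalization))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Score-distribution comparison

#' Compare two score distributions (MWW with Bonferroni correction)
#'
#' Two-sided Mann-Whitney-Wilcoxon test of `scores_a` against `scores_b`,
#' with the significance threshold Bonferroni-corrected for
#' `n_comparisons` simultaneous tests (e.g. alpha 0.05 over 3 comparisons
#' gives a corrected threshold of ~0.0167).  Medians of both samples are
#' reported alongside the U statistic.
#'
#' @param scores_a,scores_b nonempty numeric vectors
#' @param n_comparisons number of simultaneous comparisons (>= 1)
#' @param alpha family-wise significance level
#' @return list of class `mww_result`: `U`, `p_value`, `medians`,
#'   `alpha_corrected`, `significant`
#' @export
compare_score_distributions <- function(scores_a, scores_b,
                                        n_comparisons = 1L, alpha = 0.05) {
  if (!length(scores_a) || !length(scores_b))
    stopf("both score vectors must be nonempty")
  if (n_comparisons < 1L) stopf("n_comparisons must be >= 1")
  ht <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, alternative = "two.sided"))
  alpha_corrected <- alpha / n_comparisons
  structure(list(U = unname(ht$statistic), p_value = ht$p.value,
                 medians = c(a = stats::median(scores_a),
                             b = stats::median(scores_b)),
                 alpha_corrected = alpha_corrected,
                 significant = ht$p.value < alpha_corrected),
            class = "mww_result")
}

#' @export
print.mww_result <- function(x, ...) {
  cat(sprintf("<mww_result> U=%.1f p=%.4g medians=(%.4g, %.4g) alpha*=%.4g %s\n",
              x$U, x$p_value, x$medians[1], x$medians[2],
              x$alpha_corrected,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
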
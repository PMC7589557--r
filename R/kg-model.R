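#' Construct a typed knowledge graph
#'
#' A knowledge graph is a set of typed entities connected by directed,
#' labeled relations; each fact is a (subject, relation, object) triple,
#' optionally tagged with the calendar year the fact first surfaced.
#' Facts absent from the graph are treated as false (closed-world
#' assumption), which is how negative examples are obtained during
#' training and evaluation.
#'
#' Duplicate (subject, relation, object) triples are collapsed to one; if
#' duplicates carry conflicting years the earliest year is kept, matching
#' the earliest-mention rule used for time tagging.
#'
#' @param entities data.frame with columns `id` (unique character ids) and
#'   `type_label` (entity type, e.g. `"GeneProtein"`, `"Disease"`).
#' @param relations data.frame with columns `name`, `subject_type`,
#'   `object_type` declaring each directed relation's type signature.
#' @param triples data.frame with columns `subject`, `relation`, `object`
#'   and optionally `year` (4-digit integer or `NA`).
#' @return An object of class `knowledge_graph` with elements `entities`,
#'   `relations` and `triples`.
#' @seealso [read_edge_list()], [split_random()], [split_time()]
#' @export
knowledge_graph <- function(entities, relations, triples = NULL) {
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (!all(c("id", "type_label") %in% names(entities)))
    stopf("entities must have columns 'id' and 'type_label'")
  if (!all(c("name", "subject_type", "object_type") %in% names(relations)))
    stopf("relations must have columns 'name', 'subject_type', 'object_type'")
  entities$id <- as.character(entities$id)
  entities$type_label <- as.character(entities$type_label)
  if (anyDuplicated(entities$id))
    stopf("duplicate entity ids: %s",
          paste(unique(entities$id[duplicated(entities$id)]), collapse = ", "))
  if (anyDuplicated(relations$name))
    stopf("duplicate relation names")

  if (is.null(triples) || nrow(as.data.frame(triples)) == 0L) {
    triples <- data.frame(subject = character(), relation = character(),
                          object = character(), year = integer(),
                          stringsAsFactors = FALSE)
  } else {
    triples <- as.data.frame(triples, stringsAsFactors = FALSE)
    if (!all(c("subject", "relation", "object") %in% names(triples)))
      stopf("triples must have columns 'subject', 'relation', 'object'")
    if (is.null(triples$year)) triples$year <- NA_integer_
    triples <- triples[c("subject", "relation", "object", "year")]
    triples$subject <- as.character(triples$subject)
    triples$relation <- as.character(triples$relation)
    triples$object <- as.character(triples$object)
    triples$year <- as.integer(triples$year)

    bad_year <- !is.na(triples$year) &
      (triples$year < 1000L | triples$year > 9999L)
    if (any(bad_year))
      stopf("year must be a 4-digit integer; offending triple(s): %s",
            paste(utils::head(which(bad_year), 5L), collapse = ", "))

    unknown <- setdiff(c(triples$subject, triples$object), entities$id)
    if (length(unknown))
      stopf("triples reference undeclared entities: %s",
            paste(utils::head(unknown, 5L), collapse = ", "))
    unknown_rel <- setdiff(triples$relation, relations$name)
    if (length(unknown_rel))
      stopf("triples reference undeclared relations: %s",
            paste(unknown_rel, collapse = ", "))

    # type-signature check
    etype <- stats::setNames(entities$type_label, entities$id)
    sig_s <- stats::setNames(relations$subject_type, relations$name)
    sig_o <- stats::setNames(relations$object_type, relations$name)
    bad <- etype[triples$subject] != sig_s[triples$relation] |
      etype[triples$object] != sig_o[triples$relation]
    if (any(bad)) {
      b <- triples[which(bad)[1L], ]
      stopf("triple (%s, %s, %s) violates the relation's type signature",
            b$subject, b$relation, b$object)
    }

    # dedup (s, r, o), keeping the minimum year among duplicates
    key <- paste(triples$subject, triples$relation, triples$object, sep = "\r")
    if (anyDuplicated(key)) {
      n_dup <- sum(duplicated(key))
      min_year <- tapply(triples$year, key, function(y) {
        if (all(is.na(y))) NA_integer_ else min(y, na.rm = TRUE)
      })
      triples <- triples[!duplicated(key), ]
      triples$year <- as.integer(min_year[paste(triples$subject,
                                                triples$relation,
                                                triples$object, sep = "\r")])
      kg_log(sprintf("collapsed %d duplicate triple(s)", n_dup))
    }
    rownames(triples) <- NULL
  }

  structure(list(entities = entities, relations = relations,
                 triples = triples),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d entities (%d types), %d relations, %d triples\n",
              nrow(x$entities), length(unique(x$entities$type_label)),
              nrow(x$relations), nrow(x$triples)))
  tab <- table(x$triples$relation)
  if (length(tab)) {
    cat("triples per relation:\n")
    for (r in names(tab)) cat(sprintf("  %-32s %6d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Entity type lookup
#' @param kg a `knowledge_graph`
#' @return named character vector mapping entity id to type label
#' @keywords internal
entity_types <- function(kg) {
  stats::setNames(kg$entities$type_label, kg$entities$id)
}

# ---------------------------------------------------------------------------
# Edge-list I/O.  Format: UTF-8 TSV with a header line, one triple per row,
# columns subject, relation, object, year (year empty when untagged);
# comment lines are prefixed '#'.  The entity dictionary is a two-column
# TSV: id, type_label.

read_tsv_lines <- function(path, n_fields, what) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(list(fields = list(), lines = integer()))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  len <- lengths(parts)
  bad <- len < n_fields[1] | len > n_fields[2]
  if (any(bad))
    stopf("malformed %s row at line %d of %s (expected %d-%d tab-separated fields, got %d)",
          what, idx[which(bad)[1L]], path, n_fields[1], n_fields[2],
          len[which(bad)[1L]])
  list(fields = parts, lines = idx)
}

#' Read a knowledge graph from an edge list and entity dictionary
#'
#' @param path TSV edge list: columns subject, relation, object, optional
#'   year; a header row is expected; `#`-prefixed lines are comments.
#' @param entity_dict TSV entity dictionary: columns id, type_label (header
#'   row expected).
#' @param relation_schema optional data.frame (`name`, `subject_type`,
#'   `object_type`) declaring relation signatures.  When omitted, each
#'   relation's signature is inferred from its first triple and all other
#'   triples of that relation must agree with it.
#' @return a validated [knowledge_graph()]
#' @export
read_edge_list <- function(path, entity_dict, relation_schema = NULL) {
  dict <- read_tsv_lines(entity_dict, c(2L, 2L), "entity dictionary")
  df <- do.call(rbind, lapply(dict$fields, function(p) p[1:2]))
  if (is.null(df)) stopf("entity dictionary %s is empty", entity_dict)
  entities <- data.frame(id = df[, 1], type_label = df[, 2],
                         stringsAsFactors = FALSE)
  if (identical(unname(unlist(entities[1, ])), c("id", "type_label")))
    entities <- entities[-1, , drop = FALSE]
  rownames(entities) <- NULL

  edges <- read_tsv_lines(path, c(3L, 4L), "edge")
  if (length(edges$fields)) {
    pad <- lapply(edges$fields, function(p) c(p, rep("", 4L))[1:4])
    m <- do.call(rbind, pad)
    triples <- data.frame(subject = m[, 1], relation = m[, 2],
                          object = m[, 3], year = m[, 4],
                          stringsAsFactors = FALSE)
    if (identical(triples$subject[1], "subject"))
      triples <- triples[-1, , drop = FALSE]
    yr <- trimws(triples$year)
    bad_yr <- nzchar(yr) & !grepl("^[0-9]{4}$", yr)
    if (any(bad_yr))
      stopf("malformed year '%s' in edge list %s", yr[which(bad_yr)[1]], path)
    triples$year <- ifelse(nzchar(yr), suppressWarnings(as.integer(yr)),
                           NA_integer_)
  } else {
    triples <- NULL
  }

  if (is.null(relation_schema)) {
    if (is.null(triples) || nrow(triples) == 0L) {
      relation_schema <- data.frame(name = character(),
                                    subject_type = character(),
                                    object_type = character(),
                                    stringsAsFactors = FALSE)
    } else {
      etype <- stats::setNames(entities$type_label, entities$id)
      relation_schema <- unique(data.frame(
        name = triples$relation,
        subject_type = unname(etype[triples$subject]),
        object_type = unname(etype[triples$object]),
        stringsAsFactors = FALSE))
      if (anyDuplicated(relation_schema$name))
        stopf("relation '%s' appears with inconsistent type signatures",
              relation_schema$name[duplicated(relation_schema$name)][1])
    }
  }
  knowledge_graph(entities, relation_schema, triples)
}

#' Write a knowledge graph as an edge list (and optionally a dictionary)
#'
#' Round-trip guarantee: `read_edge_list()` applied to the written files
#' reproduces the graph's entity, relation and triple sets exactly.
#'
#' @param kg a `knowledge_graph`
#' @param path output edge-list TSV path
#' @param entity_dict optional path for the entity dictionary TSV
#' @return `path`, invisibly
#' @export
write_edge_list <- function(kg, path, entity_dict = NULL) {
  tr <- kg$triples
  yr <- ifelse(is.na(tr$year), "", as.character(tr$year))
  lines <- c("subject\trelation\tobject\tyear",
             if (nrow(tr)) paste(tr$subject, tr$relation, tr$object, yr,
                                 sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  if (!is.null(entity_dict))
    write_entity_dict(kg, entity_dict)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_entity_dict <- function(kg, entity_dict) {
  con <- file(entity_dict, open = "wb")
  on.exit(close(con))
  writeLines(c("id\ttype_label",
               paste(kg$entities$id, kg$entities$type_label, sep = "\t")),
             con, useBytes = TRUE)
  invisible(entity_dict)
}

# ---------------------------------------------------------------------------
# Benchmark splits

new_data_split <- function(train, valid, test, benchmark_relation, provenance) {
  empty <- data.frame(subject = character(), relation = character(),
                      object = character(), year = integer(),
                      stringsAsFactors = FALSE)
  fix <- function(d) {
    if (is.null(d) || nrow(d) == 0L) return(empty)
    rownames(d) <- NULL
    d[c("subject", "relation", "object", "year")]
  }
  structure(list(train = fix(train), valid = fix(valid), test = fix(test),
                 benchmark_relation = benchmark_relation,
                 provenance = provenance),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> [%s] train=%d valid=%d test=%d (benchmark: %s)\n",
              x$provenance$method, nrow(x$train), nrow(x$valid),
              nrow(x$test), x$benchmark_relation))
  invisible(x)
}

#' Random train/valid/test split of the benchmark relation
#'
#' Triples of the benchmark relation are partitioned by edge count into
#' train/valid/test at the given fractions (default 60\%/20\%/20\%); all
#' triples of every other relation go to train.  Rounding: the validation
#' and test sizes are `floor(fraction * count)`; train takes the remainder,
#' so train is never starved by rounding.
#'
#' @param kg a `knowledge_graph`
#' @param benchmark_relation relation name used for validation and test
#' @param fractions length-3 numeric summing to 1 (train, valid, test)
#' @param seed integer seed; the same seed always yields the same partition
#' @return a `data_split`
#' @export
split_random <- function(kg, benchmark_relation, fractions = c(0.6, 0.2, 0.2),
                         seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must be three proportions summing to 1")
  if (!benchmark_relation %in% kg$relations$name)
    stopf("benchmark relation '%s' not declared in graph", benchmark_relation)
  is_bench <- kg$triples$relation == benchmark_relation
  bench <- kg$triples[is_bench, , drop = FALSE]
  rest <- kg$triples[!is_bench, , drop = FALSE]
  n <- nrow(bench)
  if (n == 0L)
    stopf("no triples of benchmark relation '%s' to partition",
          benchmark_relation)
  n_valid <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  perm <- with_seed(seed, sample.int(n))
  valid_idx <- perm[seq_len(n_valid)]
  test_idx <- perm[n_valid + seq_len(n_test)]
  train_idx <- perm[-seq_len(n_valid + n_test)]
  new_data_split(
    train = rbind(rest, bench[train_idx, , drop = FALSE]),
    valid = bench[valid_idx, , drop = FALSE],
    test = bench[test_idx, , drop = FALSE],
    benchmark_relation = benchmark_relation,
    provenance = list(method = "random", fractions = fractions, seed = seed))
}

#' Temporal (time-sliced) train/test split
#'
#' Simulates prospective prediction: the model trains only on edges first
#' reported up to and including `year_threshold` and is tested on benchmark
#' edges reported strictly after it.  With `window_years = w` the test set
#' is bounded to years `threshold + 1 .. threshold + w` inclusive (e.g.
#' threshold 2010, window 5 tests on 2011-2015); without a window every
#' benchmark edge after the threshold is tested.  Validation is empty
#' (train/test mode).
#'
#' @param kg a `knowledge_graph`
#' @param year_threshold last year included in training
#' @param window_years test-window width in years, or `NULL` for unbounded
#' @param relations_with_years relation names whose triples must all carry
#'   year tags (an untagged triple of such a relation is an error)
#' @param benchmark_relation relation evaluated in the test set; must be in
#'   `relations_with_years`
#' @param untagged what to do with triples of relations outside
#'   `relations_with_years`: `"train"` (default) places them all in train;
#'   `"drop"` discards them
#' @return a `data_split` with empty `valid`
#' @export
split_time <- function(kg, year_threshold, window_years = NULL,
                       relations_with_years, benchmark_relation,
                       untagged = c("train", "drop")) {
  untagged <- match.arg(untagged)
  if (!benchmark_relation %in% relations_with_years)
    stopf("benchmark relation must be one of relations_with_years")
  tr <- kg$triples
  tagged <- tr$relation %in% relations_with_years
  missing_year <- tagged & is.na(tr$year)
  if (any(missing_year)) {
    off <- tr[missing_year, , drop = FALSE]
    stopf("untagged triple(s) in a year-tagged relation, e.g. (%s, %s, %s)%s",
          off$subject[1], off$relation[1], off$object[1],
          if (nrow(off) > 1L) sprintf(" and %d more", nrow(off) - 1L) else "")
  }
  train <- tr[tagged & tr$year <= year_threshold, , drop = FALSE]
  if (untagged == "train")
    train <- rbind(tr[!tagged, , drop = FALSE], train)
  in_test <- tr$relation == benchmark_relation & tr$year > year_threshold
  if (!is.null(window_years))
    in_test <- in_test & tr$year <= year_threshold + window_years
  new_data_split(
    train = train, valid = NULL, test = tr[in_test, , drop = FALSE],
    benchmark_relation = benchmark_relation,
    provenance = list(method = "time", year_threshold = year_threshold,
                      window_years = window_years,
                      relations_with_years = relations_with_years,
                      untagged = untagged))
}

#' Earliest-mention year tag for an edge
#'
#' An edge observed in several publications is dated by the earliest year
#' in its mention list, on the assumption that the first literature mention
#' marks when the relationship surfaced.
#'
#' @param mention_years nonempty vector of 4-digit years
#' @return the minimum year, as integer
#' @export
assign_edge_year <- function(mention_years) {
  if (length(mention_years) == 0L)
    stopf("cannot time-tag an edge with an empty mention-year list")
  y <- as.integer(mention_years)
  if (anyNA(y) || any(y < 1000L | y > 9999L))
    stopf("mention years must be 4-digit integers")
  min(y)
}

#' Benchmark diseases with sufficient gene degree
#'
#' Diseases whose benchmark-relation degree (count of distinct GeneProtein
#' neighbors) falls below `min_degree` are typically disease subtypes;
#' removing them from the test set prevents information leakage between
#' near-identical train and test diseases.
#'
#' @param kg a `knowledge_graph`
#' @param benchmark_relation benchmark relation name
#' @param min_degree minimum number of distinct gene neighbors (>= 0)
#' @param gene_type type label counted as a gene neighbor
#' @return character vector of retained disease ids (sorted)
#' @export
filter_benchmark_diseases <- function(kg, benchmark_relation, min_degree = 30L,
                                      gene_type = "GeneProtein") {
  if (min_degree < 0L) stopf("min_degree must be >= 0")
  rel <- kg$relations[kg$relations$name == benchmark_relation, ]
  if (nrow(rel) != 1L) stopf("unknown benchmark relation '%s'",
                             benchmark_relation)
  tr <- kg$triples[kg$triples$relation == benchmark_relation, , drop = FALSE]
  etype <- entity_types(kg)
  # orient: disease endpoint is the non-gene side of the signature
  if (rel$object_type == gene_type) {
    disease <- tr$subject; gene <- tr$object
    disease_type <- rel$subject_type
  } else if (rel$subject_type == gene_type) {
    disease <- tr$object; gene <- tr$subject
    disease_type <- rel$object_type
  } else {
    stopf("benchmark relation '%s' has no %s endpoint", benchmark_relation,
          gene_type)
  }
  all_diseases <- kg$entities$id[kg$entities$type_label == disease_type]
  deg <- tapply(gene, disease, function(g) length(unique(g)))
  degree <- stats::setNames(integer(length(all_diseases)), all_diseases)
  degree[names(deg)] <- as.integer(deg)
  sort(names(degree)[degree >= min_degree])
}

# ---------------------------------------------------------------------------
# Clinical-phase outcome labeling

#' Ordered clinical-phase vocabulary
#'
#' @return character vector of phase labels in ascending order
#' @export
phase_levels <- function() {
  c("Discontinued", "Discovery", "Phase I", "Phase II", "Phase III",
    "Pre-registration or higher")
}

#' Build a clinical-phase record table
#'
#' One row per (gene, disease, compound) experiment, tagged with the
#' maximum clinical phase that experiment reached and whether the program
#' was discontinued at that phase.
#'
#' @param gene,disease,compound character vectors
#' @param phase character vector drawn from [phase_levels()]
#' @param discontinued logical vector: program discontinued at `phase`
#' @return data.frame of class `phase_record`
#' @export
phase_record <- function(gene, disease, compound, phase,
                         discontinued = FALSE) {
  discontinued <- rep_len(as.logical(discontinued),
                          max(length(gene), length(phase)))
  df <- data.frame(gene = as.character(gene),
                   disease = as.character(disease),
                   compound = as.character(compound),
                   phase = as.character(phase),
                   discontinued = as.logical(discontinued),
                   stringsAsFactors = FALSE)
  bad <- !df$phase %in% phase_levels()
  if (any(bad))
    stopf("unknown phase '%s' (valid: %s)", df$phase[bad][1],
          paste(phase_levels(), collapse = ", "))
  class(df) <- c("phase_record", "data.frame")
  df
}

#' Label a gene-disease pair as clinical success, failure, or unassigned
#'
#' A pair tested with several compounds is assigned the single highest
#' phase reached by any of them.  The aggregated pair is a *failure* iff
#' that highest phase is Phase II or Phase III and every program reaching
#' it was discontinued (late-stage discontinuations are overwhelmingly
#' efficacy failures); a *success* iff the highest phase is
#' "Pre-registration or higher"; anything else (Discontinued, Discovery,
#' Phase I, or an ongoing Phase II/III) is *unassigned*, since those
#' outcomes are ambiguous about efficacy.
#'
#' @param records [phase_record()] rows, all for the same gene-disease pair
#' @return character scalar `"success"`, `"failure"` or `"unassigned"`,
#'   with attributes `max_phase` and `discontinued`
#' @export
map_phase_to_outcome <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stopf("empty phase-record list")
  pair <- unique(records[c("gene", "disease")])
  if (nrow(pair) != 1L)
    stopf("records span %d gene-disease pairs; expected one", nrow(pair))
  lev <- match(records$phase, phase_levels())
  top <- max(lev)
  max_phase <- phase_levels()[top]
  disc <- all(records$discontinued[lev == top])
  outcome <-
    if (max_phase == "Pre-registration or higher") "success"
    else if (max_phase %in% c("Phase II", "Phase III") && disc) "failure"
    else "unassigned"
  structure(outcome, max_phase = max_phase, discontinued = disc)
}

#' Label every gene-disease pair in a phase table
#'
#' @param records a [phase_record()] table (any number of pairs)
#' @return data.frame with one row per pair: gene, disease, max_phase,
#'   outcome
#' @export
label_outcomes <- function(records) {
  if (nrow(records) == 0L) stopf("empty phase-record table")
  key <- paste(records$gene, records$disease, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(i) {
    r <- records[i, , drop = FALSE]
    o <- map_phase_to_outcome(r)
    data.frame(gene = r$gene[1], disease = r$disease[1],
               max_phase = attr(o, "max_phase"), outcome = as.character(o),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a clinical-phase table
#'
#' TSV columns: gene_id, disease_id, compound, phase, discontinued_flag
#' (0/1 or TRUE/FALSE), with a header row.
#'
#' @param path TSV path
#' @return a [phase_record()] table
#' @export
read_phase_table <- function(path) {
  rows <- read_tsv_lines(path, c(5L, 5L), "phase table")
  m <- do.call(rbind, rows$fields)
  if (is.null(m)) stopf("phase table %s is empty", path)
  if (identical(m[1, 1], "gene_id")) m <- m[-1, , drop = FALSE]
  phase_record(gene = m[, 1], disease = m[, 2], compound = m[, 3],
               phase = m[, 4],
               discontinued = m[, 5] %in% c("1", "TRUE", "true"))
}
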
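test_that("knowledge_graph validates schema and deduplicates triples", {
  tr <- data.frame(subject = c("D1", "D1", "D1"),
                   relation = "TherapeuticRelationship",
                   object = c("G1", "G1", "G2"),
                   year = c(2005L, 1999L, NA),
                   stringsAsFactors = FALSE)
  kg <- toy_kg(triples = tr)
  expect_equal(nrow(kg$triples), 2L)
  # duplicate (s,r,o) keeps the minimum year (earliest-mention rule)
  expect_equal(kg$triples$year[kg$triples$object == "G1"], 1999L)

  expect_error(toy_kg(triples = data.frame(subject = "G1",
                                           relation = "TherapeuticRelationship",
                                           object = "D1")),
               "type signature")
  expect_error(toy_kg(triples = data.frame(subject = "D9",
                                           relation = "TherapeuticRelationship",
                                           object = "G1")),
               "undeclared entities")
  ent <- toy_entities()
  ent$id[2] <- ent$id[1]
  expect_error(knowledge_graph(ent, toy_relations()), "duplicate entity ids")
})

test_that("edge-list I/O round-trips exactly, including years", {
  set.seed(11)
  kg <- random_toy_kg(years = TRUE)
  edges <- withr::local_tempfile(fileext = ".tsv")
  dict <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(kg, edges, entity_dict = dict)
  kg2 <- read_edge_list(edges, dict)
  ord <- function(d) d[do.call(order, d), ]
  expect_equal(ord(kg2$triples), ord(kg$triples), ignore_attr = TRUE)
  expect_equal(kg2$entities, kg$entities)
  # years preserved verbatim
  expect_identical(sort(kg2$triples$year), sort(kg$triples$year))
})

test_that("edge-list reader handles empty files, dedup and malformed rows", {
  dict <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ttype_label", "G1\tGeneProtein", "D1\tDisease"), dict)
  edges <- withr::local_tempfile(fileext = ".tsv")

  writeLines("subject\trelation\tobject\tyear", edges)
  kg <- read_edge_list(edges, dict)
  expect_equal(nrow(kg$entities), 2L)
  expect_equal(nrow(kg$triples), 0L)

  # same (s,r,o) on two lines -> one triple
  writeLines(c("subject\trelation\tobject\tyear",
               "D1\tTR\tG1\t", "D1\tTR\tG1\t"), edges)
  expect_equal(nrow(read_edge_list(edges, dict)$triples), 1L)

  writeLines(c("subject\trelation\tobject\tyear", "D1\tTR"), edges)
  expect_error(read_edge_list(edges, dict), "line 2")

  # zero-triple graph writes a header-only file
  empty <- knowledge_graph(data.frame(id = "G1", type_label = "GeneProtein"),
                           toy_relations())
  out <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(empty, out)
  expect_equal(readLines(out), "subject\trelation\tobject\tyear")
})

test_that("per-relation counts after reading match an independent text scan", {
  cfg <- small_synth_config(seed = 21)
  sim <- generate_synthetic_kg(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_kg(sim$kg, sim$truth, dir)
  kg2 <- read_edge_list(file.path(dir, "edges.tsv"),
                        file.path(dir, "entities.tsv"))
  # independent scan: count relation column occurrences in the raw text
  lines <- readLines(file.path(dir, "edges.tsv"))[-1]
  scanned <- table(vapply(strsplit(lines, "\t"), `[`, character(1), 2))
  got <- table(kg2$triples$relation)
  expect_equal(as.vector(got[names(scanned)]), as.vector(scanned))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(unlist(manifest$per_relation_counts)[names(scanned)],
               stats::setNames(as.integer(scanned), names(scanned)))
})

test_that("split_random produces exact floor counts and is deterministic", {
  set.seed(3)
  mk <- function(n_bench) {
    ent <- toy_entities(n_genes = max(10, n_bench), n_diseases = 4)
    genes <- ent$id[ent$type_label == "GeneProtein"]
    bench <- data.frame(subject = rep(paste0("D", 1:4), length.out = n_bench),
                        relation = "TherapeuticRelationship",
                        object = genes[seq_len(n_bench)])
    knowledge_graph(ent, toy_relations(), bench)
  }
  # 60/20/20 by edge count, floor for valid and test, remainder to train
  for (n in c(10L, 100L)) {
    sp <- split_random(mk(n), "TherapeuticRelationship", seed = 1)
    expect_equal(nrow(sp$valid), floor(0.2 * n))
    expect_equal(nrow(sp$test), floor(0.2 * n))
    expect_equal(nrow(sp$train), n - 2 * floor(0.2 * n))
  }
  # 60/40 train/valid mode leaves the test set empty
  sp <- split_random(mk(10), "TherapeuticRelationship",
                     fractions = c(0.6, 0.4, 0), seed = 1)
  expect_equal(nrow(sp$valid), 4L)
  expect_equal(nrow(sp$test), 0L)
  expect_equal(nrow(sp$train), 6L)

  kg <- random_toy_kg()
  a <- split_random(kg, "TherapeuticRelationship", seed = 9)
  b <- split_random(kg, "TherapeuticRelationship", seed = 9)
  c_ <- split_random(kg, "TherapeuticRelationship", seed = 10)
  expect_identical(a$test, b$test)
  expect_false(identical(a$test$object, c_$test$object))
  expect_equal(nrow(c_$test), nrow(a$test))

  expect_error(split_random(kg, "NoSuchRelation"), "not declared")
})

test_that("random splits are disjoint and complete on random graphs", {
  set.seed(99)
  for (i in 1:25) {
    kg <- random_toy_kg(n_bench = sample(10:40, 1), n_ppi = sample(5:30, 1))
    sp <- split_random(kg, "TherapeuticRelationship",
                       seed = sample.int(1000, 1))
    key <- function(d) paste(d$subject, d$relation, d$object)
    expect_length(intersect(key(sp$train), key(sp$valid)), 0)
    expect_length(intersect(key(sp$train), key(sp$test)), 0)
    expect_length(intersect(key(sp$valid), key(sp$test)), 0)
    expect_setequal(c(key(sp$train), key(sp$valid), key(sp$test)),
                    key(kg$triples))
    # valid and test hold only benchmark triples
    expect_true(all(sp$valid$relation == "TherapeuticRelationship"))
    expect_true(all(sp$test$relation == "TherapeuticRelationship"))
  }
})

test_that("split_time windows years correctly", {
  ent <- toy_entities(6, 2)
  mk_tr <- function(years) {
    data.frame(subject = "D1", relation = "TherapeuticRelationship",
               object = paste0("G", seq_along(years)), year = years)
  }
  kg <- knowledge_graph(ent, toy_relations(), mk_tr(c(2010, 2011, 2015, 2016)))
  sp <- split_time(kg, 2010, window_years = 5,
                   relations_with_years = "TherapeuticRelationship",
                   benchmark_relation = "TherapeuticRelationship")
  expect_equal(sp$train$year, 2010L)        # year == threshold trains
  expect_setequal(sp$test$year, c(2011L, 2015L)) # window is (thr, thr+5]
  expect_equal(nrow(sp$valid), 0L)

  # unbounded mode: every benchmark edge after the threshold is tested
  sp2 <- split_time(kg, 2005, window_years = NULL,
                    relations_with_years = "TherapeuticRelationship",
                    benchmark_relation = "TherapeuticRelationship")
  expect_equal(nrow(sp2$test), 4L)
  expect_equal(nrow(sp2$train), 0L)

  # threshold above all years -> empty test
  sp3 <- split_time(kg, 2020, window_years = NULL,
                    relations_with_years = "TherapeuticRelationship",
                    benchmark_relation = "TherapeuticRelationship")
  expect_equal(nrow(sp3$test), 0L)
  expect_equal(nrow(sp3$train), 4L)

  # untagged triple in a tagged relation is an error
  kg_bad <- knowledge_graph(ent, toy_relations(),
                            mk_tr(c(2010, NA)))
  expect_error(split_time(kg_bad, 2010, NULL, "TherapeuticRelationship",
                          "TherapeuticRelationship"), "untagged")
})

test_that("split_time routes untagged relations per config and stays sound", {
  set.seed(5)
  for (i in 1:10) {
    kg <- random_toy_kg(years = TRUE)
    # PPI untagged: scrub its years, tag only the benchmark
    kg$triples$year[kg$triples$relation == "PPI"] <- NA_integer_
    thr <- sample(1995:2010, 1)
    sp <- split_time(kg, thr, window_years = 5,
                     relations_with_years = "TherapeuticRelationship",
                     benchmark_relation = "TherapeuticRelationship")
    tagged_train <- sp$train[sp$train$relation == "TherapeuticRelationship", ]
    expect_true(all(tagged_train$year <= thr))
    expect_true(all(sp$test$year > thr & sp$test$year <= thr + 5))
    # untagged PPI triples all land in train by default, none with drop
    expect_equal(sum(sp$train$relation == "PPI"),
                 sum(kg$triples$relation == "PPI"))
    sp_drop <- split_time(kg, thr, window_years = 5,
                          relations_with_years = "TherapeuticRelationship",
                          benchmark_relation = "TherapeuticRelationship",
                          untagged = "drop")
    expect_equal(sum(sp_drop$train$relation == "PPI"), 0L)
  }
})

test_that("assign_edge_year takes the earliest mention and rejects bad input", {
  expect_equal(assign_edge_year(c(2007, 1999, 2015)), 1999L)
  expect_equal(assign_edge_year(2005), 2005L)
  set.seed(2)
  y <- sample(1950:2020, 8)
  expect_equal(assign_edge_year(sample(y)), assign_edge_year(y))
  expect_error(assign_edge_year(integer()), "empty")
  expect_error(assign_edge_year(c(2005, 99)), "4-digit")
})

test_that("filter_benchmark_diseases applies the degree threshold", {
  n_genes <- 40
  ent <- toy_entities(n_genes, 3)
  genes <- paste0("G", 1:n_genes)
  tr <- rbind(
    data.frame(subject = "D1", relation = "TherapeuticRelationship",
               object = genes[1:30]),   # degree 30: retained at cutoff 30
    data.frame(subject = "D2", relation = "TherapeuticRelationship",
               object = genes[1:29]))   # degree 29: removed
  kg <- knowledge_graph(ent, toy_relations(), tr)
  expect_equal(filter_benchmark_diseases(kg, "TherapeuticRelationship", 30),
               "D1")
  # vacuous filter keeps every disease, including the degree-0 one
  expect_setequal(filter_benchmark_diseases(kg, "TherapeuticRelationship", 0),
                  c("D1", "D2", "D3"))
})

test_that("disease filter matches brute force and is monotone in min_degree", {
  set.seed(7)
  for (i in 1:10) {
    kg <- random_toy_kg(n_bench = 50)
    bench <- kg$triples[kg$triples$relation == "TherapeuticRelationship", ]
    brute <- function(min_deg) {
      counts <- tapply(bench$object, bench$subject,
                       function(g) length(unique(g)))
      all_d <- kg$entities$id[kg$entities$type_label == "Disease"]
      deg <- stats::setNames(rep(0L, length(all_d)), all_d)
      deg[names(counts)] <- as.integer(counts)
      sort(names(deg)[deg >= min_deg])
    }
    prev <- NULL
    for (m in c(0, 2, 5, 8)) {
      got <- filter_benchmark_diseases(kg, "TherapeuticRelationship", m)
      expect_equal(got, brute(m))
      if (!is.null(prev)) expect_true(all(got %in% prev)) # monotone
      prev <- got
    }
  }
})

test_that("phase aggregation follows the highest-phase rule", {
  # multi-compound pair: Discovery, Discontinued, Phase II -> Phase II
  rec <- phase_record(gene = "SSTR2", disease = "acromegaly",
                      compound = c("g-02113", "l-363377", "ptr-3172"),
                      phase = c("Discovery", "Discontinued", "Phase II"),
                      discontinued = c(FALSE, TRUE, FALSE))
  out <- map_phase_to_outcome(rec)
  expect_equal(attr(out, "max_phase"), "Phase II")
  expect_equal(as.character(out), "unassigned") # ongoing Phase II: ambiguous

  # Pre-registration or higher -> success
  expect_equal(as.character(map_phase_to_outcome(
    phase_record("g", "d", "c", "Pre-registration or higher"))), "success")
  # highest phase Phase I -> unassigned
  expect_equal(as.character(map_phase_to_outcome(
    phase_record("g", "d", c("c1", "c2"), c("Discovery", "Phase I")))),
    "unassigned")
  # Phase II / III discontinuations -> failure
  for (ph in c("Phase II", "Phase III")) {
    expect_equal(as.character(map_phase_to_outcome(
      phase_record("g", "d", "c", ph, discontinued = TRUE))), "failure")
  }
  # early discontinuation is not a failure
  expect_equal(as.character(map_phase_to_outcome(
    phase_record("g", "d", "c", "Phase I", discontinued = TRUE))),
    "unassigned")
  expect_error(map_phase_to_outcome(phase_record(character(), character(),
                                                 character(), character())),
               "empty")
  expect_error(phase_record("g", "d", "c", "Phase IV"), "unknown phase")
})

test_that("phase outcome is invariant to record order", {
  set.seed(13)
  phases <- phase_levels()
  for (i in 1:20) {
    n <- sample(1:6, 1)
    rec <- phase_record("g", "d", paste0("c", 1:n),
                        sample(phases, n, replace = TRUE),
                        discontinued = sample(c(TRUE, FALSE), n,
                                              replace = TRUE))
    perm <- rec[sample.int(n), ]
    expect_identical(as.character(map_phase_to_outcome(rec)),
                     as.character(map_phase_to_outcome(perm)))
  }
})

test_that("label_outcomes handles multi-pair tables and file round-trip", {
  tbl <- phase_record(gene = c("A", "A", "B"),
                      disease = c("d1", "d1", "d2"),
                      compound = c("c1", "c2", "c3"),
                      phase = c("Discovery", "Phase III",
                                "Pre-registration or higher"),
                      discontinued = c(FALSE, TRUE, FALSE))
  out <- label_outcomes(tbl)
  expect_equal(out$outcome[out$gene == "A"], "failure")
  expect_equal(out$outcome[out$gene == "B"], "success")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tdisease_id\tcompound\tphase\tdiscontinued_flag",
               "A\td1\tc1\tDiscovery\t0",
               "A\td1\tc2\tPhase III\t1"), path)
  rec <- read_phase_table(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(label_outcomes(rec)$outcome, "failure")
})
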
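# Shared in-code fixtures: tiny typed graphs and random-graph generators.

options(kgprio.verbose = FALSE)

toy_entities <- function(n_genes = 5, n_diseases = 3) {
  data.frame(
    id = c(paste0("G", seq_len(n_genes)), paste0("D", seq_len(n_diseases))),
    type_label = c(rep("GeneProtein", n_genes), rep("Disease", n_diseases)),
    stringsAsFactors = FALSE)
}

toy_relations <- function() {
  data.frame(name = c("TherapeuticRelationship", "PPI"),
             subject_type = c("Disease", "GeneProtein"),
             object_type = c("GeneProtein", "GeneProtein"),
             stringsAsFactors = FALSE)
}

toy_kg <- function(n_genes = 5, n_diseases = 3, triples = NULL) {
  knowledge_graph(toy_entities(n_genes, n_diseases), toy_relations(),
                  triples)
}

# random typed graph over the toy schema, for property-style loops
random_toy_kg <- function(n_genes = 20, n_diseases = 6, n_bench = 30,
                          n_ppi = 20, years = FALSE) {
  ent <- toy_entities(n_genes, n_diseases)
  genes <- ent$id[ent$type_label == "GeneProtein"]
  diseases <- ent$id[ent$type_label == "Disease"]
  bench <- unique(data.frame(
    subject = sample(diseases, n_bench, replace = TRUE),
    relation = "TherapeuticRelationship",
    object = sample(genes, n_bench, replace = TRUE),
    stringsAsFactors = FALSE))
  ppi <- unique(data.frame(
    subject = sample(genes, n_ppi, replace = TRUE),
    relation = "PPI",
    object = sample(genes, n_ppi, replace = TRUE),
    stringsAsFactors = FALSE))
  tr <- rbind(bench, ppi)
  tr$year <- if (years) sample(1990:2015, nrow(tr), replace = TRUE)
             else NA_integer_
  knowledge_graph(ent, toy_relations(), tr)
}

# small planted graph used by the slower learning tests
small_synth_config <- function(seed = 1L, ...) {
  synthetic_config(
    entities_per_type = c(GeneProtein = 60L, Disease = 12L, GOProcess = 20L,
                          Pathway = 8L, Compound = 20L),
    edge_density = c(default = 0.04, TherapeuticRelationship = 0.1),
    seed = seed, ...)
}

random_complex_vec <- function(d) {
  list(re = stats::rnorm(d), im = stats::rnorm(d))
}
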
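# Training recipe: Xavier Gaussian initialization, typed negative
# sampling under the closed-world assumption, relation-balanced batches,
# inverted dropout on entity embeddings, binary cross-entropy with logits,
# Adam updates of every embedding matrix, early stopping on a validation
# ranking metric.

#' Training configuration
#'
#' Defaults follow the recipe used at full scale: embedding dimension 200,
#' 5 typed negatives per positive, batches of 3000 with equal per-relation
#' counts, dropout 0.5 on the entity embeddings, Adam, early stopping once
#' the validation metric has not improved for 5 consecutive epochs.
#'
#' @param embedding_dim embedding dimensionality d
#' @param negatives_per_positive corrupted triples drawn per positive
#' @param batch_size examples per batch before negatives are added
#' @param dropout_p per-coordinate zeroing probability, in [0, 1)
#' @param learning_rate Adam step size
#' @param patience_epochs epochs without improvement before stopping
#' @param max_epochs hard cap on training epochs
#' @param seed RNG seed governing initialization, batching, negatives and
#'   dropout
#' @param decoder_name `"complex"`, `"distmult"`, `"cp"` or `"hole"`
#' @param score_normalization `"sigmoid"` maps reported scores to (0, 1)
#' @param improvement_tol minimum validation-metric gain that counts as an
#'   improvement for early stopping
#' @param lr_decay reduce-on-plateau factor: the Adam step size is
#'   multiplied by this after every epoch without validation improvement
#'   (1 disables the schedule); iterates then settle instead of
#'   oscillating around the optimum as stopping approaches
#' @param eval_k rank cutoff of the default validation metric (filtered
#'   average recall at `eval_k` on the benchmark relation)
#' @return a validated list of class `train_config`
#' @export
train_config <- function(embedding_dim = 200L, negatives_per_positive = 5L,
                         batch_size = 3000L, dropout_p = 0.5,
                         learning_rate = 0.01, patience_epochs = 5L,
                         max_epochs = 100L, seed = 1L,
                         decoder_name = "complex",
                         score_normalization = c("sigmoid", "none"),
                         improvement_tol = 1e-4, lr_decay = 0.5,
                         eval_k = 200L) {
  decoder_name <- match.arg(decoder_name, DECODERS)
  score_normalization <- match.arg(score_normalization)
  if (dropout_p < 0 || dropout_p >= 1) stopf("dropout_p must be in [0, 1)")
  for (nm in c("embedding_dim", "negatives_per_positive", "batch_size",
               "patience_epochs")) {
    if (get(nm) < 1L) stopf("%s must be positive", nm)
  }
  if (max_epochs < 0L) stopf("max_epochs must be >= 0")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stopf("lr_decay must be in (0, 1]")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 batch_size = as.integer(batch_size),
                 dropout_p = dropout_p, learning_rate = learning_rate,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), decoder_name = decoder_name,
                 score_normalization = score_normalization,
                 improvement_tol = improvement_tol,
                 lr_decay = lr_decay,
                 eval_k = as.integer(eval_k)),
            class = "train_config")
}

#' Xavier-Gaussian initialized embeddings
#'
#' Every matrix required by the decoder is drawn from a zero-mean Gaussian
#' with Glorot variance scaling, \eqn{\sigma^2 = 2 / (rows + d)}; matrices
#' a decoder does not use (e.g. imaginary parts for DistMult or HolE) are
#' allocated as zeros so the layout is uniform across decoders.
#'
#' @param n entity count
#' @param k relation count
#' @param d embedding dimension
#' @param decoder_name decoder tag, see [embedding_set()]
#' @param seed integer seed, or `NULL` to draw from the current RNG stream
#' @param entity_ids,relation_ids optional rownames for the matrices
#' @return an [embedding_set()]
#' @export
init_embeddings <- function(n, k, d, decoder_name = "complex", seed = NULL,
                            entity_ids = NULL, relation_ids = NULL) {
  decoder_name <- match.arg(decoder_name, DECODERS)
  if (n < 1L || k < 1L || d < 1L) stopf("n, k, d must be positive")
  xavier <- function(rows) {
    matrix(stats::rnorm(rows * d, sd = sqrt(2 / (rows + d))), rows, d)
  }
  zero <- function(rows) matrix(0, rows, d)
  model <- with_seed(seed, {
    switch(decoder_name,
      complex = embedding_set(xavier(n), xavier(n), xavier(k), xavier(k),
                              decoder = "complex"),
      distmult = embedding_set(xavier(n), zero(n), xavier(k), zero(k),
                               decoder = "distmult"),
      cp = embedding_set(xavier(n), zero(n), xavier(k), zero(k),
                         object_real = xavier(n), decoder = "cp"),
      hole = embedding_set(xavier(n), zero(n), xavier(k), zero(k),
                           decoder = "hole"))
  })
  if (!is.null(entity_ids)) {
    rownames(model$entity_real) <- rownames(model$entity_imag) <- entity_ids
    if (!is.null(model$object_real)) rownames(model$object_real) <- entity_ids
  }
  if (!is.null(relation_ids))
    rownames(model$relation_real) <- rownames(model$relation_imag) <-
      relation_ids
  model
}

# ---------------------------------------------------------------------------
# Negative sampling

# entity index pools by type, for a kg whose entities are ordered as in
# kg$entities (row index = embedding row)
type_pools <- function(kg) {
  split(seq_len(nrow(kg$entities)), kg$entities$type_label)
}

#' Typed negative sampling for one positive triple
#'
#' Each corruption replaces the subject or the object (side chosen
#' uniformly) with a uniformly drawn *different* entity of the same type,
#' keeping the relation.  Under the closed-world assumption the corrupted
#' triples are taken as false without checking them against known
#' positives.  If one side has no alternative entity of the required type
#' the other side is corrupted; if neither side is corruptible this is an
#' error.
#'
#' @param positive one-row data.frame (subject, relation, object)
#' @param kg the `knowledge_graph` supplying entity types
#' @param ratio number of negatives to draw (>= 1)
#' @param seed optional seed for reproducible draws
#' @return data.frame of `ratio` corrupted triples
#' @export
sample_negatives <- function(positive, kg, ratio = 5L, seed = NULL) {
  if (ratio < 1L) stopf("ratio must be >= 1")
  etype <- entity_types(kg)
  pools <- split(kg$entities$id, kg$entities$type_label)
  s_pool <- setdiff(pools[[etype[[positive$subject]]]], positive$subject)
  o_pool <- setdiff(pools[[etype[[positive$object]]]], positive$object)
  if (!length(s_pool) && !length(o_pool))
    stopf("no alternative entity of either endpoint type; triple cannot be corrupted")
  with_seed(seed, {
    side <- if (!length(s_pool)) rep("o", ratio)
            else if (!length(o_pool)) rep("s", ratio)
            else sample(c("s", "o"), ratio, replace = TRUE)
    subj <- ifelse(side == "s",
                   sample(c(s_pool, s_pool), ratio, replace = TRUE),
                   positive$subject)
    obj <- ifelse(side == "o",
                  sample(c(o_pool, o_pool), ratio, replace = TRUE),
                  positive$object)
    data.frame(subject = subj, relation = positive$relation, object = obj,
               year = NA_integer_, stringsAsFactors = FALSE)
  })
}

# Vectorized corruption on integer indices (training hot path).
# s_idx/o_idx: positives; each is repeated `ratio` times and one side of
# each copy is replaced by a random same-type entity index.
corrupt_batch <- function(s_idx, r_idx, o_idx, ratio, pools, etype_idx) {
  m <- length(s_idx)
  s <- rep(s_idx, each = ratio)
  r <- rep(r_idx, each = ratio)
  o <- rep(o_idx, each = ratio)
  side_s <- stats::runif(length(s)) < 0.5
  draw <- function(orig) {
    pool_names <- etype_idx[orig]
    new <- orig
    for (tp in unique(pool_names)) {
      rows <- which(pool_names == tp)
      pool <- pools[[tp]]
      if (length(pool) <= 1L) next
      cand <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
      # redraw collisions with the uncorrupted entity
      while (any(hit <- cand == orig[rows]))
        cand[hit] <- pool[sample.int(length(pool), sum(hit), replace = TRUE)]
      new[rows] <- cand
    }
    list(new = new, movable = vapply(pool_names,
                                     function(tp) length(pools[[tp]]) > 1L,
                                     logical(1)))
  }
  ds <- draw(s)
  do_ <- draw(o)
  # fall back to the other side where a pool has no alternative entity
  side_s <- (side_s & ds$movable) | (!do_$movable & ds$movable)
  side_o <- !side_s & do_$movable
  if (any(!side_s & !side_o))
    stopf("triple with no corruptible endpoint in negative sampling")
  s_new <- ifelse(side_s, ds$new, s)
  o_new <- ifelse(side_s, o, do_$new)
  list(s = s_new, r = r, o = o_new)
}

#' Relation-balanced batches
#'
#' Every batch carries `floor(batch_size / #relations)` examples of each
#' relation present in the training set.  Relations with fewer triples
#' than an epoch requires are sampled with replacement, which oversamples
#' rare relations (such as the benchmark relation) and raises their weight
#' during training.  One epoch covers the most frequent relation once:
#' epoch length is `ceiling(max per-relation count / per-relation quota)`
#' batches.
#'
#' @param train data.frame of training triples (subject, relation, object)
#' @param batch_size total examples per batch; must be at least the number
#'   of distinct relations
#' @param seed optional seed; the same seed yields the same batch sequence
#' @return list of integer vectors, each a batch of row indices into
#'   `train`
#' @export
make_balanced_batches <- function(train, batch_size, seed = NULL) {
  rels <- sort(unique(train$relation))
  n_rel <- length(rels)
  if (n_rel == 0L) stopf("empty training set")
  quota <- batch_size %/% n_rel
  if (quota < 1L)
    stopf("batch_size (%d) is smaller than the number of relations (%d)",
          batch_size, n_rel)
  by_rel <- split(seq_len(nrow(train)), train$relation)[rels]
  counts <- lengths(by_rel)
  n_batch <- ceiling(max(counts) / quota)
  needed <- n_batch * quota
  with_seed(seed, {
    seqs <- lapply(by_rel, function(rows) {
      perm <- rows[sample.int(length(rows))]
      if (needed > length(rows)) {
        extra <- rows[sample.int(length(rows), needed - length(rows),
                                 replace = TRUE)]
        c(perm, extra)
      } else perm[seq_len(needed)]
    })
    lapply(seq_len(n_batch), function(b) {
      take <- ((b - 1L) * quota + 1L):(b * quota)
      unlist(lapply(seqs, `[`, take), use.names = FALSE)
    })
  })
}

#' Inverted dropout on embedding coordinates
#'
#' In training mode each coordinate is independently zeroed with
#' probability `p` and survivors are scaled by `1/(1-p)`, so activations
#' keep their expectation and evaluation-mode scoring needs no rescaling.
#' In evaluation mode the input is returned unchanged.
#'
#' @param x numeric vector or matrix of embedding coordinates
#' @param p zeroing probability in [0, 1)
#' @param training logical; dropout only acts when `TRUE`
#' @param seed optional seed
#' @return masked (or untouched) copy of `x`
#' @export
apply_dropout <- function(x, p, training = TRUE, seed = NULL) {
  if (p >= 1 || p < 0) stopf("dropout probability must be in [0, 1)")
  if (!training || p == 0) return(x)
  with_seed(seed, {
    mask <- (stats::runif(length(x)) >= p) / (1 - p)
    x * mask
  })
}

# mask with the same shape as a gathered m x d matrix
dropout_mask <- function(m, d, p) {
  if (p == 0) return(NULL)
  matrix((stats::runif(m * d) >= p) / (1 - p), m, d)
}

#' Binary cross-entropy with logits
#'
#' Positives are labeled 1 and negatives 0; edge probabilities come from
#' the logistic function of the decoder score.  Computed in the
#' numerically stabilized softplus form, so it stays finite for any finite
#' scores.
#'
#' @param pos_scores decoder scores of positive triples (nonempty)
#' @param neg_scores decoder scores of sampled negatives (nonempty)
#' @return mean loss over all examples (nonnegative scalar)
#' @export
bce_loss <- function(pos_scores, neg_scores) {
  if (!length(pos_scores) || !length(neg_scores))
    stopf("pos_scores and neg_scores must be nonempty")
  # -log sigma(phi) = softplus(-phi); -log(1 - sigma(phi)) = softplus(phi)
  mean(c(softplus(-pos_scores), softplus(neg_scores)))
}

# ---------------------------------------------------------------------------
# Loss + analytic gradients

# Accumulate per-row gradient contributions into a dense matrix by index.
scatter_add <- function(G, idx, contrib) {
  A <- rowsum(contrib, idx)
  rows <- as.integer(rownames(A))
  G[rows, ] <- G[rows, , drop = FALSE] + A
  G
}

#' Loss and gradients for a batch of labeled triples
#'
#' Computes the mean binary cross-entropy of the decoder scores against
#' 0/1 labels, together with its analytic gradient with respect to every
#' embedding matrix.  Optional dropout masks (entries 0 or `1/(1-p)`) are
#' applied to the gathered subject and object entity rows before scoring,
#' and the gradient is chained through them.
#'
#' @param model an [embedding_set()]
#' @param s_idx,r_idx,o_idx integer index vectors of equal length
#' @param y 0/1 label vector (1 = positive triple)
#' @param mask_s,mask_o optional dropout mask matrices (m x d), one row
#'   per example
#' @return list with elements `loss` (scalar) and `grads` (named list of
#'   matrices matching the model layout)
#' @export
loss_gradients <- function(model, s_idx, r_idx, o_idx, y,
                           mask_s = NULL, mask_o = NULL) {
  d <- ncol(model$entity_real)
  m <- length(s_idx)
  stopifnot(length(r_idx) == m, length(o_idx) == m, length(y) == m)
  obj <- object_tables(model)
  Esa <- model$entity_real[s_idx, , drop = FALSE]
  Esb <- model$entity_imag[s_idx, , drop = FALSE]
  Lra <- model$relation_real[r_idx, , drop = FALSE]
  Lrb <- model$relation_imag[r_idx, , drop = FALSE]
  Eoa <- obj$re[o_idx, , drop = FALSE]
  Eob <- obj$im[o_idx, , drop = FALSE]
  if (!is.null(mask_s)) { Esa <- Esa * mask_s; Esb <- Esb * mask_s }
  if (!is.null(mask_o)) { Eoa <- Eoa * mask_o; Eob <- Eob * mask_o }

  phi <- phi_rows(model$decoder, Esa, Esb, Lra, Lrb, Eoa, Eob)
  loss <- mean(ifelse(y == 1, softplus(-phi), softplus(phi)))
  dphi <- (sigmoid(phi) - y) / m

  dec <- model$decoder
  if (dec == "complex") {
    Gsa <- dphi * (Lra * Eoa + Lrb * Eob)
    Gsb <- dphi * (Lra * Eob - Lrb * Eoa)
    Goa <- dphi * (Lra * Esa - Lrb * Esb)
    Gob <- dphi * (Lra * Esb + Lrb * Esa)
    Gra <- dphi * (Esa * Eoa + Esb * Eob)
    Grb <- dphi * (Esa * Eob - Esb * Eoa)
  } else if (dec %in% c("distmult", "cp")) {
    Gsa <- dphi * (Lra * Eoa)
    Goa <- dphi * (Lra * Esa)
    Gra <- dphi * (Esa * Eoa)
    Gsb <- Gob <- Grb <- NULL
  } else { # hole
    Gsa <- dphi * row_circ_corr(Lra, Eoa)
    Goa <- dphi * row_circ_conv(Esa, Lra)
    Gra <- dphi * row_circ_corr(Esa, Eoa)
    Gsb <- Gob <- Grb <- NULL
  }
  # chain rule through the dropout masks
  if (!is.null(mask_s)) {
    Gsa <- Gsa * mask_s
    if (!is.null(Gsb)) Gsb <- Gsb * mask_s
  }
  if (!is.null(mask_o)) {
    Goa <- Goa * mask_o
    if (!is.null(Gob)) Gob <- Gob * mask_o
  }

  zero_like <- function(M) matrix(0, nrow(M), ncol(M))
  grads <- list(entity_real = zero_like(model$entity_real),
                entity_imag = zero_like(model$entity_imag),
                relation_real = zero_like(model$relation_real),
                relation_imag = zero_like(model$relation_imag))
  if (dec == "cp") {
    grads$object_real <- zero_like(model$object_real)
    grads$entity_real <- scatter_add(grads$entity_real, s_idx, Gsa)
    grads$object_real <- scatter_add(grads$object_real, o_idx, Goa)
  } else {
    grads$entity_real <- scatter_add(grads$entity_real, s_idx, Gsa)
    grads$entity_real <- scatter_add(grads$entity_real, o_idx, Goa)
  }
  grads$relation_real <- scatter_add(grads$relation_real, r_idx, Gra)
  if (dec == "complex") {
    grads$entity_imag <- scatter_add(grads$entity_imag, s_idx, Gsb)
    grads$entity_imag <- scatter_add(grads$entity_imag, o_idx, Gob)
    grads$relation_imag <- scatter_add(grads$relation_imag, r_idx, Grb)
  }
  list(loss = loss, grads = grads)
}

# ---------------------------------------------------------------------------
# Adam

adam_init <- function(model) {
  mats <- trainable_matrices(model)
  list(t = 0L,
       m = lapply(mats, function(M) matrix(0, nrow(M), ncol(M))),
       v = lapply(mats, function(M) matrix(0, nrow(M), ncol(M))))
}

trainable_matrices <- function(model) {
  nm <- switch(model$decoder,
    complex = c("entity_real", "entity_imag", "relation_real",
                "relation_imag"),
    distmult = ,
    hole = c("entity_real", "relation_real"),
    cp = c("entity_real", "object_real", "relation_real"))
  stats::setNames(model[nm], nm)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    model[[nm]] <- model[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(model = model, state = state)
}

# ---------------------------------------------------------------------------
# Training loop

#' Train an embedding model on a data split
#'
#' Runs epochs of relation-balanced batches.  Per batch: typed negatives
#' are drawn for every positive, dropout masks are applied to the entity
#' embeddings entering the decoder, the binary cross-entropy and its
#' analytic gradients are computed, and every embedding matrix is updated
#' by Adam.  After each epoch the validation metric (by default, filtered
#' average recall at `config$eval_k` on the benchmark relation) is
#' computed on `split$valid`; training stops once the metric has not
#' improved by more than `config$improvement_tol` for
#' `config$patience_epochs` consecutive epochs, and the model from the
#' best epoch is restored.  With an empty validation set the negative
#' epoch loss serves as the stopping metric.
#'
#' @param kg the `knowledge_graph` the split was derived from (supplies
#'   entity types for negative sampling and the ranking candidate pool)
#' @param split a `data_split`
#' @param config a [train_config()]
#' @param validation_metric optional `function(model)` returning a scalar
#'   to maximize; overrides the default metric
#' @param verbose print one line per epoch
#' @return list of class `train_state`: `model`, `epoch`,
#'   `validation_history`, `loss_history`, `stopped_early`, `best_metric`
#' @export
train <- function(kg, split, config, validation_metric = NULL,
                  verbose = FALSE) {
  if (nrow(split$train) == 0L) stopf("empty training set")
  ids <- kg$entities$id
  rels <- kg$relations$name
  model <- with_seed(config$seed,
    init_embeddings(length(ids), length(rels), config$embedding_dim,
                    config$decoder_name, seed = NULL,
                    entity_ids = ids, relation_ids = rels))

  if (is.null(validation_metric)) {
    validation_metric <-
      if (nrow(split$valid) > 0L)
        function(model) validation_recall(model, kg, split,
                                          k = config$eval_k)
      else NULL
  }

  s_all <- match(split$train$subject, ids)
  o_all <- match(split$train$object, ids)
  r_all <- match(split$train$relation, rels)
  pools <- type_pools(kg)
  etype_by_index <- kg$entities$type_label

  state <- list(model = model, epoch = 0L,
                validation_history = numeric(), loss_history = numeric(),
                stopped_early = FALSE, best_metric = -Inf)
  class(state) <- "train_state"
  if (config$max_epochs == 0L) return(state)

  adam <- adam_init(model)
  best_model <- model
  best_metric <- -Inf
  stall <- 0L
  cur_lr <- config$learning_rate
  p <- config$dropout_p
  ratio <- config$negatives_per_positive

  # one RNG stream (seeded once) drives batching, negatives and dropout,
  # so a fixed seed reproduces the whole run bit for bit
  run <- with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      batches <- make_balanced_batches(split$train, config$batch_size)
      epoch_loss <- 0
      for (rows in batches) {
        s_p <- s_all[rows]; r_p <- r_all[rows]; o_p <- o_all[rows]
        neg <- corrupt_batch(s_p, r_p, o_p, ratio, pools, etype_by_index)
        s_b <- c(s_p, neg$s); r_b <- c(r_p, neg$r); o_b <- c(o_p, neg$o)
        y <- c(rep(1, length(s_p)), rep(0, length(neg$s)))
        m <- length(s_b)
        d <- config$embedding_dim
        lg <- loss_gradients(model, s_b, r_b, o_b, y,
                             mask_s = dropout_mask(m, d, p),
                             mask_o = dropout_mask(m, d, p))
        if (!is.finite(lg$loss))
          stopf("non-finite loss at epoch %d; lower the learning rate",
                epoch)
        upd <- adam_step(model, lg$grads, adam, cur_lr)
        model <- upd$model
        adam <- upd$state
        epoch_loss <- epoch_loss + lg$loss
      }
      epoch_loss <- epoch_loss / length(batches)
      metric <- if (is.null(validation_metric)) -epoch_loss
                else validation_metric(model)
      state$loss_history <- c(state$loss_history, epoch_loss)
      state$validation_history <- c(state$validation_history, metric)
      if (verbose)
        kg_log(sprintf("epoch %d: loss %.4f, validation metric %.4f",
                       epoch, epoch_loss, metric))
      if (metric > best_metric + config$improvement_tol) {
        best_metric <- metric
        best_model <- model
        stall <- 0L
      } else {
        stall <- stall + 1L
        cur_lr <- cur_lr * config$lr_decay
        if (stall >= config$patience_epochs) {
          state$stopped_early <- TRUE
          break
        }
      }
    }
    list(epoch = epoch)
  })
  state$epoch <- run$epoch
  state$model <- best_model
  state$best_metric <- best_metric
  state
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> %d epoch(s)%s, best validation metric %.4f\n",
              x$epoch, if (x$stopped_early) " (stopped early)" else "",
              x$best_metric))
  invisible(x)
}

# Default stopping metric: filtered average recall@k on the validation
# triples of the benchmark relation, filtering train edges.
validation_recall <- function(model, kg, split, k) {
  rl <- per_disease_rankings(model, kg,
                             eval_triples = split$valid,
                             filter_triples = split$train,
                             benchmark_relation = split$benchmark_relation)
  if (!length(rl)) return(NA_real_)
  mean(vapply(rl, function(x) recall_at_k(x$ranked, x$positives, k),
              numeric(1)))
}

#' Normalize a decoder score
#'
#' `"sigmoid"` maps the un-normalized score through the logistic function
#' into (0, 1) — the scale on which prioritization scores are reported —
#' preserving order; `"none"` is the identity.
#'
#' @param phi numeric score(s)
#' @param mode `"sigmoid"` or `"none"`
#' @return transformed scores
#' @export
normalize_score <- function(phi, mode = c("sigmoid", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") phi else sigmoid(phi)
}
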
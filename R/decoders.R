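# Trilinear scoring decoders.
#
# A decoder maps the embeddings of a (subject, relation, object) triple to
# a real-valued un-normalized likelihood phi of that edge.  Four decoders
# are provided: ComplEx (complex embeddings, asymmetric), DistMult (real,
# symmetric), canonical polyadic / CP (real, separate subject and object
# entity tables, asymmetric) and HolE (real, circular correlation,
# asymmetric).

DECODERS <- c("complex", "distmult", "cp", "hole")

check_dims <- function(...) {
  d <- unique(lengths(list(...)))
  if (length(d) != 1L)
    stopf("embedding dimension mismatch: %s", paste(d, collapse = " vs "))
  invisible(d)
}

#' ComplEx trilinear score
#'
#' The real part of the trilinear product of complex subject, relation and
#' conjugated object embeddings, supplied as separate real (`_re`) and
#' imaginary (`_im`) vectors:
#' \deqn{\phi = \langle e_{sa}, l_{ra}, e_{oa}\rangle
#'   + \langle e_{sb}, l_{ra}, e_{ob}\rangle
#'   + \langle e_{sa}, l_{rb}, e_{ob}\rangle
#'   - \langle e_{sb}, l_{rb}, e_{oa}\rangle}
#' where \eqn{\langle x,y,z\rangle = \sum_j x_j y_j z_j}, `a` denotes a
#' real part and `b` an imaginary part.  The imaginary relation component
#' makes the score asymmetric under subject/object exchange, which is what
#' lets one complex embedding space model directed biomedical relations.
#'
#' @param e_s_re,e_s_im subject embedding, real and imaginary parts
#' @param l_r_re,l_r_im relation embedding, real and imaginary parts
#' @param e_o_re,e_o_im object embedding, real and imaginary parts
#' @return scalar score (un-normalized log-likelihood of the edge)
#' @export
complex_score <- function(e_s_re, e_s_im, l_r_re, l_r_im, e_o_re, e_o_im) {
  check_dims(e_s_re, e_s_im, l_r_re, l_r_im, e_o_re, e_o_im)
  # entity product first, so the all-zero-imaginary case reduces to
  # DistMult bit for bit
  sum((e_s_re * e_o_re) * l_r_re) + sum((e_s_im * e_o_im) * l_r_re) +
    sum((e_s_re * e_o_im) * l_r_im) - sum((e_s_im * e_o_re) * l_r_im)
}

#' DistMult trilinear score
#'
#' \eqn{\phi = \sum_j l_{rj} e_{sj} e_{oj}} over real embeddings; exactly
#' symmetric in subject and object, so it cannot model directed relations.
#' Equals the ComplEx score when all imaginary parts are zero.
#'
#' @param e_s,l_r,e_o real embedding vectors of equal length
#' @return scalar score
#' @export
distmult_score <- function(e_s, l_r, e_o) {
  check_dims(e_s, l_r, e_o)
  # association (e_s * e_o) * l_r keeps the subject/object swap bit-exact
  sum((e_s * e_o) * l_r)
}

#' Canonical polyadic (CP) trilinear score
#'
#' \eqn{\phi = \sum_j u_{sj} v_{rj} w_{oj}} where the subject factor `u`
#' and object factor `w` come from *separate* entity tables, which is what
#' makes CP asymmetric despite the symmetric-looking product.
#'
#' @param u_s subject embedding (subject entity table)
#' @param v_r relation embedding
#' @param w_o object embedding (object entity table)
#' @return scalar score
#' @export
cp_score <- function(u_s, v_r, w_o) {
  check_dims(u_s, v_r, w_o)
  sum(u_s * v_r * w_o)
}

#' Circular correlation
#'
#' \eqn{[x \star y]_k = \sum_i x_i y_{(i+k) \bmod d}} (zero-based
#' indices), the compression underlying the HolE decoder.  `method =
#' "fft"` computes the identical quantity in the spectral domain via
#' \eqn{\mathrm{IDFT}(\overline{\mathrm{DFT}(x)} \cdot \mathrm{DFT}(y))}.
#'
#' @param x,y real vectors of equal length
#' @param method `"direct"` (O(d^2) sum) or `"fft"`
#' @return real vector of length `length(x)`
#' @export
circular_correlation <- function(x, y, method = c("direct", "fft")) {
  method <- match.arg(method)
  d <- check_dims(x, y)
  if (method == "fft")
    return(Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y),
                         inverse = TRUE)) / d)
  vapply(0:(d - 1L), function(k) {
    sum(x * y[((seq_len(d) - 1L + k) %% d) + 1L])
  }, numeric(1))
}

#' Holographic embeddings (HolE) score
#'
#' \eqn{\phi = \sum_k l_{rk} [e_s \star e_o]_k}: the relation embedding
#' dotted with the circular correlation of subject and object embeddings.
#' Circular correlation is not commutative, so the score is asymmetric.
#'
#' @param e_s,l_r,e_o real embedding vectors of equal length
#' @param method correlation evaluation path, see [circular_correlation()]
#' @return scalar score
#' @export
hole_score <- function(e_s, l_r, e_o, method = c("direct", "fft")) {
  check_dims(e_s, l_r, e_o)
  sum(l_r * circular_correlation(e_s, e_o, method = match.arg(method)))
}

# ---------------------------------------------------------------------------
# Embedding containers

#' Construct an embedding set
#'
#' The learned model state: entity and relation embedding matrices whose
#' layout depends on the decoder.  ComplEx uses real and imaginary entity
#' and relation matrices; DistMult and HolE use the real matrices only
#' (imaginary parts held at zero); CP uses an additional separate
#' object-entity table so the trainer stays decoder-agnostic.
#'
#' Use [init_embeddings()] to create a randomly initialized set.
#'
#' @param entity_real,entity_imag n x d matrices (rownames = entity ids)
#' @param relation_real,relation_imag k x d matrices (rownames = relation
#'   names)
#' @param object_real separate n x d object-entity table (CP only)
#' @param decoder one of `"complex"`, `"distmult"`, `"cp"`, `"hole"`
#' @return an object of class `embedding_set`
#' @export
embedding_set <- function(entity_real, entity_imag, relation_real,
                          relation_imag, object_real = NULL,
                          decoder = "complex") {
  decoder <- match.arg(decoder, DECODERS)
  d <- ncol(entity_real)
  stopifnot(ncol(entity_imag) == d, ncol(relation_real) == d,
            ncol(relation_imag) == d,
            nrow(entity_imag) == nrow(entity_real),
            nrow(relation_imag) == nrow(relation_real))
  if (decoder == "cp") {
    stopifnot(!is.null(object_real), ncol(object_real) == d,
              nrow(object_real) == nrow(entity_real))
  } else {
    object_real <- NULL
  }
  structure(list(entity_real = entity_real, entity_imag = entity_imag,
                 relation_real = relation_real,
                 relation_imag = relation_imag,
                 object_real = object_real, decoder = decoder),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> decoder=%s n=%d k=%d d=%d\n", x$decoder,
              nrow(x$entity_real), nrow(x$relation_real),
              ncol(x$entity_real)))
  invisible(x)
}

# object-side entity table: CP reads objects from its own table, everyone
# else shares the (real, imag) entity matrices
object_tables <- function(model) {
  if (model$decoder == "cp")
    list(re = model$object_real,
         im = matrix(0, nrow(model$object_real), ncol(model$object_real)))
  else
    list(re = model$entity_real, im = model$entity_imag)
}

# Batched phi over gathered row-matrices (m x d each).  All four decoders
# reduce to row-wise trilinear sums; HolE goes through shift loops.
phi_rows <- function(decoder, Esa, Esb, Lra, Lrb, Eoa, Eob) {
  switch(decoder,
    complex = rowSums(Esa * Lra * Eoa) + rowSums(Esb * Lra * Eob) +
      rowSums(Esa * Lrb * Eob) - rowSums(Esb * Lrb * Eoa),
    distmult = ,
    cp = rowSums(Esa * Lra * Eoa),
    hole = rowSums(Lra * row_circ_corr(Esa, Eoa)),
    stopf("unknown decoder '%s'", decoder))
}

# row-wise circular correlation: C[, k+1] = sum_i A[, i] * B[, (i+k) mod d]
row_circ_corr <- function(A, B) {
  d <- ncol(A)
  C <- matrix(0, nrow(A), d)
  i0 <- seq_len(d) - 1L
  for (k in 0:(d - 1L))
    C[, k + 1L] <- rowSums(A * B[, ((i0 + k) %% d) + 1L, drop = FALSE])
  C
}

# row-wise circular convolution: C[, j+1] = sum_i A[, i] * B[, (j-i) mod d]
row_circ_conv <- function(A, B) {
  d <- ncol(A)
  C <- matrix(0, nrow(A), d)
  i0 <- seq_len(d) - 1L
  for (j in 0:(d - 1L))
    C[, j + 1L] <- rowSums(A * B[, ((j - i0) %% d) + 1L, drop = FALSE])
  C
}

#' Score a batch of candidate objects for one (subject, relation)
#'
#' Vectorized form of the scalar decoders: element `i` of the result
#' equals the single-triple decoder applied to
#' `(subject, relation, candidates[i])`, in candidate order.  This is the
#' ranking primitive: scoring all candidate genes for one disease is a
#' single matrix-vector product.
#'
#' @param model an [embedding_set()]
#' @param subject entity row index (integer)
#' @param relation relation row index (integer)
#' @param candidates nonempty integer vector of entity row indices
#' @return numeric score vector, one per candidate
#' @export
score_candidates <- function(model, subject, relation, candidates) {
  n <- nrow(model$entity_real)
  k <- nrow(model$relation_real)
  if (length(candidates) == 0L) stopf("candidates must be nonempty")
  if (subject < 1L || subject > n) stopf("subject index out of range")
  if (relation < 1L || relation > k) stopf("relation index out of range")
  if (any(candidates < 1L | candidates > n))
    stopf("candidate index out of range")
  esa <- model$entity_real[subject, ]
  esb <- model$entity_imag[subject, ]
  lra <- model$relation_real[relation, ]
  lrb <- model$relation_imag[relation, ]
  obj <- object_tables(model)
  Eoa <- obj$re[candidates, , drop = FALSE]
  Eob <- obj$im[candidates, , drop = FALSE]
  switch(model$decoder,
    complex = as.numeric(Eoa %*% (esa * lra) + Eob %*% (esb * lra) +
                           Eob %*% (esa * lrb) - Eoa %*% (esb * lrb)),
    distmult = ,
    cp = as.numeric(Eoa %*% (esa * lra)),
    hole = {
      # phi(c) = sum_j [e_s (*) l_r]_j e_oj  (circular convolution)
      d <- length(esa)
      i0 <- seq_len(d) - 1L
      w <- vapply(0:(d - 1L), function(j) {
        sum(esa * lra[((j - i0) %% d) + 1L])
      }, numeric(1))
      as.numeric(Eoa %*% w)
    })
}

# Batched phi over arbitrary index triples (used by the trainer and tests)
score_triples <- function(model, s_idx, r_idx, o_idx) {
  obj <- object_tables(model)
  phi_rows(model$decoder,
           Esa = model$entity_real[s_idx, , drop = FALSE],
           Esb = model$entity_imag[s_idx, , drop = FALSE],
           Lra = model$relation_real[r_idx, , drop = FALSE],
           Lrb = model$relation_imag[r_idx, , drop = FALSE],
           Eoa = obj$re[o_idx, , drop = FALSE],
           Eob = obj$im[o_idx, , drop = FALSE])
}
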
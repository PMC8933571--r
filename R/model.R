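# Model surface: structural hyperparameters, parameter initialization, the
# encoder (backed by the compiled core), embedding layers, fused classifier
# and checkpointing.

#' Structural hyperparameters of the encoder and fusion head
#'
#' Defaults follow the published configuration: four parallel CNN blocks
#' with kernel sizes 50/100/200/400, two convolution layers per block, 64
#' filters, stride 5, batch-norm + ReLU after each convolution, global max
#' pooling per block (encoder output `S_e = 4 * n_filters`), and 64-d alarm
#' and rule embeddings.
#'
#' @param n_filters filters per convolution layer.
#' @param kernels kernel size per parallel block.
#' @param stride convolution stride.
#' @param Sa,Sr alarm / rule embedding sizes.
#' @param components character subset of
#'   `c("constraint", "rule_embedding", "alarm_embedding")`.
#' @param M number of input channels (canonical roles).
#' @return a `model_structure` list (includes derived `Se` and fused input
#'   size `K`).
#' @export
model_structure <- function(n_filters = 64L, kernels = c(50L, 100L, 200L, 400L),
                            stride = 5L, Sa = 64L, Sr = 64L,
                            components = c("constraint", "rule_embedding",
                                           "alarm_embedding"),
                            M = length(ALARM_ROLES)) {
  bad <- setdiff(components, c("constraint", "rule_embedding", "alarm_embedding"))
  if (length(bad)) abort_validation("unknown component '%s'", bad[1])
  use_alarm <- "alarm_embedding" %in% components
  use_rule <- "rule_embedding" %in% components
  Se <- as.integer(n_filters) * length(kernels)
  K <- Se + (if (use_alarm) as.integer(Sa) else 0L) +
    (if (use_rule) as.integer(Sr) else 0L)
  structure(list(M = as.integer(M), n_filters = as.integer(n_filters),
                 kernels = as.integer(kernels), stride = as.integer(stride),
                 Sa = as.integer(Sa), Sr = as.integer(Sr),
                 n_types = length(ALARM_TYPES),
                 use_alarm = use_alarm, use_rule = use_rule,
                 use_constraint = "constraint" %in% components,
                 Se = Se, K = K),
            class = "model_structure")
}

#' Initialize model parameters
#'
#' Convolution and classifier weights use uniform fan-in scaling
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`); embeddings `U(-0.1, 0.1)`;
#' batch-norm scale 1 / shift 0; biases 0. Seeded and reproducible.
#'
#' @param structure a [model_structure()].
#' @param rng_seed integer seed.
#' @return an `alarm_model` list with `structure` and `params`.
#' @export
init_model <- function(structure = model_structure(), rng_seed = 1L) {
  s <- structure
  with_seed(rng_seed, {
    u <- function(n, fan_in) runif(n, -1, 1) / sqrt(fan_in)
    blocks <- lapply(s$kernels, function(D) {
      f1 <- s$M * D
      f2 <- s$n_filters * D
      list(W1 = matrix(u(s$n_filters * f1, f1), s$n_filters, f1),
           b1 = numeric(s$n_filters), g1 = rep(1, s$n_filters),
           be1 = numeric(s$n_filters), rm1 = numeric(s$n_filters),
           rv1 = rep(1, s$n_filters),
           W2 = matrix(u(s$n_filters * f2, f2), s$n_filters, f2),
           b2 = numeric(s$n_filters), g2 = rep(1, s$n_filters),
           be2 = numeric(s$n_filters), rm2 = numeric(s$n_filters),
           rv2 = rep(1, s$n_filters))
    })
    params <- list(blocks = blocks, Wc = u(s$K, s$K), bc = 0)
    if (s$use_alarm)
      params$Wa <- matrix(runif(s$n_types * s$Sa, -0.1, 0.1), s$n_types, s$Sa)
    if (s$use_rule) params$Wr <- runif(s$Sr, -0.1, 0.1)
    structure(list(structure = s, params = params, history = NULL),
              class = "alarm_model")
  })
}

#' @export
print.alarm_model <- function(x, ...) {
  s <- x$structure
  cat(sprintf("<alarm_model: %d blocks (kernels %s), %d filters, Se=%d, K=%d%s%s>\n",
              length(s$kernels), paste(s$kernels, collapse = "/"),
              s$n_filters, s$Se, s$K,
              if (s$use_alarm) ", +alarm" else "",
              if (s$use_rule) ", +rule" else ""))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final loss %.4f\n",
                nrow(x$history), tail(x$history$loss_total, 1)))
  invisible(x)
}

segments_to_cube <- function(segments) {
  Tlen <- ncol(segments[[1]])
  M <- nrow(segments[[1]])
  arr <- array(0, dim = c(M, Tlen, length(segments)))
  for (i in seq_along(segments)) arr[, , i] <- segments[[i]]
  arr
}

#' Encode waveform segments
#'
#' Applies the parallel multi-kernel CNN encoder: per block dropout
#' (training only), two rounds of conv(stride 5, zero 'same' padding) ->
#' batch norm -> ReLU, then a global max over time; block outputs are
#' concatenated. Deterministic in inference mode (running batch-norm
#' statistics, no dropout).
#'
#' @param segments one M x T matrix or a list of them.
#' @param model an `alarm_model`.
#' @param training use batch statistics + dropout (never updates running
#'   statistics).
#' @param dropout dropout rate in training mode.
#' @param rng_seed dropout seed.
#' @return `S_e` x n feature matrix.
#' @export
encode <- function(segments, model, training = FALSE, dropout = 0,
                   rng_seed = 1L) {
  if (is.matrix(segments)) segments <- list(segments)
  if (ncol(segments[[1]]) < 1) abort_validation("segment has no samples")
  if (nrow(segments[[1]]) != model$structure$M)
    abort_validation("segment must have %d channels", model$structure$M)
  cpp_encode(segments_to_cube(segments), model$params,
             unclass(model$structure), training, dropout, as.integer(rng_seed))
}

#' Alarm-type embedding
#'
#' Selects the row of the embedding matrix `W_a` indicated by the one-hot
#' alarm-type vector: `E_a = A W_a`.
#'
#' @param A length-5 one-hot vector.
#' @param W_a `5 x S_a` embedding matrix.
#' @return length-`S_a` embedding.
#' @export
embed_alarm <- function(A, W_a) {
  if (length(A) != nrow(W_a) || !all(A %in% c(0, 1)) || sum(A) != 1)
    abort_validation("A must be a one-hot vector of length %d", nrow(W_a))
  as.numeric(A %*% W_a)
}

#' Rule-score embedding
#'
#' Scales the learned embedding vector by the scalar rule-based verifier
#' output: `E_r = R W_r`.
#'
#' @param R scalar in `[0, 1]`.
#' @param W_r length-`S_r` embedding vector.
#' @return length-`S_r` embedding.
#' @export
embed_rule <- function(R, W_r) {
  if (!is.numeric(R) || length(R) != 1 || is.na(R) || R < 0 || R > 1)
    abort_validation("rule score must be a scalar in [0, 1]")
  R * W_r
}

#' Fuse embeddings and classify
#'
#' `O = sigmoid(concat(E_e, E_a, E_r) . W_c + b)`, the probability that the
#' triggered alarm is true.
#'
#' @param E_e encoder feature vector.
#' @param E_a,E_r alarm / rule embeddings (`NULL` when the component is
#'   disabled).
#' @param W_c classifier weight vector matching the concatenation.
#' @param bias scalar bias.
#' @return probability in (0, 1).
#' @export
fuse_and_classify <- function(E_e, E_a = NULL, E_r = NULL, W_c, bias = 0) {
  E <- c(E_e, E_a, E_r)
  if (length(E) != length(W_c))
    abort_validation("fused vector length %d does not match W_c length %d",
                     length(E), length(W_c))
  sigmoid(sum(E * W_c) + bias)
}

#' Siamese forward pass on a segment pair
#'
#' Both segments are encoded with the *same* parameter store (weight sharing
#' is structural, not copied), and the classification output is computed
#' from the alarm-segment feature only, fused with the alarm-type and rule
#' embeddings.
#'
#' @param pair a `segment_pair` from [extract_pair()].
#' @param model an `alarm_model`.
#' @return list `O` (probability), `f_A`, `f_R` (feature vectors).
#' @export
forward_pair <- function(pair, model) {
  s <- model$structure
  feats <- encode(list(pair$alarm_segment, pair$baseline_segment), model)
  f_A <- feats[, 1]; f_R <- feats[, 2]
  E_a <- if (s$use_alarm) embed_alarm(pair$alarm_onehot, model$params$Wa)
  E_r <- if (s$use_rule) {
    if (is.null(pair$rule_score))
      abort_validation("pair has no rule_score but the model uses one")
    embed_rule(pair$rule_score, model$params$Wr)
  }
  O <- fuse_and_classify(f_A, E_a, E_r, model$params$Wc, model$params$bc)
  list(O = O, f_A = f_A, f_R = f_R)
}

#' Save / load a model checkpoint
#'
#' Single-file archive of all parameter tensors plus the structural
#' hyperparameters (stored alongside as a JSON string); bit-exact on round
#' trip.
#'
#' @param model an `alarm_model`.
#' @param path file path.
#' @return invisibly `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(structure_json = jsonlite::toJSON(unclass(model$structure),
                                                auto_unbox = TRUE),
              structure = unclass(model$structure),
              params = model$params, history = model$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(structure = structure(obj$structure, class = "model_structure"),
                 params = obj$params, history = obj$history),
            class = "alarm_model")
}
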
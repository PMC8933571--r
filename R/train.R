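# Training loop (Adam on the combined objective), prediction, Challenge
# metrics, fivefold cross-validation and the ablation grid.

#' Training configuration
#'
#' Defaults follow the published setup: up to 1000 epochs, mini-batch 256,
#' Adam with learning rate 0.001, L2 5e-4 on convolution/linear weights,
#' dropout 0.8 before each CNN block, constraint weight 1.5, positive-class
#' weight 1.5. The structural arguments (`n_filters`, `kernels`, embedding
#' sizes) are exposed so desk-scale runs can use a tiny encoder.
#'
#' @param max_epochs,batch_size,learning_rate,l2_lambda,dropout optimizer
#'   settings.
#' @param constraint_weight weight `w` on the discriminative constraint.
#' @param positive_class_weight BCE weight on true alarms.
#' @param decision_threshold probability threshold (>= means true alarm).
#' @param folds cross-validation folds.
#' @param rng_seed root seed; all sub-streams derive from it.
#' @param components model components to enable.
#' @param baseline_mode `"resample"` (fresh baseline segment each epoch,
#'   the data-augmentation reading) or `"frozen"` (one fixed segment).
#' @param n_filters,kernels,stride,embedding_size encoder structure.
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 1000L, batch_size = 256L,
                         learning_rate = 0.001, l2_lambda = 0.0005,
                         dropout = 0.8, constraint_weight = 1.5,
                         positive_class_weight = 1.5,
                         decision_threshold = 0.5, folds = 5L, rng_seed = 1L,
                         components = c("constraint", "rule_embedding",
                                        "alarm_embedding"),
                         baseline_mode = c("resample", "frozen"),
                         n_filters = 64L, kernels = c(50L, 100L, 200L, 400L),
                         stride = 5L, embedding_size = 64L) {
  baseline_mode <- match.arg(baseline_mode)
  num <- c(max_epochs = max_epochs, batch_size = batch_size,
           learning_rate = learning_rate, l2_lambda = l2_lambda,
           dropout = dropout, constraint_weight = constraint_weight,
           positive_class_weight = positive_class_weight)
  if (any(!is.finite(num)) || any(num < 0))
    abort_validation("rates and weights must be nonnegative")
  if (positive_class_weight <= 0)
    abort_validation("positive_class_weight must be positive")
  if (decision_threshold <= 0 || decision_threshold >= 1)
    abort_validation("decision_threshold must lie in (0, 1)")
  if (dropout >= 1) abort_validation("dropout must be < 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, l2_lambda = l2_lambda,
                 dropout = dropout, constraint_weight = constraint_weight,
                 positive_class_weight = positive_class_weight,
                 decision_threshold = decision_threshold,
                 folds = as.integer(folds), rng_seed = as.integer(rng_seed),
                 components = components, baseline_mode = baseline_mode,
                 n_filters = as.integer(n_filters),
                 kernels = as.integer(kernels), stride = as.integer(stride),
                 embedding_size = as.integer(embedding_size)),
            class = "train_config")
}

config_structure <- function(config) {
  model_structure(n_filters = config$n_filters, kernels = config$kernels,
                  stride = config$stride, Sa = config$embedding_size,
                  Sr = config$embedding_size, components = config$components)
}

# Adam state and update over the nested parameter list. L2 is applied to
# convolution/linear weights only (not biases, not batch-norm parameters).
get_path <- function(x, path) { for (p in path) x <- x[[p]]; x }

set_path <- function(x, path, value) {
  if (length(path) == 1) { x[[path[[1]]]] <- value; return(x) }
  x[[path[[1]]]] <- set_path(x[[path[[1]]]], path[-1], value)
  x
}

trainable_paths <- function(params) {
  out <- list()
  for (b in seq_along(params$blocks))
    for (nm in c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2"))
      out[[length(out) + 1]] <- list(path = list("blocks", b, nm),
                                     l2 = grepl("^W", nm))
  for (nm in intersect(c("Wa", "Wr", "Wc"), names(params)))
    out[[length(out) + 1]] <- list(path = list(nm), l2 = TRUE)
  out[[length(out) + 1]] <- list(path = list("bc"), l2 = FALSE)
  out
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) 0 * x else numeric(length(x))
  paths <- trainable_paths(params)
  list(m = lapply(paths, function(p) zero_like(get_path(params, p$path))),
       v = lapply(paths, function(p) zero_like(get_path(params, p$path))),
       t = 0L, paths = paths)
}

adam_step <- function(params, grads, state, lr, l2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(state$paths)) {
    p <- state$paths[[i]]
    g <- tryCatch(get_path(grads, p$path), error = function(e) NULL)
    if (is.null(g)) next
    th <- get_path(params, p$path)
    if (is.matrix(th) && !is.matrix(g)) g <- matrix(g, nrow(th), ncol(th))
    if (p$l2 && l2 > 0) g <- g + l2 * th
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    params <- set_path(params, p$path, th -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps))
  }
  list(params = params, state = state)
}

prepare_records <- function(records) {
  lapply(records, function(r) if (r$preprocessed) r else preprocess(r))
}

compute_rule_scores <- function(records, scorer) {
  vapply(records, scorer, 0)
}

#' Train the contrastive alarm classifier
#'
#' Minimizes `L = L_BCE + w * C` with Adam. Baseline segments are resampled
#' every epoch from a seeded stream (a data-augmentation scheme: each epoch
#' pairs the fixed alarm segment with a fresh pre-alarm window of the same
#' patient). Fully seeded: the same seed, data and numeric backend give an
#' identical history.
#'
#' @param records list of [waveform_record()]s with known labels.
#' @param config a [train_config()].
#' @param rule_scores optional precomputed numeric vector aligned with
#'   `records`; otherwise `scorer` is applied when the rule embedding is
#'   enabled.
#' @param scorer a [rule_scorer()] specification.
#' @param verbose print per-epoch loss lines.
#' @return an `alarm_model` with a per-epoch `history` data.frame
#'   (`epoch`, `loss_bce`, `loss_constraint`, `loss_total`).
#' @export
train_model <- function(records, config = train_config(), rule_scores = NULL,
                        scorer = "reference", verbose = FALSE) {
  records <- prepare_records(records)
  labels <- vapply(records, `[[`, "", "label")
  if (!length(records)) abort_validation("empty training set")
  if (any(labels == "unknown"))
    abort_validation("all training records need labels")
  y <- as.numeric(labels == "true_alarm")
  if (length(unique(y)) < 2)
    warning("single-label training set: the discriminative constraint degenerates to one term")
  s <- config_structure(config)
  model <- init_model(s, rng_seed = substream_seed(config$rng_seed, "init"))
  rs <- if (s$use_rule) {
    if (!is.null(rule_scores)) rule_scores
    else compute_rule_scores(records, rule_scorer(scorer))
  } else numeric(length(records))
  type_idx <- match(vapply(records, `[[`, "", "alarm_type"), ALARM_TYPES)
  alarm_segs <- lapply(records, function(r) {
    Tlen <- as.integer(round(r$fs * 10))
    r$channels[, (r$onset - Tlen + 1):r$onset, drop = FALSE]
  })
  n <- length(records)
  state <- adam_init(model$params)
  hist <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    base_epoch <- if (config$baseline_mode == "resample") epoch else 0L
    base_segs <- if (s$use_constraint) lapply(seq_len(n), function(i) {
      seed <- substream_seed(config$rng_seed, "baseline", base_epoch, i)
      extract_pair(records[[i]], rng_seed = seed)$baseline_segment
    })
    ord <- with_seed(substream_seed(config$rng_seed, "shuffle", epoch),
                     sample.int(n))
    sums <- c(bce = 0, con = 0, tot = 0)
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xA <- segments_to_cube(alarm_segs[idx])
      xR <- if (s$use_constraint) segments_to_cube(base_segs[idx])
            else array(0, dim = c(s$M, 1, 0))
      step <- cpp_siamese_step(
        xA, xR, as.integer(type_idx[idx]), rs[idx], y[idx],
        model$params, unclass(s),
        config$constraint_weight, config$positive_class_weight,
        config$dropout,
        substream_seed(config$rng_seed, "dropout", epoch, start),
        s$use_constraint, s$use_alarm, s$use_rule)
      # BN running statistics come back from the step
      for (b in seq_along(model$params$blocks))
        model$params$blocks[[b]][c("rm1", "rv1", "rm2", "rv2")] <-
          step$running[[b]][c("rm1", "rv1", "rm2", "rv2")]
      upd <- adam_step(model$params, step$grads, state,
                       config$learning_rate, config$l2_lambda)
      model$params <- upd$params
      state <- upd$state
      wgt <- length(idx)
      sums <- sums + wgt * c(step$loss_bce, step$loss_constraint,
                             step$loss_total)
      nb <- nb + wgt
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss_bce = sums[[1]] / nb,
                                loss_constraint = sums[[2]] / nb,
                                loss_total = sums[[3]] / nb)
    if (verbose)
      message(sprintf("epoch %d: bce %.4f constraint %.4f total %.4f",
                      epoch, sums[[1]] / nb, sums[[2]] / nb, sums[[3]] / nb))
  }
  model$history <- do.call(rbind, hist)
  model$config <- config
  model
}

#' Classify alarms
#'
#' Uses only signal before the alarm onset (the real-time contract); the
#' predicted label is `true_alarm` when the probability is at or above the
#' threshold.
#'
#' @param model a trained `alarm_model`.
#' @param records list of [waveform_record()]s.
#' @param rule_scores optional precomputed scores aligned with `records`.
#' @param scorer a [rule_scorer()] specification.
#' @param threshold decision threshold.
#' @return data.frame: `record_id`, `probability`, `label`.
#' @export
predict_alarms <- function(model, records, rule_scores = NULL,
                           scorer = "reference", threshold = 0.5) {
  records <- prepare_records(records)
  s <- model$structure
  rs <- if (s$use_rule) {
    if (!is.null(rule_scores)) rule_scores
    else compute_rule_scores(records, rule_scorer(scorer))
  } else numeric(length(records))
  segs <- lapply(records, function(r) {
    Tlen <- as.integer(round(r$fs * 10))
    r$channels[, (r$onset - Tlen + 1):r$onset, drop = FALSE]
  })
  probs <- numeric(length(records))
  for (start in seq(1, length(records), by = 64)) {
    idx <- start:min(start + 63, length(records))
    feats <- encode(segs[idx], model)
    if (ncol(feats) != length(idx) || nrow(feats) != s$Se)
      abort_validation("encoder output does not match checkpoint structure")
    for (j in seq_along(idx)) {
      i <- idx[j]
      E_a <- if (s$use_alarm)
        embed_alarm(as.numeric(ALARM_TYPES == records[[i]]$alarm_type),
                    model$params$Wa)
      E_r <- if (s$use_rule) embed_rule(rs[i], model$params$Wr)
      probs[i] <- fuse_and_classify(feats[, j], E_a, E_r, model$params$Wc,
                                    model$params$bc)
    }
  }
  data.frame(record_id = vapply(records, `[[`, "", "record_id"),
             probability = probs,
             label = ifelse(probs >= threshold, "true_alarm", "false_alarm"),
             stringsAsFactors = FALSE)
}

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth label vectors (`true_alarm`/`false_alarm`).
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- predicted == "true_alarm"
  t <- truth == "true_alarm"
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' PhysioNet Challenge 2015 score
#'
#' `(TP + TN) / (TP + TN + FP + 5 * FN)`: missed true alarms are penalized
#' five-fold.
#'
#' @param cc a [confusion_counts()] or list with TP/TN/FP/FN.
#' @return scalar in `[0, 1]`.
#' @export
challenge_score <- function(cc) {
  tot <- cc$TP + cc$TN + cc$FP + cc$FN
  if (tot <= 0) abort_validation("all confusion counts are zero")
  (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + 5 * cc$FN)
}

#' TPR, TNR and accuracy
#'
#' Rates with a zero denominator are returned as `NA` (flagged undefined,
#' not propagated as NaN).
#'
#' @param cc a [confusion_counts()].
#' @return named vector `c(TPR, TNR, ACC)`.
#' @export
tpr_tnr_acc <- function(cc) {
  tot <- cc$TP + cc$TN + cc$FP + cc$FN
  if (tot <= 0) abort_validation("all confusion counts are zero")
  c(TPR = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_,
    TNR = if (cc$TN + cc$FP > 0) cc$TN / (cc$TN + cc$FP) else NA_real_,
    ACC = (cc$TP + cc$TN) / tot)
}

#' Fivefold cross-validation
#'
#' Stratified folds from [make_folds()]; each fold is held out once while
#' the remaining folds train a fresh model. Reports per-fold and pooled
#' confusion counts, the per-fold Challenge scores and their mean and sd.
#'
#' @param records labeled [waveform_record()]s.
#' @param config a [train_config()] (`folds`, seeds, components).
#' @param rule_scores optional precomputed scores aligned with `records`.
#' @param scorer a [rule_scorer()] specification.
#' @param folds optional precomputed fold id-sets (shared across ablation
#'   rows).
#' @param verbose print progress.
#' @return a `cv_result` list.
#' @export
cross_validate <- function(records, config = train_config(),
                           rule_scores = NULL, scorer = "reference",
                           folds = NULL, verbose = FALSE) {
  records <- prepare_records(records)
  ids <- vapply(records, `[[`, "", "record_id")
  labels <- vapply(records, `[[`, "", "label")
  types <- vapply(records, `[[`, "", "alarm_type")
  if (length(records) < config$folds)
    abort_validation("fewer records than folds")
  if (is.null(folds))
    folds <- make_folds(ids, labels, types, k = config$folds,
                        rng_seed = substream_seed(config$rng_seed, "folds"))
  s <- config_structure(config)
  if (s$use_rule && is.null(rule_scores))
    rule_scores <- compute_rule_scores(records, rule_scorer(scorer))
  fold_scores <- numeric(length(folds))
  per_fold <- list()
  pooled <- data.frame()
  for (f in seq_along(folds)) {
    test_idx <- match(folds[[f]], ids)
    train_idx <- setdiff(seq_along(records), test_idx)
    cfg <- config
    cfg$rng_seed <- substream_seed(config$rng_seed, "fold", f)
    model <- train_model(records[train_idx], cfg,
                         rule_scores = rule_scores[train_idx],
                         scorer = scorer)
    pred <- predict_alarms(model, records[test_idx],
                           rule_scores = rule_scores[test_idx],
                           scorer = scorer,
                           threshold = config$decision_threshold)
    pred$truth <- labels[test_idx]
    pred$alarm_type <- types[test_idx]
    pred$fold <- f
    cc <- confusion_counts(pred$label, pred$truth)
    fold_scores[f] <- challenge_score(cc)
    per_fold[[f]] <- list(confusion = cc, score = fold_scores[f],
                          metrics = tpr_tnr_acc(cc))
    pooled <- rbind(pooled, pred)
    if (verbose)
      message(sprintf("fold %d/%d: score %.4f (n=%d)", f, length(folds),
                      fold_scores[f], length(test_idx)))
  }
  cc_all <- confusion_counts(pooled$label, pooled$truth)
  structure(list(fold_scores = fold_scores, mean_score = mean(fold_scores),
                 sd_score = sd(fold_scores), per_fold = per_fold,
                 predictions = pooled, confusion = cc_all,
                 metrics = tpr_tnr_acc(cc_all), folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, challenge score %.4f +/- %.4f>\n",
              length(x$fold_scores), x$mean_score, x$sd_score))
  invisible(x)
}

ablation_grid <- list(
  basic = c("alarm_embedding"),
  constraint = c("alarm_embedding", "constraint"),
  rule = c("alarm_embedding", "rule_embedding"),
  full = c("alarm_embedding", "rule_embedding", "constraint")
)

#' Ablation study over model components
#'
#' Cross-validates the four configurations (basic encoder; + discriminative
#' constraint; + rule embedding; both) with shared fold splits and seeds so
#' component effects are paired. Reports per-type and overall Challenge
#' scores.
#'
#' @param records labeled [waveform_record()]s.
#' @param config base [train_config()] (its `components` entry is
#'   overridden per row).
#' @param rule_scores,scorer see [cross_validate()].
#' @param verbose print progress.
#' @return an `ablation_result`: `table` (data.frame, one row per
#'   configuration) and `runs` (the `cv_result`s).
#' @export
ablate <- function(records, config = train_config(), rule_scores = NULL,
                   scorer = "reference", verbose = FALSE) {
  records <- prepare_records(records)
  ids <- vapply(records, `[[`, "", "record_id")
  labels <- vapply(records, `[[`, "", "label")
  types <- vapply(records, `[[`, "", "alarm_type")
  folds <- make_folds(ids, labels, types, k = config$folds,
                      rng_seed = substream_seed(config$rng_seed, "folds"))
  if (is.null(rule_scores))
    rule_scores <- compute_rule_scores(records, rule_scorer(scorer))
  runs <- list(); rows <- list()
  for (nm in names(ablation_grid)) {
    cfg <- config
    cfg$components <- ablation_grid[[nm]]
    if (verbose) message("ablation row: ", nm)
    cv <- cross_validate(records, cfg, rule_scores = rule_scores,
                         folds = folds, verbose = verbose)
    runs[[nm]] <- cv
    per_type <- vapply(ALARM_TYPES, function(ty) {
      sub <- cv$predictions[cv$predictions$alarm_type == ty, ]
      if (!nrow(sub)) return(NA_real_)
      challenge_score(confusion_counts(sub$label, sub$truth))
    }, 0)
    rows[[nm]] <- data.frame(configuration = nm,
                             rule = "rule_embedding" %in% cfg$components,
                             constraint = "constraint" %in% cfg$components,
                             t(per_type), overall = cv$mean_score,
                             pooled = challenge_score(cv$confusion))
  }
  structure(list(table = do.call(rbind, rows), runs = runs),
            class = "ablation_result")
}
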
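# Training objective: pair-wise discriminative constraint plus class-
# weighted binary cross entropy. These are the reference (pure R) forms;
# the C++ training step computes the identical quantities and is tested
# against them.

check_pair <- function(f_A, f_R) {
  if (!is.numeric(f_A) || !is.numeric(f_R) || length(f_A) != length(f_R))
    abort_validation("feature vectors must be numeric and of equal length")
}

#' Discriminative constraint for a false-alarm record
#'
#' `C_false = -log(sigmoid(f_A . f_R))`: small when the alarm-segment and
#' baseline-segment features agree (large positive dot product), large when
#' they disagree — a false alarm's final 10 s should look like the
#' patient's own baseline.
#'
#' @param f_A,f_R equal-length feature vectors (alarm / baseline encoding).
#' @return scalar constraint value.
#' @export
constraint_false <- function(f_A, f_R) {
  check_pair(f_A, f_R)
  neg_log_sigmoid(sum(f_A * f_R))
}

#' Discriminative constraint for a true-alarm record
#'
#' `C_true = -log(sigmoid(-(f_A . f_R))) = constraint_false(f_A, -f_R)`:
#' a true alarm's trigger segment should be distant from the baseline.
#'
#' @inheritParams constraint_false
#' @return scalar constraint value.
#' @export
constraint_true <- function(f_A, f_R) {
  check_pair(f_A, f_R)
  neg_log_sigmoid(-sum(f_A * f_R))
}

#' Mini-batch discriminative constraint
#'
#' `C = (1/N1) sum C_false + (1/N2) sum C_true` over the false / true
#' records of the batch; a class absent from the batch contributes nothing
#' (its normalizer would be undefined).
#'
#' @param features list of per-record lists with elements `f_A`, `f_R` and
#'   `label` (`"true_alarm"`/`"false_alarm"` or 1/0).
#' @return scalar batch constraint.
#' @export
batch_constraint <- function(features) {
  if (!length(features)) abort_validation("empty batch")
  lab <- vapply(features, function(p) {
    l <- p$label
    if (is.character(l)) l == "true_alarm" else as.logical(l)
  }, TRUE)
  c_false <- c_true <- 0
  for (i in seq_along(features)) {
    p <- features[[i]]
    if (lab[i]) c_true <- c_true + constraint_true(p$f_A, p$f_R)
    else c_false <- c_false + constraint_false(p$f_A, p$f_R)
  }
  out <- 0
  if (sum(!lab) > 0) out <- out + c_false / sum(!lab)
  if (sum(lab) > 0) out <- out + c_true / sum(lab)
  out
}

#' Class-weighted binary cross entropy
#'
#' Mean over the batch of `-w_pos * y * log(p) - (1 - y) * log(1 - p)`,
#' with the positive class (true alarm) up-weighted to counter the ~1.5:1
#' negative:positive imbalance.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities in (0, 1).
#' @param positive_class_weight weight on positive (true-alarm) terms.
#' @param eps clamp for log arguments.
#' @return scalar loss.
#' @export
weighted_bce <- function(labels, probabilities, positive_class_weight = 1.5,
                         eps = 1e-12) {
  if (!all(labels %in% c(0, 1))) abort_validation("labels must be 0/1")
  if (length(labels) != length(probabilities))
    abort_validation("labels and probabilities must align")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  mean(-positive_class_weight * labels * log(p) - (1 - labels) * log(1 - p))
}

#' Combined training loss
#'
#' `L = L_BCE + w * C`.
#'
#' @param L_BCE binary cross entropy value.
#' @param C batch discriminative constraint.
#' @param w constraint weight (default 1.5).
#' @return scalar total loss.
#' @export
total_loss <- function(L_BCE, C, w = 1.5) {
  if (!is.finite(L_BCE) || !is.finite(C) || !is.finite(w))
    abort_validation("loss inputs must be finite")
  L_BCE + w * C
}
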
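# Training behaviour (descent, determinism, ablation wiring), prediction
# contracts, the Challenge metrics, cross-validation and the ablation grid.
# All runs use the fs-50 toy world with ground-truth rule scores.

test_that("challenge score and rates match direct arithmetic", {
  cc <- list(TP = 96, TN = 86, FP = 14, FN = 4)
  expect_equal(challenge_score(cc), 182 / 216, tolerance = 1e-12)
  expect_equal(challenge_score(list(TP = 50, TN = 50, FP = 0, FN = 0)), 1)
  expect_equal(challenge_score(list(TP = 0, TN = 0, FP = 10, FN = 10)), 0)
  m <- tpr_tnr_acc(list(TP = 9, TN = 0, FP = 10, FN = 1))
  expect_equal(unname(m["TPR"]), 0.9)
  expect_equal(unname(m["TNR"]), 0.0)
  expect_equal(unname(m["ACC"]), 9 / 20)
  # undefined rates flagged as NA, not NaN
  m2 <- tpr_tnr_acc(list(TP = 0, TN = 5, FP = 2, FN = 0))
  expect_true(is.na(m2["TPR"]) && !is.nan(m2["TPR"]))
  expect_error(challenge_score(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               class = "alarmsieve_validation_error")
})

test_that("challenge score <= ACC, equal iff FN = 0, decreasing in FN", {
  set.seed(20)
  for (i in 1:200) {
    cc <- as.list(setNames(sample(0:40, 4, replace = TRUE),
                           c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cc)) == 0) cc$TP <- 1
    sc <- challenge_score(cc)
    acc <- unname(tpr_tnr_acc(cc)["ACC"])
    expect_lte(sc, acc + 1e-12)
    if (cc$FN == 0) expect_equal(sc, acc)
    if (cc$FN > 0 && cc$TP + cc$TN > 0) {
      expect_lt(sc, acc)
      cc2 <- cc; cc2$FN <- cc$FN + 5
      expect_lt(challenge_score(cc2), sc)
    }
  }
})

test_that("training descends, is seeded, and honours w = 0", {
  tw <- toy_world()
  cfg <- toy_config(max_epochs = 6L)
  m <- train_model(tw$records, cfg, rule_scores = tw$rule_scores)
  h <- m$history
  expect_equal(nrow(h), 6)
  expect_lt(tail(h$loss_total, 1), h$loss_total[1])
  expect_equal(h$loss_total, h$loss_bce + 1.5 * h$loss_constraint,
               tolerance = 1e-6)
  # determinism: identical history under the same seed
  m2 <- train_model(tw$records, cfg, rule_scores = tw$rule_scores)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
  # w = 0: no constraint term, loss equals BCE
  cfg0 <- toy_config(max_epochs = 3L, constraint_weight = 0,
                     components = c("rule_embedding", "alarm_embedding"))
  m0 <- train_model(tw$records, cfg0, rule_scores = tw$rule_scores)
  expect_equal(m0$history$loss_total, m0$history$loss_bce, tolerance = 1e-9)
  expect_true(all(m0$history$loss_constraint == 0))
  # validation failures
  expect_error(train_model(list(), cfg), class = "alarmsieve_validation_error")
  unl <- tw$records[1:4]
  for (i in seq_along(unl)) unl[[i]]$label <- "unknown"
  expect_error(train_model(unl, cfg), class = "alarmsieve_validation_error")
  single <- tw$records[tw$labels == "true_alarm"][1:6]
  expect_warning(train_model(single, toy_config(max_epochs = 1L),
                             rule_scores = rep(0.9, 6)),
                 "single-label")
})

test_that("prediction obeys threshold tie-break and the real-time contract", {
  tw <- toy_world()
  cfg <- toy_config(max_epochs = 4L)
  m <- train_model(tw$records[1:30], cfg, rule_scores = tw$rule_scores[1:30])
  # threshold tie-break: O = 0.5 exactly -> true_alarm. A zeroed classifier
  # head gives exactly 0.5 for every record.
  m05 <- m
  m05$params$Wc <- 0 * m05$params$Wc
  m05$params$bc <- 0
  pred05 <- predict_alarms(m05, tw$records[1:5],
                           rule_scores = tw$rule_scores[1:5])
  expect_true(all(pred05$probability == 0.5))
  expect_true(all(pred05$label == "true_alarm"))
  # appending garbage after onset never changes predictions
  pred <- predict_alarms(m, tw$records[1:10],
                         rule_scores = tw$rule_scores[1:10])
  garbled <- lapply(tw$records[1:10], function(r) {
    junk <- matrix(rnorm(5 * 100, sd = 10), 5, 100)
    r$channels <- cbind(r$channels, junk)
    r
  })
  pred_g <- predict_alarms(m, garbled, rule_scores = tw$rule_scores[1:10])
  expect_identical(pred$probability, pred_g$probability)
  # constant-zero record: valid deterministic probability
  z <- tw$records[[1]]
  z$channels[] <- 0
  pz <- predict_alarms(m, list(z), rule_scores = 0.5)
  expect_true(pz$probability > 0 && pz$probability < 1)
})

test_that("cross-validation evaluates each record exactly once per fold", {
  tw <- toy_world()
  cfg <- toy_config(max_epochs = 4L, folds = 3L)
  cv <- cross_validate(tw$records, cfg, rule_scores = tw$rule_scores)
  expect_length(cv$fold_scores, 3)
  expect_equal(nrow(cv$predictions), 60)
  expect_setequal(cv$predictions$record_id,
                  vapply(tw$records, `[[`, "", "record_id"))
  expect_equal(cv$mean_score, mean(cv$fold_scores))
  expect_equal(cv$sd_score, sd(cv$fold_scores))
  tot <- with(cv$confusion, TP + TN + FP + FN)
  expect_equal(tot, 60)
  expect_error(cross_validate(tw$records[1:2], toy_config(folds = 5L)),
               class = "alarmsieve_validation_error")
})

test_that("ablation wires components into the classifier dimensions", {
  # component sets map onto structure sizes: Se + Sa (+ Sr)
  s_basic <- model_structure(n_filters = 64L, components = "alarm_embedding")
  expect_equal(s_basic$K, 256 + 64)
  expect_false(s_basic$use_rule)
  s_full <- model_structure(n_filters = 64L)
  expect_equal(s_full$K, 256 + 64 + 64)
  # configuration mapping: {} vs {constraint} differ only through w
  tw <- toy_world()
  cfg <- toy_config(max_epochs = 3L, folds = 2L)
  ab <- ablate(tw$records[1:30], cfg, rule_scores = tw$rule_scores[1:30])
  expect_equal(nrow(ab$table), 4)
  expect_setequal(ab$table$configuration,
                  c("basic", "constraint", "rule", "full"))
  expect_true(all(ab$table$overall >= 0 & ab$table$overall <= 1))
  # per-type columns present
  expect_true(all(ALARM_TYPES %in% names(ab$table)))
  # shared folds: every run evaluated the same held-out sets
  expect_identical(ab$runs$basic$folds, ab$runs$full$folds)
})
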
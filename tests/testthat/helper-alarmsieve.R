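# Shared fixtures, built in code. The fs-50 "toy world" keeps encoder tests
# fast (T = 500 samples); rule-scorer tests use fs 250, where the beat
# detector is meant to operate. Expensive fixtures are memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

toy_spec <- function(n = 60, seed = 2, noise = 0.01) {
  synthetic_spec(n_records = n, type_mix = rep(0.2, 5), true_fraction = 0.5,
                 record_seconds = 40, fs = 50, noise_sd = noise,
                 rng_seed = seed)
}

# 60 balanced fs-50 records with ground truth; rule scores taken from the
# truth labels (the reference detector is not designed for fs 50)
toy_world <- function() {
  memo("toy_world", {
    ds <- generate_dataset(toy_spec())
    records <- lapply(ds$records, function(g) preprocess(g$record))
    list(ds = ds, records = records,
         labels = vapply(records, `[[`, "", "label"),
         rule_scores = vapply(ds$records, function(g)
           if (g$truth$label == "true_alarm") 0.9 else 0.1, 0))
  })
}

toy_config <- function(...) {
  defaults <- list(max_epochs = 8L, batch_size = 16L, dropout = 0,
                   learning_rate = 0.01, n_filters = 4L,
                   kernels = c(10L, 20L, 40L, 80L), embedding_size = 8L,
                   rng_seed = 3L)
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

tiny_model <- function(seed = 5) {
  s <- model_structure(n_filters = 2L, kernels = c(4L, 7L), stride = 2L,
                       Sa = 3L, Sr = 3L)
  init_model(s, rng_seed = seed)
}

# one clean fs-250 record per (type, label), memoized
clean_record <- function(alarm_type, label, seed = 42) {
  key <- paste("rec", alarm_type, label, seed)
  memo(key, {
    spec <- synthetic_spec(record_seconds = 60, noise_sd = 0)
    generate_record(alarm_type, label, spec, rng_seed = seed)
  })
}
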
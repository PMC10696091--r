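# Shared fixtures. The trained classifier is expensive (~half a minute),
# so it is built once per test run and cached for every file that needs it.

.fixture_cache <- new.env(parent = emptyenv())

# Training references whose class total lengths roughly match the
# 13 : 1 : 65 stride ratio, so per-class segment counts are balanced.
fixture_train_refs <- function(seed = 11L) {
  models <- microseek::default_origin_models()
  dplyr::bind_rows(
    microseek::make_references(models["human"], 12L, c(2000L, 2600L),
                               microseek::derive_seed(seed, "h")),
    microseek::make_references(models["viral"], 12L, c(250L, 350L),
                               microseek::derive_seed(seed, "v")),
    microseek::make_references(models["bacterial"], 12L, c(11000L, 13000L),
                               microseek::derive_seed(seed, "b")))
}

fixture_dataset <- function(seed = 11L) {
  if (is.null(.fixture_cache$dataset)) {
    refs <- fixture_train_refs(seed)
    .fixture_cache$dataset <-
      microseek::build_dataset(refs, microseek::segmentation_config(),
                               rng_seed = microseek::derive_seed(seed, "split"))
  }
  .fixture_cache$dataset
}

fixture_classifier <- function(seed = 11L) {
  if (is.null(.fixture_cache$classifier)) {
    ds <- fixture_dataset(seed)
    .fixture_cache$classifier <- microseek::train_classifier(
      ds, microseek::classifier_config(
        epochs = 4L, rng_seed = microseek::derive_seed(seed, "train")))
  }
  .fixture_cache$classifier
}

# Brute-force pairwise AUROC with half credit for ties (independent of
# the rank-based implementation under test).
brute_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
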
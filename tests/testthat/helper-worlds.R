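# Shared fixtures. Expensive cross-validation runs on the default synthetic
# world are cached so several tests can reuse one computation.

.cache <- new.env(parent = emptyenv())

smallWorld <- function(seed = 3L) {
  key <- paste0("small", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- benchmarkWorld("small", seed)
  .cache[[key]]
}

# 5-fold CV on the default world under the reference training configuration
# (k = 16, L = 3, lrMax = 0.01, dropouts 0.6/0.4, 200 epochs), one run per
# seed, optionally with an ablation toggle.
defaultWorldCV <- function(variant = c("full", "linear", "uniform"),
                           seeds = 1:3) {
  variant <- match.arg(variant)
  key <- paste0("cv_", variant)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  perFold <- lapply(seeds, function(s) {
    w <- benchmarkWorld("default", s)
    p <- pdaParams(epochs = 200L, seed = s,
                   etgActivation = variant != "linear",
                   useAttention = variant != "uniform")
    cv <- crossValidate(syntheticDataset(w), p, repeats = 1L)
    cbind(seed = s, cv$perFold)
  })
  .cache[[key]] <- do.call(rbind, perFold)
  .cache[[key]]
}
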
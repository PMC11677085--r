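## Stage-indexed substreams: a single global seed expands into one seed per
## named pipeline stage, so adding a stage never perturbs the randomness of
## earlier stages. Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) g <- alpha / sum(alpha)
  g / sum(g)
}
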
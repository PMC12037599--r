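# Derive n reproducible 32-bit sub-seeds from one master seed. Keeps every
# source of randomness traceable to a single integer without reusing streams.
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
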
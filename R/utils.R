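`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw k child seeds from a master seed without disturbing downstream use.
derive_seeds <- function(master_seed, k) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, k)
}
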
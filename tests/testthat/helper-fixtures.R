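# Shared fixtures, built in code. The small dataset uses a reduced tablet
# count so unit tests stay fast; tests that need the full 148-tablet study
# generate it themselves.

small_dataset <- local({
  cache <- NULL
  function(seed = 7) {
    if (is.null(cache)) cache <<- generate_dataset(seed = seed)
    cache
  }
})

# spectrum_set wrapper around a plain matrix
as_specset <- function(m, wn = seq_len(ncol(m)), modality = "test") {
  spectrum_set(wn, m, modality = modality)
}

subset_specset <- function(s, idx) {
  spectrum_set(s$wavenumbers, s$intensities[idx, , drop = FALSE],
               s$sample_ids[idx], s$modality, s$provenance)
}
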
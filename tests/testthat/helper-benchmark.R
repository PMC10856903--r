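# the simulation study is expensive; run it once and share across the
# acceptance blocks
benchmark_cache <- new.env(parent = emptyenv())

cached_benchmark <- function() {
  if (is.null(benchmark_cache$run))
    benchmark_cache$run <- spindle_benchmark(seed = 1, n_epochs = 50,
                                             n_spindles = 150,
                                             n_iterations = 40,
                                             verbose = FALSE)
  benchmark_cache$run
}
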
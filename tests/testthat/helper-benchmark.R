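# Shared scaled-down benchmark, computed once per test run and reused by the
# acceptance tests: 20 datasets of the primary mechanism setting plus 8 each
# of the two alternative settings (300 genes, 3 cohorts of 500, 200 SNPs).

.benchmark_env <- new.env(parent = emptyenv())

benchmark_reports <- function() {
  if (!is.null(.benchmark_env$reports)) {
    return(.benchmark_env$reports)
  }
  mkc <- function(seed, mp) {
    sim_config(n_genes = 300, seed = seed, mech_probs = mp)
  }
  reports <- list(
    s1 = run_benchmark(lapply(1:20, function(k) {
      mkc(1000 + k, c(0.8, 0.10, 0.05, 0.05))
    })),
    s2 = run_benchmark(lapply(1:8, function(k) {
      mkc(2000 + k, c(0.8, 0.05, 0.10, 0.05))
    })),
    s3 = run_benchmark(lapply(1:8, function(k) {
      mkc(3000 + k, c(0.8, 0.05, 0.05, 0.10))
    })))
  .benchmark_env$reports <- reports
  reports
}
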
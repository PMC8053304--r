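# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

default_library <- function() memo("lib", build_library())

# A small but non-trivial chromatin landscape: noiseless so closed-loop
# checks are exact.
small_chromatin_sim <- function() memo("chrom_small", {
  simulate_chromatin(chromatin_sim_config(
    chrom_lengths = c(chrS1 = 250000L, chrS2 = 180000L),
    n_sites = c(a = 12L, b = 12L, c = 12L, d = 60L),
    n_shared = 48L, n_b_only = 16L, n_genes = 20L,
    noise = 0, seed = 401L))
})

# Profile matrix with the geometry attributes binned_profile() sets.
make_profile_matrix <- function(m, window_half = 1000L, bin_size = 10L) {
  m <- as.matrix(m)
  attr(m, "window_half") <- as.integer(window_half)
  attr(m, "bin_size") <- as.integer(bin_size)
  attr(m, "standard_total") <- 1e8
  m
}

# Monte-Carlo standard error of a relative-shift value via the delta
# method on the four Poisson-like band counts involved.
rs_se <- function(c_n, c_ref, i_n, i_ref) {
  sqrt(1 / c_n + 1 / c_ref + 1 / i_n + 1 / i_ref) / log(2)
}
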
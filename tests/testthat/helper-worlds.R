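# Shared simulated worlds, built once per test session and memoized.
# Generator parameters are the stated experimental conditions (100 bp reads,
# insert 600 +/- 50, 50x coverage, circular 50 kb chromosome) and are fixed
# independently of any test outcome.

.world_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

# circular 50 kb chromosome shared by the end-to-end experiments
e2e_genome <- function() memo("genome", make_genome(50000, rng_seed = 101))

# error-free 50x library + 1000-seed run + validation
e2e_errorfree <- function() memo("ef", {
  g <- e2e_genome()
  pp <- make_pairs(g, coverage = 50, read_len = 100, insert_mean = 600,
                   insert_sd = 50, err_rate = 0, rng_seed = 102, circular = TRUE)
  run <- mate_fill(pp$reads1, pp$reads2, insert_mean = 600, insert_sd = 50,
                   seed_limit = 1000)
  val <- validate_run(run, pp$truth, g, circular = TRUE)
  list(genome = g, pairs = pp, run = run, val = val)
})

# 0.5% substitution-error library + 500-seed run + validation
e2e_errors <- function() memo("err", {
  g <- e2e_genome()
  pp <- make_pairs(g, coverage = 50, read_len = 100, insert_mean = 600,
                   insert_sd = 50, err_rate = 0.005, rng_seed = 103, circular = TRUE)
  run <- mate_fill(pp$reads1, pp$reads2, insert_mean = 600, insert_sd = 50,
                   seed_limit = 500)
  val <- validate_run(run, pp$truth, g, circular = TRUE)
  list(genome = g, pairs = pp, run = run, val = val)
})

# 20 kb linear genome with two exact 2 kb repeat copies 6 kb apart, plus a
# 50x error-free library and an index ready for single-seed extensions
repeat_world <- function() memo("rep", {
  g <- make_genome(20000, rng_seed = 7,
                   repeat_spec = list(list(len = 2000, copies = 2,
                                           starts = c(4000, 12000))))
  pp <- make_pairs(g, coverage = 50, read_len = 100, insert_mean = 600,
                   insert_sd = 50, err_rate = 0, rng_seed = 8)
  idx <- build_read_index(c(pp$reads1, pp$reads2), fingerprint_params(), 50L)
  ep <- extension_params(Lmax = 750)
  list(genome = g, pairs = pp, index = idx, ep = ep)
})

# small 5 kb world for fast unit-level end-to-end checks
small_world <- function() memo("small", {
  g <- make_genome(5000, rng_seed = 11)
  pp <- make_pairs(g, coverage = 50, read_len = 100, insert_mean = 600,
                   insert_sd = 50, err_rate = 0, rng_seed = 12)
  idx <- build_read_index(c(pp$reads1, pp$reads2), fingerprint_params(), 50L)
  ep <- extension_params(Lmax = 750)
  list(genome = g, pairs = pp, index = idx, ep = ep)
})
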
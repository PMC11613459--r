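# shared fixtures; expensive simulations are computed once per run on demand

.fixtures <- new.env(parent = emptyenv())

# full reference-condition simulation (140 s) at a given length, cached
reference_kymo <- function(length) {
  key <- paste0("kymo_", length)
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(length = length)
    .fixtures[[key]] <- simulate_min(reference_params(), cfg)
  }
  .fixtures[[key]]
}

# a random strictly positive concentration field on a small grid
random_field <- function(n = 7, seed = 1) {
  set.seed(seed)
  x <- (seq_len(n) - 0.5) * 0.2
  min_field(x,
            c_DD = runif(n, 1, 100), c_DT = runif(n, 1, 100),
            c_E = runif(n, 1, 100), c_d = runif(n, 1, 100),
            c_de = runif(n, 1, 100))
}
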
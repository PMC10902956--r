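# Shared fixtures: the default configuration and a base-case fit are
# cheap to build (< 0.1 s) and are reconstructed where needed.

default_cfg <- function() load_config()

base_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- markov_cua(default_cfg())
    cache
  }
})

# Table of printed base-case arm totals used by arithmetic-tier tests.
printed_arms <- function() {
  list(
    drd = list(label = "DRd", total_cost = 15370, total_qaly = 1.56,
               total_ly = 5.86),
    krd = list(label = "KRd", total_cost = 15106, total_qaly = 1.28,
               total_ly = 3.52))
}

# A valid random 3x3 transition matrix respecting the model structure
# (death absorbing, no PD -> PFS recovery).
random_transition_matrix <- function() {
  p1 <- diff(sort(c(0, stats::runif(2), 1)))
  p2 <- stats::runif(1)
  rbind(c(p1[1], p1[2], p1[3]),
        c(0, p2, 1 - p2),
        c(0, 0, 1))
}
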
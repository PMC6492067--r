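# Shared fixtures built in code.

# A 12-respondent worked sample: 2 seeds, fixed degrees and recruitment
# links, used to check RDS-I against independent hand evaluation.
worked_sample_12 <- function() {
  rds_sample(data.frame(
    id = 1:12,
    recruiter_id = c(NA, NA, 1, 1, 2, 2, 3, 4, 5, 6, 8, 9),
    degree = c(2, 4, 3, 6, 2, 8, 4, 5, 10, 2, 4, 6),
    app_30d = c(1, 0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1)
  ))
}

# Build a sample realising an explicit multiset of recruiter->recruit
# trait pairs: one recruiter row per pair (as a seed) plus one recruit.
sample_from_pairs <- function(pairs, degree = 2) {
  n <- nrow(pairs)
  df <- data.frame(
    id = seq_len(2 * n),
    recruiter_id = c(rep(NA, n), seq_len(n)),
    degree = degree,
    trait = c(pairs$recruiter, pairs$recruit)
  )
  rds_sample(df)
}

# A simple linear chain with given trait and degree vectors (first
# `n_seeds` rows are seeds, every later row recruited by the previous).
chain_sample <- function(trait, degree = rep(2, length(trait)), n_seeds = 1) {
  n <- length(trait)
  rds_sample(data.frame(
    id = seq_len(n),
    recruiter_id = c(rep(NA, n_seeds), seq_len(n - n_seeds)),
    degree = degree,
    trait = trait
  ))
}

sim_setup <- function(rng_seed, N = 10000, prevalence = 0.35,
                      sample_target = 400, ...) {
  spec <- population_spec(
    N = N, prevalence = prevalence,
    sample_target = sample_target, rng_seed = rng_seed, ...
  )
  net <- generate_network(spec)
  list(spec = spec, net = net, sample = simulate_rds(net))
}
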
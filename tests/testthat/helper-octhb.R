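# shared fixtures: reduced sampler settings and a constructed posterior

quick_settings <- function(chains = 2, iterations = 800, adapt = 200) {
  sampler_settings(chains = chains, iterations = iterations, thin = 1,
                   adapt = adapt)
}

# a hand-built drug-model posterior with constant draws, for exercising the
# normalized-response arithmetic without sampling
fake_drug_post <- function(values, n = 200, reference = "ACZ") {
  draws <- matrix(rep(unlist(values), each = n), nrow = n,
                  dimnames = list(NULL, names(values)))
  structure(list(draws = draws, n_chains = 1L, n_iter = n,
                 model = "drug_mixed", settings = NULL,
                 diagnostics = tibble::tibble(term = colnames(draws),
                                              rhat = 1, ess = n),
                 data_info = list(reference = reference)),
            class = "octhb_post")
}

# flat-baseline profile with an arbitrary deviation shape, plus matching
# baseline tibble: lets the HB operations be tested against closed forms
profile_with_dip <- function(dip, level = 200, pad = 5, ax = 1.6) {
  intensity <- c(rep(level, pad), level - dip, rep(level, pad))
  prof <- octhb:::new_trp(intensity, ax)
  n <- length(intensity)
  baseline <- tibble::tibble(index = seq_len(n), baseline = rep(level, n))
  list(profile = prof, baseline = baseline)
}
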
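# shared fixture builders (everything generated in code, no files)

# small founder pools plus the full factorial plan and projected hybrids
tiny_population <- function(n_b = 10, n_r = 10, n_markers = 200, seed = 42) {
  pools <- simulate_founders(n_b, n_r, n_markers, seed = seed)
  inbreds <- combine_pools(pools)
  plan <- make_cross_plan(pools$B$genotypes$entries$id,
                          pools$R$genotypes$entries$id)
  list(pools = pools, inbreds = inbreds, plan = plan,
       hybrids = project_all(plan, inbreds))
}

# a geno_matrix built directly from a dosage matrix
gm_from <- function(m, types = NULL, n_alleles = NULL) {
  gm <- geno_matrix(m)
  if (!is.null(types)) gm$entries$type <- types
  if (!is.null(n_alleles)) gm$markers$n_alleles <- n_alleles
  gm
}

# hybrid population with a simulated trait observed with iid noise, the
# noise SD expressed as a fraction of the genetic SD
noisy_values <- function(true_values, noise_frac, seed) {
  set.seed(seed)
  true_values + stats::rnorm(length(true_values),
                             0, noise_frac * stats::sd(true_values))
}
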
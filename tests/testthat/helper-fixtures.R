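# small fixtures built in code; all randomness under explicit seeds

tiny_matrix <- function() {
  matrix(c(1.5, 0.0, 3.0, 2.0), nrow = 2, byrow = TRUE,
         dimnames = list(c("isoA", "isoB"), c("s1", "s2")))
}

# gamma draws with E = mu, Var = phi * mu (same moment pair as the package
# generator, but written independently of it)
rqp <- function(n, mu, phi) rgamma(n, shape = mu / phi, scale = phi)

# balanced planted scenario used by recovery tests
planted_scenario <- function(seed, n_per_group = 30, n_genes = 1000,
                             phi = 5, fold = 8, n_specific = 20,
                             n_coexpressed = 5) {
  simulation_config(samples_per_subtype = rep(n_per_group, 5),
                    n_genes = n_genes, isoforms_per_gene = 2,
                    dispersion_phi = phi, n_specific = n_specific,
                    n_coexpressed = n_coexpressed, effect_fold = fold,
                    seed = seed)
}

discovery_part <- function(d) {
  keep <- d$samples$split == "discovery"
  list(x = d$expression[, d$samples$sample_id[keep], drop = FALSE],
       subtype = factor(d$samples$subtype[keep]))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
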
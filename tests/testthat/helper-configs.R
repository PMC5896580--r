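# Shared configuration builders for small and full-scale test runs.

linear_spec <- function(s_b = 0.1, s_d = 0, n_ref = 50, gamma_ref = 5,
                        s_FL = 1)
  fitness_spec(s_b = s_b, s_d = s_d, beneficial_shape = "linear",
               deleterious_shape = "linear", n_ref = n_ref,
               gamma_ref = gamma_ref, s_FL = s_FL)

# default-condition beneficial-only run (stop once all genomes reach gamma)
beneficial_config <- function(inheritance, b, seed = NULL)
  sim_config(b = b, mu_b = 1e-8, mu_d = 0, fitness = linear_spec(),
             inheritance = inheritance,
             stop_rule = "all_genomes_reach_gamma",
             max_generations = 60000, seed = seed)

# default-condition combined run (10000 generations)
combined_config <- function(inheritance, b, seed = NULL)
  sim_config(b = b, mu_b = 1e-8, mu_d = 1e-7,
             fitness = fitness_spec(s_b = 0.1, s_d = 0.1,
                                    beneficial_shape = "linear",
                                    deleterious_shape = "concave_down"),
             inheritance = inheritance, stop_rule = "fixed_generations",
             max_generations = 10000, seed = seed)

# default-condition deleterious-only run (10000 generations)
deleterious_config <- function(inheritance, b, seed = NULL)
  sim_config(b = b, mu_b = 0, mu_d = 1e-7,
             fitness = fitness_spec(s_b = 0, s_d = 0.1,
                                    beneficial_shape = "linear",
                                    deleterious_shape = "concave_down"),
             inheritance = inheritance, stop_rule = "fixed_generations",
             max_generations = 10000, seed = seed)

# small, fast cytoplasmic instance for distributional checks
small_config <- function(..., seed = NULL)
  sim_config(N = 100, n = 10, b = 5, l = 2000, mu_b = 1e-5, mu_d = 0,
             fitness = linear_spec(n_ref = 10, gamma_ref = 3),
             stop_rule = "fixed_generations", max_generations = 200,
             seed = seed, ...)
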
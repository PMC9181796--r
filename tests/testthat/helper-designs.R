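# Shared fixtures: all data is generated in code.

# Proportions planting every class, background-dominated.
planted_props <- function(planted = 0.05, none_down = 0.025) {
  p <- c(up_local = planted, up_systemic = planted, up_both = planted,
         up_none = planted, up_unrecovered = planted,
         down_local = planted, down_systemic = planted,
         down_both = planted, down_none = none_down,
         down_unrecovered = none_down)
  c(background = 1 - sum(p), p)
}

# High-expression design where every DE call should be near-certain.
planted_design <- function(n_genes = 2000, seed = 42, ...) {
  simulation_design(n_genes, class_proportions = planted_props(),
                    base_mean_log_range = c(2, 3.5), seed = seed, ...)
}

all_background_design <- function(n_genes = 1000, seed = 42, ...) {
  simulation_design(n_genes, class_proportions = c(background = 1),
                    seed = seed, ...)
}

# Root-tissue truth/label confusion for one simulated run.
root_confusion <- function(sim, labels) {
  truth <- sim$truth[sim$truth$tissue == "root", ]
  m <- merge(truth, labels[labels$tissue == "root", ],
             by = "gene_id", all.x = TRUE)
  m$called <- ifelse(is.na(m$label), "(none)", m$label)
  m
}

# Random deg_sets over a small universe (for set-algebra properties).
random_pair <- function(universe, p_up = 0.2, p_down = 0.2) {
  r <- stats::runif(length(universe))
  deg_sets(universe[r < p_up],
           universe[r >= p_up & r < p_up + p_down])
}
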
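test_that("plan_truth allocates classes by the rounding rule", {
  d <- simulation_design(10, class_proportions = c(background = 1))
  tr <- plan_truth(d)
  root <- tr[tr$tissue == "root", ]
  expect_equal(nrow(root), 10)
  expect_true(all(root$response_class == "background"))
  expect_true(all(root$direction == "none"))

  d <- simulation_design(100, class_proportions = c(
    background = 0.5, up_local = 0.25, down_both = 0.25))
  root <- subset(plan_truth(d), tissue == "root")
  tab <- table(root$response_class, root$direction)
  expect_equal(unname(tab["background", "none"]), 50L)
  expect_equal(unname(tab["local", "up"]), 25L)
  expect_equal(unname(tab["both", "down"]), 25L)
})

test_that("class counts always sum to n_genes", {
  set.seed(1)
  for (i in 1:10) {
    w <- stats::runif(6)
    props <- setNames(w / sum(w),
                      c("background", "up_local", "up_systemic",
                        "down_both", "up_unrecovered", "down_none"))
    n <- sample(50:500, 1)
    tr <- plan_truth(simulation_design(n, class_proportions = props,
                                       seed = i))
    expect_equal(nrow(subset(tr, tissue == "root")), n)
    expect_equal(nrow(subset(tr, tissue == "shoot")), n)
  }
})

test_that("truth planting is deterministic per seed", {
  d <- simulation_design(100, class_proportions = c(
    background = 0.9, up_local = 0.1), seed = 1)
  expect_identical(plan_truth(d), plan_truth(d))
  d2 <- simulation_design(100, class_proportions = c(
    background = 0.9, up_local = 0.1), seed = 2)
  expect_false(identical(plan_truth(d), plan_truth(d2)))
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(10, class_proportions = c(
    background = 0.6, up_local = 0.2)), "sum to 1")
  expect_error(simulation_design(10, class_proportions = c(
    background = 0.5, wrong_class = 0.5)), "unknown planted classes")
  expect_error(simulation_design(10, replicates = 1), "replicates")
  expect_error(simulation_design(10, effect_log2fc = 0), "effect_log2fc")
  expect_error(simulation_design(10, dispersion = -0.1), "dispersion")
  expect_error(simulation_design(0), "n_genes")
})

test_that("expected_mean_pattern matches the class definitions", {
  expect_equal(expected_mean_pattern("none", "background", 2),
               c(CK_R = 1, S0_R = 1, SR_R = 1, SPSR_R = 1, SPS0_R = 1))
  expect_equal(expected_mean_pattern("up", "both", 1),
               c(CK_R = 1, S0_R = 2, SR_R = 1, SPSR_R = 1, SPS0_R = 1))
  expect_equal(expected_mean_pattern("down", "systemic", 2),
               c(CK_R = 1, S0_R = 0.25, SR_R = 1, SPSR_R = 0.25,
                 SPS0_R = 1))
  expect_equal(expected_mean_pattern("up", "local", 3),
               c(CK_R = 1, S0_R = 8, SR_R = 1, SPSR_R = 1, SPS0_R = 8))
  expect_equal(expected_mean_pattern("up", "unrecovered", 1),
               c(CK_R = 1, S0_R = 2, SR_R = 2, SPSR_R = 2, SPS0_R = 2))
  expect_error(expected_mean_pattern("up", "sideways", 1),
               "unknown response class")
  expect_error(expected_mean_pattern("up", "background", 1), "coincide")
})

test_that("shoot patterns mirror the homogeneous/heterogeneous roles", {
  expect_equal(expected_mean_pattern("up", "both", 2, tissue = "shoot"),
               c(CK_Sh = 1, S0_Sh = 4, SR_Sh = 1, SP_Sh = 1))
  expect_equal(expected_mean_pattern("up", "none", 2, tissue = "shoot"),
               c(CK_Sh = 1, S0_Sh = 4, SR_Sh = 1, SP_Sh = 4))
  expect_equal(
    expected_mean_pattern("down", "unrecovered", 1, tissue = "shoot"),
    c(CK_Sh = 1, S0_Sh = 0.5, SR_Sh = 0.5, SP_Sh = 0.5))
  # shoot vocabulary accepted directly
  expect_equal(
    expected_mean_pattern("up", "hetero_responsive", 1, tissue = "shoot"),
    expected_mean_pattern("up", "local", 1, tissue = "shoot"))
})

test_that("simulation is reproducible and phi = 0 is Poisson", {
  d <- planted_design(n_genes = 300, seed = 9)
  s1 <- simulate_counts(d)
  s2 <- simulate_counts(d)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)

  # Poisson limit: variance/mean ratio near 1 across replicated samples
  dp <- simulation_design(200, replicates = 50, dispersion = 0,
                          libsize_cv = 0,
                          class_proportions = c(background = 1),
                          base_mean_log_range = c(3, 3), seed = 5)
  cm <- simulate_counts(dp)$counts
  ck <- cm$counts[, group_samples(cm, "CK_R")]
  ratio <- apply(ck, 1, var) / rowMeans(ck)
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("planted deficiency effect reaches the generating mean", {
  # planted up_both genes: S0_R mean is 2^3 = 8x the CK_R mean
  d <- simulation_design(2000, class_proportions = c(
    background = 0.9, up_both = 0.1), effect_log2fc = 3,
    dispersion = 0.05, base_mean_log_range = c(2, 3.5), seed = 11)
  sim <- simulate_counts(d)
  cm <- sim$counts
  planted <- subset(sim$truth, tissue == "root" &
                      response_class == "both")$gene_id
  s0 <- rowMeans(cm$counts[planted, group_samples(cm, "S0_R")])
  ck <- rowMeans(cm$counts[planted, group_samples(cm, "CK_R")])
  expect_equal(mean(s0 / ck), 8, tolerance = 0.15)
})

test_that("background group means converge to a common baseline", {
  # libsize_cv = 0, phi = 0: every group's sample mean estimates the
  # baseline; at 200 replicates all groups agree within 5%
  d <- simulation_design(100, replicates = 200, dispersion = 0,
                         libsize_cv = 0,
                         class_proportions = c(background = 1),
                         base_mean_log_range = c(2, 3), seed = 21)
  cm <- simulate_counts(d)$counts
  overall <- rowMeans(cm$counts)
  for (g in root_groups()) {
    gm <- rowMeans(cm$counts[, group_samples(cm, g)])
    expect_true(all(abs(gm / overall - 1) < 0.05))
  }
})

test_that("simulated tables round-trip through the TSV writers", {
  sim <- simulate_counts(planted_design(n_genes = 120, seed = 3))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_identical(counts, sim$counts$counts)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sheet$sample, sim$counts$samples$sample)
  lens <- read_gene_lengths(file.path(dir, "gene_lengths.tsv"))
  expect_identical(lens, sim$counts$gene_lengths)
  truth <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(truth$response_class, sim$truth$response_class)
})
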
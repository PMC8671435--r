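refs4 <- c("Out1", "Out2", "Out3", "Out4")

test_that("the f4 system has the documented dimensions and consistent errors", {
  cfg <- sim_config(seed = 54, n_snps_per_chromosome = 500, n_chromosomes = 10,
                    n_target_individuals = 15, missing_rate = 0,
                    n_reference_individuals = 12)
  x <- simulate_study(cfg)$data
  # no missingness, so system statistics match standalone f4 calls exactly
  bl <- make_blocks(x)
  sys <- build_f4_system(x, "Target", c("Source1", "Source2"), refs4, blocks = bl)
  k <- 2; m <- 4
  expect_equal(length(sys$y), m - 1)
  expect_equal(dim(sys$X), c(m - 1, k))
  expect_equal(dim(sys$cov), rep((k + 1) * (m - 1), 2))
  r <- f4(x, "Target", "Out1", "Out2", "Out1", blocks = bl)
  expect_equal(sys$y[1], r$estimate, tolerance = 1e-10)
  expect_equal(sqrt(sys$cov[1, 1]), r$std_error, tolerance = 0.05 * r$std_error)
  expect_error(build_f4_system(x, "Target", c("Source1", "Source2"),
                               c("Out1", "Out2")), "under-identified")
})

test_that("a target identical to the single source gives a matching column", {
  st <- demo_study()
  x <- st$data
  sys <- build_f4_system(x, "Source1", "Source1", refs4)
  expect_equal(sys$y, sys$X[, 1])
})

test_that("qpAdm recovers a 50/50 mixture and the pure-source limit", {
  cfg <- sim_config(seed = 51, n_snps_per_chromosome = 900, n_chromosomes = 16,
                    n_target_individuals = 30, ancestry_mean = 0.5,
                    ancestry_sd = 0, missing_rate = 0.1)
  st <- simulate_study(cfg)
  auto <- partition_compartments(st$data)$autosomes
  fit <- fit_qpadm(build_f4_system(auto, "Target", c("Source1", "Source2"), refs4))
  expect_lt(abs(fit$weights[["Source2"]] - 0.5), 2 * fit$std_errors[["Source2"]])
  expect_gt(fit$p_value, 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)

  # pure-source target: half of Source1 relabeled
  x <- auto
  s1 <- which(x$ind$group == "Source1")
  x$ind$group[s1[1:12]] <- "PureTarget"
  pfit <- fit_qpadm(build_f4_system(x, "PureTarget", c("Source1", "Source2"), refs4))
  expect_lt(abs(pfit$weights[["Source1"]] - 1), 2 * pfit$std_errors[["Source1"]] + 0.02)
})

test_that("a target from an unrelated source is rejected by the model fit", {
  st <- demo_study()
  x <- partition_compartments(st$data)$autosomes
  o3 <- which(x$ind$group == "Out3")
  x$ind$group[o3[1:10]] <- "Impostor"
  fit <- fit_qpadm(build_f4_system(x, "Impostor", c("Source1", "Source2"),
                                   c("Out1", "Out2", "Out4")))
  expect_lt(fit$p_value, 0.05)
})

test_that("model competition keeps the true source and kills shared-drift proxies", {
  st <- demo_study()
  x <- partition_compartments(st$data)$autosomes
  # two interchangeable proxies: halves of one outgroup population related
  # to (but not identical with) the true West-Eurasian-like source; each
  # carries the other's full drift, so each kills the other's model
  o2 <- which(x$ind$group == "Out2")
  x$ind$group[o2[1:10]] <- "ProxyA"
  x$ind$group[o2[11:20]] <- "ProxyB"
  comp <- model_competition(x, "Target", c("ProxyA", "ProxyB"), "Source1",
                            c("Out1", "Out3", "Out4"))
  expect_equal(nrow(comp), 2L)
  expect_false(any(comp$fits))

  # true source against a diverged decoy: only the true source survives
  x2 <- partition_compartments(st$data)$autosomes
  comp2 <- model_competition(x2, "Target", c("Source2", "Out2"), "Source1",
                             c("Out1", "Out3", "Out4"))
  keep_true <- comp2$fits[comp2$keep == "Source2"]
  keep_decoy <- comp2$fits[comp2$keep == "Out2"]
  expect_true(keep_true)
  expect_false(keep_decoy)
})

test_that("qpWave clade test: identity gives p = 1, shifted groups reject", {
  st <- demo_study()
  x <- partition_compartments(st$data)$autosomes
  tgt <- which(x$ind$group == "Target")
  expect_equal(qpwave_clade_test(x, tgt[1:10], tgt[1:10], refs4)$p_value, 1)
  set.seed(9)
  h <- sample(tgt, 15)
  null_res <- qpwave_clade_test(x, h, setdiff(tgt, h), refs4)
  expect_true(null_res$consistent_with_clade)
  # 10-point ancestry shift between the halves
  cfg2 <- sim_config(seed = 52, n_snps_per_chromosome = 700, n_chromosomes = 12,
                     n_target_individuals = 15, ancestry_mean = 0.675,
                     ancestry_sd = 0.02, missing_rate = 0.1,
                     n_reference_individuals = 2)
  st2 <- simulate_admixed_cohort(cfg2, simulate_source_frequencies(
    sim_config(seed = 42, n_snps_per_chromosome = 700, n_chromosomes = 12)))
  y <- st$data
  y$geno[tgt[16:30], ] <- st2$data$geno[1:15, ]
  y <- partition_compartments(y)$autosomes
  shift <- qpwave_clade_test(y, tgt[1:15], tgt[16:30], refs4)
  expect_lt(shift$p_value, 0.05)
})

test_that("sex-bias closed forms reproduce the published decomposition", {
  d <- sex_bias_decompose(0.575, 0.003, 0.644, 0.018)
  expect_equal(round(d$z, 2), 3.78)
  expect_equal(round(100 * d$P), 68)
  expect_equal(round(100 * d$P_lower), 59)
  expect_equal(round(100 * d$P_upper), 77)
  expect_equal(round(sex_bias_decompose(0.568, 0.004, 0.638, 0.017)$z, 2), 4.01)
  expect_equal(round(sex_bias_decompose(0.577, 0.004, 0.663, 0.029)$z, 2), 2.94)
})

test_that("sex-bias identities hold for arbitrary inputs", {
  set.seed(10)
  for (i in 1:20) {
    pa <- runif(1, 0.3, 0.7); px <- runif(1, 0.3, 0.7)
    d <- sex_bias_decompose(pa, 0.01, px, 0.02)
    expect_equal(d$F + d$M, 2 * pa, tolerance = 1e-12)
    expect_equal(d$F, 3 * px - 2 * pa, tolerance = 1e-12)
  }
  nb <- sex_bias_decompose(0.6, 0.01, 0.6, 0.02)
  expect_equal(nb$F, nb$M)
  expect_equal(nb$P, 0.5)
  expect_equal(nb$z, 0)
})

test_that("estimate_sex_bias recovers a female-biased cohort end to end", {
  cfg <- sim_config(seed = 53, n_snps_per_chromosome = 900, n_chromosomes = 16,
                    n_target_individuals = 40, missing_rate = 0.1)
  st <- simulate_study(cfg)
  sb <- estimate_sex_bias(st$data, "Target", c("Source1", "Source2"), refs4,
                          we_source = "Source2")
  d <- tidy(sb)
  truth_p <- mean(st$truth$F_component) /
    (mean(st$truth$F_component) + mean(st$truth$M_component))
  expect_lt(abs(d$P - truth_p), 2.5 * d$P_se)
  expect_equal(nrow(glance(sb)), 2L)
  expect_equal(tidy(sb$autosomes)$weight, unname(sb$autosomes$weights))
})
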
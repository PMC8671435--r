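test_that("ancestry covariance matches hand arithmetic on two SNPs", {
  # refs with exact frequencies: ref1 = (0.8, 0.2), ref2 = (0.2, 0.6)
  f <- cbind(r1 = c(0.8, 0.2), r2 = c(0.2, 0.6))
  refs <- freq_pops_gen(f, n_per_pop = 5)
  subj_ind <- tibble::tibble(individual_id = "subj1", sex = "unknown",
                             group = "subj")
  x <- gen_dataset(rbind(c(2L, 0L), refs$geno), refs$snp,
                   dplyr::bind_rows(subj_ind, refs$ind))
  # SNP distance 0.01 M -> bin 10 at binsize 0.001
  curve <- ancestry_covariance(x, "subj", "r1", "r2", binsize = 0.001, maxdis = 0.05)
  w <- f[, 1] - f[, 2]                      # (0.6, -0.4)
  xs <- c(1, 0) - (f[, 1] + f[, 2]) / 2     # (0.5, -0.4)
  oracle <- prod(xs * w) / prod(w^2)
  expect_equal(nrow(curve$bins), 1L)
  expect_equal(curve$bins$covariance, oracle, tolerance = 1e-12)
  expect_equal(curve$bins$distance, 0.0095)
})

test_that("the curve is invariant to reference swap and SNP order", {
  st <- demo_study()
  x <- partition_compartments(st$data)$autosomes
  a <- ancestry_covariance(x, "Target", "Source1", "Source2", maxdis = 0.3)
  b <- ancestry_covariance(x, "Target", "Source2", "Source1", maxdis = 0.3)
  expect_equal(a$bins$covariance, b$bins$covariance, tolerance = 1e-12)
  perm <- sample(ncol(x$geno))
  y <- x
  y$geno <- y$geno[, perm, drop = FALSE]
  y$snp <- y$snp[perm, ]
  cp <- ancestry_covariance(y, "Target", "Source1", "Source2", maxdis = 0.3)
  expect_equal(cp$bins$covariance, a$bins$covariance, tolerance = 1e-12)
})

test_that("fit_decay recovers a noiseless exponential and scales correctly", {
  d <- seq(0.005, 0.3, length.out = 100)
  curve <- tibble::tibble(distance = d, covariance = 0.05 * exp(-20 * d) + 0.001)
  fit <- fit_decay(curve, start_distance = 0.0045)
  expect_equal(fit$lambda, 20, tolerance = 1e-6)
  expect_equal(fit$A, 0.05, tolerance = 1e-6)
  expect_equal(fit$c0, 0.001, tolerance = 1e-8)
  curve2 <- curve; curve2$covariance <- 2 * curve2$covariance
  fit2 <- fit_decay(curve2, start_distance = 0.0045)
  expect_equal(fit2$lambda, fit$lambda, tolerance = 1e-5)
  expect_equal(fit2$A, 2 * fit$A, tolerance = 1e-5)
  expect_error(fit_decay(curve[1:5, ]), "at least 10")
})

test_that("an unadmixed subject shows no significant decay", {
  st <- demo_study()
  x <- partition_compartments(st$data)$autosomes
  # pure-source subjects: Source1 individuals carry no admixture LD
  contrast <- function(subjects) {
    curve <- ancestry_covariance(x, subjects, "Source1", "Source2", maxdis = 0.3)
    b <- curve$bins
    mean(b$covariance[b$distance < 0.05]) - mean(b$covariance[b$distance > 0.2])
  }
  flat <- contrast(which(x$ind$group == "Source1")[1:5])
  admixed <- contrast(which(x$ind$group == "Target")[1:5])
  expect_gt(admixed, 5 * abs(flat))  # decay signal only in the admixed cohort
})

test_that("date conversion reproduces the published arithmetic", {
  conv <- convert_generations(22.2, 1.4, generation_time = 28, midpoint_ce = 810)
  expect_equal(round(conv$years, -1), 620)
  expect_equal(round(conv$years_se * 1.96, -1), 80)  # ~+/-40 at 1 SE
  expect_equal(conv$years_lower, (22.2 - qnorm(0.975) * 1.4) * 28)
  expect_equal(conv$years_upper, (22.2 + qnorm(0.975) * 1.4) * 28)
  # published calendar interval 111-265 CE; half-up rounding gives 112
  expect_lte(abs(conv$calendar_lower_ce - 111), 1)
  expect_equal(conv$calendar_upper_ce, 265)
  # SE -> 0 collapses to the point date
  pt <- convert_generations(22.2, 0, midpoint_ce = 810)
  expect_equal(pt$calendar_lower_ce, pt$calendar_upper_ce)
  expect_equal(pt$calendar_lower_raw, 810 - 28 * 22.2)
})

test_that("pairwise date Z matrix and Bonferroni threshold behave", {
  dates <- tibble::tibble(id = c("a", "b", "c"),
                          generations = c(20, 20, 40),
                          std_error = c(2, 2, 3))
  pz <- pairwise_date_z(dates, n_tests = 190)
  expect_equal(pz$z_matrix["a", "b"], 0)
  expect_equal(pz$threshold, qnorm(1 - 0.025 / 190))
  expect_equal(round(pz$threshold, 2), 3.65)
  expect_equal(pz$z_matrix["c", "a"], 20 / sqrt(13))
  expect_true(pz$multiple_waves)
  same <- pairwise_date_z(dates[1:2, ])
  expect_false(same$multiple_waves)
})

test_that("dating recovers the simulated admixture time", {
  cfg <- sim_config(seed = 71, n_snps_per_chromosome = 600, n_chromosomes = 16,
                    n_target_individuals = 30, admixture_generations = 20,
                    missing_rate = 0.1)
  st <- simulate_study(cfg)
  auto <- partition_compartments(st$data)$autosomes
  de <- date_estimate(auto, "Target", "Source1", "Source2", maxdis = 0.4,
                      midpoint_ce = 810)
  expect_true(de$valid)
  expect_lt(abs(de$generations - 20), 2.5 * de$std_error)
  expect_equal(de$years, de$generations * 28)
})
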
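# exact-frequency substrate: 5 SNPs, 5 populations, denominators of 10
freq5 <- function() {
  f <- cbind(A = c(0.1, 0.5, 0.9, 0.3, 0.6),
             B = c(0.2, 0.4, 0.8, 0.3, 0.1),
             C = c(0.7, 0.2, 0.5, 0.9, 0.4),
             D = c(0.3, 0.6, 0.1, 0.5, 0.8),
             E = c(0.5, 0.5, 0.5, 0.2, 0.7))
  list(freq = f, gen = freq_pops_gen(f))
}

test_that("f4 equals the hand-computed mean of per-SNP products", {
  fx <- freq5()
  bl <- rep(1:5, length.out = 5)  # one block per SNP
  r <- f4(fx$gen, "A", "B", "C", "D", blocks = bl)
  oracle <- mean((fx$freq[, "A"] - fx$freq[, "B"]) *
                 (fx$freq[, "C"] - fx$freq[, "D"]))
  expect_equal(r$estimate, oracle, tolerance = 1e-12)
  expect_equal(r$n_snps, 5L)
})

test_that("f4 is antisymmetric and vanishes for duplicated right pairs", {
  fx <- freq5()
  bl <- rep(1:5, length.out = 5)
  base <- f4(fx$gen, "A", "B", "C", "D", blocks = bl)$estimate
  expect_equal(f4(fx$gen, "B", "A", "C", "D", blocks = bl)$estimate, -base)
  expect_equal(f4(fx$gen, "A", "B", "D", "C", blocks = bl)$estimate, -base)
  zero <- f4(fx$gen, "A", "B", "C", "C", blocks = bl)
  expect_equal(zero$estimate, 0)
  expect_equal(zero$std_error, 0)
})

test_that("f4 is additive across the fourth slot on identical SNP sets", {
  fx <- freq5()
  bl <- rep(1:5, length.out = 5)
  abcd <- f4(fx$gen, "A", "B", "C", "D", blocks = bl)$estimate
  abde <- f4(fx$gen, "A", "B", "D", "E", blocks = bl)$estimate
  abce <- f4(fx$gen, "A", "B", "C", "E", blocks = bl)$estimate
  expect_equal(abcd + abde, abce, tolerance = 1e-12)
})

test_that("f4 is invariant to a global ref/alt allele flip", {
  fx <- freq5()
  bl <- rep(1:5, length.out = 5)
  flipped <- fx$gen
  flipped$geno <- 2L - flipped$geno
  expect_equal(f4(flipped, "A", "B", "C", "D", blocks = bl)$estimate,
               f4(fx$gen, "A", "B", "C", "D", blocks = bl)$estimate)
})

test_that("f-statistics are invariant to individual ordering", {
  st <- demo_study()
  x <- st$data
  y <- gen_subset(x, individuals = sample(nrow(x$geno)))
  bl <- make_blocks(x)
  expect_equal(f4(y, "Source1", "Out3", "Source2", "Out4")$estimate,
               f4(x, "Source1", "Out3", "Source2", "Out4")$estimate)
})

test_that("admixture f3 geometry: midway target negative, identical refs non-negative", {
  set.seed(4)
  p1 <- runif(400, 0.1, 0.9)
  p2 <- runif(400, 0.1, 0.9)
  f <- cbind(R1 = p1, R2 = p2, T = (p1 + p2) / 2)
  # many individuals so the sampling-variance correction is small
  x <- freq_pops_gen(round(f * 50) / 50, n_per_pop = 50)
  bl <- make_blocks(x, 0.5)
  mid <- f3_admixture_test(x, "T", "R1", "R2", blocks = bl)
  expect_lt(mid$estimate, 0)
  same <- f3_admixture_test(x, "T", "R1", "R1", blocks = bl)
  expect_gte(same$estimate, 0)
  expect_error(
    f3_admixture_test(gen_subset(x, individuals = c(1:50, 101)), "T", "R1", "R1"),
    "at least 2")
})

test_that("a synthetic two-source cohort shows f3 admixture evidence beyond -7.5", {
  st <- demo_study()
  r <- f3_admixture_test(st$data, "Target", "Source1", "Source2")
  expect_lt(r$z, -7.5)
})

test_that("leave-one-out f4 scan flags a planted ancestry outlier, and only it", {
  cfg <- sim_config(seed = 21, n_snps_per_chromosome = 1000, n_chromosomes = 16,
                    n_target_individuals = 30, ancestry_sd = 0, missing_rate = 0.1)
  src <- simulate_source_frequencies(cfg)
  st <- simulate_admixed_cohort(cfg, src)
  cfg2 <- sim_config(seed = 22, n_snps_per_chromosome = 1000, n_chromosomes = 16,
                     n_target_individuals = 4, ancestry_mean = 0.725,
                     ancestry_sd = 0, missing_rate = 0.1)
  st2 <- simulate_admixed_cohort(cfg2, src)
  x <- st$data
  x$geno[3, ] <- st2$data$geno[1, ]
  scan <- f4_outlier_scan(x, "Source1", "Source2", "Target")
  expect_true(scan$outlier[3])
  # documented orientation: positive z = excess West-Eurasian-related ancestry
  expect_gt(scan$z[3], 0)
  expect_equal(sum(scan$outlier), 1L)
  # an individual with no callable genotypes is unscorable, not flagged
  x$geno[5, ] <- NA_integer_
  scan2 <- f4_outlier_scan(x, "Source1", "Source2", "Target")
  expect_true(scan2$unscorable[5])
  expect_false(scan2$outlier[5])
})

test_that("clade f4 scan accepts random splits and rejects shifted splits", {
  st <- demo_study()
  x <- st$data
  tgt <- which(x$ind$group == "Target")
  expect_equal(clade_f4_scan(x, "Source1", c("Source2", "Out2"),
                             tgt[1:15], tgt[1:15])$table$estimate, c(0, 0))
  set.seed(7)
  h <- sample(tgt, 15)
  sc <- clade_f4_scan(x, "Source1", c("Source2", "Out2"), h, setdiff(tgt, h))
  expect_true(sc$consistent_with_clade)
  # theta shifted by ~15 points: splice a shifted cohort as groupB
  cfg2 <- sim_config(seed = 23, n_snps_per_chromosome = 700, n_chromosomes = 12,
                     n_target_individuals = 15, ancestry_mean = 0.725,
                     ancestry_sd = 0.02, missing_rate = 0.1,
                     n_reference_individuals = 2)
  st2 <- simulate_admixed_cohort(cfg2, simulate_source_frequencies(
    sim_config(seed = 42, n_snps_per_chromosome = 700, n_chromosomes = 12)))
  y <- x
  y$geno[tgt[16:30], ] <- st2$data$geno[1:15, ]
  sc2 <- clade_f4_scan(y, "Source1", c("Source2", "Out2"),
                       tgt[1:15], tgt[16:30])
  expect_false(sc2$consistent_with_clade)
})

test_that("Hudson FST recovers nominal divergence and is monotone in it", {
  ests <- sapply(c(0.004, 0.04, 0.15), function(fst) {
    cfg <- sim_config(seed = 31, n_snps_per_chromosome = 2500, n_chromosomes = 8,
                      n_target_individuals = 2, n_reference_individuals = 25,
                      fst_source_divergence = fst, missing_rate = 0)
    st <- simulate_study(cfg)
    r <- fst_hudson(st$data, "Source1", "Source2")
    expect_lt(abs(r$estimate - fst), 2 * r$std_error + 0.2 * fst)
    r$estimate
  })
  expect_true(all(diff(ests) > 0))
})

test_that("FST between two samples of one population is near zero", {
  st <- demo_study()
  x <- st$data
  tgt <- which(x$ind$group == "Target")
  set.seed(8)
  h <- sample(tgt, 15)
  r <- fst_hudson(x, h, setdiff(tgt, h))
  expect_lt(abs(r$estimate), 2 * r$std_error + 1e-3)
  expect_error(fst_hudson(x, tgt[1], tgt[-1]), "at least 2")
})

test_that("jackknife SE tracks the empirical SD across replicates", {
  # 60 replicate datasets of drifted populations; f4 SE vs spread
  ests <- ses <- numeric(60)
  for (i in seq_len(60)) {
    cfg <- sim_config(seed = 1000 + i, n_snps_per_chromosome = 300,
                      n_chromosomes = 8, n_target_individuals = 2,
                      n_reference_individuals = 12, missing_rate = 0)
    st <- simulate_study(cfg)
    r <- f4(st$data, "Source1", "Out3", "Source2", "Out4")
    ests[i] <- r$estimate; ses[i] <- r$std_error
  }
  ratio <- mean(ses) / sd(ests)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})
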
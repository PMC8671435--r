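test_that("source frequencies stay in range and realize the nominal FST", {
  cfg <- sim_config(seed = 81, n_snps_per_chromosome = 2500, n_chromosomes = 20,
                    fst_source_divergence = 0.1)
  src <- simulate_source_frequencies(cfg)
  expect_true(all(src$freq >= 0 & src$freq <= 1))
  # Hudson FST on the frequencies themselves (ratio of averages)
  p1 <- src$freq[, "Source1"]; p2 <- src$freq[, "Source2"]
  fst <- sum((p1 - p2)^2 - 0) / sum(p1 * (1 - p2) + p2 * (1 - p1))
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("the no-drift limit collapses all populations onto the ancestral frequency", {
  p <- c(0.2, 0.5, 0.9)
  expect_identical(paleostrat:::bn_draw(p, 0), p)
})

test_that("SNP maps are valid: ordered positions, 22+X chromosomes", {
  src <- simulate_source_frequencies(sim_config(seed = 82, n_snps_per_chromosome = 100))
  expect_setequal(unique(src$snp$chromosome), c(as.character(1:22), "23"))
  for (ch in unique(src$snp$chromosome)) {
    g <- src$snp$genetic_position[src$snp$chromosome == ch]
    expect_true(all(diff(g) >= 0))
    p <- src$snp$physical_position[src$snp$chromosome == ch]
    expect_true(all(diff(p) > 0))
  }
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 83, n_snps_per_chromosome = 150, n_chromosomes = 4,
                    n_target_individuals = 8, n_reference_individuals = 3,
                    relative_plan = list(list(degree = 2, cemeteries = c("R", "S"))))
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$data$geno, b$data$geno)
  expect_identical(a$truth, b$truth)
  d1 <- file.path(withr::local_tempdir(), "w1")
  d2 <- file.path(withr::local_tempdir(), "w2")
  write_study(a, d1); write_study(b, d2)
  for (ext in c(".geno", ".snp", ".ind", ".meta.tsv", ".truth.json")) {
    expect_identical(readLines(paste0(d1, ext)), readLines(paste0(d2, ext)))
  }
})

test_that("realized cohort ancestry matches the configured distribution", {
  st <- demo_study()   # 30 individuals at mean 0.575, sd 0.045
  tr <- st$truth
  se <- sd(tr$realized_autosomal_we) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$realized_autosomal_we) - 0.575), 2.5 * se)
  # truth identity: F + M = 2 * autosomal proportion
  expect_equal(tr$F_component + tr$M_component, 2 * tr$theta_autosomal,
               tolerance = 1e-12)
  # sex-biased default: X ancestry expectation above autosomal
  expect_gt(mean(tr$theta_x), mean(tr$theta_autosomal))
})

test_that("a symmetric female fraction equalizes X and autosomal ancestry", {
  cfg <- sim_config(seed = 84, n_snps_per_chromosome = 200, n_chromosomes = 6,
                    n_target_individuals = 20, female_fraction_WE = 0.5,
                    n_reference_individuals = 2)
  st <- simulate_study(cfg)
  expect_equal(st$truth$theta_x, st$truth$theta_autosomal, tolerance = 1e-12)
})

test_that("ancestry tract lengths follow the Markov expectation", {
  # direct tract-length measurement from the haplotype simulator
  set.seed(85)
  theta <- 0.6; g <- 20; L <- 3
  gpos <- seq(0, L, by = 1e-4)
  freq2 <- cbind(rep(0.5, length(gpos)), rep(0.5, length(gpos)))
  lens <- unlist(lapply(1:60, function(i) {
    h <- paleostrat:::sim_haplotype(gpos, L, theta, g, freq2)
    r <- rle(h$anc)
    # interior WE tracts only (edge tracts are censored)
    keep <- r$values == 1L
    if (length(r$lengths) > 2) keep[c(1, length(keep))] <- FALSE
    r$lengths[keep] * 1e-4
  }))
  expected <- 1 / (g * (1 - theta))
  expect_lt(abs(mean(lens) - expected) / expected, 0.15)
})

test_that("diploid no-missingness genotypes recover per-individual ancestry", {
  cfg <- sim_config(seed = 86, n_snps_per_chromosome = 800, n_chromosomes = 10,
                    n_target_individuals = 15, missing_rate = 0,
                    output_ploidy = "diploid", n_reference_individuals = 2)
  st <- simulate_study(cfg)
  src <- simulate_source_frequencies(cfg)
  auto <- st$data$snp$chromosome != "23"
  w <- (src$freq[auto, "Source2"] - src$freq[auto, "Source1"])
  tgt <- which(st$data$ind$group == "Target")
  est <- sapply(tgt, function(i) {
    gi <- st$data$geno[i, auto] / 2
    sum(w * (gi - src$freq[auto, "Source1"])) / sum(w^2)
  })
  expect_gt(cor(est, st$truth$realized_autosomal_we), 0.9)
  expect_lt(mean(abs(est - st$truth$realized_autosomal_we)), 0.03)
})

test_that("planted first-degree pairs beat every unrelated pair on mismatch", {
  plan <- list(list(degree = 1, cemeteries = c("S", "S")))
  cfg <- sim_config(seed = 87, n_snps_per_chromosome = 1200, n_chromosomes = 10,
                    n_target_individuals = 12, n_reference_individuals = 2,
                    missing_rate = 0.1, relative_plan = plan)
  st <- simulate_study(cfg)
  pm <- pairwise_mismatch(st$data, individuals = which(st$data$ind$group == "Target"),
                          min_overlap = 1000)
  key <- paste(pm$id1, pm$id2)
  expect_lt(pm$p0[key == "T001 T002"], min(pm$p0[key != "T001 T002"]))
})

test_that("the config guards its invariants", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_target_individuals = 4,
                          relative_plan = rep(list(list(degree = 1,
                                                        cemeteries = c("R", "S"))), 3)),
               "relative_plan")
  expect_error(sim_config(seed = 1, missing_rate = 1.2))
})
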
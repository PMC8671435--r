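# Shared fixtures, built in code at test time.

# tiny hand-assembled dataset: explicit genotypes, one chromosome
tiny_gen <- function(geno, chromosome = "1", ploidy = "pseudohaploid",
                     groups = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); S <- ncol(geno)
  snp <- tibble::tibble(snp_id = paste0("s", seq_len(S)),
                        chromosome = chromosome,
                        genetic_position = seq(0, by = 0.01, length.out = S),
                        physical_position = seq_len(S) * 1000L,
                        ref_allele = "A", alt_allele = "G")
  ind <- tibble::tibble(individual_id = paste0("i", seq_len(n)),
                        sex = "unknown",
                        group = groups %||% rep("pop", n))
  gen_dataset(geno, snp, ind, ploidy = ploidy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a dataset of "frequency populations": each population is a set of
# pseudo-haploid individuals engineered so its sample frequency at SNP s is
# exactly freq_mat[s, pop] (denominators = n_per_pop). Used as an exact
# oracle substrate for f-statistics.
freq_pops_gen <- function(freq_mat, n_per_pop = 10) {
  S <- nrow(freq_mat); P <- ncol(freq_mat)
  geno <- matrix(0L, n_per_pop * P, S)
  for (j in seq_len(P)) {
    counts <- round(freq_mat[, j] * n_per_pop)
    for (s in seq_len(S)) {
      rows <- (j - 1) * n_per_pop + seq_len(n_per_pop)
      geno[rows[seq_len(counts[s])], s] <- 2L
    }
  }
  tiny_gen(geno, groups = rep(colnames(freq_mat), each = n_per_pop))
}

# pair list reproducing the published cross-cemetery counts:
# degree 1: 1 within-R + 3 within-S pairs (2 R, 6 S individuals)
# degree 2: 2 within-R + 5 within-S + 2 cross (6 R, 11 S)
# degree 3: 1 within-R + 8 within-S + 4 cross (4 R, 17 S)
study_pairs <- function() {
  p <- function(a, b, d) tibble::tibble(id1 = a, id2 = b, degree_class = d)
  dplyr::bind_rows(
    p("R1", "R2", "1"), p("S1", "S2", "1"), p("S3", "S4", "1"), p("S5", "S6", "1"),
    p("R3", "R4", "2"), p("R5", "R6", "2"),
    p("S1", "S7", "2"), p("S8", "S9", "2"), p("S10", "S11", "2"),
    p("S12", "S13", "2"), p("S14", "S15", "2"),
    p("R7", "S16", "2"), p("R8", "S8", "2"),
    p("R9", "R10", "3"),
    p("S17", "S18", "3"), p("S19", "S20", "3"), p("S21", "S22", "3"),
    p("S1", "S2", "3"), p("S3", "S4", "3"), p("S5", "S6", "3"),
    p("S7", "S8", "3"), p("S9", "S10", "3"),
    p("R9", "S1", "3"), p("R10", "S3", "3"), p("R1", "S5", "3"), p("R3", "S11", "3"))
}

study_cemeteries <- function() {
  ids <- c(paste0("R", 1:10), paste0("S", 1:22))
  stats::setNames(substr(ids, 1, 1), ids)
}

# one shared small simulated study, cached across test files
.study_cache <- new.env(parent = emptyenv())
demo_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- sim_config(seed = 42, n_snps_per_chromosome = 700,
                      n_chromosomes = 12, n_target_individuals = 30,
                      missing_rate = 0.1, n_reference_individuals = 20)
    .study_cache$study <- simulate_study(cfg)
  }
  .study_cache$study
}
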
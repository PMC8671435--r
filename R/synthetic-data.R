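#' Configuration for the synthetic admixed-cohort generator
#'
#' Defines the study conditions the generator emulates: two
#' allele-frequency-diverged source populations (a Nilotic-like and a
#' West-Eurasian-like proxy) plus differentially related outgroups, an
#' admixed target cohort with per-individual ancestry variation, sex-biased
#' ancestry contributions (X-chromosome expectation `(2F+M)/3` against the
#' autosomal `(F+M)/2`), dated ancestry-tract mosaics, planted relative
#' pairs split across two cemetery labels, and pseudo-haploid sampling with
#' per-site missingness.
#'
#' Defaults mirror the cohort the package's analyses were designed around:
#' 60 admixed individuals averaging 57.5% West-Eurasian-related ancestry
#' (s.d. 4.5%, giving roughly the 46--64% individual range), 68% of that
#' ancestry from female ancestors, admixture 22 generations before
#' sampling, and cemetery labels split 27/33 between "R" and "S".
#'
#' @param seed integer; mandatory, governs all randomness.
#' @param n_snps_per_chromosome SNPs per autosome (X gets proportionally
#'   more by length).
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length autosome genetic length in Morgans; the X uses
#'   `x_length`.
#' @param x_length X-chromosome genetic length in Morgans.
#' @param fst_source_divergence nominal Hudson FST between the two sources.
#' @param n_target_individuals admixed cohort size (planted relatives count
#'   toward it).
#' @param ancestry_mean,ancestry_sd per-individual West-Eurasian-like
#'   autosomal ancestry proportion distribution (truncated normal).
#' @param female_fraction_WE fraction F/(F+M) of West-Eurasian-like
#'   ancestry contributed by female ancestors.
#' @param admixture_generations generations since admixture (scalar, or
#'   length-`n_target_individuals` vector).
#' @param missing_rate per-call Bernoulli missingness.
#' @param relative_plan list of planted pairs, each
#'   `list(degree = 1|2|3, cemeteries = c("R","S"))`.
#' @param cemetery_split named counts `c(R = ..., S = ...)` summing to
#'   `n_target_individuals`.
#' @param n_reference_individuals individuals simulated per source/outgroup
#'   population.
#' @param output_ploidy `"pseudohaploid"` (default) or `"diploid"` for the
#'   emitted genotypes.
#' @return a `paleo_sim_config` list
#' @export
sim_config <- function(seed,
                       n_snps_per_chromosome = 500,
                       n_chromosomes = 22,
                       chromosome_length = 1.5,
                       x_length = 1.8,
                       fst_source_divergence = 0.15,
                       n_target_individuals = 60,
                       ancestry_mean = 0.575,
                       ancestry_sd = 0.045,
                       female_fraction_WE = 0.68,
                       admixture_generations = 22,
                       missing_rate = 0.2,
                       relative_plan = list(),
                       cemetery_split = NULL,
                       n_reference_individuals = 25,
                       output_ploidy = c("pseudohaploid", "diploid")) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  output_ploidy <- match.arg(output_ploidy)
  if (is.null(cemetery_split)) {
    nR <- round(n_target_individuals * 27 / 60)
    cemetery_split <- c(R = nR, S = n_target_individuals - nR)
  }
  stopifnot(fst_source_divergence > 0, fst_source_divergence < 1,
            ancestry_mean > 0, ancestry_mean < 1,
            female_fraction_WE > 0, female_fraction_WE < 1,
            missing_rate >= 0, missing_rate < 1,
            all(admixture_generations > 0),
            sum(cemetery_split) == n_target_individuals)
  if (2 * length(relative_plan) > n_target_individuals) {
    stop("relative_plan requests more individuals than n_target_individuals",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_snps_per_chromosome = n_snps_per_chromosome,
                 n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length,
                 x_length = x_length,
                 fst_source_divergence = fst_source_divergence,
                 n_target_individuals = n_target_individuals,
                 ancestry_mean = ancestry_mean, ancestry_sd = ancestry_sd,
                 female_fraction_WE = female_fraction_WE,
                 admixture_generations = admixture_generations,
                 missing_rate = missing_rate,
                 relative_plan = relative_plan,
                 cemetery_split = cemetery_split,
                 n_reference_individuals = n_reference_individuals,
                 output_ploidy = output_ploidy),
            class = "paleo_sim_config")
}

# Balding-Nichols draw: frequency with mean p and variance F*p*(1-p)
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

#' Simulate source and outgroup allele frequencies
#'
#' Frequencies follow a Balding--Nichols drift model on a small fixed
#' population tree: an ancestral frequency (uniform on 0.05--0.95) drifts
#' into a "Nilotic-like" branch and a "West-Eurasian-like" branch, each
#' carrying one source (`Source1`, `Source2`) and one outgroup (`Out1`,
#' `Out2`); two further outgroups (`Out3`, `Out4`) drift directly from the
#' root. Per-branch drift is calibrated so the nominal Hudson FST between
#' `Source1` and `Source2` equals `fst_source_divergence`. The branch-shared
#' outgroups make the reference set differentially related to the two
#' sources, which is what qpAdm-style fitting requires.
#'
#' @param config a [sim_config()]
#' @return list with `snp` (SNP map tibble, autosomes then X as "23") and
#'   `freq` (SNPs x populations frequency matrix)
#' @export
simulate_source_frequencies <- function(config) {
  stopifnot(inherits(config, "paleo_sim_config"))
  set.seed(config$seed)
  n_x <- round(config$n_snps_per_chromosome * config$x_length / config$chromosome_length)
  counts <- c(rep(config$n_snps_per_chromosome, config$n_chromosomes), n_x)
  lens <- c(rep(config$chromosome_length, config$n_chromosomes), config$x_length)
  chroms <- c(as.character(seq_len(config$n_chromosomes)), "23")
  snp <- purrr::map_dfr(seq_along(chroms), function(i) {
    gpos <- sort(stats::runif(counts[i], 0, lens[i]))
    tibble::tibble(snp_id = sprintf("snp_%s_%d", chroms[i], seq_len(counts[i])),
                   chromosome = chroms[i],
                   genetic_position = gpos,
                   physical_position = as.integer(round(gpos * 1e8)) + seq_len(counts[i]),
                   ref_allele = "A", alt_allele = "G")
  })
  S <- nrow(snp)
  f_branch <- 1 - sqrt(1 - config$fst_source_divergence)
  anc <- stats::runif(S, 0.05, 0.95)
  branchN <- bn_draw(anc, f_branch)
  branchW <- bn_draw(anc, f_branch)
  freq <- cbind(Source1 = bn_draw(branchN, f_branch),
                Source2 = bn_draw(branchW, f_branch),
                Out1 = bn_draw(branchN, f_branch),
                Out2 = bn_draw(branchW, f_branch),
                Out3 = bn_draw(anc, f_branch),
                Out4 = bn_draw(anc, f_branch))
  list(snp = snp, freq = freq)
}

# One ancestry-mosaic haplotype along one chromosome.
# Two-state Markov process: WE<->Nilotic switches at total rate g per
# Morgan scaled by the opposite state's stationary mass, giving stationary
# P(WE) = theta and mean WE tract length 1/(g*(1-theta)).
# Returns list(anc = 0/1 WE indicator at SNPs, allele = 0/1 alt allele).
sim_haplotype <- function(gpos, L, theta, g, freq2) {
  state0 <- stats::rbinom(1, 1, theta)
  r_out_we <- g * (1 - theta)
  r_out_n <- g * theta
  # states alternate, so gap rates alternate deterministically after the start
  first <- if (state0 == 1L) r_out_we else r_out_n
  second <- if (state0 == 1L) r_out_n else r_out_we
  brk <- numeric(0)
  offset <- 0
  repeat {
    m <- max(16L, 2L * ceiling(g * L))
    rates <- rep_len(c(first, second), m)
    if (length(brk) %% 2L == 1L) rates <- rep_len(c(second, first), m)
    gaps <- stats::rexp(m) / rates
    new <- offset + cumsum(gaps)
    brk <- c(brk, new[new < L])
    if (new[m] >= L) break
    offset <- new[m]
  }
  seg <- findInterval(gpos, brk)
  anc <- (state0 + seg) %% 2L   # state alternates at each breakpoint
  p <- freq2[seq_along(gpos) + anc * nrow(freq2)]  # column-major 2-col lookup
  allele <- stats::rbinom(length(gpos), 1, p)
  list(anc = as.integer(anc), allele = as.integer(allele))
}

# Meiosis: recombine a parent's two chromosome haplotypes (Poisson(L)
# crossovers, uniform positions) into one transmitted haplotype.
meiose <- function(h1, h2, gpos, L) {
  k <- stats::rpois(1, L)
  xo <- sort(stats::runif(k, 0, L))
  phase <- (stats::rbinom(1, 1, 0.5) + findInterval(gpos, xo)) %% 2L
  anc <- h1$anc; allele <- h1$allele
  from2 <- phase == 1L
  anc[from2] <- h2$anc[from2]
  allele[from2] <- h2$allele[from2]
  list(anc = anc, allele = allele)
}

# Build a full autosomal diploid genome as per-chromosome haplotype pairs.
# theta_f/theta_m: WE proportion of the maternally/paternally derived
# haplotype. Returns list over chromosomes of list(h1, h2).
sim_autosomes <- function(chrom_split, L, theta_f, theta_m, g, freqs) {
  lapply(seq_along(chrom_split), function(ci) {
    gpos <- chrom_split[[ci]]$gpos
    f2 <- chrom_split[[ci]]$freq2
    list(h1 = sim_haplotype(gpos, L, theta_f, g, f2),
         h2 = sim_haplotype(gpos, L, theta_m, g, f2))
  })
}

#' Simulate the admixed cohort, references and truth sidecar
#'
#' Generates the full synthetic study: an admixed target cohort whose
#' chromosomes are Markov ancestry-tract mosaics (switch rate =
#' generations-since-admixture per Morgan; stationary distribution = the
#' individual's ancestry proportion), X chromosomes drawn at the sex-biased
#' expectation `(2F+M)/3`, planted relatives produced by gene-dropping
#' (recombining meioses chained once per degree), pseudo-haploid sampling,
#' missingness, cemetery labels, plus simulated individuals for the two
#' source populations and four outgroups. Group labels: `Target`,
#' `Source1` (Nilotic-like), `Source2` (West-Eurasian-like), `Out1`..`Out4`.
#'
#' @param config a [sim_config()]
#' @param src output of [simulate_source_frequencies()] (regenerated if
#'   omitted)
#' @return list with `data` (a `paleo_gen`) and `truth` (per-individual
#'   tibble: configured and realized autosomal/X West-Eurasian ancestry,
#'   female- and male-derived components F and M, generations, pedigree
#'   links, cemetery)
#' @export
simulate_admixed_cohort <- function(config, src = simulate_source_frequencies(config)) {
  stopifnot(inherits(config, "paleo_sim_config"))
  set.seed(config$seed + 1L)
  snp <- src$snp
  n <- config$n_target_individuals
  P <- config$female_fraction_WE
  g_vec <- rep(config$admixture_generations, length.out = n)

  auto_idx <- which(snp$chromosome != "23")
  x_idx <- which(snp$chromosome == "23")
  chroms <- unique(snp$chromosome[auto_idx])
  chrom_split <- lapply(chroms, function(ch) {
    i <- which(snp$chromosome == ch)
    list(idx = i, gpos = snp$genetic_position[i],
         freq2 = src$freq[i, c("Source1", "Source2")])
  })
  x_split <- list(idx = x_idx, gpos = snp$genetic_position[x_idx],
                  freq2 = src$freq[x_idx, c("Source1", "Source2"), drop = FALSE])
  L <- config$chromosome_length

  theta <- pmin(0.95, pmax(0.05,
    stats::rnorm(n, config$ancestry_mean, config$ancestry_sd)))
  Fc <- pmin(1, pmax(0, 2 * theta * P))
  Mc <- pmax(0, pmin(1, 2 * theta - Fc))
  sex <- rep(c("female", "male"), length.out = n)
  theta_x <- (2 * Fc + Mc) / 3

  # pedigree bookkeeping for planted relatives
  relative_of <- rep(NA_character_, n)
  degree <- rep(NA_integer_, n)
  pair_slots <- if (length(config$relative_plan)) {
    matrix(seq_len(2 * length(config$relative_plan)), ncol = 2, byrow = TRUE)
  } else matrix(integer(0), ncol = 2)

  genomes <- vector("list", n)          # autosomal haplotype pairs
  x_haps <- vector("list", n)           # list of 1 or 2 X haplotypes
  for (i in seq_len(n)) {
    genomes[[i]] <- sim_autosomes(chrom_split, L, Fc[i], Mc[i], g_vec[i], src$freq)
    nx <- if (sex[i] == "male") 1 else 2
    x_haps[[i]] <- lapply(seq_len(nx), function(k)
      sim_haplotype(x_split$gpos, config$x_length, theta_x[i], g_vec[i], x_split$freq2))
  }

  # overwrite the second member of each planted pair with a gene-dropped
  # relative of the first (autosomes; X stays an independent mosaic)
  for (r in seq_along(config$relative_plan)) {
    plan <- config$relative_plan[[r]]
    i1 <- pair_slots[r, 1]; i2 <- pair_slots[r, 2]
    deg <- plan$degree
    stopifnot(deg %in% 1:3)
    lineage <- genomes[[i1]]
    for (m in seq_len(deg)) {
      mate_theta <- pmin(0.95, pmax(0.05,
        stats::rnorm(1, config$ancestry_mean, config$ancestry_sd)))
      mateF <- pmin(1, 2 * mate_theta * P); mateM <- pmax(0, 2 * mate_theta - mateF)
      mate <- sim_autosomes(chrom_split, L, mateF, mateM, g_vec[i2], src$freq)
      lineage <- lapply(seq_along(chrom_split), function(ci) {
        gp <- chrom_split[[ci]]$gpos
        list(h1 = meiose(lineage[[ci]]$h1, lineage[[ci]]$h2, gp, L),
             h2 = meiose(mate[[ci]]$h1, mate[[ci]]$h2, gp, L))
      })
    }
    genomes[[i2]] <- lineage
    relative_of[i2] <- sprintf("T%03d", i1)
    degree[i2] <- deg
  }

  # assemble genotype matrix for the target cohort
  S <- nrow(snp)
  geno <- matrix(NA_integer_, n, S)
  real_auto <- real_x <- numeric(n)
  for (i in seq_len(n)) {
    dip <- integer(length(auto_idx))
    anc_share <- 0
    off <- 0
    for (ci in seq_along(chrom_split)) {
      idx <- chrom_split[[ci]]$idx
      h <- genomes[[i]][[ci]]
      geno[i, idx] <- h$h1$allele + h$h2$allele
      anc_share <- anc_share + sum(h$h1$anc) + sum(h$h2$anc)
    }
    real_auto[i] <- anc_share / (2 * length(auto_idx))
    xa <- sapply(x_haps[[i]], function(h) h$allele)
    xanc <- sapply(x_haps[[i]], function(h) h$anc)
    if (sex[i] == "male") {
      geno[i, x_idx] <- 2L * as.integer(xa)    # haploid call, never 1
      real_x[i] <- mean(xanc)
    } else {
      geno[i, x_idx] <- as.integer(rowSums(xa))
      real_x[i] <- mean(xanc)
    }
  }

  if (config$output_ploidy == "pseudohaploid") {
    # sample one allele slot per call (males already haploid on X)
    half <- which(geno == 1L)
    geno[half] <- 2L * (stats::runif(length(half)) < 0.5)
  }

  # reference populations: iid draws from their frequencies
  ref_pops <- colnames(src$freq)
  nr <- config$n_reference_individuals
  ref_geno <- matrix(NA_integer_, nr * length(ref_pops), S)
  for (j in seq_along(ref_pops)) {
    p <- src$freq[, j]
    rows <- (j - 1) * nr + seq_len(nr)
    if (config$output_ploidy == "pseudohaploid") {
      ref_geno[rows, ] <- 2L * matrix(stats::rbinom(nr * S, 1, rep(p, each = nr)), nr, S)
    } else {
      ref_geno[rows, ] <- matrix(stats::rbinom(nr * S, 2, rep(p, each = nr)), nr, S)
    }
  }

  geno_all <- rbind(geno, ref_geno)
  if (config$missing_rate > 0) {
    drop <- which(stats::runif(length(geno_all)) < config$missing_rate)
    geno_all[drop] <- NA_integer_
  }

  # cemetery labels: planted pairs get theirs from the plan, the rest fill
  # the configured split at random (independent of genotype)
  cemetery <- rep(NA_character_, n)
  for (r in seq_along(config$relative_plan)) {
    cem <- config$relative_plan[[r]]$cemeteries
    cemetery[pair_slots[r, ]] <- cem
  }
  remaining <- table(factor(cemetery, levels = c("R", "S")))
  fill <- c(rep("R", max(0, config$cemetery_split[["R"]] - remaining[["R"]])),
            rep("S", max(0, config$cemetery_split[["S"]] - remaining[["S"]])))
  n_missing <- sum(is.na(cemetery))
  if (length(fill) < n_missing) fill <- c(fill, rep("S", n_missing - length(fill)))
  cemetery[is.na(cemetery)] <- sample(fill)[seq_len(n_missing)]

  ids <- sprintf("T%03d", seq_len(n))
  ind <- tibble::tibble(
    individual_id = c(ids, sprintf("%s_%02d", rep(ref_pops, each = nr),
                                   rep(seq_len(nr), length(ref_pops)))),
    sex = c(sex, rep("unknown", nr * length(ref_pops))),
    group = c(rep("Target", n), rep(ref_pops, each = nr)),
    cemetery = c(cemetery, rep(NA_character_, nr * length(ref_pops))),
    date_midpoint_ce = NA_real_, exclude = FALSE)

  data <- gen_dataset(geno_all, snp, ind, ploidy = config$output_ploidy)
  truth <- tibble::tibble(
    individual_id = ids, sex = sex, cemetery = cemetery,
    theta_autosomal = theta, realized_autosomal_we = real_auto,
    theta_x = theta_x, realized_x_we = real_x,
    F_component = Fc, M_component = Mc,
    generations = g_vec, relative_of = relative_of, degree = degree)
  list(data = data, truth = truth)
}

#' One-call synthetic study generator
#'
#' @param config a [sim_config()]
#' @return list `data`, `truth`, `freq` (source frequencies), `config`
#' @export
simulate_study <- function(config) {
  src <- simulate_source_frequencies(config)
  out <- simulate_admixed_cohort(config, src)
  c(out, list(freq = src, config = config))
}

#' Write a simulated study to disk
#'
#' Emits the EIGENSTRAT triple plus metadata sidecar via
#' [write_eigenstrat()] and a JSON truth sidecar.
#'
#' @param study output of [simulate_study()]
#' @param prefix output path prefix
#' @return invisibly, the paths written
#' @export
write_study <- function(study, prefix) {
  paths <- write_eigenstrat(study$data, prefix)
  truth_path <- paste0(prefix, ".truth.json")
  jsonlite::write_json(study$truth, truth_path, digits = NA, na = "null")
  invisible(c(paths, truth_path))
}
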
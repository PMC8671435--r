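#' f-statistics with block-jackknife errors
#'
#' Allele-frequency covariance statistics for admixture inference on
#' (pseudo-haploid) genotype data. Per-SNP terms are averaged as a
#' ratio-of-sums across jackknife blocks; only SNPs where every involved
#' population has at least one called allele slot contribute
#' (complete-cases per statistic). Standard errors come from the weighted
#' delete-one block jackknife, blocks weighted by usable SNP count.
#'
#' Orientation conventions (asserted by the test suite):
#' * `f4(A,B;C,D)` estimates `E[(pA-pB)(pC-pD)]`; it is antisymmetric in
#'   (A,B) and in (C,D) and invariant to a joint ref/alt allele flip.
#' * a *negative* admixture `f3(target; ref1, ref2)` is evidence that the
#'   target is admixed between populations related to the two references.
#'
#' @param x a `paleo_gen`
#' @param A,B,C,D group labels (each may be a vector of labels pooled
#'   together)
#' @param blocks integer block ids per SNP from [make_blocks()]; default 5 cM
#'   blocks
#' @return a one-row tibble: `stat`, `pops`, `estimate`, `std_error`,
#'   `z`, `n_snps`, `n_blocks`
#' @name fstats
NULL

# shared worker: per-SNP numerator terms -> jackknifed result row
fstat_result <- function(stat, pops, term, usable, blocks) {
  if (!any(usable)) stop("no usable SNPs for ", stat, "(", pops, ")", call. = FALSE)
  num <- ifelse(usable, term, 0)
  den <- as.numeric(usable)
  jk <- ratio_jackknife(num, den, blocks)
  tibble::tibble(stat = stat, pops = pops,
                 estimate = jk$estimate, std_error = jk$std_error,
                 z = ifelse(jk$std_error > 0, jk$estimate / jk$std_error, 0),
                 n_snps = as.integer(sum(usable)), n_blocks = jk$n_blocks)
}

pops_idx <- function(x, ...) {
  labs <- list(...)
  lapply(labs, function(l) if (is.numeric(l)) as.integer(l) else group_members(x, l))
}

#' @rdname fstats
#' @export
f4 <- function(x, A, B, C, D, blocks = make_blocks(x)) {
  idx <- pops_idx(x, A = A, B = B, C = C, D = D)
  pf <- pop_freq_matrix(x, idx)
  p <- pf$freq
  usable <- rowSums(pf$slots > 0) == 4
  term <- (p[, 1] - p[, 2]) * (p[, 3] - p[, 4])
  fstat_result("f4", paste(sapply(list(A, B, C, D), paste, collapse = "+"),
                           collapse = ","), term, usable, blocks)
}

#' f2 distance between two populations (bias-corrected)
#' @rdname fstats
#' @export
f2 <- function(x, A, B, blocks = make_blocks(x)) {
  idx <- pops_idx(x, A = A, B = B)
  pf <- pop_freq_matrix(x, idx)
  p <- pf$freq; n <- pf$slots
  usable <- n[, 1] > 1 & n[, 2] > 1
  corr <- p[, 1] * (1 - p[, 1]) / (n[, 1] - 1) + p[, 2] * (1 - p[, 2]) / (n[, 2] - 1)
  term <- (p[, 1] - p[, 2])^2 - corr
  fstat_result("f2", paste(paste(A, collapse = "+"), paste(B, collapse = "+"),
                           sep = ","), term, usable, blocks)
}

#' Admixture f3 test
#'
#' `f3(target; ref1, ref2)` with the finite-sample ("inbreed"-style)
#' correction subtracting the target's allele-frequency sampling variance,
#' computed from haploid allele slots — appropriate for pseudo-haploid
#' calls. A significantly negative Z (the cohort the statistic was designed
#' around used |Z| > 7.5) is unambiguous evidence of admixture.
#'
#' @param target,ref1,ref2 group labels
#' @param inbreed_correction subtract the sampling-variance term (needs >= 2
#'   called slots in the target at a SNP)
#' @inheritParams fstats
#' @return one-row tibble as in [f4()]
#' @export
f3_admixture_test <- function(x, target, ref1, ref2, blocks = make_blocks(x),
                              inbreed_correction = TRUE) {
  idx <- pops_idx(x, T = target, A = ref1, B = ref2)
  if (inbreed_correction && length(idx[[1]]) < 2) {
    stop("inbreed correction needs at least 2 individuals in the target",
         call. = FALSE)
  }
  pf <- pop_freq_matrix(x, idx)
  p <- pf$freq; n <- pf$slots
  usable <- n[, 2] > 0 & n[, 3] > 0 &
    (if (inbreed_correction) n[, 1] > 1 else n[, 1] > 0)
  term <- (p[, 1] - p[, 2]) * (p[, 1] - p[, 3])
  if (inbreed_correction) term <- term - p[, 1] * (1 - p[, 1]) / (n[, 1] - 1)
  fstat_result("f3", paste(paste(target, collapse = "+"),
                           paste(ref1, collapse = "+"),
                           paste(ref2, collapse = "+"), sep = ","),
               term, usable, blocks)
}

#' Leave-one-out f4 outlier scan for ancestry outliers
#'
#' For each individual i in the pool, computes
#' `f4(we_proxy, nilotic_proxy; individual_i, pool_without_i)` so that a
#' *positive* Z means the individual carries excess West-Eurasian-related
#' ancestry relative to the rest of the pool (and a negative Z excess
#' Nilotic-related ancestry). Individuals with |Z| above `z_threshold` are
#' flagged as outliers; individuals with no usable SNPs are marked
#' unscorable rather than flagged.
#'
#' @param x a `paleo_gen`
#' @param nilotic_proxy,we_proxy reference group labels anchoring the two
#'   ancestry components
#' @param pool group label of the admixed cohort to scan
#' @param z_threshold absolute-Z flag threshold (default 5)
#' @inheritParams fstats
#' @return tibble with one row per pool member: `individual_id`, `estimate`,
#'   `std_error`, `z`, `n_snps`, `outlier`, `unscorable`
#' @export
f4_outlier_scan <- function(x, nilotic_proxy, we_proxy, pool,
                            z_threshold = 5, blocks = make_blocks(x)) {
  pool_idx <- group_members(x, pool)
  if (length(pool_idx) < 3) stop("pool needs at least 3 individuals", call. = FALSE)
  refs <- pop_freq_matrix(x, list(N = group_members(x, nilotic_proxy),
                                  W = group_members(x, we_proxy)))
  per_slot <- if (x$ploidy == "pseudohaploid") 1 else 2
  gp <- x$geno[pool_idx, , drop = FALSE]
  called <- !is.na(gp)
  gp0 <- gp; gp0[!called] <- 0L
  alt_tot <- .colSums(gp0, nrow(gp0), ncol(gp0)) * (per_slot / 2)
  slot_tot <- .colSums(called, nrow(gp0), ncol(gp0)) * per_slot

  out <- vector("list", length(pool_idx))
  for (i in seq_along(pool_idx)) {
    gi <- gp[i, ]
    ci <- called[i, ]
    p_ind <- ifelse(ci, gi / 2, NA_real_)
    slot_rest <- slot_tot - ifelse(ci, per_slot, 0)
    alt_rest <- alt_tot - ifelse(ci, gi * per_slot / 2, 0)
    p_rest <- ifelse(slot_rest > 0, alt_rest / slot_rest, NA_real_)
    usable <- refs$slots[, 1] > 0 & refs$slots[, 2] > 0 & ci & slot_rest > 0
    id <- x$ind$individual_id[pool_idx[i]]
    if (!any(usable)) {
      out[[i]] <- tibble::tibble(individual_id = id, estimate = NA_real_,
                                 std_error = NA_real_, z = NA_real_,
                                 n_snps = 0L, outlier = FALSE, unscorable = TRUE)
      next
    }
    term <- (refs$freq[, 2] - refs$freq[, 1]) * (p_ind - p_rest)
    r <- fstat_result("f4", id, term, usable, blocks)
    out[[i]] <- tibble::tibble(individual_id = id, estimate = r$estimate,
                               std_error = r$std_error, z = r$z,
                               n_snps = r$n_snps,
                               outlier = abs(r$z) > z_threshold,
                               unscorable = FALSE)
  }
  dplyr::bind_rows(out)
}

#' f4 clade scan between two subgroups
#'
#' Computes `f4(base_pop, test; groupA, groupB)` for every test population
#' and applies a Bonferroni-corrected two-sided threshold. If no statistic
#' exceeds it the two subgroups are reported as consistent with forming a
#' clade with respect to the test populations.
#'
#' @param base_pop outgroup anchoring the contrast
#' @param test_pops character vector of test population labels
#' @param groupA,groupB the two subgroups being compared
#' @param alpha family-wise error rate for the Bonferroni threshold
#' @inheritParams fstats
#' @return list with `table` (one row per test pop, with `significant`
#'   flags), `z_threshold`, and `consistent_with_clade`
#' @export
clade_f4_scan <- function(x, base_pop, test_pops, groupA, groupB,
                          alpha = 0.05, blocks = make_blocks(x)) {
  stopifnot(length(test_pops) >= 1)
  zcrit <- stats::qnorm(1 - alpha / 2 / length(test_pops))
  tab <- purrr::map_dfr(test_pops, function(tp) {
    f4(x, base_pop, tp, groupA, groupB, blocks = blocks)
  })
  tab$significant <- abs(tab$z) > zcrit
  list(table = tab, z_threshold = zcrit,
       consistent_with_clade = !any(tab$significant))
}

#' Hudson FST with block-jackknife standard error
#'
#' Ratio-of-averages Hudson estimator with the finite-sample correction of
#' Bhatia and colleagues, counting haploid allele slots so that
#' pseudo-haploid and diploid data are handled uniformly. Unbiased for
#' independent samples from the two populations; both populations need at
#' least two called slots at a SNP for it to contribute.
#'
#' @param popA,popB group labels
#' @inheritParams fstats
#' @return one-row tibble as in [f4()]
#' @export
fst_hudson <- function(x, popA, popB, blocks = make_blocks(x)) {
  idx <- pops_idx(x, A = popA, B = popB)
  if (length(idx[[1]]) < 2 || length(idx[[2]]) < 2) {
    stop("fst_hudson needs at least 2 individuals per population", call. = FALSE)
  }
  pf <- pop_freq_matrix(x, idx)
  p <- pf$freq; n <- pf$slots
  usable <- n[, 1] > 1 & n[, 2] > 1
  num <- (p[, 1] - p[, 2])^2 -
    p[, 1] * (1 - p[, 1]) / (n[, 1] - 1) -
    p[, 2] * (1 - p[, 2]) / (n[, 2] - 1)
  den <- p[, 1] * (1 - p[, 2]) + p[, 2] * (1 - p[, 1])
  num[!usable] <- 0; den[!usable] <- 0
  jk <- ratio_jackknife(num, den, blocks,
                        weight = as.numeric(rowsum(as.numeric(usable), blocks)))
  tibble::tibble(stat = "fst", pops = paste(paste(popA, collapse = "+"),
                                            paste(popB, collapse = "+"), sep = ","),
                 estimate = jk$estimate, std_error = jk$std_error,
                 z = ifelse(jk$std_error > 0, jk$estimate / jk$std_error, 0),
                 n_snps = as.integer(sum(usable)), n_blocks = jk$n_blocks)
}
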
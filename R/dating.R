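#' Ancestry-covariance decay curve
#'
#' Measures the covariance of ancestry-informative genotype signal between
#' pairs of SNPs as a function of genetic distance — the quantity whose
#' exponential decay rate (per Morgan) equals the number of generations
#' since admixture. Per SNP s, the weight is the reference frequency
#' difference `w_s = p_ref1 - p_ref2` and the signal for an individual is
#' `x_s = g_s/2 - (p_ref1 + p_ref2)/2`. For each same-chromosome SNP pair
#' in a distance bin, the bin's covariance is
#' `C(d) = sum(x_i w_i x_j w_j) / sum(w_i^2 w_j^2)`, summed over subjects;
#' pairs with a missing call in a subject contribute nothing for that
#' subject. Bins with no pairs are dropped.
#'
#' @param x a `paleo_gen`
#' @param subjects individuals to pool: a group label, ids, or indices
#' @param ref1,ref2 reference group labels (the ancestry anchors); swapping
#'   them leaves the curve unchanged since weights enter quadratically
#' @param binsize distance bin width in Morgans (default 0.001 = 0.1 cM)
#' @param maxdis maximum pair distance in Morgans
#' @return a `paleo_decay` object; `$bins` holds the aggregated curve
#' @export
ancestry_covariance <- function(x, subjects, ref1, ref2,
                                binsize = 0.001, maxdis = 1.0) {
  stopifnot(inherits(x, "paleo_gen"))
  if (is.character(subjects) && all(subjects %in% x$ind$group)) {
    subjects <- group_members(x, subjects)
  } else if (is.character(subjects)) {
    subjects <- match(subjects, x$ind$individual_id)
    if (anyNA(subjects)) stop("unknown subject id", call. = FALSE)
  }
  refs <- pop_freq_matrix(x, list(r1 = group_members(x, ref1),
                                  r2 = group_members(x, ref2)))
  ok <- refs$slots[, 1] > 0 & refs$slots[, 2] > 0
  w <- refs$freq[, 1] - refs$freq[, 2]
  ok <- ok & !is.na(w) & w != 0
  if (!any(ok)) stop("no polymorphic weighted SNPs", call. = FALSE)
  mid <- (refs$freq[, 1] + refs$freq[, 2]) / 2

  chroms <- unique(x$snp$chromosome)
  B <- ceiling(maxdis / binsize)
  num <- den <- matrix(0, B, length(chroms), dimnames = list(NULL, chroms))
  npairs <- matrix(0L, B, length(chroms), dimnames = list(NULL, chroms))
  gmat <- x$geno[subjects, , drop = FALSE] / 2   # 0/1 (pseudo-haploid) or 0/.5/1

  for (ci in seq_along(chroms)) {
    idx <- which(x$snp$chromosome == chroms[ci] & ok)
    if (length(idx) < 2) next
    gp <- x$snp$genetic_position[idx]
    pr <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
    d <- abs(gp[pr[, 2]] - gp[pr[, 1]])   # robust to unsorted SNP input
    keep <- d > 0 & d <= maxdis
    pr <- pr[keep, , drop = FALSE]
    bin <- pmin(B, pmax(1L, as.integer(ceiling(d[keep] / binsize))))
    wi <- w[idx]
    for (s in seq_along(subjects)) {
      g <- gmat[s, idx]
      v <- (g - mid[idx]) * wi
      u <- wi^2
      miss <- is.na(g)
      v[miss] <- 0; u[miss] <- 0
      num[, ci] <- num[, ci] + .bincode_sum(v[pr[, 1]] * v[pr[, 2]], bin, B)
      den[, ci] <- den[, ci] + .bincode_sum(u[pr[, 1]] * u[pr[, 2]], bin, B)
    }
    npairs[, ci] <- npairs[, ci] + as.integer(tabulate(bin, B)) * length(subjects)
  }
  centers <- (seq_len(B) - 0.5) * binsize
  tot_num <- rowSums(num); tot_den <- rowSums(den)
  bins <- tibble::tibble(distance = centers,
                         covariance = ifelse(tot_den > 0, tot_num / tot_den, NA_real_),
                         n_pairs = rowSums(npairs))
  bins <- bins[tot_den > 0, ]
  structure(list(bins = bins, num = num, den = den, n_pairs = npairs,
                 binsize = binsize, maxdis = maxdis, chromosomes = chroms),
            class = "paleo_decay")
}

.bincode_sum <- function(vals, bin, B) {
  out <- numeric(B)
  agg <- rowsum(vals, bin)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Fit an exponential decay to an ancestry-covariance curve
#'
#' Least-squares fit of `C(d) = A * exp(-lambda * d) + c` over distances in
#' `[start_distance, maxdis]`; `lambda` (per Morgan) is the admixture date
#' in generations. The affine offset absorbs baseline covariance; the fit
#' start distance skips unmodeled short-range background LD.
#'
#' @param curve a `paleo_decay`, or a tibble with `distance`/`covariance`
#' @param start_distance smallest pair distance (Morgans) entering the fit
#' @return list: `A`, `lambda`, `c0`, `fitted` tibble, `n_bins`
#' @export
fit_decay <- function(curve, start_distance = 0.0045) {
  bins <- if (inherits(curve, "paleo_decay")) curve$bins else tibble::as_tibble(curve)
  bins <- bins[!is.na(bins$covariance) & bins$distance >= start_distance, ]
  if (nrow(bins) < 10) stop("need at least 10 usable bins to fit the decay",
                            call. = FALSE)
  d <- bins$distance; y <- bins$covariance
  # profile the decay rate on a log grid, solving (A, c) linearly at each
  # candidate -- globally robust even for flat or noisy curves
  grid <- exp(seq(log(0.5), log(500), length.out = 80))
  prof <- vapply(grid, function(l) {
    e <- exp(-l * d)
    fit <- stats::lm.fit(cbind(e, 1), y)
    sum(fit$residuals^2)
  }, 0)
  lam0 <- grid[which.min(prof)]
  e <- exp(-lam0 * d)
  ab <- stats::lm.fit(cbind(e, 1), y)$coefficients
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-lam * d) + cc,
                      start = list(A = unname(ab[1]), lam = lam0,
                                   cc = unname(ab[2])),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (!is.finite(lam0) || !all(is.finite(ab))) {
      stop("decay fit failed to converge (", nrow(bins), " bins, grid optimum ",
           signif(lam0, 3), " per Morgan)", call. = FALSE)
    }
    cf <- c(A = unname(ab[1]), lam = lam0, cc = unname(ab[2]))
    pred <- ab[1] * e + ab[2]
  } else {
    cf <- stats::coef(fit)
    pred <- stats::predict(fit)
  }
  list(A = unname(cf["A"]), lambda = max(0, unname(cf["lam"])), c0 = unname(cf["cc"]),
       fitted = tibble::tibble(distance = d, covariance = y, fitted = pred),
       n_bins = nrow(bins))
}

#' Estimate the admixture date with a chromosome jackknife
#'
#' Computes the ancestry-covariance curve, fits the exponential decay, and
#' obtains the standard error of the date (in generations) by
#' leave-one-chromosome-out refits with Busing-weighted jackknife
#' (chromosomes weighted by their pair-denominator mass). Estimates with
#' `z = g/SE` below `z_valid` are flagged invalid rather than dropped.
#'
#' @inheritParams ancestry_covariance
#' @param start_distance passed to [fit_decay()]
#' @param generation_time years per generation (default 28)
#' @param midpoint_ce calendar midpoint (CE; negative = BCE) of the sampled
#'   individuals, for calendar placement; optional
#' @param z_valid minimum `g/SE` for a valid estimate (default 2.8)
#' @param level confidence level for intervals
#' @return a `paleo_date` (one-row tibble subclass): `generations`,
#'   `std_error`, `z`, `valid`, `years`, `years_lower`, `years_upper`,
#'   `calendar_lower_ce`, `calendar_upper_ce`
#' @export
date_estimate <- function(x, subjects, ref1, ref2, binsize = 0.001,
                          maxdis = 1.0, start_distance = 0.0045,
                          generation_time = 28, midpoint_ce = NULL,
                          z_valid = 2.8, level = 0.95) {
  curve <- ancestry_covariance(x, subjects, ref1, ref2,
                               binsize = binsize, maxdis = maxdis)
  full <- fit_decay(curve, start_distance = start_distance)
  chroms_used <- which(colSums(curve$den) > 0)
  if (length(chroms_used) < 2) stop("chromosome jackknife needs >= 2 chromosomes",
                                    call. = FALSE)
  centers <- (seq_len(nrow(curve$num)) - 0.5) * curve$binsize
  loo <- vapply(chroms_used, function(ci) {
    tn <- rowSums(curve$num[, -ci, drop = FALSE])
    td <- rowSums(curve$den[, -ci, drop = FALSE])
    bins <- tibble::tibble(distance = centers,
                           covariance = ifelse(td > 0, tn / td, NA_real_))
    fit_decay(bins, start_distance = start_distance)$lambda
  }, 0)
  wts <- colSums(curve$den)[chroms_used]
  g_hat <- full$lambda
  se <- loo_se(g_hat, loo, wts)
  conv <- convert_generations(g_hat, se, generation_time = generation_time,
                              midpoint_ce = midpoint_ce, level = level)
  z <- if (se > 0) g_hat / se else Inf
  out <- tibble::tibble(generations = g_hat, std_error = se, z = z,
                        valid = z >= z_valid)
  out <- dplyr::bind_cols(out, conv)
  structure(out, class = c("paleo_date", class(out)),
            curve = curve, fit = full)
}

#' Convert an admixture date in generations to years and calendar dates
#'
#' @param generations point estimate g
#' @param std_error jackknife SE of g
#' @param generation_time years per generation (default 28)
#' @param midpoint_ce sampling midpoint in calendar years CE (negative =
#'   BCE); if `NULL` calendar columns are `NA`
#' @param level confidence level
#' @return one-row tibble: `years`, `years_se`, `years_lower`,
#'   `years_upper` (years before sampling) and `calendar_lower_ce`,
#'   `calendar_upper_ce` (rounded to whole years; raw values in
#'   `calendar_lower_raw`/`calendar_upper_raw`)
#' @export
convert_generations <- function(generations, std_error, generation_time = 28,
                                midpoint_ce = NULL, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  yrs <- generations * generation_time
  lo <- (generations - q * std_error) * generation_time
  hi <- (generations + q * std_error) * generation_time
  cal_lo <- if (is.null(midpoint_ce)) NA_real_ else midpoint_ce - hi
  cal_hi <- if (is.null(midpoint_ce)) NA_real_ else midpoint_ce - lo
  tibble::tibble(years = yrs, years_se = std_error * generation_time,
                 years_lower = lo, years_upper = hi,
                 calendar_lower_ce = round(cal_lo), calendar_upper_ce = round(cal_hi),
                 calendar_lower_raw = cal_lo, calendar_upper_raw = cal_hi)
}

#' Pairwise Z-tests for differences between admixture dates
#'
#' `Z_ij = (g_i - g_j)/sqrt(SE_i^2 + SE_j^2)` for all pairs, with a
#' two-sided Bonferroni threshold at family-wise level `alpha` over
#' `n_tests` hypotheses (default: all pairs). Any |Z| above the threshold
#' yields the verdict that admixture happened in multiple waves.
#'
#' @param dates tibble with columns `generations` and `std_error` (one row
#'   per subject; rownames or an `id` column label the subjects)
#' @param n_tests number of hypotheses for the Bonferroni correction
#' @param alpha family-wise error rate
#' @return list: `z_matrix`, `threshold`, `multiple_waves`, `pairs` tibble
#' @export
pairwise_date_z <- function(dates, n_tests = NULL, alpha = 0.05) {
  dates <- tibble::as_tibble(dates)
  n <- nrow(dates)
  stopifnot(n >= 2)
  if (is.null(n_tests)) n_tests <- choose(n, 2)
  ids <- if ("id" %in% names(dates)) dates$id else paste0("subject", seq_len(n))
  g <- dates$generations; s <- dates$std_error
  z <- outer(g, g, "-") / sqrt(outer(s^2, s^2, "+"))
  dimnames(z) <- list(ids, ids)
  thr <- stats::qnorm(1 - alpha / 2 / n_tests)
  iu <- which(upper.tri(z), arr.ind = TRUE)
  zv <- z[iu]
  pairs <- tibble::tibble(id1 = ids[iu[, 1]], id2 = ids[iu[, 2]],
                          z = zv, significant = abs(zv) > thr)
  list(z_matrix = z, threshold = thr,
       multiple_waves = any(pairs$significant), pairs = pairs)
}
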
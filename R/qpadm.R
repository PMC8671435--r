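#' Build the f4 system relating a target and sources to a reference set
#'
#' Computes the vector of statistics `f4(pop, R1; Rj, R1)` for
#' `pop` in (target, sources) and `j = 2..m`, on SNPs where every involved
#' population has at least one called allele slot, together with the full
#' block-jackknife covariance of the stacked statistic vector. Under a
#' k-source admixture model the target's statistic vector is the
#' weight-combination of the source vectors, which is what [fit_qpadm()]
#' exploits.
#'
#' @param x a `paleo_gen`
#' @param target target group label
#' @param sources character vector of k >= 1 source labels
#' @param references character vector of m >= k+1 reference (outgroup)
#'   labels; the first anchors the contrasts
#' @param blocks jackknife block ids per SNP ([make_blocks()])
#' @return a `paleo_f4_system`
#' @export
build_f4_system <- function(x, target, sources, references, blocks = make_blocks(x)) {
  srcs <- if (is.list(sources)) sources else as.list(sources)
  refs <- if (is.list(references)) references else as.list(references)
  k <- length(srcs); m <- length(refs)
  if (m <= k) stop("under-identified system: need more references (m) than sources (k); ",
                   "got k = ", k, ", m = ", m, call. = FALSE)
  pop_list <- c(list(target), srcs, refs)
  idx <- lapply(pop_list, function(l)
    if (is.numeric(l)) as.integer(l) else group_members(x, l))
  names(idx) <- vapply(pop_list, paste, "", collapse = "+")
  pf <- pop_freq_matrix(x, idx)
  usable <- rowSums(pf$slots > 0) == length(pop_list)
  p <- pf$freq
  r1 <- p[, k + 2]                      # first reference
  dref <- p[, (k + 3):(k + m + 1), drop = FALSE] - r1   # S x (m-1)
  terms <- do.call(cbind, lapply(seq_len(k + 1), function(i) (p[, i] - r1) * dref))
  terms[!usable, ] <- 0
  den <- as.numeric(usable)
  bl <- rowsum(cbind(terms, den), blocks)
  jk <- vector_jackknife(bl[, seq_len(ncol(terms)), drop = FALSE], bl[, ncol(bl)])
  est <- matrix(jk$estimate, ncol = k + 1)              # (m-1) x (k+1)
  structure(list(y = est[, 1], X = est[, -1, drop = FALSE],
                 loo = jk$loo, w_blocks = jk$w, cov = jk$cov,
                 k = k, m = m, target = paste(target, collapse = "+"),
                 sources = vapply(srcs, paste, "", collapse = "+"),
                 references = vapply(refs, paste, "", collapse = "+"),
                 n_snps = sum(usable), n_blocks = length(jk$w)),
            class = "paleo_f4_system")
}

# residual covariance A(w) C A(w)' for weight vector w
.resid_cov <- function(C, w, p) {
  A <- cbind(diag(p), do.call(cbind, lapply(w, function(wi) -wi * diag(p))))
  A %*% C %*% t(A)
}

.safe_solve <- function(Q, b) {
  out <- tryCatch(solve(Q, b), error = function(e) NULL)
  ridge <- 0
  while (is.null(out)) {
    ridge <- if (ridge == 0) 1e-9 * mean(diag(Q)) else ridge * 10
    out <- tryCatch(solve(Q + ridge * diag(nrow(Q)), b), error = function(e) NULL)
    if (ridge > mean(diag(Q))) stop("covariance irreparably singular", call. = FALSE)
  }
  if (ridge > 0) warning("singular covariance: ridge-regularized solve (magnitude ",
                         signif(ridge, 3), ")", call. = FALSE)
  out
}

# p-value for a jackknife-whitened quadratic form: the covariance is
# estimated from g blocks, so the statistic is Hotelling-T2 rather than
# chi-square distributed; the F transform calibrates the tail at small g
# and converges to the chi-square p-value as g grows.
.qform_p <- function(stat, dof, g) {
  if (g <= dof + 1) return(stats::pchisq(stat, dof, lower.tail = FALSE))
  stats::pf(stat * (g - dof) / (dof * (g - 1)), dof, g - dof, lower.tail = FALSE)
}

# constrained GLS weight solve for one statistic set, fixed covariance C
.solve_weights <- function(y, X, C, n_iter = 20, tol = 1e-10) {
  p <- length(y); k <- ncol(X)
  if (k == 1) return(1)
  w <- rep(1 / k, k)
  B <- diff(diag(k))        # (k-1) x k; t(B) spans the sum-zero space
  w0 <- rep(1 / k, k)
  for (it in seq_len(n_iter)) {
    Q <- .resid_cov(C, w, p)
    XB <- X %*% t(B)
    r0 <- y - X %*% w0
    Qi_XB <- .safe_solve(Q, XB)
    z <- solve(crossprod(XB, Qi_XB), crossprod(Qi_XB, r0))
    w_new <- as.numeric(w0 + t(B) %*% z)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  w
}

#' Fit admixture proportions from an f4 system
#'
#' Finds source weights summing to one that minimize the
#' covariance-weighted quadratic form of the target-minus-mixture residual
#' vector; the residual chi-square against `(m-1) - (k-1)` degrees of
#' freedom gives the model-fit p-value (p > 0.05 read as a fitting model).
#' Weight standard errors come from refitting on each leave-one-block-out
#' replicate (weighted delete-one jackknife).
#'
#' @param system a [build_f4_system()] result
#' @return a `paleo_qpadm` object; see [tidy.paleo_qpadm()] and
#'   [glance.paleo_qpadm()]
#' @export
fit_qpadm <- function(system) {
  stopifnot(inherits(system, "paleo_f4_system"))
  p <- system$m - 1; k <- system$k
  w <- .solve_weights(system$y, system$X, system$cov)
  Q <- .resid_cov(system$cov, w, p)
  r <- system$y - system$X %*% w
  chisq <- as.numeric(crossprod(r, .safe_solve(Q, r)))
  dof <- (system$m - 1) - (system$k - 1)
  p_value <- .qform_p(chisq, dof, system$n_blocks)

  # jackknife refits for weight SEs
  if (k > 1) {
    g <- length(system$w_blocks)
    refits <- matrix(NA_real_, g, k)
    for (b in seq_len(g)) {
      vb <- matrix(system$loo[b, ], ncol = k + 1)
      refits[b, ] <- .solve_weights(vb[, 1], vb[, -1, drop = FALSE], system$cov,
                                    n_iter = 8)
    }
    se <- sapply(seq_len(k), function(j)
      loo_se(w[j], refits[, j], system$w_blocks))
  } else se <- 0

  structure(list(weights = stats::setNames(w, system$sources),
                 std_errors = stats::setNames(se, system$sources),
                 chisq = chisq, dof = dof, p_value = p_value,
                 target = system$target, references = system$references,
                 n_snps = system$n_snps, n_blocks = system$n_blocks),
            class = "paleo_qpadm")
}

#' @export
print.paleo_qpadm <- function(x, ...) {
  cat("<paleo_qpadm> target:", x$target, "\n")
  for (s in names(x$weights)) {
    cat(sprintf("  %-12s %6.1f%% +/- %.1f%%\n", s, 100 * x$weights[[s]],
                100 * x$std_errors[[s]]))
  }
  cat(sprintf("  model fit: chisq = %.2f, dof = %d, p = %.3g (%s)\n",
              x$chisq, x$dof, x$p_value,
              if (x$p_value > 0.05) "fits" else "rejected"))
  invisible(x)
}

#' Model competition between candidate sources
#'
#' For each ordered pair of candidates (keep, move), refits the two-source
#' model `target ~ fixed_source + keep` with `move` appended to the
#' reference set. A model that stops fitting (p <= 0.05) indicates that the
#' moved candidate shares drift with the target not captured by the kept
#' source.
#'
#' @param x a `paleo_gen`
#' @param target target group label
#' @param candidate_sources >= 2 competing source labels
#' @param fixed_source source kept in every model
#' @param references base reference labels
#' @param blocks jackknife block ids
#' @return tibble with one row per ordered (keep, move) pair: weights,
#'   p-value, and a `fits` flag
#' @export
model_competition <- function(x, target, candidate_sources, fixed_source,
                              references, blocks = make_blocks(x)) {
  stopifnot(length(candidate_sources) >= 2)
  pairs <- expand.grid(keep = candidate_sources, move = candidate_sources,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$keep != pairs$move, ]
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    keep <- pairs$keep[i]; move <- pairs$move[i]
    fit <- fit_qpadm(build_f4_system(x, target, c(fixed_source, keep),
                                     c(references, move), blocks = blocks))
    tibble::tibble(keep = keep, move = move,
                   weight_keep = unname(fit$weights[keep]),
                   se_keep = unname(fit$std_errors[keep]),
                   p_value = fit$p_value, fits = fit$p_value > 0.05)
  })
}

#' qpWave-style clade test between two groups
#'
#' Tests whether two groups have identical f4 relationships to the
#' reference set (rank-0 residual): chi-square on the jackknife-whitened
#' difference of their statistic vectors with m-1 degrees of freedom.
#' p > 0.05 is reported as consistent with the two groups forming a clade.
#'
#' @param x a `paleo_gen`
#' @param groupA,groupB group labels
#' @param references reference labels (m >= 2)
#' @param blocks jackknife block ids
#' @return list: `p_value`, `chisq`, `dof`, `consistent_with_clade`
#' @export
qpwave_clade_test <- function(x, groupA, groupB, references, blocks = make_blocks(x)) {
  m <- length(references)
  stopifnot(m >= 2)
  sys <- build_f4_system(x, groupA, list(groupB), references, blocks = blocks)
  p <- m - 1
  d <- sys$y - sys$X[, 1]
  if (all(abs(d) < 1e-14)) {
    return(list(p_value = 1, chisq = 0, dof = p, consistent_with_clade = TRUE))
  }
  Q <- .resid_cov(sys$cov, 1, p)
  chisq <- as.numeric(crossprod(d, .safe_solve(Q, d)))
  p_value <- .qform_p(chisq, p, sys$n_blocks)
  list(p_value = p_value, chisq = chisq, dof = p,
       consistent_with_clade = p_value > 0.05)
}

#' Closed-form X-vs-autosome sex-bias decomposition
#'
#' Given West-Eurasian-related ancestry proportions on the autosomes (`pA`)
#' and the X chromosome (`pX`) with standard errors, computes the
#' female-derived and male-derived components `F = 3*pX - 2*pA` and
#' `M = 4*pA - 3*pX` (which satisfy `F + M = 2*pA` identically), the female
#' fraction `P = F/(2*pA)` with a delta-method confidence interval, and the
#' X-autosome Z-score `(pX - pA)/sqrt(sA^2 + sX^2)` — positive when the X
#' carries more West-Eurasian-related ancestry than the autosomes, i.e.
#' female-biased admixture.
#'
#' @param p_auto,se_auto autosomal proportion and SE (fractions)
#' @param p_x,se_x X-chromosome proportion and SE
#' @param level confidence level for the interval on P
#' @param df degrees of freedom for the interval quantile: `Inf` (default)
#'   uses the normal quantile, appropriate when the SEs rest on many
#'   jackknife blocks; with few blocks pass blocks - 1 for a Student-t
#'   interval
#' @return one-row tibble: `pA`, `pX`, `z`, `F`, `M`, `P`, `P_se`,
#'   `P_lower`, `P_upper`
#' @export
sex_bias_decompose <- function(p_auto, se_auto, p_x, se_x, level = 0.95,
                               df = Inf) {
  z <- (p_x - p_auto) / sqrt(se_auto^2 + se_x^2)
  Fem <- 3 * p_x - 2 * p_auto
  Mal <- 4 * p_auto - 3 * p_x
  P <- Fem / (2 * p_auto)
  # delta method: dP/dpX = 3/(2 pA), dP/dpA = -3 pX / (2 pA^2)
  P_se <- sqrt((3 / (2 * p_auto) * se_x)^2 + (3 * p_x / (2 * p_auto^2) * se_auto)^2)
  q <- stats::qt(1 - (1 - level) / 2, df = df)
  tibble::tibble(pA = p_auto, pX = p_x, z = z, F = Fem, M = Mal,
                 P = P, P_se = P_se,
                 P_lower = P - q * P_se, P_upper = P + q * P_se)
}

#' Estimate sex-biased admixture from autosomes versus X
#'
#' Runs the qpAdm-style fit separately on the autosomal and X compartments
#' and decomposes the difference into female- and male-derived ancestry
#' components via [sex_bias_decompose()]. A poor X-compartment model fit
#' (p below `x_fit_threshold`) is flagged, not raised.
#'
#' @param x a `paleo_gen` containing autosomal and X SNPs
#' @param target target group label
#' @param sources source labels; `we_source` names the one whose weight is
#'   the West-Eurasian-related proportion
#' @param references reference labels
#' @param we_source which source is the West-Eurasian-like component
#'   (default: the last source)
#' @param block_size jackknife block width in Morgans
#' @param x_fit_threshold p-value below which the X fit is flagged poor
#' @param level confidence level for the interval on P
#' @return a `paleo_sexbias` object (list with `autosomes`, `X` fits and
#'   `decomposition` tibble); see [tidy.paleo_sexbias()]
#' @export
estimate_sex_bias <- function(x, target, sources, references,
                              we_source = sources[length(sources)],
                              block_size = 0.05, x_fit_threshold = 0.05,
                              level = 0.95) {
  parts <- partition_compartments(x)
  if (ncol(parts$X$geno) == 0) stop("X compartment is empty", call. = FALSE)
  fitA <- fit_qpadm(build_f4_system(parts$autosomes, target, sources, references,
                                    blocks = make_blocks(parts$autosomes, block_size)))
  fitX <- fit_qpadm(build_f4_system(parts$X, target, sources, references,
                                    blocks = make_blocks(parts$X, block_size)))
  dec <- sex_bias_decompose(unname(fitA$weights[we_source]),
                            unname(fitA$std_errors[we_source]),
                            unname(fitX$weights[we_source]),
                            unname(fitX$std_errors[we_source]), level = level,
                            df = min(fitA$n_blocks, fitX$n_blocks) - 1)
  structure(list(autosomes = fitA, X = fitX, decomposition = dec,
                 we_source = we_source,
                 poor_x_fit = fitX$p_value < x_fit_threshold),
            class = "paleo_sexbias")
}

#' @export
print.paleo_sexbias <- function(x, ...) {
  d <- x$decomposition
  cat("<paleo_sexbias>\n")
  cat(sprintf("  autosomes: %.1f%% +/- %.1f%% (model p = %.3f)\n",
              100 * d$pA, 100 * x$autosomes$std_errors[[x$we_source]],
              x$autosomes$p_value))
  cat(sprintf("  X:         %.1f%% +/- %.1f%% (model p = %.3f)%s\n",
              100 * d$pX, 100 * x$X$std_errors[[x$we_source]], x$X$p_value,
              if (x$poor_x_fit) "  [poor X model fit]" else ""))
  cat(sprintf("  Z (X - autosomes): %.2f\n", d$z))
  cat(sprintf("  female fraction P = %.0f%% (CI %.0f-%.0f%%)\n",
              100 * d$P, 100 * d$P_lower, 100 * d$P_upper))
  invisible(x)
}
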
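#' Assign SNPs to contiguous jackknife blocks
#'
#' Blocks are contiguous runs of SNPs along the genetic map, never spanning a
#' chromosome boundary. The default block width of 0.05 Morgans (5 cM) is
#' standard practice for f-statistic jackknives. On sparse maps, blocks are
#' widened so each holds at least `min_snps` SNPs (per chromosome, the block
#' count is capped at `floor(S/min_snps)` and SNPs are chunked contiguously):
#' block sums over too few SNPs are visibly non-normal and make the
#' jackknife-whitened chi-square statistics anticonservative in the tail.
#' At real capture-panel densities (hundreds of SNPs per 5 cM) the cap is
#' never active. The `"chromosome"` mode falls back to one block per
#' chromosome.
#'
#' @param x a `paleo_gen` (or its `$snp` tibble)
#' @param size block width in Morgans, or the string `"chromosome"`
#' @param min_snps minimum SNPs per block before blocks are widened
#' @return integer vector of block ids (1..B), one per SNP
#' @export
make_blocks <- function(x, size = 0.05, min_snps = 40) {
  snp <- if (inherits(x, "paleo_gen")) x$snp else tibble::as_tibble(x)
  chrom <- snp$chromosome
  if (identical(size, "chromosome")) {
    return(as.integer(factor(chrom, levels = unique(chrom))))
  }
  out <- integer(nrow(snp))
  offset <- 0L
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    g <- snp$genetic_position[i]
    by_size <- max(1L, ceiling((max(g) - min(g) + 1e-12) / size))
    B <- max(1L, min(by_size, floor(length(i) / min_snps)))
    out[i] <- offset + as.integer(ceiling(seq_along(i) * B / length(i)))
    offset <- offset + B
  }
  out
}

#' Weighted delete-one block jackknife
#'
#' Computes the weighted-mean estimate `sum(w*x)/sum(w)` and its standard
#' error by the weighted delete-one jackknife of Busing and colleagues,
#' which reduces to the classical delete-one jackknife when all weights are
#' equal. This is the error model used throughout the package for
#' f-statistics, FST and admixture-proportion estimates, where blocks are
#' contiguous genomic segments so the resampling is robust to linkage.
#'
#' @param x per-block statistics
#' @param w per-block positive weights (e.g. usable SNP counts)
#' @return tibble: `estimate`, `std_error`, `n_blocks`
#' @export
block_jackknife <- function(x, w = rep(1, length(x))) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  g <- length(x)
  if (g < 2) stop("block jackknife needs at least 2 non-empty blocks", call. = FALSE)
  W <- sum(w)
  tot <- sum(w * x)
  est <- tot / W
  loo <- (tot - w * x) / (W - w)          # leave-one-block-out estimates
  h <- W / w
  theta_j <- g * est - sum((1 - w / W) * loo)
  tau <- h * est - (h - 1) * loo
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / g
  tibble::tibble(estimate = est, std_error = sqrt(var_j), n_blocks = g)
}

# Internal: jackknife for a ratio-of-sums statistic sum(num)/sum(den),
# blocks indexed by `block`. Returns estimate, SE, n_blocks using per-block
# `weight` (defaults to per-block den).
ratio_jackknife <- function(num, den, block, weight = NULL) {
  nb <- rowsum(cbind(num, den), block)
  good <- nb[, 2] != 0
  nb <- nb[good, , drop = FALSE]
  if (nrow(nb) < 2) stop("block jackknife needs at least 2 non-empty blocks",
                         call. = FALSE)
  w <- if (is.null(weight)) abs(nb[, 2]) else weight[good]
  block_jackknife(nb[, 1] / nb[, 2], w)
}

# Internal: Busing weighted-jackknife SE from a full-data estimate and its
# leave-one-block-out replicates (w = per-block weights).
loo_se <- function(est, loo, w) {
  g <- length(loo)
  W <- sum(w)
  h <- W / w
  theta_j <- g * est - sum((1 - w / W) * loo)
  tau <- h * est - (h - 1) * loo
  sqrt(sum((tau - theta_j)^2 / (h - 1)) / g)
}

# Internal: leave-one-block-out replicates of a vector-valued ratio-of-sums
# statistic. num: B x p matrix of per-block numerator sums; den: length-B
# denominator (SNP counts). Returns list(estimate = p-vector,
# loo = B x p matrix, w = per-block weights, cov = weighted jackknife
# covariance matrix of the estimate).
vector_jackknife <- function(num, den) {
  num <- as.matrix(num)
  good <- den > 0
  num <- num[good, , drop = FALSE]
  den <- den[good]
  g <- length(den)
  if (g < 2) stop("need at least 2 non-empty blocks", call. = FALSE)
  W <- sum(den)
  tot <- colSums(num)
  est <- tot / W
  loo <- sweep(-num, 2, tot, "+") / (W - den)   # g x p
  h <- W / den
  theta_j <- g * est - colSums((1 - den / W) * loo)
  tau <- outer(h, est) - (h - 1) * loo          # g x p
  dev <- sweep(tau, 2, theta_j)
  covm <- crossprod(dev / sqrt(h - 1)) / g
  list(estimate = est, loo = loo, w = den, cov = covm)
}
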
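#' Pairwise mismatch rates between individuals
#'
#' For every pair of individuals, the fraction of SNPs called in both whose
#' pseudo-haploid calls disagree (p0). Because pseudo-haploid calls are
#' single allele draws, relatives show reduced mismatch in proportion to
#' their kinship coefficient: expected p0 is `baseline * (1 - k)` with
#' k = 1/4, 1/8, 1/16 for degrees 1-3. Pairs overlapping at fewer than
#' `min_overlap` SNPs are marked `unknown`.
#'
#' @param x a pseudo-haploid `paleo_gen`
#' @param individuals optional subset (indices or ids); default all
#' @param min_overlap minimum overlapping SNP count for a scorable pair
#' @return tibble: `id1`, `id2`, `n_overlap`, `p0`, `unknown`
#' @export
pairwise_mismatch <- function(x, individuals = NULL, min_overlap = 15000) {
  stopifnot(inherits(x, "paleo_gen"))
  if (x$ploidy != "pseudohaploid") {
    stop("pairwise_mismatch expects a pseudo-haploid dataset", call. = FALSE)
  }
  if (is.null(individuals)) individuals <- seq_len(nrow(x$geno))
  if (is.character(individuals)) individuals <- match(individuals, x$ind$individual_id)
  g <- x$geno[individuals, , drop = FALSE]
  ids <- x$ind$individual_id[individuals]
  called <- !is.na(g)
  a <- g == 2L; a[!called] <- FALSE          # alt-carrier indicator
  cl <- called * 1
  av <- a * 1
  overlap <- tcrossprod(cl)                   # pairwise overlap counts
  both_alt <- tcrossprod(av)
  alt_called <- av %*% t(cl)                  # i alt & j called
  # mismatches = (i alt & j ref) + (i ref & j alt)
  mism <- (alt_called - both_alt) + (t(alt_called) - both_alt)
  n <- length(ids)
  iu <- which(upper.tri(overlap), arr.ind = TRUE)
  ov <- overlap[iu]
  p0 <- ifelse(ov > 0, mism[iu] / ov, NA_real_)
  tibble::tibble(id1 = ids[iu[, 1]], id2 = ids[iu[, 2]],
                 n_overlap = as.integer(ov), p0 = p0,
                 unknown = ov < min_overlap)
}

#' Classify relatedness degrees from pairwise mismatch
#'
#' Normalizes each pair's mismatch rate by an unrelated baseline (median p0
#' over all scorable pairs, assuming most pairs are unrelated) and assigns
#' degree classes by the halving-of-shared-ancestry geometry: the
#' normalized coefficient phi = p0/baseline is expected at 1 - k for
#' kinship k, so class bands sit at the midpoints 0.625, 0.8125, 0.90625
#' and 0.953125 separating identical, degree 1, 2, 3 and unrelated.
#'
#' @param pairs output of [pairwise_mismatch()]
#' @param baseline unrelated-pair baseline p0; by default the median over
#'   scorable pairs (requires >= `min_pairs` of them)
#' @param min_pairs minimum scorable pairs for a median baseline
#' @return list: `pairs` (input plus `phi`, `degree_class`) and `baseline`
#' @export
classify_degrees <- function(pairs, baseline = NULL, min_pairs = 20) {
  usable <- !pairs$unknown & !is.na(pairs$p0)
  if (is.null(baseline)) {
    if (sum(usable) < min_pairs) {
      stop("fewer than ", min_pairs, " scorable pairs: supply `baseline` explicitly",
           call. = FALSE)
    }
    baseline <- stats::median(pairs$p0[usable])
  }
  phi <- pairs$p0 / baseline
  cls <- cut(phi, breaks = c(-Inf, 0.625, 0.8125, 0.90625, 0.953125, Inf),
             labels = c("identical", "1", "2", "3", "unrelated"),
             right = FALSE)
  cls <- as.character(cls)
  cls[pairs$unknown] <- "unknown"
  pairs$phi <- phi
  pairs$degree_class <- cls
  list(pairs = pairs, baseline = baseline)
}

#' Cross-cemetery relative-pair expectation and binomial test
#'
#' For each requested degree set, counts relative pairs within and across
#' two cemeteries and compares the observed number of cross-cemetery pairs
#' with the expectation under random burial: with nR and nS distinct
#' individuals involved in pairs of that set per cemetery, the probability
#' that two randomly chosen involved individuals are a cross-cemetery pair
#' is `p = nR*nS / choose(nR+nS, 2)`, the expected count is `T*p`, and the
#' one-sided binomial p-value is `P(X <= observed_cross)` for
#' `X ~ Binomial(T, p)` — small values mean fewer cross-cemetery relatives
#' than random burial predicts.
#'
#' @param pairs tibble with columns `id1`, `id2`, `degree_class` (e.g. from
#'   [classify_degrees()]`$pairs`, or constructed directly from counts)
#' @param cemeteries named character vector mapping individual id ->
#'   cemetery label (two labels, canonically "R" and "S")
#' @param degree_sets list of character vectors of degree classes; default
#'   single degrees 1-3 plus pooled 1+2 and 1+2+3
#' @return tibble shaped like the study's stratification table: per degree
#'   set, observed within/cross counts, `n_R`, `n_S`, `expected_probability`,
#'   `expected_count`, `obs_over_expected`, `binomial_p`, `computable`
#' @export
cross_cemetery_test <- function(pairs, cemeteries,
                                degree_sets = list("1", "2", "3",
                                                   c("1", "2"), c("1", "2", "3"))) {
  labs <- sort(unique(stats::na.omit(unname(cemeteries))))
  if (length(labs) != 2) stop("need exactly two cemetery labels", call. = FALSE)
  purrr::map_dfr(degree_sets, function(ds) {
    sel <- pairs[pairs$degree_class %in% ds, , drop = FALSE]
    c1 <- unname(cemeteries[sel$id1]); c2 <- unname(cemeteries[sel$id2])
    if (any(is.na(c(c1, c2))) && nrow(sel)) {
      stop("every individual in a relative pair needs a cemetery label", call. = FALSE)
    }
    inds <- unique(c(sel$id1, sel$id2))
    nR <- sum(cemeteries[inds] == labs[1]); nS <- sum(cemeteries[inds] == labs[2])
    Tn <- nrow(sel)
    within_R <- sum(c1 == labs[1] & c2 == labs[1])
    within_S <- sum(c1 == labs[2] & c2 == labs[2])
    cross <- Tn - within_R - within_S
    computable <- (nR + nS) >= 2
    p <- if (computable) nR * nS / choose(nR + nS, 2) else NA_real_
    tibble::tibble(
      degrees = paste(ds, collapse = "+"),
      within_R = within_R, within_S = within_S, cross = cross, n_pairs = Tn,
      n_R = nR, n_S = nS,
      expected_probability = p,
      expected_count = if (computable) Tn * p else NA_real_,
      obs_over_expected = if (computable && Tn * p > 0) cross / (Tn * p) else
        ifelse(computable, NA_real_, NA_real_),
      binomial_p = if (computable) stats::pbinom(cross, Tn, p) else NA_real_,
      computable = computable)
  })
}

#' Sum runs of homozygosity into reporting length bins
#'
#' Utility summarizing user-supplied ROH segments per individual into the
#' conventional length-bin totals (all segments > 4 cM; 8-20 cM; > 20 cM).
#'
#' @param segments tibble with columns `individual_id`, `length_cm`
#' @return tibble per individual: `sum_gt4`, `sum_8_20`, `sum_gt20`,
#'   `n_segments`
#' @export
bin_roh <- function(segments) {
  segments <- tibble::as_tibble(segments)
  dplyr::summarise(
    dplyr::group_by(segments, .data$individual_id),
    sum_gt4 = sum(.data$length_cm[.data$length_cm > 4]),
    sum_8_20 = sum(.data$length_cm[.data$length_cm >= 8 & .data$length_cm <= 20]),
    sum_gt20 = sum(.data$length_cm[.data$length_cm > 20]),
    n_segments = dplyr::n(), .groups = "drop")
}
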
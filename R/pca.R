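#' Principal component analysis on reference individuals
#'
#' Computes principal components from (typically modern, low-missingness)
#' reference individuals: SNPs are centered by the reference mean frequency
#' and scaled by `sqrt(p*(1-p))`, residual missing calls are mean-imputed,
#' SNPs monomorphic in the reference are dropped (count logged via a
#' message), and components come from the singular value decomposition of
#' the standardized matrix.
#'
#' @param x a `paleo_gen`
#' @param reference group labels (or indices) of the individuals the axes
#'   are computed from
#' @param n_components number of components to keep
#' @return a `paleo_pca`: loadings (SNPs x components), per-SNP centers and
#'   scales, reference coordinates, eigenvalues
#' @export
fit_pca <- function(x, reference, n_components = 10) {
  idx <- if (is.numeric(reference)) as.integer(reference) else group_members(x, reference)
  per_slot <- if (x$ploidy == "pseudohaploid") 1 else 2
  g <- x$geno[idx, , drop = FALSE] / 2      # dosage on 0..1
  p <- colMeans(g, na.rm = TRUE)
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) message(sum(mono), " SNP(s) monomorphic or uncalled in reference dropped")
  keep <- which(!mono)
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  scl <- sqrt(p * (1 - p))
  zm <- sweep(sweep(g, 2, p), 2, scl, "/")
  zm[is.na(zm)] <- 0
  n_components <- min(n_components, nrow(zm) - 1, ncol(zm))
  sv <- svd(zm, nu = n_components, nv = n_components)
  loadings <- sv$v
  coords <- zm %*% loadings
  colnames(coords) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(snp_index = keep, center = p, scale = scl,
                 loadings = loadings,
                 eigenvalues = sv$d[seq_len(n_components)]^2 / (nrow(zm) - 1),
                 reference_coords = tibble::tibble(
                   individual_id = x$ind$individual_id[idx],
                   group = x$ind$group[idx]) |>
                   dplyr::bind_cols(tibble::as_tibble(coords))),
            class = "paleo_pca")
}

#' Least-squares projection of individuals onto fitted components
#'
#' Projects (typically ancient, high-missingness) individuals onto the
#' reference axes using only their non-missing SNPs: the projected
#' coordinates solve the least-squares regression of the centered/scaled
#' observed genotypes on the loadings restricted to called SNPs. A
#' complete-data individual inside the reference span is recovered exactly.
#' Individuals sharing fewer than `min_snps` called SNPs with the loading
#' support are marked unreliable (coordinates still returned).
#'
#' @param pca a [fit_pca()] result
#' @param x the `paleo_gen` holding the individuals to project
#' @param individuals group labels, ids or indices
#' @param min_snps reliability threshold on called SNP count
#' @return tibble: `individual_id`, `group`, `n_snps`, `reliable`, PC
#'   coordinates
#' @export
pca_project <- function(pca, x, individuals, min_snps = 30000) {
  stopifnot(inherits(pca, "paleo_pca"))
  idx <- if (is.numeric(individuals)) as.integer(individuals) else
    if (all(individuals %in% x$ind$group)) group_members(x, individuals) else
      match(individuals, x$ind$individual_id)
  g <- x$geno[idx, pca$snp_index, drop = FALSE] / 2
  out <- matrix(NA_real_, length(idx), ncol(pca$loadings))
  nsnp <- integer(length(idx))
  for (i in seq_along(idx)) {
    obs <- which(!is.na(g[i, ]))
    nsnp[i] <- length(obs)
    if (length(obs) < ncol(pca$loadings)) next
    zz <- (g[i, obs] - pca$center[obs]) / pca$scale[obs]
    V <- pca$loadings[obs, , drop = FALSE]
    out[i, ] <- solve(crossprod(V), crossprod(V, zz))
  }
  colnames(out) <- colnames(pca$loadings)
  dplyr::bind_cols(
    tibble::tibble(individual_id = x$ind$individual_id[idx],
                   group = x$ind$group[idx],
                   n_snps = nsnp, reliable = nsnp >= min_snps),
    tibble::as_tibble(out))
}
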
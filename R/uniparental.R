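#' Bound maternal ancestry by inverting an exact binomial CI
#'
#' Given `k` of `n` individuals carrying mtDNA haplogroups of one origin
#' class, finds the range of underlying maternal-ancestry proportions whose
#' exact central (equal-tail) binomial acceptance region at the given level
#' contains `k`: a proportion p is accepted iff neither tail probability of
#' `Binomial(n, p)` at `k` falls at or below `(1-level)/2`. The search runs
#' on a percent grid (default 1%); exact tail sums, no normal
#' approximation.
#'
#' @param n number of counted individuals
#' @param k observed haplogroup count of the focal origin class
#' @param level central CI level (default 0.95)
#' @param grid_step grid resolution as a proportion (default 0.01 = 1%)
#' @return one-row tibble: `lower_pct`, `upper_pct`, plus the accepted grid
#'   as an attribute `"accepted"`
#' @export
maternal_ancestry_range <- function(n, k, level = 0.95, grid_step = 0.01) {
  stopifnot(k >= 0, k <= n, level > 0, level < 1)
  alpha <- 1 - level
  grid <- seq(0, 1, by = grid_step)
  accepted <- vapply(grid, function(p) {
    stats::pbinom(k, n, p) > alpha / 2 &&
      (1 - stats::pbinom(k - 1, n, p)) > alpha / 2
  }, TRUE)
  if (!any(accepted)) stop("no grid proportion accepts the observed count",
                           call. = FALSE)
  out <- tibble::tibble(lower_pct = 100 * min(grid[accepted]),
                        upper_pct = 100 * max(grid[accepted]))
  attr(out, "accepted") <- grid[accepted]
  out
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Continuity-corrected chi-square `sum((|O-E| - 0.5)^2 / E)` with expected
#' counts from the margins; the correction is clamped at zero when
#' `|O-E| < 0.5`. One degree of freedom.
#'
#' @param table 2x2 matrix of non-negative counts
#' @return one-row tibble: `statistic`, `p_value`, `n`
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  N <- sum(table)
  if (N == 0) stop("empty table", call. = FALSE)
  E <- outer(rowSums(table), colSums(table)) / N
  if (any(E == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  adj <- pmax(abs(table - E) - 0.5, 0)
  stat <- sum(adj^2 / E)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 n = N)
}

#' Summarize haplogroup counts by cemetery and origin class
#'
#' Tabulates individuals per cemetery and haplogroup origin class,
#' honoring exclusion flags (first-degree relatives sharing a matriline or
#' patriline are counted once by flagging all but one).
#'
#' @param haplogroups tibble with columns `individual_id`, `cemetery`, an
#'   origin-class column named by `origin_col` (e.g. `origin_class_mt`),
#'   and optionally an exclusion flag column named by `exclude_col`
#' @param origin_col name of the origin-class column
#' @param exclude_col name of the logical exclusion column (rows with TRUE
#'   are dropped); `NULL` to keep all
#' @return tibble: per cemetery x origin class, `count` and `frequency`
#'   (within cemetery)
#' @export
haplogroup_summary <- function(haplogroups, origin_col = "origin_class_mt",
                               exclude_col = NULL) {
  h <- tibble::as_tibble(haplogroups)
  if (nrow(h) == 0) {
    return(tibble::tibble(cemetery = character(), origin_class = character(),
                          count = integer(), frequency = numeric()))
  }
  if (!is.null(exclude_col)) h <- h[!isTRUE_vec(h[[exclude_col]]), ]
  counts <- dplyr::count(h, cemetery = .data$cemetery,
                         origin_class = .data[[origin_col]], name = "count")
  dplyr::mutate(dplyr::group_by(counts, .data$cemetery),
                frequency = .data$count / sum(.data$count)) |> dplyr::ungroup()
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
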
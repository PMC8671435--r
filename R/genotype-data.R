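#' Construct a genotype dataset
#'
#' The central data container of paleostrat: an individuals-by-SNPs genotype
#' matrix of alternate-allele counts together with SNP and individual
#' metadata. Pseudo-haploid data (one sequencing read standing in for the
#' diploid genotype) is represented on the same 0/2 scale as diploid data,
#' with a dataset-level ploidy flag controlling how allele "slots" are
#' counted in downstream frequency calculations.
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns; entries
#'   0, 1, 2 (alternate-allele count) or `NA` for missing. A pseudo-haploid
#'   dataset must not contain the value 1.
#' @param snp tibble with columns `snp_id`, `chromosome` (autosomes
#'   `"1"`..`"22"`, X as `"23"`), `genetic_position` (Morgans, non-decreasing
#'   within a chromosome), `physical_position` (bp, strictly increasing
#'   within a chromosome), `ref_allele`, `alt_allele`.
#' @param ind tibble with columns `individual_id`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`), `group`; optionally `cemetery`,
#'   `date_midpoint_ce`, `exclude`.
#' @param ploidy `"pseudohaploid"` (each called genotype contributes one
#'   allele slot) or `"diploid"` (two slots).
#'
#' @return An object of class `paleo_gen`.
#' @export
gen_dataset <- function(geno, snp, ind, ploidy = c("pseudohaploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  geno <- as.matrix(geno)
  snp <- tibble::as_tibble(snp)
  ind <- tibble::as_tibble(ind)
  if (!"cemetery" %in% names(ind)) ind$cemetery <- NA_character_
  if (!"date_midpoint_ce" %in% names(ind)) ind$date_midpoint_ce <- NA_real_
  if (!"exclude" %in% names(ind)) ind$exclude <- FALSE
  if (nrow(geno) != nrow(ind)) {
    stop("genotype matrix has ", nrow(geno), " rows but ", nrow(ind),
         " individual records", call. = FALSE)
  }
  if (ncol(geno) != nrow(snp)) {
    stop("genotype matrix has ", ncol(geno), " columns but ", nrow(snp),
         " SNP records", call. = FALSE)
  }
  if (anyDuplicated(ind$individual_id)) {
    stop("individual_id values must be unique", call. = FALSE)
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    stop("genotype entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (ploidy == "pseudohaploid" && any(vals == 1L)) {
    stop("pseudo-haploid dataset contains heterozygous calls (value 1)",
         call. = FALSE)
  }
  snp$chromosome <- as.character(snp$chromosome)
  drop <- !snp$chromosome %in% as.character(1:23)
  if (any(drop)) {
    warning(sum(drop), " SNP(s) on non-autosomal/non-X chromosomes dropped",
            call. = FALSE)
    geno <- geno[, !drop, drop = FALSE]
    snp <- snp[!drop, ]
  }
  dimnames(geno) <- list(ind$individual_id, snp$snp_id)
  structure(list(geno = geno, snp = snp, ind = ind, ploidy = ploidy),
            class = "paleo_gen")
}

#' @export
print.paleo_gen <- function(x, ...) {
  cat("<paleo_gen> ", nrow(x$geno), " individuals x ", ncol(x$geno), " SNPs (",
      x$ploidy, ")\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$snp$chromosome), collapse = ","), "\n")
  cat("  groups: ", paste(unique(x$ind$group), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat("  missingness: ", sprintf("%.1f%%", 100 * miss), "\n")
  invisible(x)
}

#' @export
dim.paleo_gen <- function(x) dim(x$geno)

#' Subset a genotype dataset
#'
#' @param x a [gen_dataset()] object
#' @param individuals logical/integer/character index into individuals
#'   (character values match `individual_id`)
#' @param snps logical/integer index into SNPs
#' @return a `paleo_gen`
#' @export
gen_subset <- function(x, individuals = NULL, snps = NULL) {
  stopifnot(inherits(x, "paleo_gen"))
  if (is.null(individuals)) individuals <- seq_len(nrow(x$geno))
  if (is.character(individuals)) {
    individuals <- match(individuals, x$ind$individual_id)
    if (anyNA(individuals)) stop("unknown individual_id", call. = FALSE)
  }
  if (is.null(snps)) snps <- seq_len(ncol(x$geno))
  gen_dataset(x$geno[individuals, snps, drop = FALSE],
              x$snp[snps, ], x$ind[individuals, ], ploidy = x$ploidy)
}

#' Individuals belonging to a group label
#' @param x a `paleo_gen`
#' @param group group label (or vector of labels) to match against `ind$group`
#' @return integer row indices
#' @export
group_members <- function(x, group) {
  idx <- which(x$ind$group %in% group)
  if (!length(idx)) stop("no individuals carry group label '",
                         paste(group, collapse = ","), "'", call. = FALSE)
  idx
}

# sex codes used in .ind files
.sex_to_code <- c(male = "M", female = "F", unknown = "U")
.code_to_sex <- c(M = "male", F = "female", U = "unknown")

#' Read an EIGENSTRAT geno/snp/ind triple
#'
#' Plain-text EIGENSTRAT convention: the .geno file holds one row per SNP,
#' one character per individual, with `9` meaning missing; here the digits
#' count alternate alleles. The .snp file has columns snp_id, chromosome,
#' genetic position and physical position (plus optional ref/alt alleles);
#' genetic positions are interpreted as Morgans (this dialect is fixed, not
#' auto-detected). An optional metadata sidecar TSV adds cemetery labels,
#' date midpoints and exclusion flags.
#'
#' @param prefix path prefix; `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#'   are read, and `<prefix>.meta.tsv` if present.
#' @param ploidy passed to [gen_dataset()].
#' @return a `paleo_gen`
#' @export
read_eigenstrat <- function(prefix, ploidy = c("pseudohaploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  snp_cols <- c("snp_id", "chromosome", "genetic_position",
                "physical_position", "ref_allele", "alt_allele")
  if (file.size(paths[2]) == 0) {
    snp_raw <- stats::setNames(
      data.frame(character(), character(), numeric(), integer(),
                 character(), character()), snp_cols)
  } else {
    snp_raw <- utils::read.table(paths[2], header = FALSE,
                                 stringsAsFactors = FALSE, fill = TRUE)
    names(snp_raw) <- snp_cols[seq_len(ncol(snp_raw))]
  }
  snp <- tibble::tibble(
    snp_id = as.character(snp_raw$snp_id),
    chromosome = as.character(snp_raw$chromosome),
    genetic_position = as.numeric(snp_raw$genetic_position),
    physical_position = as.integer(snp_raw$physical_position),
    ref_allele = if ("ref_allele" %in% names(snp_raw)) as.character(snp_raw$ref_allele) else "A",
    alt_allele = if ("alt_allele" %in% names(snp_raw)) as.character(snp_raw$alt_allele) else "G"
  )

  ind_raw <- if (file.size(paths[3]) == 0) {
    data.frame(individual_id = character(), sex_code = character(),
               group = character())
  } else {
    utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("individual_id", "sex_code", "group"))
  }
  ind <- tibble::tibble(
    individual_id = as.character(ind_raw$individual_id),
    sex = unname(.code_to_sex[match(ind_raw$sex_code, names(.code_to_sex))]),
    group = as.character(ind_raw$group)
  )
  ind$sex[is.na(ind$sex)] <- "unknown"

  lines <- readLines(paths[1])
  lines <- lines[nzchar(lines)]
  if (length(lines) != nrow(snp)) {
    stop("dimension mismatch in ", paths[1], ": ", length(lines),
         " genotype rows but ", nrow(snp), " SNP records in ", paths[2],
         call. = FALSE)
  }
  widths <- nchar(lines)
  if (length(lines) && any(widths != nrow(ind))) {
    bad <- which(widths != nrow(ind))[1]
    stop("dimension mismatch in ", paths[1], " line ", bad, ": width ",
         widths[bad], " but ", nrow(ind), " individuals in ", paths[3],
         call. = FALSE)
  }
  geno <- matrix(NA_integer_, nrow = nrow(ind), ncol = nrow(snp))
  if (length(lines)) {
    chars <- matrix(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE),
                    nrow = nrow(ind))  # SNPs in columns
    ok <- chars %in% c("0", "1", "2", "9")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("unknown genotype character '", chars[bad], "' in ", paths[1],
           " line ", ((bad - 1) %/% nrow(ind)) + 1, call. = FALSE)
    }
    geno <- matrix(as.integer(chars), nrow = nrow(ind))
    geno[geno == 9L] <- NA_integer_
  }

  meta_path <- paste0(prefix, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    m <- match(ind$individual_id, meta$individual_id)
    if ("cemetery" %in% names(meta)) ind$cemetery <- as.character(meta$cemetery[m])
    if ("date_midpoint_ce" %in% names(meta)) ind$date_midpoint_ce <- as.numeric(meta$date_midpoint_ce[m])
    if ("exclude" %in% names(meta)) ind$exclude <- as.logical(meta$exclude[m])
    if ("group" %in% names(meta)) {
      grp <- as.character(meta$group[m])
      ind$group[!is.na(grp)] <- grp[!is.na(grp)]
    }
  }

  gen_dataset(geno, snp, ind, ploidy = ploidy)
}

#' Write an EIGENSTRAT geno/snp/ind triple (plus metadata sidecar)
#'
#' Missing genotypes are serialized as `9`. The written triple round-trips
#' through [read_eigenstrat()] to an identical dataset.
#'
#' @param x a `paleo_gen`
#' @param prefix output path prefix
#' @return invisibly, the vector of file paths written
#' @export
write_eigenstrat <- function(x, prefix) {
  stopifnot(inherits(x, "paleo_gen"))
  paths <- paste0(prefix, c(".geno", ".snp", ".ind", ".meta.tsv"))
  g <- x$geno
  g[is.na(g)] <- 9L
  lines <- if (ncol(g) == 0) character(0) else
    apply(g, 2, paste, collapse = "")  # one line per SNP
  writeLines(as.character(lines), paths[1])
  utils::write.table(
    data.frame(x$snp$snp_id, x$snp$chromosome,
               format(x$snp$genetic_position, digits = 10, scientific = FALSE, trim = TRUE),
               x$snp$physical_position, x$snp$ref_allele, x$snp$alt_allele),
    paths[2], quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(x$ind$individual_id, unname(.sex_to_code[x$ind$sex]), x$ind$group),
    paths[3], quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(individual_id = x$ind$individual_id, sex = x$ind$sex,
               group = x$ind$group, cemetery = x$ind$cemetery,
               date_midpoint_ce = x$ind$date_midpoint_ce, exclude = x$ind$exclude),
    paths[4], quote = FALSE, sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(paths)
}

#' Per-SNP allele frequencies for a group
#'
#' Frequencies are alternate-allele counts over called allele "slots": one
#' slot per called genotype for pseudo-haploid data, two for diploid. SNPs
#' where the group has no called slots get `NA` frequency and are flagged.
#'
#' @param x a `paleo_gen`
#' @param group group label (or vector pooled together)
#' @param chromosomes optional character vector restricting SNPs
#' @return tibble: `snp_id`, `chromosome`, `frequency`, `n_slots`, `usable`
#' @export
allele_frequencies <- function(x, group, chromosomes = NULL) {
  idx <- group_members(x, group)
  keep <- if (is.null(chromosomes)) rep(TRUE, nrow(x$snp)) else
    x$snp$chromosome %in% as.character(chromosomes)
  g <- x$geno[idx, keep, drop = FALSE]
  per_slot <- if (x$ploidy == "pseudohaploid") 1 else 2
  called <- colSums(!is.na(g))
  slots <- called * per_slot
  alt <- colSums(g, na.rm = TRUE) * (per_slot / 2)
  freq <- ifelse(slots > 0, alt / slots, NA_real_)
  tibble::tibble(snp_id = x$snp$snp_id[keep],
                 chromosome = x$snp$chromosome[keep],
                 frequency = unname(freq), n_slots = as.integer(unname(slots)),
                 usable = unname(slots > 0))
}

#' Split a dataset into autosomal and X compartments
#'
#' @param x a `paleo_gen`
#' @return named list with elements `autosomes` and `X`, each a `paleo_gen`
#'   (possibly with zero SNPs)
#' @export
partition_compartments <- function(x) {
  stopifnot(inherits(x, "paleo_gen"))
  is_x <- x$snp$chromosome == "23"
  list(autosomes = gen_subset(x, snps = which(!is_x)),
       X = gen_subset(x, snps = which(is_x)))
}

# Internal: frequency matrices for several populations at once.
# Returns list(freq = SNPs x pops, slots = SNPs x pops). `pops` is a named
# list mapping population name -> integer individual indices.
pop_freq_matrix <- function(x, pops) {
  per_slot <- if (x$ploidy == "pseudohaploid") 1 else 2
  S <- ncol(x$geno)
  freq <- matrix(NA_real_, S, length(pops), dimnames = list(NULL, names(pops)))
  slots <- matrix(0L, S, length(pops), dimnames = list(NULL, names(pops)))
  for (j in seq_along(pops)) {
    g <- x$geno[pops[[j]], , drop = FALSE]
    called <- .colSums(!is.na(g), nrow(g), S)
    gg <- g
    gg[is.na(gg)] <- 0L
    alt <- .colSums(gg, nrow(g), S) * (per_slot / 2)
    sl <- called * per_slot
    freq[, j] <- ifelse(sl > 0, alt / sl, NA_real_)
    slots[, j] <- as.integer(sl)
  }
  list(freq = freq, slots = slots)
}
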
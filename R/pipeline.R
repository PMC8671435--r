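#' Run the simulate-analyze-report pipeline
#'
#' Orchestrates a reproducible end-to-end run on synthetic data: cohort
#' simulation, kinship classification and the cross-cemetery table,
#' admixture f3, cemetery clade f4 scan and FST, qpAdm-style fits with the
#' X-vs-autosome sex-bias decomposition, qpWave-style cemetery clade test,
#' admixture dating, and (optionally) projection PCA. One seed governs all
#' stages; per-stage seeds are derived deterministically. Outputs are
#' returned as a named list and, if `out_dir` is given, written as JSON and
#' TSV files plus a run log recording parameters and a config hash.
#'
#' @param config a named list, or path to a YAML file, with optional blocks
#'   `simulation` (arguments to [sim_config()]; `seed` mandatory) and
#'   `analysis` (fields `block_size`, `f3_z_threshold`,
#'   `outlier_z_threshold`, `min_overlap`, `binsize`, `maxdis`,
#'   `start_distance`, `generation_time`, `midpoint_ce`, `run_pca`)
#' @param out_dir optional output directory
#' @return a list of stage results (invisible when writing to `out_dir`)
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulation", "analysis")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sim_args <- config$simulation %||% list()
  bad_sim <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad_sim)) stop("unknown simulation key(s): ",
                            paste(bad_sim, collapse = ", "), call. = FALSE)
  ana <- utils::modifyList(
    list(block_size = 0.05, f3_z_threshold = 7.5, outlier_z_threshold = 5,
         min_overlap = 100, binsize = 0.001, maxdis = 0.5,
         start_distance = 0.0045, generation_time = 28, midpoint_ce = 810,
         run_pca = FALSE),
    config$analysis %||% list())

  cfg <- do.call(sim_config, sim_args)
  study <- simulate_study(cfg)
  x <- study$data
  blocks <- make_blocks(x, ana$block_size)
  refs <- c("Out1", "Out2", "Out3", "Out4")

  message("stage: kinship")
  kin <- tryCatch({
    pm <- pairwise_mismatch(x, individuals = which(x$ind$group == "Target"),
                            min_overlap = ana$min_overlap)
    cls <- classify_degrees(pm)
    cem <- stats::setNames(x$ind$cemetery, x$ind$individual_id)
    list(pairs = cls$pairs, baseline = cls$baseline,
         table1 = cross_cemetery_test(cls$pairs, cem))
  }, error = function(e) stop("stage 'kinship' failed: ", conditionMessage(e),
                              call. = FALSE))

  message("stage: fstats")
  fst_stage <- tryCatch({
    cem_r <- which(x$ind$cemetery == "R" & x$ind$group == "Target")
    cem_s <- which(x$ind$cemetery == "S" & x$ind$group == "Target")
    list(
      f3 = f3_admixture_test(x, "Target", "Source1", "Source2", blocks = blocks),
      outliers = f4_outlier_scan(x, "Source1", "Source2", "Target",
                                 z_threshold = ana$outlier_z_threshold,
                                 blocks = blocks),
      clade_scan = clade_f4_scan(x, "Source1", c("Source2", "Out2"),
                                 cem_r, cem_s, blocks = blocks),
      fst_cemeteries = fst_hudson(x, cem_r, cem_s, blocks = blocks))
  }, error = function(e) stop("stage 'fstats' failed: ", conditionMessage(e),
                              call. = FALSE))

  message("stage: qpadm")
  qp <- tryCatch({
    auto <- partition_compartments(x)$autosomes
    fit <- fit_qpadm(build_f4_system(auto, "Target", c("Source1", "Source2"),
                                     refs, blocks = make_blocks(auto, ana$block_size)))
    sb <- estimate_sex_bias(x, "Target", c("Source1", "Source2"), refs,
                            we_source = "Source2", block_size = ana$block_size)
    cem_r <- which(x$ind$cemetery == "R" & x$ind$group == "Target")
    cem_s <- which(x$ind$cemetery == "S" & x$ind$group == "Target")
    clade <- qpwave_clade_test(auto, cem_r, cem_s, refs,
                               blocks = make_blocks(auto, ana$block_size))
    list(fit = fit, sex_bias = sb, cemetery_clade = clade)
  }, error = function(e) stop("stage 'qpadm' failed: ", conditionMessage(e),
                              call. = FALSE))

  message("stage: dating")
  dating <- tryCatch({
    auto <- partition_compartments(x)$autosomes
    date_estimate(auto, "Target", "Source1", "Source2",
                  binsize = ana$binsize, maxdis = ana$maxdis,
                  start_distance = ana$start_distance,
                  generation_time = ana$generation_time,
                  midpoint_ce = ana$midpoint_ce)
  }, error = function(e) stop("stage 'dating' failed: ", conditionMessage(e),
                              call. = FALSE))

  pca <- NULL
  if (isTRUE(ana$run_pca)) {
    message("stage: pca")
    pca <- tryCatch({
      fitp <- fit_pca(x, c("Source1", "Source2", "Out3"), n_components = 4)
      list(fit = fitp,
           projected = pca_project(fitp, x, "Target", min_snps = ana$min_overlap))
    }, error = function(e) stop("stage 'pca' failed: ", conditionMessage(e),
                                call. = FALSE))
  }

  report <- list(
    config_hash = rlang::hash(config),
    seed = cfg$seed,
    table1 = kin$table1,
    admixture_f3 = fst_stage$f3,
    n_outliers = sum(fst_stage$outliers$outlier, na.rm = TRUE),
    cemetery_clade_f4 = fst_stage$clade_scan$consistent_with_clade,
    fst_cemeteries = fst_stage$fst_cemeteries$estimate,
    qpadm_weights = qp$fit$weights,
    qpadm_p = qp$fit$p_value,
    sex_bias = qp$sex_bias$decomposition,
    cemetery_clade_p = qp$cemetery_clade$p_value,
    date_generations = dating$generations,
    date_se = dating$std_error)

  out <- list(config = config, study = study, kinship = kin,
              fstats = fst_stage, qpadm = qp, dating = dating, pca = pca,
              report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      c(report[c("config_hash", "seed")],
        list(table1 = kin$table1,
             sex_bias = qp$sex_bias$decomposition,
             qpadm_weights = as.list(qp$fit$weights),
             qpadm_p = qp$fit$p_value,
             cemetery_clade_p = qp$cemetery_clade$p_value,
             fst_cemeteries = fst_stage$fst_cemeteries$estimate,
             n_outliers = report$n_outliers,
             date_generations = dating$generations,
             date_se = dating$std_error)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(kin$table1, file.path(out_dir, "table1.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tidy(qp$sex_bias), file.path(out_dir, "sex_bias.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(paste("paleostrat run", format(Sys.time())),
                 paste("seed:", cfg$seed),
                 paste("config hash:", report$config_hash),
                 utils::capture.output(utils::str(ana))),
               file.path(out_dir, "run.log"))
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
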
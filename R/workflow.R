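#' Run the full single-step evaluation workflow
#'
#' Orchestrates the complete analysis from a configuration: load (or
#' simulate) the data, run SNP quality control, build the relationship
#' matrices, estimate heritability per trait under the pedigree model
#' and the single-step model across the tau grid, and run both
#' leave-one-family-out cross-validation schemes. Returns a report
#' bundle and optionally writes JSON and text-table renderings.
#'
#' @param config a list, or the path to a YAML file, with entries:
#'   \describe{
#'     \item{pedigree, genotypes, phenotypes}{input file paths
#'       (see [read_pedigree], [read_genotypes]); alternatively
#'       `simulate` = a list of [sim_config] overrides to generate the
#'       data in place.}
#'     \item{traits}{trait labels to analyse (default: all in the
#'       phenotype table).}
#'     \item{qc}{list: `call_rate_min`, `maf_min`, `r2_max`.}
#'     \item{h_matrix}{list: `alpha`, `beta`, `tau_grid`.}
#'     \item{cv}{list: `genotyped`, `nongenotyped` (logical toggles),
#'       `refit_varcomp`.}
#'     \item{out_dir}{optional output directory for `report.json` and
#'       `report.txt`.}
#'     \item{seed}{integer seed for anything stochastic.}
#'   }
#' @return an `ssgblup_report`: list with `qc`, `heritability` (data
#'   frame: trait, method, tau, sigma_u2, sigma_e2, h2),
#'   `cv_genotyped`, `cv_nongenotyped` (data frames with r and SE per
#'   model), `best_tau` per trait, and `log` (stage messages).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }

  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config_small,
                   utils::modifyList(list(seed = seed),
                                     as.list(config$simulate)))
    say("simulating population (seed %d)", cfg$seed)
    data <- simulate_population(cfg)
  } else {
    for (f in c("pedigree", "genotypes", "phenotypes"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("config$", f, " must point to an existing file")
    ped <- read_pedigree(config$pedigree,
                         unknown_code = config$unknown_code %||% "0")
    g <- read_genotypes(config$genotypes)
    ph <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
    data <- gs_dataset(ped, g, ph)
  }
  say("data: %d individuals, %d genotyped, %d records",
      nrow(data$ped), length(data$genotyped_ids), nrow(data$pheno))

  qc_cfg <- config$qc %||% list()
  qc <- qc_genotypes(data$genotypes, data$ped,
                     call_rate_min = qc_cfg$call_rate_min %||% 0.80,
                     maf_min = qc_cfg$maf_min %||% 0.01,
                     r2_max = qc_cfg$r2_max %||% 0.99)
  data$genotypes <- qc$genotypes
  data$genotyped_ids <- rownames(qc$genotypes)
  say("QC: %d -> %d loci (call rate %d, MAF %d, correlated %d removed)",
      qc$report$n_loci_in, qc$report$n_loci_out,
      qc$report$removed[["call_rate"]], qc$report$removed[["maf"]],
      qc$report$removed[["correlated"]])

  hm <- config$h_matrix %||% list()
  alpha <- hm$alpha %||% 0.95
  beta <- hm$beta %||% 0.05
  tau_grid <- as.numeric(hm$tau_grid %||% c(1, 0.75, 0.5))
  if (!length(tau_grid)) stop("tau grid must be non-empty")
  traits <- config$traits %||% unique(data$pheno$trait)

  mats <- cv_matrices(data, alpha, beta)
  say("relationship matrices built (%d individuals, %d genotyped)",
      nrow(mats$A), nrow(mats$A22))

  herit <- NULL
  for (tr in traits) {
    fa <- fit_blup(data$pheno, tr, mats$A, kernel_inv = mats$A_inv,
                   method = "ABLUP")
    herit <- rbind(herit, data.frame(trait = tr, method = "ABLUP",
                                     tau = NA_real_,
                                     sigma_u2 = fa$vc$sigma_u2,
                                     sigma_e2 = fa$vc$sigma_e2,
                                     h2 = fa$vc$h2))
    for (tau in tau_grid) {
      k <- ss_kernel(mats$A, mats$A_inv, mats$G_star, mats$A22,
                     h_params(alpha, beta, tau))
      fh <- fit_blup(data$pheno, tr, k$K, kernel_inv = k$K_inv,
                     method = "ssGBLUP")
      herit <- rbind(herit, data.frame(trait = tr, method = "ssGBLUP",
                                       tau = tau,
                                       sigma_u2 = fh$vc$sigma_u2,
                                       sigma_e2 = fh$vc$sigma_e2,
                                       h2 = fh$vc$h2))
    }
    say("heritability, trait %s: done", tr)
  }

  cv_cfg <- config$cv %||% list()
  refit <- cv_cfg$refit_varcomp %||% TRUE
  do_gen <- cv_cfg$genotyped %||% TRUE
  do_non <- cv_cfg$nongenotyped %||% TRUE

  cv_gen_tab <- NULL; cv_non_tab <- NULL
  best <- stats::setNames(rep(tau_grid[1L], length(traits)), traits)
  cv_gen_all <- list(); cv_non_all <- list()
  if (do_gen) {
    for (tr in traits) {
      cvg <- cv_genotyped(data, tr, tau_grid = tau_grid, alpha = alpha,
                          beta = beta, refit_varcomp = refit)
      cv_gen_all[[tr]] <- cvg
      for (m in cvg)
        cv_gen_tab <- rbind(cv_gen_tab,
                            data.frame(trait = tr, model = m$model,
                                       r = m$r, se = m$se, n = m$n))
      best[tr] <- best_tau(cvg)
      say("genotyped CV, trait %s: best tau = %.2f", tr, best[tr])
    }
  }
  if (do_non) {
    for (tr in traits) {
      cvn <- cv_nongenotyped(data, tr, tau = best[tr], alpha = alpha,
                             beta = beta, refit_varcomp = refit)
      cv_non_all[[tr]] <- cvn
      for (m in cvn)
        cv_non_tab <- rbind(cv_non_tab,
                            data.frame(trait = tr, model = m$model,
                                       tau = m$tau, r = m$r, se = m$se,
                                       n_families = m$n))
      say("non-genotyped CV, trait %s: done", tr)
    }
  }

  report <- structure(list(qc = qc$report, heritability = herit,
                           cv_genotyped = cv_gen_tab,
                           cv_nongenotyped = cv_non_tab,
                           cv_genotyped_detail = cv_gen_all,
                           cv_nongenotyped_detail = cv_non_all,
                           best_tau = best, seed = seed, log = log),
                      class = "ssgblup_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a report bundle to disk
#'
#' @param report an `ssgblup_report` from [run_analysis].
#' @param dir output directory; receives `report.json` (machine
#'   readable) and `report.txt` (rendered tables).
#' @return invisibly, the file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "report.json")
  tpath <- file.path(dir, "report.txt")
  jsonlite::write_json(list(
    seed = report$seed,
    qc = list(n_loci_in = report$qc$n_loci_in,
              n_loci_out = report$qc$n_loci_out,
              removed = as.list(report$qc$removed),
              n_mendelian_blanked = report$qc$n_mendelian_blanked,
              n_imputed = report$qc$n_imputed),
    heritability = report$heritability,
    cv_genotyped = report$cv_genotyped,
    cv_nongenotyped = report$cv_nongenotyped,
    best_tau = as.list(report$best_tau),
    log = report$log
  ), jpath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, tpath)
  invisible(c(jpath, tpath))
}

#' @export
print.ssgblup_report <- function(x, ...) {
  cat("Single-step genomic evaluation report\n")
  cat("=====================================\n\n")
  print(x$qc)
  cat("\nHeritability estimates\n")
  print(x$heritability, row.names = FALSE, digits = 4)
  if (!is.null(x$cv_genotyped)) {
    cat("\nGenotyped-individual CV accuracy\n")
    print(x$cv_genotyped, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$cv_nongenotyped)) {
    cat("\nNon-genotyped-family CV accuracy (weighted)\n")
    print(x$cv_nongenotyped, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
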
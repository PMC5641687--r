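# End-to-end orchestration of the study replication on synthetic data:
# simulate -> QC -> invariance ladder -> association (FDR) -> power.

#' Pipeline configuration
#'
#' @param n_male,n_female cohort sizes (study conventions 1160/1180).
#' @param sexes which strata to analyse.
#' @param traits traits to simulate and analyse.
#' @param beta_cross,beta_change injected standardised genetic effects
#'   (male study conventions by default; females default to null effects).
#' @param power_reps Monte Carlo replicates in the power stage (the study
#'   convention is 1000; smaller values give faster demonstration runs).
#' @param power_effects latent-approach effect sizes evaluated in the
#'   power stage.
#' @param run_invariance,run_power stage switches.
#' @param seed master seed; every stage derives its randomness from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_male = 1160, n_female = 1180,
                            sexes = c("male", "female"),
                            traits = c("extraversion", "neuroticism"),
                            beta_cross = c(extraversion = -0.167,
                                           neuroticism = 0),
                            beta_change = c(extraversion = 0.197,
                                            neuroticism = 0),
                            power_reps = 250,
                            power_effects = c(0.028, 0.039),
                            run_invariance = TRUE, run_power = TRUE,
                            seed = 1L) {
  structure(list(n_male = n_male, n_female = n_female, sexes = sexes,
                 traits = traits, beta_cross = beta_cross,
                 beta_change = beta_change, power_reps = power_reps,
                 power_effects = power_effects,
                 run_invariance = run_invariance, run_power = run_power,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$beta_cross <- unlist(y$beta_cross)
  y$beta_change <- unlist(y$beta_change)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: cohort simulation per sex, genotype/item QC,
#' the longitudinal measurement-invariance ladder, the latent genetic
#' association models (cross-sectional and latent change, BH-FDR over the
#' full 2-sex x 2-trait x 3-phenotype family), and Monte Carlo power.
#' A stage failure is recorded in the manifest and downstream stages are
#' skipped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; result tables are written as TSV.
#' @return list of class `pipeline_run` with `manifest` (stage status
#'   tibble) and `results`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  manifest <- list(); results <- list()
  failed <- FALSE
  t_total <- Sys.time()
  record <- function(stage, status, elapsed, outputs = NA_character_) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, status = status, elapsed_s = round(elapsed, 2),
      outputs = outputs)
  }
  stage <- function(name, enabled, fun) {
    if (failed) { record(name, "skipped", 0); return(invisible(NULL)) }
    if (!enabled) { record(name, "disabled", 0); return(invisible(NULL)) }
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) e)
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(out, "error")) {
      failed <<- TRUE
      record(name, paste("failed:", conditionMessage(out)), el)
      return(invisible(NULL))
    }
    record(name, "ok", el)
    results[[name]] <<- out
    invisible(out)
  }

  stage("simulate", TRUE, function() {
    cohorts <- list()
    for (sx in config$sexes) {
      cfg <- sim_config(sex = sx,
                        n = if (sx == "male") config$n_male else
                          config$n_female,
                        traits = config$traits,
                        beta_cross = if (sx == "male") config$beta_cross else
                          c(extraversion = 0, neuroticism = 0),
                        beta_change = if (sx == "male") config$beta_change
                        else c(extraversion = 0, neuroticism = 0),
                        seed = config$seed + match(sx, c("male", "female")))
      cohorts[[sx]] <- generate_full_study(cfg)
    }
    cohorts
  })

  stage("qc", TRUE, function() {
    lapply(results$simulate, function(ch) qc_report(ch$geno, ch$items))
  })

  stage("invariance", config$run_invariance, function() {
    lapply(results$simulate, function(ch) run_invariance(ch$items))
  })

  stage("association", TRUE, function() {
    trait_items <- function(ch, tr) {
      ch$config$items$item[ch$config$items$trait == tr]
    }
    rows <- list()
    for (sx in names(results$simulate)) {
      ch <- results$simulate[[sx]]
      traits <- stats::setNames(
        lapply(config$traits, function(tr) trait_items(ch, tr)),
        config$traits)
      res <- run_association(ch$geno, ch$items, traits, ch$config$snps$snp,
                             family_size = length(config$sexes) *
                               length(config$traits) * 3)
      rows[[sx]] <- res
    }
    out <- dplyr::bind_rows(rows)
    # re-adjust over the combined family
    out$fdr_p <- fdr_adjust(out$p, family_size = max(nrow(out), 12))
    assoc_result(out)
  })

  stage("power", config$run_power, function() {
    rows <- list()
    for (ev in config$power_effects) {
      sc <- power_scenario("latent", "cross_sectional", ev,
                           n = config$n_male, reps = config$power_reps,
                           seed = config$seed + 900000L)
      rows[[length(rows) + 1]] <- run_power(sc)
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("power_result", class(out))
    out
  })

  manifest <- dplyr::bind_rows(manifest)
  run <- structure(list(manifest = manifest, results = results,
                        config = config,
                        elapsed_s = as.numeric(difftime(Sys.time(), t_total,
                                                        units = "secs"))),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$manifest, file.path(out_dir, "manifest.tsv"))
  res <- run$results
  if (!is.null(res$qc)) {
    for (sx in names(res$qc)) {
      write_qc_report(res$qc[[sx]], file.path(out_dir, paste0("qc_", sx)))
    }
  }
  if (!is.null(res$invariance)) {
    inv <- dplyr::bind_rows(lapply(names(res$invariance), function(sx) {
      dplyr::mutate(res$invariance[[sx]]$summary, sex = sx)
    }))
    readr::write_tsv(inv, file.path(out_dir, "invariance.tsv"))
  }
  if (!is.null(res$association)) {
    readr::write_tsv(tibble::as_tibble(res$association),
                     file.path(out_dir, "association.tsv"))
  }
  if (!is.null(res$power)) {
    readr::write_tsv(tibble::as_tibble(res$power),
                     file.path(out_dir, "power.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (", round(x$elapsed_s, 1), " s)\n", sep = "")
  print(x$manifest)
  invisible(x)
}
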
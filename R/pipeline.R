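# End-to-end orchestration: simulate -> preprocess -> synchrony -> surrogate
# -> behavior -> outcomes -> models -> mediation, with plain-file stage
# outputs and a run manifest.

#' Default pipeline configuration
#'
#' @param n_dyads_per_condition dyads per cell.
#' @param seed master seed.
#' @param ... overrides forwarded to \code{\link{sim_config}}.
#' @return List with \code{simulation} (a \code{sim_config}),
#'   \code{structural} (a \code{structural_params}), \code{surrogate}
#'   settings and analysis options.
#' @export
pipeline_config <- function(n_dyads_per_condition = 2, seed = 1L, ...) {
  list(
    simulation = sim_config(n_dyads_per_condition = n_dyads_per_condition,
                            seed = seed, ...),
    structural = structural_params(),
    surrogate = list(n_surrogates = 10, roi_pairs = NULL),
    analysis = list(intervals_per_phase = 2, min_period_s = 8,
                    voices_per_octave = 12, signal = "hbo",
                    mcmc_chains = 4, mcmc_iterations = 1000),
    seed = as.integer(seed)
  )
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks: band vs phase durations, positive rates,
#' seed presence. Returns (and optionally prints) a diagnostics list; errors
#' are raised for violations, warnings collected for soft issues.
#'
#' @param config list as from \code{\link{pipeline_config}}, or a path to a
#'   JSON file with the same structure.
#' @return Invisibly, a list with \code{errors} (character) and
#'   \code{warnings}; an error is thrown when \code{errors} is nonempty.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg$simulation$phase_plan <- as.data.frame(cfg$simulation$phase_plan)
    sim_args <- cfg$simulation[intersect(names(cfg$simulation),
                                         names(formals(sim_config)))]
    config <- pipeline_config(seed = cfg$seed %||% 1L)
    config$simulation <- do.call(sim_config, sim_args)
  }
  errs <- character(0)
  warns <- character(0)
  sim <- config$simulation
  if (is.null(sim)) errs <- c(errs, "/simulation: missing")
  if (!is.null(sim)) {
    if (any(sim$coupling_period_band_s[2] > sim$phase_plan$duration_s / 4))
      errs <- c(errs, "/simulation/coupling_period_band_s: upper bound exceeds duration/4")
    if (any(sim$coupling_strength < 0 | sim$coupling_strength > 1))
      errs <- c(errs, "/simulation/coupling_strength: outside [0,1]")
  }
  if (is.null(config$seed)) {
    warns <- c(warns, "/seed: missing; auto-seed 1 recorded")
    config$seed <- 1L
  }
  if (length(errs)) stop_input(paste(errs, collapse = "; "))
  invisible(list(errors = errs, warnings = warns, config = config))
}

#' Run the analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order, writing each stage's output as CSV/JSON
#' under \code{out_dir} together with a manifest (seeds, counts, file
#' checksums). A subset of stages can be run when the upstream outputs are
#' already present in \code{out_dir}.
#'
#' @param config list from \code{\link{pipeline_config}} (validated).
#' @param out_dir output directory.
#' @param stages character subset of \code{c("simulate", "synchrony",
#'   "surrogate", "behavior", "outcomes", "models", "mediate")}.
#' @return The manifest (invisibly), with stage results attached as
#'   attribute \code{"results"}.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         stages = c("simulate", "synchrony", "surrogate",
                                    "behavior", "outcomes", "models",
                                    "mediate")) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis
  manifest <- list(seed = config$seed, stages = stages, files = list(),
                   counts = list())
  res <- list()
  need <- function(stage, value, maker) {
    if (!is.null(value)) return(value)
    stop_input("stage '", stage, "' needs upstream output; run stage '",
               maker, "' first")
  }
  save_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    write.csv(df, f, row.names = FALSE)
    manifest$files[[name]] <<- unname(tools::md5sum(f))
    f
  }

  cohort <- NULL
  if ("simulate" %in% stages) {
    cohort <- generate_cohort(config$simulation, config$structural)
    res$cohort <- cohort
    save_csv(cohort$ground_truth, "ground_truth.csv")
    save_csv(cohort$outcomes, "outcomes_raw.csv")
    f <- file.path(out_dir, "annotations.tsv")
    write.table(cohort$annotations, f, sep = "\t", row.names = FALSE,
                quote = FALSE)
    manifest$files[["annotations.tsv"]] <- unname(tools::md5sum(f))
    manifest$counts$dyads <- length(cohort$recordings)
  }

  if ("synchrony" %in% stages) {
    cohort <- need("synchrony", cohort, "simulate")
    syn <- do.call(rbind, lapply(cohort$recordings, dyad_synchrony,
                                 intervals_per_phase = an$intervals_per_phase,
                                 min_period_s = an$min_period_s,
                                 voices_per_octave = an$voices_per_octave,
                                 signal = an$signal))
    res$synchrony <- syn
    save_csv(syn, "synchrony.csv")
    manifest$counts$synchrony_rows <- nrow(syn)
  }

  if ("surrogate" %in% stages) {
    cohort <- need("surrogate", cohort, "simulate")
    plan <- surrogate_plan(n_surrogates = config$surrogate$n_surrogates,
                           seed = substream_seed(config$seed, 777L))
    sur <- pseudo_dyad_table(cohort$recordings, plan,
                             roi_pairs = config$surrogate$roi_pairs,
                             intervals_per_phase = an$intervals_per_phase,
                             min_period_s = an$min_period_s,
                             voices_per_octave = an$voices_per_octave,
                             signal = an$signal)
    res$surrogate <- sur
    save_csv(sur, "surrogate.csv")
    if (!is.null(res$synchrony)) {
      cmp <- lapply(unique(sur$roi_pair), function(pp) {
        rv <- real_vs_surrogate(
          res$synchrony$wtc_value[res$synchrony$roi_pair == pp],
          sur$wtc_value[sur$roi_pair == pp],
          priors = synchrony_priors(),
          chains = an$mcmc_chains, iterations = an$mcmc_iterations,
          seed = substream_seed(config$seed, 778L))
        list(roi_pair = pp, difference = as.list(rv$difference))
      })
      jsonlite::write_json(cmp, file.path(out_dir, "real_vs_surrogate.json"),
                           auto_unbox = TRUE, digits = NA)
      res$real_vs_surrogate <- cmp
    }
  }

  behavior <- NULL
  if ("behavior" %in% stages) {
    cohort <- need("behavior", cohort, "simulate")
    behavior <- dyad_behavior(cohort$annotations,
                              config$simulation$phase_plan,
                              dyad_ids = cohort$ground_truth$dyad_id)
    res$behavior <- behavior
    save_csv(behavior, "behavior.csv")
  }

  dyads <- NULL
  if ("outcomes" %in% stages) {
    cohort <- need("outcomes", cohort, "simulate")
    scored <- score_outcomes(cohort$outcomes)
    res$scored_outcomes <- scored
    save_csv(scored, "outcomes_scored.csv")
    syn <- need("outcomes", res$synchrony, "synchrony")
    behavior <- need("outcomes", behavior, "behavior")
    dyads <- build_dyad_dataset(scored, syn, behavior, cohort$ground_truth)
    res$dyad_dataset <- dyads
    save_csv(dyads, "dyad_dataset.csv")
    manifest$counts$dyad_rows <- nrow(dyads)
  }

  if ("models" %in% stages) {
    dyads <- need("models", dyads, "outcomes")
    dd <- dyads
    dd$liking1_c <- grand_mean_center(dd$liking1_sum)
    models <- list()
    for (oc in c("liking2_sum", "ios_sum", "money_ratio_sum", "help_ratio_sum")) {
      full <- stats::as.formula(paste(oc, "~ laughter + social + lbmp + lbfi",
                                      if (oc == "liking2_sum") "+ liking1_c"))
      bf_laughter <- bayes_factor(
        full, stats::update(full, . ~ . - laughter), dd, method = "marginal")
      models[[oc]] <- list(outcome = oc, bf10_laughter = bf_laughter$bf10)
    }
    res$models <- models
    jsonlite::write_json(models, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("mediate" %in% stages) {
    dyads <- need("mediate", dyads, "outcomes")
    dd <- dyads
    dd$laughter_num <- as.numeric(dd$laughter == "yes")
    dd$social_num <- as.numeric(dd$social == "yes")
    med_cols <- grep("^syn_", names(dd), value = TRUE)
    grid <- mediation_grid(dd, treatments = "laughter_num",
                           mediator_columns = med_cols,
                           outcomes = c("liking2_sum", "ios_sum"),
                           covariates = "social_num",
                           seed = substream_seed(config$seed, 779L))
    res$mediation <- grid
    save_csv(grid, "mediation.csv")
  }

  manifest$counts$files <- length(manifest$files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- res
  invisible(manifest)
}
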
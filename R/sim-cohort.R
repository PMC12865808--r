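# Assemble a full synthetic cohort: recordings, annotations, outcomes, truth.

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a complete synthetic cohort
#'
#' Produces, for \code{4 * n_dyads_per_condition} dyads balanced over the 2x2
#' design (Laughter x Social), (i) a \code{dyad_recording} with the cell's
#' coupling strength, (ii) laughter annotation tracks per phase, (iii) a
#' per-participant outcome table (Liking items at two time points, IOS,
#' money and helping items), and (iv) a ground-truth table with the condition
#' labels, the realized coupling, the realized dyad-union laughter totals and
#' the noise-free structural values. The dyad's coupling
#' \eqn{\kappa = \mathrm{clip}_{[0,1]}(\kappa_{cell} + a T + e)} doubles as
#' the true mediator passed to the outcome generator, so the
#' treatment -> synchrony -> outcome chain is physically realized in the
#' signals whenever \code{a_path} or the cell couplings are nonzero.
#'
#' All randomness derives from \code{config$seed} through documented
#' substreams, so identical configurations reproduce identical cohorts.
#'
#' @param config a \code{\link{sim_config}}.
#' @param sp a \code{\link{structural_params}}.
#' @return List with \code{recordings} (list of \code{dyad_recording}),
#'   \code{annotations} (long data frame: dyad_id, participant, tier,
#'   onset_s, offset_s), \code{outcomes} (per-participant table),
#'   \code{ground_truth} (per-dyad table) and \code{seeds} (manifest).
#' @export
generate_cohort <- function(config, sp = structural_params()) {
  cells <- condition_cells()
  n_per <- config$n_dyads_per_condition
  cell_of <- rep(cells, each = n_per)
  n_dyads <- length(cell_of)
  treatment <- as.numeric(substr(cell_of, 1, 1) == "L") # Laughter yes/no
  social <- as.numeric(grepl("_S$", cell_of))

  # dyad-level coupling: cell baseline + a-path shift, clipped to [0, 1]
  kappa_cell <- unname(config$coupling_strength[cell_of])
  kappa_dyad <- with_seed(substream_seed(config$seed, 900001L),
    clip01(kappa_cell + sp$a_path * treatment +
             rnorm(n_dyads, 0, sp$sd_mediator_noise)))

  recordings <- vector("list", n_dyads)
  ann <- list()
  seeds <- list(master = config$seed)
  for (d in seq_len(n_dyads)) {
    recordings[[d]] <- generate_dyad_timeseries(config, d, kappa_dyad[d])
    seeds[[sprintf("recording_%03d", d)]] <- substream_seed(config$seed, d)
    for (i in seq_len(nrow(config$phase_plan))) {
      ph <- config$phase_plan$phase[i]
      s <- substream_seed(config$seed, 10000L + d * 10L + i)
      seeds[[sprintf("bouts_%03d_%s", d, ph)]] <- s
      tr <- generate_laughter_bouts(config, cell_of[d], ph, s)
      for (p in c("A", "B")) {
        if (nrow(tr[[p]]) > 0)
          ann[[length(ann) + 1]] <- data.frame(
            dyad_id = recordings[[d]]$dyad_id,
            participant = paste0(recordings[[d]]$dyad_id, "_", p),
            tier = "laughter",
            onset_s = tr[[p]]$onset_s,
            offset_s = tr[[p]]$offset_s
          )
      }
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(dyad_id = character(0), participant = character(0),
               tier = character(0), onset_s = numeric(0), offset_s = numeric(0))

  out_seed <- substream_seed(config$seed, 900002L)
  seeds$outcomes <- out_seed
  dyad_out <- generate_outcomes(sp, treatment, mediator = kappa_dyad,
                                seed = out_seed)
  outcomes <- participant_outcomes(dyad_out,
                                   dyad_ids = vapply(recordings, `[[`, "",
                                                     "dyad_id"),
                                   seed = substream_seed(config$seed, 900003L))

  tl <- phase_timeline(config$phase_plan)
  truth <- data.frame(
    dyad_id = vapply(recordings, `[[`, "", "dyad_id"),
    cell = cell_of,
    laughter = ifelse(treatment == 1, "yes", "no"),
    social = ifelse(social == 1, "yes", "no"),
    kappa_cell = kappa_cell,
    kappa = kappa_dyad,
    mediator_true = kappa_dyad,
    liking_raw = dyad_out$liking_raw,
    bonding_raw = dyad_out$bonding_raw,
    money_raw = dyad_out$money_raw,
    help_raw = dyad_out$help_raw
  )
  for (i in seq_len(nrow(tl))) {
    ph <- tl$phase[i]
    win <- phase_window(ph, tl)
    tot <- vapply(seq_len(n_dyads), function(d) {
      a <- annotations[annotations$dyad_id == truth$dyad_id[d] &
                         endsWith(annotations$participant, "_A"), ]
      b <- annotations[annotations$dyad_id == truth$dyad_id[d] &
                         endsWith(annotations$participant, "_B"), ]
      ai <- assign_to_phase(a[, c("onset_s", "offset_s")], list(win))[[ph]]
      bi <- assign_to_phase(b[, c("onset_s", "offset_s")], list(win))[[ph]]
      dyad_union(ai, bi)$total_s
    }, 0)
    truth[[paste0("laughter_total_", ph, "_s")]] <- tot
  }

  list(recordings = recordings, annotations = annotations,
       outcomes = outcomes, ground_truth = truth, seeds = seeds,
       config = config, structural = sp)
}

# Expand dyad-level raw outcomes into per-participant questionnaire rows.
participant_outcomes <- function(dyad_out, dyad_ids, seed) {
  n <- nrow(dyad_out)
  with_seed(seed, {
    rows <- list()
    for (d in seq_len(n)) {
      for (p in c("A", "B")) {
        l1 <- clip(rnorm(1, 5.9, 1.0), 0, 8)
        l2 <- clip(0.7 * l1 + 0.3 * 5.9 + dyad_out$liking_raw[d] +
                     rnorm(1, 0, 0.4), 0, 8)
        liking1 <- round(clip(l1 + rnorm(3, 0, 0.7), 0, 8))
        liking2 <- round(clip(l2 + rnorm(3, 0, 0.7), 0, 8))
        ios <- round(clip(2.6 + dyad_out$bonding_raw[d] + rnorm(1, 0, 0.8), 1, 7))
        friend <- round(clip(rnorm(1, 15, 6), 0, 30))
        mr <- clip01(0.6 + 0.25 * dyad_out$money_raw[d] + rnorm(1, 0, 0.1))
        other <- round(clip(mr * friend, 0, 30))
        hg <- sample(3:4, 1)
        hr <- clip01(0.85 + 0.1 * dyad_out$help_raw[d] + rnorm(1, 0, 0.1))
        ho <- max(1, round(hr * hg))
        rows[[length(rows) + 1]] <- data.frame(
          dyad_id = dyad_ids[d],
          participant = paste0(dyad_ids[d], "_", p),
          liking1_1 = liking1[1], liking1_2 = liking1[2], liking1_3 = liking1[3],
          liking2_1 = liking2[1], liking2_2 = liking2[2], liking2_3 = liking2[3],
          ios = ios,
          money_other_eur = other, money_friend_eur = friend,
          help_other = ho, help_general = hg
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Write a cohort to plain-text files
#'
#' One CSV per participant per phase (columns = channels, with a
#' channel-to-ROI header), a tab-delimited annotation export
#' (participant, tier, onset_s, offset_s), outcome and ground-truth CSVs and
#' the configuration as JSON.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (rec in cohort$recordings) {
    for (ph in names(rec$phases)) {
      for (p in c("A", "B")) {
        f <- file.path(dir, sprintf("%s_%s_%s_hbo.csv", rec$dyad_id, p, ph))
        con <- file(f, "w")
        writeLines(paste0("# roi_map: ",
                          paste(rec$channels, rec$channel_roi, sep = "=",
                                collapse = ";")), con)
        write.csv(as.data.frame(rec$phases[[ph]]$hbo[[p]]), con,
                  row.names = FALSE)
        close(con)
        files <- c(files, f)
      }
    }
  }
  f <- file.path(dir, "annotations.tsv")
  write.table(cohort$annotations[, c("participant", "tier", "onset_s", "offset_s")],
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "outcomes.csv")
  write.csv(cohort$outcomes, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "ground_truth.csv")
  write.csv(cohort$ground_truth, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "config.json")
  cfg <- cohort$config
  cfg$phase_plan <- as.list(cfg$phase_plan)
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- c(files, f)
  invisible(files)
}
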
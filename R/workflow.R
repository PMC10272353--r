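#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults at the analysis'
#' reference values: 5-ms bins, 15 uV amplitude floor, 450 uV artifact
#' criterion, +/-4 ms halo/blanking, 2.4 sqrt(spikes/s) inclusion cutoff,
#' 3-SD evoked threshold, 21-sample/beta-38/order-3 smoothing, 3 components
#' and the 250-ms post-solenoid analysis window.
#'
#' @param sim a [sim_config()].
#' @param filter a [filter_spec()].
#' @param detection a [detection_params()].
#' @param peth_window PETH window, ms relative to trial zero.
#' @param bin_ms PETH bin width, ms.
#' @param baseline_window baseline-statistics window, ms.
#' @param include_cutoff baseline-mean inclusion cutoff, sqrt(spikes/s).
#' @param sd_mult evoked-threshold multiplier on the baseline sd.
#' @param n_boot PETH bootstrap resamples (0 disables the band).
#' @param response_window component-analysis window, ms.
#' @param k number of components.
#' @param lambda,maxit reconstruction-ICA settings.
#' @param model_family `"gaussian"` or `"quasibinomial"`.
#' @param seed global seed; overrides `sim$rng_seed` when given.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            filter = filter_spec(),
                            detection = detection_params(),
                            peth_window = c(-250, 350),
                            bin_ms = 5,
                            baseline_window = c(-200, -50),
                            include_cutoff = 2.4,
                            sd_mult = 3,
                            n_boot = 0,
                            response_window = c(50, 300),
                            k = 3,
                            lambda = 1,
                            maxit = 1000,
                            model_family = "gaussian",
                            seed = NULL) {
  if (!is.null(seed)) sim$rng_seed <- as.integer(seed)
  structure(list(sim = sim, filter = filter, detection = detection,
                 peth_window = peth_window, bin_ms = bin_ms,
                 baseline_window = baseline_window,
                 include_cutoff = include_cutoff, sd_mult = sd_mult,
                 n_boot = n_boot, response_window = response_window,
                 k = k, lambda = lambda, maxit = maxit,
                 model_family = model_family),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trippable JSON representation of all stage parameters.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, raw$sim[setdiff(names(raw$sim), character(0))])
  filt <- do.call(filter_spec, raw$filter)
  det <- do.call(detection_params, raw$detection)
  pipeline_config(sim = sim, filter = filt, detection = det,
                  peth_window = raw$peth_window, bin_ms = raw$bin_ms,
                  baseline_window = raw$baseline_window,
                  include_cutoff = raw$include_cutoff,
                  sd_mult = raw$sd_mult, n_boot = raw$n_boot,
                  response_window = raw$response_window, k = raw$k,
                  lambda = raw$lambda, maxit = raw$maxit,
                  model_family = raw$model_family)
}

stage_files <- function(dir) {
  list(simulate = file.path(dir, c("channels.csv", "schedule.csv",
                                   "truth_spikes.csv", "lesions.csv")),
       detect = file.path(dir, "events.csv"),
       peth = file.path(dir, c("peth.csv", "peth_summary.csv")),
       decompose = file.path(dir, c("components.csv", "weights.csv",
                                    "basis.json")),
       model = file.path(dir, c("coefficients_w2.csv", "coefficients_w3.csv")))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages run in order: simulate (cohort plan and ground-truth spike times),
#' detect (per-animal trace synthesis, conditioning and spike detection),
#' peth, decompose, model. All stage outputs are written as CSV/JSON to
#' `out_dir` together with a manifest recording the configuration, seeds and
#' stage timings. Re-running with the same configuration and seed reproduces
#' all outputs bit-identically. With `resume = TRUE`, stages whose outputs
#' already exist are skipped, and any stage that is re-run forces every
#' downstream stage to re-run.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param resume skip stages whose outputs are present.
#' @param verbose print stage progress.
#' @return invisibly, a list with the in-memory stage outputs (`plan`,
#'   `events`, `peths`, `decomposition`, `models`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sf <- stage_files(out_dir)
  manifest <- list(package_version = as.character(utils::packageVersion("evokedmua")),
                   seed = config$sim$rng_seed,
                   config = unclass_deep(config), stages = list())
  say <- function(...) if (verbose) message(...)
  done <- function(stage) all(file.exists(sf[[stage]]))
  force_from <- FALSE
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[stage]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

  ## -- simulate ------------------------------------------------------------
  plan <- cohort_plan(config$sim)
  truth <- NULL
  if (resume && done("simulate") && !force_from) {
    say("simulate: outputs present, skipping")
    truth <- utils::read.csv(file.path(out_dir, "truth_spikes.csv"))
  } else {
    force_from <- TRUE
    say("simulate: planning cohort and drawing ground-truth spikes")
    truth <- timed("simulate", {
      tr <- do.call(rbind, lapply(seq_len(config$sim$n_animals), function(a) {
        s <- simulate_animal_spikes(plan, a)
        if (nrow(s)) cbind(animal = a, s) else NULL
      }))
      utils::write.csv(plan$channels, sf$simulate[1], row.names = FALSE)
      utils::write.csv(plan$schedule, sf$simulate[2], row.names = FALSE)
      utils::write.csv(tr, sf$simulate[3], row.names = FALSE)
      utils::write.csv(data.frame(animal = seq_along(plan$lesion_volumes),
                                  lesion_volume_mm3 = plan$lesion_volumes),
                       sf$simulate[4], row.names = FALSE)
      tr
    })
  }

  ## -- detect --------------------------------------------------------------
  if (resume && done("detect") && !force_from) {
    say("detect: outputs present, skipping")
    events <- utils::read.csv(file.path(out_dir, "events.csv"),
                              stringsAsFactors = FALSE)
  } else {
    force_from <- TRUE
    say("detect: synthesizing traces and detecting spikes per animal")
    events <- timed("detect", {
      evs <- vector("list", config$sim$n_animals)
      for (a in seq_len(config$sim$n_animals)) {
        say(sprintf("  animal %d/%d", a, config$sim$n_animals))
        sp <- truth[truth$animal == a, c("channel", "trial", "time")]
        evs[[a]] <- detect_animal(plan, a, sp, config$detection, config$filter)
      }
      ev <- do.call(rbind, evs)
      ev$reason[is.na(ev$reason)] <- ""
      utils::write.csv(ev, sf$detect, row.names = FALSE)
      ev
    })
  }

  ## -- peth ----------------------------------------------------------------
  if (resume && done("peth") && !force_from) {
    say("peth: outputs present, skipping")
    peths <- list(peth = utils::read.csv(sf$peth[1], stringsAsFactors = FALSE),
                  summary = utils::read.csv(sf$peth[2], stringsAsFactors = FALSE))
  } else {
    force_from <- TRUE
    say("peth: binning, transforming and smoothing spike rates")
    peths <- timed("peth", {
      pl <- lapply(seq_len(config$sim$n_animals), function(a) {
        ch <- plan$channels[plan$channels$animal == a, ]
        compute_peths(events[events$animal == a, ], plan$schedule, ch,
                      window = config$peth_window, bin_ms = config$bin_ms,
                      stim_onset_ms = config$sim$solenoid_onset_ms,
                      sd_mult = config$sd_mult,
                      include_cutoff = config$include_cutoff,
                      n_boot = config$n_boot)
      })
      out <- list(peth = do.call(rbind, lapply(pl, `[[`, "peth")),
                  summary = do.call(rbind, lapply(pl, `[[`, "summary")))
      utils::write.csv(out$peth, sf$peth[1], row.names = FALSE)
      utils::write.csv(out$summary, sf$peth[2], row.names = FALSE)
      out
    })
  }

  ## -- decompose -----------------------------------------------------------
  if (resume && done("decompose") && !force_from) {
    say("decompose: outputs present, skipping")
    weights <- utils::read.csv(file.path(out_dir, "weights.csv"),
                               stringsAsFactors = FALSE)
    decomp <- list(weights = weights)
  } else {
    force_from <- TRUE
    say("decompose: component analysis of evoked responses")
    decomp <- timed("decompose", {
      dc <- decompose_responses(peths$peth, peths$summary,
                                trial_types = config$sim$trial_types,
                                window_ms = config$response_window,
                                k = config$k, lambda = config$lambda,
                                maxit = config$maxit)
      shp <- do.call(rbind, lapply(names(dc$per_type), function(ty) {
        b <- dc$per_type[[ty]]
        do.call(rbind, lapply(seq_len(ncol(b$A)), function(j)
          data.frame(grouping = ty, component = j,
                     bin_start_ms = seq(config$response_window[1],
                                        by = config$bin_ms,
                                        length.out = nrow(b$A)),
                     coefficient = b$A[, j])))
      }))
      shp_c <- do.call(rbind, lapply(seq_len(ncol(dc$combined$A)), function(j)
        data.frame(grouping = "combined", component = j,
                   bin_start_ms = seq(config$response_window[1],
                                      by = config$bin_ms,
                                      length.out = nrow(dc$combined$A)),
                   coefficient = dc$combined$A[, j])))
      utils::write.csv(rbind(shp, shp_c), sf$decompose[1], row.names = FALSE)
      utils::write.csv(dc$weights, sf$decompose[2], row.names = FALSE)
      jsonlite::write_json(list(mu = dc$combined$mu, A = dc$combined$A,
                                objective = dc$combined$objective,
                                converged = dc$combined$converged,
                                iterations = dc$combined$iterations),
                           sf$decompose[3], digits = NA, auto_unbox = TRUE)
      dc
    })
  }

  ## -- model ---------------------------------------------------------------
  if (resume && done("model") && !force_from) {
    say("model: outputs present, skipping")
    models <- list(w2 = utils::read.csv(sf$model[1]),
                   w3 = utils::read.csv(sf$model[2]))
  } else {
    say("model: mixed-effects models of component weights")
    models <- timed("model", {
      m2 <- fit_weight_model(decomp$weights, "w2", config$model_family)
      m3 <- fit_weight_model(decomp$weights, "w3", config$model_family)
      utils::write.csv(as.data.frame(m2), sf$model[1], row.names = FALSE)
      utils::write.csv(as.data.frame(m3), sf$model[2], row.names = FALSE)
      list(w2 = m2, w3 = m3)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(plan = plan, events = events, peths = peths,
                 decomposition = decomp, models = models, out_dir = out_dir))
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs of a run directory and produces one
#' machine-readable summary: grand-average PETHs by area and trial type
#' (over included channels only), component shapes, mean component weights
#' with standard errors, reconstructed rates from the group-mean weights,
#' and the model coefficient tables.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param write write `summary.json` into `run_dir` (default TRUE).
#' @return list with `grand_peth`, `components`, `mean_weights`,
#'   `reconstructions`, `coefficients`.
#' @export
summarize_run <- function(run_dir, write = TRUE) {
  sf <- stage_files(run_dir)
  for (stage in names(sf))
    if (!all(file.exists(sf[[stage]])))
      stop("missing output for stage '", stage, "'")
  peth <- utils::read.csv(sf$peth[1], stringsAsFactors = FALSE)
  summ <- utils::read.csv(sf$peth[2], stringsAsFactors = FALSE)
  comps <- utils::read.csv(sf$decompose[1], stringsAsFactors = FALSE)
  weights <- utils::read.csv(sf$decompose[2], stringsAsFactors = FALSE)
  basis <- jsonlite::read_json(sf$decompose[3], simplifyVector = TRUE)

  inc <- summ[summ$included, c("animal", "channel", "trial_type")]
  key <- function(d) paste(d$animal, d$channel, d$trial_type)
  pin <- peth[key(peth) %in% key(inc), ]
  grand <- stats::aggregate(cbind(raw_sqrt_rate, smoothed) ~
                              area + trial_type + bin_start_ms,
                            data = pin, FUN = mean)
  grand <- grand[order(grand$area, grand$trial_type, grand$bin_start_ms), ]

  mw <- summarize_weights(weights)
  A <- matrix(unlist(basis$A), nrow = length(basis$mu))
  wcols <- grep("^w[0-9]+_mean$", names(mw), value = TRUE)
  recon <- do.call(rbind, lapply(seq_len(nrow(mw)), function(i) {
    w <- as.numeric(mw[i, wcols])
    data.frame(area = mw$area[i], trial_type = mw$trial_type[i],
               bin = seq_along(basis$mu),
               rate = as.numeric(unlist(basis$mu) + A %*% w))
  }))
  out <- list(grand_peth = grand, components = comps, mean_weights = mw,
              reconstructions = recon,
              coefficients = list(w2 = utils::read.csv(sf$model[1]),
                                  w3 = utils::read.csv(sf$model[2])))
  if (write)
    jsonlite::write_json(out, file.path(run_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  out
}
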
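#' @include classification.R
NULL

#' Default pipeline configuration
#'
#' Returns the full configuration list used by \code{\link{runPipeline}},
#' optionally overridden by a (possibly partial) user list or YAML file.
#' Every report written by the pipeline embeds the MD5 hash of the resolved
#' configuration and the seed, so artifacts from different configurations
#' are never silently mixed.
#'
#' @param config partial configuration list or path to a YAML file.
#' @return complete configuration list.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      n_shapes = 8, n_segments = 2,
      maneuvers = list(list(label = "ctrl", n_steps = 2),
                       list(label = "capsa", n_steps = 2)),
      symbols_per_step = 600, separation = 0.45, pause_prob = 0.25,
      pause_duration_s = 0.12, noise_sd = defaultNoiseSd,
      perturb_weight = 0.1, render = TRUE),
    detection = list(window_ms = 100, smooth_cutoff_hz = 70,
                     min_amplitude_mv = 0.1, baseline_fraction = 0.1,
                     target_rate_hz = 1600),
    dictionary = list(variance_target = 0.98, k_min = 2, k_max = 15,
                      forced_k = NULL),
    tests = list(n_surrogates_order1 = 999, n_surrogates_order2 = 199,
                 alpha_level = 0.05),
    classification = list(k_lengths = c(50, 100), alpha = 0.5))
  mergeList <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]) &&
                     !is.null(names(b[[nm]])))
        mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  mergeList(def, config)
}

.configHash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

.stamp <- function(config) {
  sprintf("# config: %s seed: %d", .configHash(config),
          as.integer(config$seed))
}

.writeStamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, detect, build dictionaries,
#' symbolize, Markov-order tests, classify — on a synthetic experiment
#' defined by the configuration (see \code{\link{pipelineConfig}}). One
#' dictionary is built per segment from that segment's pooled event windows.
#' When \code{out_dir} is set, sequence files, transition matrices, test
#' reports and the evaluation tables are persisted, each stamped with the
#' configuration hash and seed; rerunning with the same configuration
#' reproduces identical artifacts.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{pipelineConfig}}).
#' @return list of class \code{"cdpPipelineResult"} with the experiment,
#'   dictionaries, sequences, per-sequence order tests, and the evaluation
#'   report.
#' @export
runPipeline <- function(config = list()) {
  config <- pipelineConfig(config)
  stageName <- "simulate"
  result <- tryCatch({
    set.seed(config$seed)
    sim <- config$simulate
    tpl <- makeTemplates(sim$n_shapes)
    mats <- maneuverMatrices(tpl@labels,
                             vapply(sim$maneuvers, `[[`, "", "label"),
                             separation = sim$separation,
                             pauseProb = sim$pause_prob)
    states <- lapply(sim$maneuvers, function(m)
      stateSpec(m$label, mats[[m$label]], m$n_steps, sim$symbols_per_step))
    exp <- makeExperiment(states, sim$n_segments, tpl, seed = config$seed,
                          perturbWeight = sim$perturb_weight,
                          render = isTRUE(sim$render),
                          pauseDurationS = sim$pause_duration_s,
                          noiseSd = sim$noise_sd)

    dpar <- detectionParams(config$detection$window_ms,
                            config$detection$smooth_cutoff_hz,
                            config$detection$min_amplitude_mv,
                            config$detection$baseline_fraction,
                            config$detection$target_rate_hz)
    if (isTRUE(sim$render)) {
      stageName <- "detect"
      eventSets <- lapply(exp@recordings, function(r)
        preprocessEvents(detectEvents(r, dpar), dpar))
      stageName <- "dictionary"
      segOf <- vapply(eventSets, function(e) e@segmentId, "")
      dicts <- lapply(unique(segOf), function(seg) {
        w <- do.call(rbind, lapply(eventSets[segOf == seg],
                                   processedWindows))
        buildDictionary(w, config$dictionary$variance_target,
                        config$dictionary$k_min:config$dictionary$k_max,
                        config$dictionary$forced_k, seed = config$seed)
      })
      names(dicts) <- unique(segOf)
      stageName <- "symbolize"
      sequences <- lapply(eventSets, function(ev) {
        lab <- labelEvents(ev@processedWindows, dicts[[ev@segmentId]])
        discretize(lab, peakTimes(ev), sim$pause_duration_s,
                   ev@segmentId, ev@stepId, ev@maneuver)
      })
    } else {
      eventSets <- list()
      dicts <- list()
      sequences <- exp@truthSymbols
    }

    stageName <- "markov-tests"
    orderTests <- lapply(sequences, function(s) {
      list(chi2 = chi2TestOrder1(s),
           permutation = permutationTestOrder1(
             s, nSurrogates = config$tests$n_surrogates_order1))
    })

    stageName <- "classify"
    evalReport <- evaluateExperiment(
      sequences, kLengths = config$classification$k_lengths,
      alpha = config$classification$alpha)

    list(config = config, experiment = exp, eventSets = eventSets,
         dictionaries = dicts, sequences = sequences,
         orderTests = orderTests, evaluation = evalReport)
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stageName,
                 conditionMessage(e)), call. = FALSE))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- .stamp(config)
    for (nm in names(result$sequences)) {
      writeSymbolSequence(result$sequences[[nm]],
                          file.path(config$out_dir, paste0(nm, ".seq")))
      mod <- fitModel(result$sequences[[nm]], alpha = 0)
      M <- probs(mod)
      dimnames(M) <- list(alphabet(mod), alphabet(mod))
      .writeStamped(as.data.frame(M),
                    file.path(config$out_dir, paste0(nm, "_transitions.csv")),
                    stamp)
    }
    testDf <- do.call(rbind, lapply(names(result$orderTests), function(nm) {
      ot <- result$orderTests[[nm]]
      data.frame(sequence = nm,
                 chi2_statistic = statistic(ot$chi2),
                 chi2_df = ot$chi2@df, chi2_p = pValue(ot$chi2),
                 perm_statistic = statistic(ot$permutation),
                 perm_p = pValue(ot$permutation),
                 n_surrogates = ot$permutation@nSurrogates)
    }))
    .writeStamped(testDf, file.path(config$out_dir, "order1_tests.csv"), stamp)
    .writeStamped(result$evaluation$accuracyByK,
                  file.path(config$out_dir, "classification_accuracy.csv"),
                  stamp)
    .writeStamped(result$evaluation$predictions,
                  file.path(config$out_dir, "classification_predictions.csv"),
                  stamp)
  }
  structure(result, class = "cdpPipelineResult")
}

#' @export
print.cdpPipelineResult <- function(x, ...) {
  cat("cdpMarkov pipeline result\n")
  cat(sprintf("  sequences: %d; dictionaries: %d\n", length(x$sequences),
              length(x$dictionaries)))
  ps <- vapply(x$orderTests, function(t) pValue(t$permutation), 0)
  cat(sprintf("  order-1 permutation p-values: max %.4g\n", max(ps)))
  print(x$evaluation)
  invisible(x)
}

#' Robustness of the order-1 result to the dictionary size
#'
#' Rebuilds the dictionaries at each forced size k, re-symbolizes all
#' recordings and reruns the permutation order-1 test, reporting for each k
#' the maximum p-value across all (segment, step) sequences — the
#' worst-case significance of the Markov property when the dictionary size
#' is deliberately suboptimal. k = 1 would produce degenerate single-symbol
#' sequences and is flagged and skipped.
#'
#' @param eventSets named list of preprocessed \code{\link{CdpEventSet}}
#'   objects (e.g. from \code{\link{runPipeline}}).
#' @param kValues dictionary sizes to sweep (e.g. \code{c(8, 12, 15)}).
#' @param pauseDurationS pause duration used for re-symbolization.
#' @param nSurrogates surrogates for the permutation test.
#' @param varianceTarget PCA target for dictionary building.
#' @param seed optional integer seed.
#' @return data.frame with one row per k: maxP over sequences, nSequences,
#'   skipped flag.
#' @export
robustnessSweep <- function(eventSets, kValues, pauseDurationS = 0.12,
                            nSurrogates = 999, varianceTarget = 0.98,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segOf <- vapply(eventSets, function(e) e@segmentId, "")
  nWin <- min(vapply(eventSets, length, 0L))
  rows <- lapply(kValues, function(k) {
    if (k < 2 || k > nWin) {
      warning("k = ", k, " infeasible; skipped")
      return(data.frame(k = k, maxP = NA_real_, nSequences = 0L,
                        skipped = TRUE))
    }
    dicts <- lapply(unique(segOf), function(seg) {
      w <- do.call(rbind, lapply(eventSets[segOf == seg], processedWindows))
      buildDictionary(w, varianceTarget, forcedK = k)
    })
    names(dicts) <- unique(segOf)
    ps <- vapply(eventSets, function(ev) {
      lab <- labelEvents(ev@processedWindows, dicts[[ev@segmentId]])
      s <- discretize(lab, peakTimes(ev), pauseDurationS,
                      ev@segmentId, ev@stepId, ev@maneuver)
      pValue(permutationTestOrder1(s, nSurrogates = nSurrogates))
    }, 0)
    data.frame(k = k, maxP = max(ps), nSequences = length(ps),
               skipped = FALSE)
  })
  do.call(rbind, rows)
}
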
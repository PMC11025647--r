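#' Configuration of the full simulation-and-analysis pipeline
#'
#' Bundles every stage's parameters: toy-language corpus generation,
#' language-model training, stimulus construction, surprisal
#' extraction, language-model evaluation, synthetic ERP generation,
#' topographic model fitting and stacking. Per-stage seeds are derived
#' deterministically from the master seed, so stages are reproducible
#' independently of execution order.
#'
#' @param design_name one of the three factorial designs.
#' @param language_spec a [language_spec()]; defaults to the design's
#'   preset.
#' @param n_sentences training-corpus size.
#' @param vocab_cap vocabulary cap for all models.
#' @param n_items stimulus items per design (default 40).
#' @param lms named list of language-model configurations; each entry
#'   is a list with `kind`, optional `smoothing`, `alpha` and `mode`
#'   (surprisal extraction mode). Names are the model ids. The default
#'   set mirrors a recurrent model (bigram, incremental), a
#'   bidirectional transformer stand-in (trigram, mask-and-truncate)
#'   and a unidirectional transformer stand-in (trigram, incremental).
#' @param erp_surprisal_model model id whose surprisal drives the ERP
#'   generator.
#' @param erp an [erp_gen_config()]; its seed is overridden by the
#'   derived stage seed.
#' @param layout electrode layout (default the 32-channel montage).
#' @param run_lm_evaluation logical; run the grammaticality test and
#'   condition-contrast stage.
#' @param n_eval_sentences corpus sentences used by the grammaticality
#'   test.
#' @param k_by,k_re tensor-basis dimensions for the topographic
#'   models.
#' @param loo_method,n_draws stacking controls.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design_name = "german_like",
                            language_spec = NULL,
                            n_sentences = 2000L,
                            vocab_cap = 5000L,
                            n_items = 40L,
                            lms = list(
                              lstm = list(kind = "bigram", alpha = 0.1,
                                          mode = "incremental"),
                              bert = list(kind = "trigram", alpha = 0.1,
                                          mode = "mask_truncate"),
                              gpt = list(kind = "trigram", alpha = 0.1,
                                         mode = "incremental")),
                            erp_surprisal_model = names(lms)[1],
                            erp = erp_gen_config(),
                            layout = make_layout(montage = "montage32"),
                            run_lm_evaluation = TRUE,
                            n_eval_sentences = 30L,
                            k_by = c(5, 5), k_re = c(3, 3),
                            loo_method = "psis", n_draws = 1000L,
                            out_dir = "n400stack_out", seed = 1L) {
  design_name <- match.arg(design_name,
                           c("german_like", "hindi_like", "basque_like"))
  if (is.null(language_spec)) language_spec <-
      default_language_spec(design_name)
  stopifnot(inherits(language_spec, "language_spec"),
            inherits(erp, "erp_gen_config"),
            inherits(layout, "electrode_layout"))
  if (is.null(names(lms)) || anyDuplicated(names(lms))) {
    stop("`lms` must be a uniquely named list of model configs",
         call. = FALSE)
  }
  if (!erp_surprisal_model %in% names(lms)) {
    stop(sprintf("erp_surprisal_model '%s' is not among the configured model ids (%s)",
                 erp_surprisal_model, paste(names(lms), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(design_name = design_name, language_spec = language_spec,
                 n_sentences = as.integer(n_sentences),
                 vocab_cap = as.integer(vocab_cap),
                 n_items = as.integer(n_items), lms = lms,
                 erp_surprisal_model = erp_surprisal_model, erp = erp,
                 layout = layout,
                 run_lm_evaluation = isTRUE(run_lm_evaluation),
                 n_eval_sentences = as.integer(n_eval_sentences),
                 k_by = k_by, k_re = k_re, loo_method = loo_method,
                 n_draws = as.integer(n_draws), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes, in dependency order: corpus generation, language-model
#' training, stimulus generation, critical-word surprisal extraction,
#' (optionally) language-model evaluation, synthetic ERP generation,
#' topographic model fitting with leave-one-out stacking, and the
#' grand-mean topography report. Every stage writes its interchange
#' files into the output directory; a run manifest with per-stage
#' seeds, timings and file checksums is written last.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; the full set of stage
#'   results is attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()
  t_all <- proc.time()[3]
  run_stage <- function(name, fun) {
    t0 <- proc.time()[3]
    res <- fun(derive_seed(config$seed, name))
    stages[[name]] <<- list(seed = derive_seed(config$seed, name),
                            seconds = round(proc.time()[3] - t0, 3))
    res
  }

  results$corpus <- run_stage("corpus", function(seed) {
    corpus <- generate_corpus(config$language_spec, config$n_sentences,
                              seed = seed)
    write_corpus(corpus, file.path(out, "corpus.txt"))
    corpus
  })

  results$lms <- run_stage("train_lm", function(seed) {
    vocab <- build_vocab(results$corpus, cap = config$vocab_cap)
    lms <- list()
    for (id in names(config$lms)) {
      cfg <- config$lms[[id]]
      lms[[id]] <- train_lm(results$corpus, kind = cfg$kind,
                            smoothing = cfg$smoothing %||% "additive",
                            alpha = cfg$alpha %||% 1,
                            vocab = vocab, model_id = id,
                            seed = derive_seed(seed, id))
      write_lm(lms[[id]], file.path(out, paste0("lm_", id, ".json")))
    }
    lms
  })

  results$stimuli <- run_stage("stimuli", function(seed) {
    stim <- generate_stimuli(config$language_spec, config$design_name,
                             n_items = config$n_items, seed = seed)
    write_stimuli(stim, file.path(out, "stimuli.tsv"))
    stim
  })

  results$surprisal <- run_stage("surprisal", function(seed) {
    recs <- do.call(rbind, lapply(names(results$lms), function(id) {
      stimulus_surprisal(results$stimuli, results$lms[[id]],
                         mode = config$lms[[id]]$mode %||% "incremental")
    }))
    utils::write.table(recs, file.path(out, "surprisal.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    recs
  })

  if (config$run_lm_evaluation) {
    results$lm_evaluation <- run_stage("evaluate_lm", function(seed) {
      n_eval <- min(config$n_eval_sentences, length(results$corpus))
      sents <- results$corpus[seq_len(n_eval)]
      gram <- lapply(results$lms, function(lm) {
        withCallingHandlers(
          grammaticality_test(lm, sents, config$language_spec,
                              seed = derive_seed(seed, lm$model_id)),
          warning = function(w) invokeRestart("muffleWarning"))
      })
      contrasts <- lapply(names(results$lms), function(id) {
        recs <- results$surprisal[results$surprisal$model_id == id, ]
        condition_contrast_model(recs,
                                 seed = derive_seed(seed, paste0("cc_", id)))
      })
      names(contrasts) <- names(results$lms)
      tab <- do.call(rbind, lapply(names(results$lms), function(id) {
        g <- gram[[id]]
        cbind(data.frame(model_id = id,
                         delta_surprisal = g$estimate,
                         gram_ci_low = g$interval[1],
                         gram_ci_high = g$interval[2],
                         passes = g$passes),
              contrasts[[id]]$contrasts)
      }))
      utils::write.table(tab, file.path(out, "lm_evaluation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(grammaticality = gram, contrasts = contrasts, table = tab)
    })
  }

  results$trials <- run_stage("simulate_erp", function(seed) {
    # only stimuli scored by every model enter the ERP simulation, so
    # each model's z-scored surprisal column is complete
    key_of <- function(df) paste(df$item_id, df$cond1, df$cond2, sep = ".")
    keys <- lapply(split(results$surprisal, results$surprisal$model_id),
                   key_of)
    common <- Reduce(intersect, keys)
    recs <- results$surprisal[
      results$surprisal$model_id == config$erp_surprisal_model &
        key_of(results$surprisal) %in% common, ]
    input <- erp_input_from_records(recs)
    erp <- config$erp
    erp$seed <- seed
    trials <- generate_erp(input, config$layout, erp,
                           presentation = "rotate")
    # one z-scored surprisal column per language model, joined by stimulus
    for (id in names(results$lms)) {
      recs_id <- results$surprisal[results$surprisal$model_id == id, ]
      key <- paste(recs_id$item_id, recs_id$cond1, recs_id$cond2,
                   sep = ".")
      s <- recs_id$surprisal_nats[match(trials$stim_id, key)]
      trials[[paste0("surp_", id, "_z")]] <- zscore(s)
    }
    write_trials(trials, file.path(out, "trials.csv"), config = erp)
    trials
  })

  results$stacking <- run_stage("stack", function(seed) {
    surp_vars <- stats::setNames(
      paste0("surp_", names(results$lms), "_z"), names(results$lms))
    specs <- default_gam_specs(surp_vars)
    res <- compare_models(results$trials, specs,
                          loo_method = config$loo_method,
                          k_by = config$k_by, k_re = config$k_re,
                          n_draws = config$n_draws, seed = seed)
    utils::write.table(res$weights, file.path(out, "stack_weights.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(weights = res$weights, objective = res$objective,
           excluded = as.list(res$excluded)),
      file.path(out, "stack_result.json"), auto_unbox = TRUE, digits = NA)
    res
  })

  results$report <- run_stage("report", function(seed) {
    rep <- grand_mean_report(results$trials)
    utils::write.csv(rep, file.path(out, "grand_means.csv"),
                     row.names = FALSE)
    top <- results$stacking$weights$model_name[1]
    fit <- results$stacking$fits[[top]]
    surfaces <- list()
    for (pred in c("cond", "surp")) {
      if (pred %in% names(fit$terms)) {
        td <- difference_surface(fit, pred,
                                 seed = derive_seed(seed, pred))
        utils::write.csv(as.data.frame(td),
                         file.path(out, paste0("surface_", pred, ".csv")),
                         row.names = FALSE)
        surfaces[[pred]] <- td
      }
    }
    list(grand_means = rep, surfaces = surfaces, top_model = top)
  })

  files <- list.files(out, full.names = TRUE, recursive = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("n400stack")),
    design_name = config$design_name,
    master_seed = config$seed,
    stages = stages,
    total_seconds = round(proc.time()[3] - t_all, 3),
    artifacts = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- results
  invisible(manifest)
}

#' Grand-mean difference topographies
#'
#' Computes, per electrode, the observed grand-mean amplitude
#' difference between reanalysis and no-reanalysis trials, and between
#' high- and low-surprisal trials (z-scored surprisal above vs below
#' 0). An empty surprisal bin yields `NA` rather than zero.
#'
#' @param data trial-amplitude data.frame.
#' @param surp_var surprisal column used for the binning (default
#'   `"surp_z"`).
#' @return data.frame with columns `electrode`, `x`, `y`,
#'   `cond_diff`, `surp_diff`, `n_trials`.
#' @export
grand_mean_report <- function(data, surp_var = "surp_z") {
  check_columns(data, c("electrode", "x", "y", "amplitude", "cond",
                        surp_var), "data")
  s <- data[[surp_var]]
  els <- unique(data[, c("electrode", "x", "y")])
  els <- els[order(els$electrode), ]
  out <- do.call(rbind, lapply(seq_len(nrow(els)), function(i) {
    sub <- data[data$electrode == els$electrode[i], ]
    ssub <- sub[[surp_var]]
    cond_diff <- if (any(sub$cond == 1) && any(sub$cond == 0)) {
      mean(sub$amplitude[sub$cond == 1]) -
        mean(sub$amplitude[sub$cond == 0])
    } else NA_real_
    surp_diff <- if (any(ssub > 0) && any(ssub < 0)) {
      mean(sub$amplitude[ssub > 0]) - mean(sub$amplitude[ssub < 0])
    } else NA_real_
    data.frame(electrode = els$electrode[i], x = els$x[i], y = els$y[i],
               cond_diff = cond_diff, surp_diff = surp_diff,
               n_trials = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
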
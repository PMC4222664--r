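#' Run the representational-geometry pipeline from a configuration
#'
#' Declarative driver binding the stages together: simulate or load inputs,
#' compute model RDMs, compare them to the reference with randomization and
#' bootstrap inference, estimate the noise ceiling from the subject
#' ensemble, fit the category-cluster model, assemble the crossvalidated
#' reweighted RDM, and measure categorization performance. All inputs are
#' validated (stimulus-id alignment, stage names) before any computation;
#' an RDM over a subset of the stimulus set is embedded automatically with
#' missing cells. Results are returned as tibbles/objects and, when
#' `out_dir` is set, written as delimited text together with a
#' machine-readable run manifest (seeds, parameters, decisions).
#'
#' @param config A nested list, or the path to a YAML file holding one.
#'   Recognized sections: `seed`; `stages` (subset of `"rdm"`, `"compare"`,
#'   `"ceiling"`, `"categoricality"`, `"reweight"`, `"categorize"`);
#'   `synthetic` (arguments to [synthetic_spec()] plus `n_models` and
#'   `model_tightness`, a list of per-model tightness settings); `params`
#'   (`n_perm`, `n_boot`, `n_rand`, `holdout_size`, `k`, `cost`,
#'   `max_folds`).
#' @param out_dir Optional output directory.
#' @return A named list of stage results plus the `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  stages <- config$stages %||%
    c("rdm", "compare", "ceiling", "categoricality", "reweight", "categorize")
  known <- c("rdm", "compare", "ceiling", "categoricality", "reweight",
             "categorize")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  par <- config$params %||% list()
  n_perm <- par$n_perm %||% 1000L
  n_boot <- par$n_boot %||% 500L
  n_rand <- par$n_rand %||% 500L
  holdout <- par$holdout_size %||% 8L
  kfold <- par$k %||% 12L
  cost <- par$cost %||% 1
  max_folds <- par$max_folds %||% 50000L

  inputs <- assemble_inputs(config, seed)
  stimuli <- inputs$stimuli
  models <- inputs$models
  reference <- inputs$reference
  ensemble <- inputs$ensemble
  log_lines <- inputs$log

  # id alignment (with automatic embedding of subset RDMs) happens up front
  target_ids <- stimuli$id
  reference <- align_rdm(reference, target_ids, "reference",
                         log = function(msg) log_lines <<- c(log_lines, msg))

  results <- list()
  model_rdms <- lapply(models, compute_rdm, metric = "correlation")
  if ("rdm" %in% stages) results$rdms <- model_rdms

  if ("compare" %in% stages) {
    perm <- dplyr::bind_rows(lapply(names(model_rdms), function(nm) {
      dplyr::mutate(
        permutation_test(reference, model_rdms[[nm]], n_perm = n_perm,
                         seed = seed),
        model = nm, .before = 1
      )
    }))
    bs <- bootstrap_stimuli(reference, model_rdms, strata = stimuli,
                            n_boot = n_boot, seed = seed)
    results$compare <- dplyr::mutate(perm, se = unname(bs$se[model]))
    if (length(model_rdms) >= 2) {
      results$pairwise <- compare_candidates(reference, model_rdms,
                                             strata = stimuli,
                                             n_boot = n_boot, seed = seed)$pairs
    }
  }

  if ("ceiling" %in% stages) {
    if (is.null(ensemble)) stop("ceiling stage needs a subject ensemble")
    results$ceiling <- noise_ceiling(ensemble)
  }

  if ("categoricality" %in% stages) {
    cm <- build_category_model(stimuli)
    results$categoricality <- dplyr::bind_rows(lapply(
      c(list(reference = reference), model_rdms)[
        c("reference", names(model_rdms))
      ],
      function(r) glance(fit_category_model(r, cm))
    ), .id = "representation")
    results$categoricality_test <- categoricality_test(
      reference, stimuli, n_rand = n_rand, seed = seed
    )
  }

  if ("reweight" %in% stages) {
    comps <- component_set(models)
    sq_ref <- rescale_to_sqeuclidean(reference)
    results$weights <- nnls_weights(comps, sq_ref)
    # holdouts are balanced across the animacy division (e.g. 4 + 4)
    results$reweighted <- crossvalidated_weighted_rdm(
      comps, sq_ref, holdout_size = holdout,
      strata = ifelse(stimuli$animate, "animate", "inanimate"),
      seed = seed, max_folds = max_folds
    )
    results$reweighted_tau <- kendall_tau_a(reference, results$reweighted)
  }

  if ("categorize" %in% stages) {
    results$accuracy <- dplyr::bind_rows(lapply(names(models), function(nm) {
      acc <- kfold_accuracy(models[[nm]], stimuli$animate, k = kfold,
                            seed = seed, cost = cost)
      tibble::tibble(model = nm, task = "animate_vs_inanimate",
                     accuracy = as.numeric(acc))
    }))
  }

  manifest <- list(
    package = "repgeom",
    version = as.character(utils::packageVersion("repgeom")),
    seed = seed, stages = stages,
    params = list(n_perm = n_perm, n_boot = n_boot, n_rand = n_rand,
                  holdout_size = holdout, k = kfold, cost = cost),
    n_stimuli = length(target_ids),
    n_models = length(models),
    decisions = list(
      p_value = "add-one convention for all resampling tests",
      predictor_coding = "within-category pairs = -1",
      reweight_coverage = "random stratified holdouts repeated to full pair coverage; multiply-predicted cells averaged"
    ),
    log = log_lines
  )
  results$manifest <- manifest

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_rdm(reference, file.path(out_dir, "reference_rdm.tsv"))
    for (nm in names(model_rdms)) {
      write_rdm(model_rdms[[nm]], file.path(out_dir, paste0("rdm_", nm, ".tsv")))
    }
    for (nm in intersect(names(results),
                         c("compare", "pairwise", "categoricality",
                           "weights", "accuracy"))) {
      utils::write.table(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(results$ceiling)) {
      utils::write.table(results$ceiling, file.path(out_dir, "ceiling.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(results$reweighted)) {
      write_rdm(results$reweighted, file.path(out_dir, "reweighted_rdm.tsv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

align_rdm <- function(x, target_ids, what, log = function(msg) NULL) {
  if (identical(stimulus_ids(x), target_ids)) return(x)
  extra <- setdiff(stimulus_ids(x), target_ids)
  if (length(extra)) {
    stop(what, " RDM has stimuli absent from the stimulus set: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  log(sprintf("%s RDM covers %d of %d stimuli; embedded with missing cells",
              what, nrow(x), length(target_ids)))
  embed_rdm(x, target_ids)
}

# correlation-distance RDM on the doubled (squared-Euclidean) scale, so the
# weighted-sum algebra applies
rescale_to_sqeuclidean <- function(x) {
  if (rdm_metric(x) == "sqeuclidean") return(x)
  rdm(2 * unclass(x), metric = "sqeuclidean")
}

make_spec <- function(base, tightness, seed) {
  synthetic_spec(
    n_stimuli = base$n_stimuli, tightness = tightness,
    n_features = base$n_features, feature_noise_sd = base$feature_noise_sd,
    n_subjects = base$n_subjects, subject_noise_sd = base$subject_noise_sd,
    seed = seed
  )
}

assemble_inputs <- function(config, seed) {
  log_lines <- character()
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    spec <- synthetic_spec(
      n_stimuli = sc$n_stimuli %||% 96,
      tightness = unlist(sc$tightness %||% c(animate = 1, inanimate = 0.5)),
      n_features = sc$n_features %||% 100,
      feature_noise_sd = sc$feature_noise_sd %||% 1,
      n_subjects = sc$n_subjects %||% 4,
      subject_noise_sd = sc$subject_noise_sd %||% 0.15,
      seed = seed
    )
    # the "brain": a true representation measured in several noisy subjects
    true_features <- generate_model_features(spec, model_name = "true",
                                             seed = seed)
    true_rdm <- compute_rdm(true_features, metric = "correlation")
    ensemble <- generate_subject_ensemble(
      true_rdm, n_subjects = spec$n_subjects,
      noise_sd = spec$subject_noise_sd, seed = seed + 1000L
    )
    reference <- average_rdms(ensemble$rdms)
    # candidate models: variations on the true geometry
    n_models <- sc$n_models %||% 3
    model_tight <- sc$model_tightness
    models <- lapply(seq_len(n_models), function(i) {
      sp <- if (!is.null(model_tight) && length(model_tight) >= i) {
        make_spec(spec, unlist(model_tight[[i]]), seed)
      } else {
        spec
      }
      generate_model_features(sp, model_name = sprintf("model%d", i),
                              seed = seed + i)
    })
    names(models) <- sprintf("model%d", seq_len(n_models))
    return(list(stimuli = spec$stimuli, models = models,
                reference = reference, ensemble = ensemble,
                log = c(log_lines, "inputs generated synthetically")))
  }
  if (!is.null(config$inputs)) {
    ip <- config$inputs
    for (f in c(ip$reference_rdm, unlist(ip$subject_rdms),
                unlist(ip$models), ip$labels)) {
      if (!file.exists(f)) stop("missing input file: ", f)
    }
    labels <- utils::read.table(ip$labels, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    stimuli <- stimulus_set(labels$id, labels$leaf)
    models <- lapply(ip$models, read_features)
    if (is.null(names(models))) names(models) <- basename(unlist(ip$models))
    reference <- read_rdm(ip$reference_rdm)
    ensemble <- NULL
    if (!is.null(ip$subject_rdms)) {
      subj <- lapply(unlist(ip$subject_rdms), read_rdm)
      subj <- lapply(subj, align_rdm, target_ids = stimuli$id,
                     what = "subject",
                     log = function(msg) log_lines <<- c(log_lines, msg))
      ensemble <- subject_ensemble(subj)
    }
    for (m in models) {
      if (!identical(stimulus_ids(m), stimuli$id)) {
        stop("feature matrix '", attr(m, "model_name"),
             "' is not aligned with the stimulus set")
      }
    }
    return(list(stimuli = stimuli, models = models, reference = reference,
                ensemble = ensemble, log = log_lines))
  }
  stop("config must provide a 'synthetic' section or an 'inputs' section")
}
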
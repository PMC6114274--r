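#' Per-domain model bundle for training and screening
#'
#' Collects a domain's SCM and CCM profiles from a library and calibrates
#' each CCM's decoy-acceptance bit threshold (see [ccm_bit_threshold()]).
#'
#' @param lib A [model_library] with in-memory profiles.
#' @param domain_acc Domain accession.
#' @param n_cal Random sequences per CCM threshold calibration.
#' @param min_overlap Scanner minimum overlap.
#' @return List with `domain_acc`, `scm_profile`, `ccm_profiles`,
#'   `ccm_thresholds` (as consumed by [screen_decoy()] and
#'   [build_training_set()]).
#' @export
prepare_domain_models <- function(lib, domain_acc, n_cal = 1000L,
                                  min_overlap = 8L) {
  md <- models_for_domain(lib, domain_acc)
  scm_profile <- if (!is.null(md$scm)) lib$profiles[[md$scm$model_id]]
                 else NULL
  ccm_profiles <- list()
  ccm_thresholds <- numeric()
  for (id in md$ccms$model_id) {
    p <- lib$profiles[[id]]
    if (is.null(p)) next
    ccm_profiles[[id]] <- p
    ccm_thresholds[[id]] <- ccm_bit_threshold(p, n = n_cal,
                                              min_overlap = min_overlap)
  }
  list(domain_acc = domain_acc, scm_profile = scm_profile,
       ccm_profiles = ccm_profiles, ccm_thresholds = ccm_thresholds)
}

#' Learn gathering thresholds for every domain of a library
#'
#' The pre-computed step of the pipeline: for each domain, builds the
#' labelled training set (positive fragments of the SEED sequences plus
#' screened decoy negatives) and fits one probability space for the SCM and
#' one pooled space for all CCMs.
#'
#' @param lib A [model_library] with in-memory profiles.
#' @param seeds Named list (by domain accession) of SEED sequences (aligned
#'   rows or ungapped strings).
#' @param params [fragment_params()] for the positive generator.
#' @param skip_failures Skip unlearnable domains with a warning instead of
#'   failing.
#' @param n_cal,W,max_decoys,min_overlap Passed to
#'   [prepare_domain_models()] / [build_training_set()].
#' @param verbose Log per-domain training-set sizes.
#' @return Named list of `prob_space` objects keyed
#'   `"<domain_acc>/<model_type>"`.
#' @export
train_gathering_thresholds <- function(lib, seeds,
                                       params = fragment_params(),
                                       skip_failures = FALSE,
                                       n_cal = 1000L, W = 10,
                                       max_decoys = 2000L,
                                       min_overlap = 8L, verbose = FALSE) {
  spaces <- list()
  for (acc in sort(names(seeds))) {
    dm <- prepare_domain_models(lib, acc, n_cal = n_cal,
                                min_overlap = min_overlap)
    tr <- tryCatch(
      build_training_set(seeds[[acc]], dm, params = params, W = W,
                         max_decoys = max_decoys,
                         min_overlap = min_overlap),
      error = function(e) e)
    if (inherits(tr, "error")) {
      if (skip_failures) {
        warning("skipping domain ", acc, ": ", conditionMessage(tr))
        next
      }
      stop("training failed for domain ", acc, ": ", conditionMessage(tr))
    }
    if (verbose) {
      message(acc, ": ", sum(tr$label == "positive"), " positive / ",
              sum(tr$label == "negative"), " negative instances")
    }
    sp <- fit_spaces(tr, skip_failures = skip_failures)
    spaces <- c(spaces, sp)
  }
  spaces[order(names(spaces))]
}
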
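#' Frozen feature pipeline
#'
#' Captures everything needed to transform NEW sequences exactly as the
#' training data were transformed: the encoding methods, the fitted
#' TF-IDF model (vocabulary included), the PseKNC configuration, and the
#' selected feature columns. Applying a pipeline never refits anything —
#' the core requirement for leakage-free test-set and cross-species
#' evaluation.
#'
#' @param methods feature methods in concatenation order (see
#'   [extract_features()]).
#' @param tfidf_model fitted [fit_tfidf()] model (required iff `"tfidf"`
#'   is among the methods).
#' @param pseknc_k,pseknc_lam,pseknc_w,pseknc_properties PseKNC settings.
#' @param selected character vector of retained column names (`NULL` =
#'   all columns).
#' @return object of class `feature_pipeline`.
#' @export
feature_pipeline <- function(methods, tfidf_model = NULL,
                             pseknc_k = 1:3, pseknc_lam = 2L, pseknc_w = 0.5,
                             pseknc_properties = c("twist", "tilt", "roll",
                                                   "shift", "slide", "rise"),
                             selected = NULL) {
  if ("tfidf" %in% methods && is.null(tfidf_model))
    stop("pipeline with a tfidf method requires a frozen tfidf_model")
  structure(list(methods = methods, tfidf_model = tfidf_model,
                 pseknc_k = pseknc_k, pseknc_lam = pseknc_lam,
                 pseknc_w = pseknc_w, pseknc_properties = pseknc_properties,
                 selected = selected),
            class = "feature_pipeline")
}

#' Apply a frozen pipeline to a sequence set
#'
#' @param pipeline a [feature_pipeline()].
#' @param set a [labeled_seq_set()].
#' @return a [feature_matrix()] restricted to the pipeline's selected
#'   columns.
#' @export
pipeline_transform <- function(pipeline, set) {
  stopifnot(inherits(pipeline, "feature_pipeline"))
  fm <- extract_features(set, methods = pipeline$methods,
                         tfidf_model = pipeline$tfidf_model,
                         pseknc_k = pipeline$pseknc_k,
                         pseknc_lam = pipeline$pseknc_lam,
                         pseknc_w = pipeline$pseknc_w,
                         pseknc_properties = pipeline$pseknc_properties)
  if (!is.null(pipeline$selected)) {
    missing <- setdiff(pipeline$selected, colnames(fm$x))
    if (length(missing))
      stop("pipeline selected columns absent from extraction: ",
           paste(utils::head(missing, 3), collapse = ", "))
    fm <- fm_select(fm, pipeline$selected)
  }
  fm
}

#' Train the final model on a full feature matrix
#'
#' @param family classifier family.
#' @param params tuned hyperparameters.
#' @param fm training [feature_matrix()] (already restricted to the
#'   selected features).
#' @param pipeline the [feature_pipeline()] that produced `fm`, frozen
#'   into the model so new sequences can be scored end to end.
#' @param species optional species tag.
#' @param seed fit seed.
#' @return object of class `ori_model`: `family`, `params`, `fit`,
#'   `pipeline`, `species`, `version`.
#' @export
train_final <- function(family, params, fm, pipeline = NULL,
                        species = "unknown", seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$x) == 0) stop("empty feature matrix")
  fit <- fit_classifier(family, fm$x, fm$labels, params, seed = seed)
  structure(list(family = family, params = params, fit = fit,
                 pipeline = pipeline, species = species,
                 feature_names = colnames(fm$x),
                 version = ORI_MODEL_VERSION),
            class = "ori_model")
}

ORI_MODEL_VERSION <- 1L

#' @export
print.ori_model <- function(x, ...) {
  cat(sprintf("ori_model: %s trained for species '%s' on %d features\n",
              x$family, x$species, length(x$feature_names)))
  invisible(x)
}

#' Score new sequences with a trained model
#'
#' @param model an [train_final()] model with a frozen pipeline.
#' @param set a [labeled_seq_set()] (labels are ignored for scoring).
#' @return numeric decision scores (> 0 = positive call).
#' @export
score_sequences <- function(model, set) {
  stopifnot(inherits(model, "ori_model"))
  if (is.null(model$pipeline))
    stop("model has no frozen feature pipeline")
  fm <- pipeline_transform(model$pipeline, set)
  predict_scores(model$fit, fm$x)
}

#' Cross-species evaluation with a frozen pipeline
#'
#' Transforms the target species' sequences with the SOURCE species'
#' frozen feature pipeline (vocabulary, TF-IDF weights, selected
#' columns), scores them with the source model, and reports the full
#' confusion-matrix metric set plus AUC. Applying the source model to its
#' own training set reproduces resubstitution performance.
#'
#' @param model a trained [train_final()] model with pipeline.
#' @param target a [labeled_seq_set()] from another species.
#' @return an `evaluation_report` with a single pseudo-repeat.
#' @export
cross_species_evaluate <- function(model, target) {
  stopifnot(inherits(model, "ori_model"), inherits(target, "labeled_seq_set"))
  if (is.null(model$pipeline))
    stop("model lacks the frozen feature pipeline needed for transfer")
  scores <- score_sequences(model, target)
  pos <- target$records$label == "positive"
  pred_pos <- scores > 0
  m <- compute_metrics(sum(pos), sum(!pos),
                       fn = sum(pos & !pred_pos), fp = sum(!pos & pred_pos))
  per <- data.frame(repeat_ = 1L, n_pos = sum(pos), n_neg = sum(!pos),
                    fn = sum(pos & !pred_pos), fp = sum(!pos & pred_pos),
                    sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc,
                    auc = compute_auc(target$records$label, scores),
                    mcc_degenerate = m$mcc_degenerate)
  structure(list(per_repeat = per,
                 mean = c(Sn = m$sn, Sp = m$sp, Acc = m$acc, MCC = m$mcc,
                          AUC = per$auc),
                 sd = c(Sn = NA, Sp = NA, Acc = NA, MCC = NA, AUC = NA),
                 folds = NA_integer_, repeats = 1L,
                 family = model$family, params = model$params),
            class = "evaluation_report")
}

#' Persist / restore a trained model
#'
#' The archive is versioned; loading refuses archives written by an
#' incompatible package version.
#'
#' @param model an `ori_model`.
#' @param path archive path (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored `ori_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ori_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  fail <- function(c) stop("cannot read model archive '", path, "': ",
                           conditionMessage(c), call. = FALSE)
  model <- withCallingHandlers(
    tryCatch(readRDS(path), error = fail),
    warning = function(w) { invokeRestart("muffleWarning") })
  if (!inherits(model, "ori_model"))
    stop("archive does not contain an ori_model: ", path)
  if (!identical(model$version, ORI_MODEL_VERSION))
    stop(sprintf("model archive version %s is incompatible with this package (expects %d)",
                 format(model$version), ORI_MODEL_VERSION))
  model
}
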
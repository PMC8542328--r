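#' Extract a feature matrix from a labeled sequence set
#'
#' Dispatches to the three encoders — `tfidf`, `pseknc`, `base_content` —
#' or any column-wise concatenation of them (in the declared order).
#' Column names are provenance-tagged (`tfidf:ACG`, `pseknc:k3:AAC`,
#' `base:gc_skew`) so downstream selection can trace every feature.
#'
#' @param set a [labeled_seq_set()].
#' @param methods character vector, subset of
#'   `c("tfidf", "pseknc", "base_content")`, in concatenation order.
#' @param tfidf_model optional pre-fitted [fit_tfidf()] model; if absent
#'   and `"tfidf"` is requested, a model is fitted on `set` itself (only
#'   appropriate when `set` is training data).
#' @param tfidf_vocab vocabulary used when fitting a TF-IDF model here;
#'   default k = 1..6.
#' @param pseknc_k vector of tuple sizes for the PseKNC blocks.
#' @param pseknc_lam,pseknc_w PseKNC tier count and weight factor.
#' @param pseknc_properties property names for [pseknc_config()].
#' @return a [feature_matrix()]; if a TF-IDF model was fitted here it is
#'   attached as attribute `"tfidf_model"`.
#' @export
extract_features <- function(set,
                             methods = c("tfidf"),
                             tfidf_model = NULL,
                             tfidf_vocab = kmer_vocabulary(1L, 6L),
                             pseknc_k = 1:3,
                             pseknc_lam = 2L,
                             pseknc_w = 0.5,
                             pseknc_properties = c("twist", "tilt", "roll",
                                                   "shift", "slide", "rise")) {
  stopifnot(inherits(set, "labeled_seq_set"))
  known <- c("tfidf", "pseknc", "base_content")
  if (length(methods) == 0) stop("empty method list")
  if (!all(methods %in% known))
    stop("unknown feature method(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  fitted_model <- NULL
  blocks <- lapply(methods, function(m) {
    switch(m,
      tfidf = {
        if (is.null(tfidf_model)) {
          fitted_model <<- fit_tfidf(set, tfidf_vocab)
          transform_tfidf(fitted_model, set)
        } else transform_tfidf(tfidf_model, set)
      },
      pseknc = pseknc_matrix(set, k = pseknc_k, lam = pseknc_lam,
                             w = pseknc_w, properties = pseknc_properties),
      base_content = base_content_matrix(set)
    )
  })
  out <- do.call(fm_cbind, blocks)
  if (!is.null(fitted_model)) attr(out, "tfidf_model") <- fitted_model
  out
}
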
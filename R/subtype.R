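# SST subtype classification: 3-nearest-neighbour (Euclidean) on input
# resistance and membrane time constant, with leave-one-out validation.
# Features are z-scored on the training set by default so that R_in (hundreds
# of MOhm) cannot dominate tau (tens of ms); raw distances are available
# behind a flag.

.knn_features <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || any(!is.finite(m)) || any(m <= 0))
    stop("features must be finite positive numerics")
  m
}

#' Classify a query cell by k nearest neighbours
#'
#' Majority label among the `k` Euclidean-nearest training cells in
#' (optionally standardized) feature space. With two classes and odd `k` a
#' vote tie is impossible; a distance tie at the k-th neighbour is broken
#' deterministically by taking the lowest-index training cell, and a vote tie
#' (even `k`) falls back to the nearest neighbour's label.
#'
#' @param train Matrix or data frame of training features, one row per cell
#'   (columns e.g. `rin_mohm`, `tau_ms`).
#' @param labels Character vector of training labels (`"MC"` / `"nMC"`).
#' @param query Feature vector or matrix of query cells (same columns).
#' @param k Number of neighbours (default 3).
#' @param standardize Z-score features on the training set before computing
#'   distances (default TRUE).
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_classify <- function(train, labels, query, k = 3L, standardize = TRUE) {
  tr <- .knn_features(train)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  qy <- as.matrix(query)
  if (ncol(qy) != ncol(tr)) stop("query and training features differ")
  labels <- as.character(labels)
  if (length(labels) != nrow(tr)) stop("one label per training cell required")
  if (anyNA(labels)) stop("unlabeled training cell")
  if (k > nrow(tr)) stop("k exceeds training size")
  if (standardize) {
    mu <- colMeans(tr)
    sdv <- apply(tr, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    tr <- sweep(sweep(tr, 2L, mu), 2L, sdv, "/")
    qy <- sweep(sweep(qy, 2L, mu), 2L, sdv, "/")
  }
  apply(qy, 1L, function(q) {
    d <- sqrt(colSums((t(tr) - q)^2))
    nn <- order(d)[seq_len(k)]       # order() breaks distance ties by index
    votes <- table(labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else labels[nn[1L]]
  })
}

#' Leave-one-out validation of the KNN classifier
#'
#' Each training cell is classified from all the others; returns the fraction
#' classified correctly.
#'
#' @inheritParams knn_classify
#' @return List with `accuracy`, per-cell `predicted` labels and
#'   `single_class` flag (TRUE when the training set is degenerate, holding
#'   only one class; the accuracy is still defined).
#' @export
loo_validation <- function(train, labels, k = 3L, standardize = TRUE) {
  tr <- .knn_features(train)
  labels <- as.character(labels)
  if (nrow(tr) < k + 1L) stop("need at least k + 1 training cells")
  pred <- vapply(seq_len(nrow(tr)), function(i) {
    knn_classify(tr[-i, , drop = FALSE], labels[-i], tr[i, ], k = k,
                 standardize = standardize)
  }, "")
  list(accuracy = mean(pred == labels), predicted = pred,
       single_class = length(unique(labels)) < 2L)
}

#' Predict SST subtypes for a cohort table
#'
#' Adds an `mtype_predicted` column to a cohort data frame from its
#' `rin_mohm` / `tau_ms` columns, using labelled rows (`mtype` of `"MC"` or
#' `"nMC"`) as the training set.
#'
#' @param cohort Data frame with `rin_mohm`, `tau_ms` and an `mtype` column
#'   (NA for unlabeled cells).
#' @inheritParams knn_classify
#' @return The cohort with `mtype_predicted` filled for every row (labelled
#'   rows keep their own label).
#' @export
predict_mtype <- function(cohort, k = 3L, standardize = TRUE) {
  lab <- !is.na(cohort$mtype)
  if (!any(lab)) stop("no labelled training cells")
  feats <- cohort[, c("rin_mohm", "tau_ms")]
  pred <- cohort$mtype
  if (any(!lab))
    pred[!lab] <- knn_classify(feats[lab, ], cohort$mtype[lab],
                               feats[!lab, ], k = k, standardize = standardize)
  cohort$mtype_predicted <- pred
  cohort
}
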
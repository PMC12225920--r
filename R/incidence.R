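# Response-incidence modelling: per-stratum tabulation, logistic regression of
# responsiveness on cell type / layer / intracellular solution (treatment
# coding, IRLS via stats::glm), deviance-based stepwise selection and
# McFadden's pseudo-R-squared.

#' Tabulate responsiveness by stratum
#'
#' Counts and percentages of responsive cells per (type, nucleus, layer)
#' stratum plus a pooled `"all"` row per (type, nucleus) group. Percentages
#' are reported to one decimal.
#'
#' @param cohort Data frame of per-cell records with columns `type`,
#'   `nucleus`, `layer` and logical `responsive`.
#' @return Data frame with `type, nucleus, layer, n, n_responsive, pct`.
#' @export
incidence_table <- function(cohort) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  strat <- function(df, layer_lab) {
    data.frame(type = df$type[1L], nucleus = df$nucleus[1L], layer = layer_lab,
               n = nrow(df), n_responsive = sum(df$responsive),
               pct = round(100 * sum(df$responsive) / nrow(df), 1L),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (g in split(cohort, list(cohort$type, cohort$nucleus), drop = TRUE)) {
    out[[length(out) + 1L]] <- strat(g, "all")
    for (l in split(g, g$layer))
      out[[length(out) + 1L]] <- strat(l, l$layer[1L])
  }
  res <- do.call(rbind, out)
  res[order(res$type, res$nucleus, res$layer != "all", res$layer), ]
}

.ref_levels <- c(type = "VIP", layer = "LI", solution = "K")

# build the model frame with treatment coding and stated reference levels
.model_frame <- function(cohort, terms) {
  mf <- data.frame(responsive = as.logical(cohort$responsive))
  for (tm in terms) {
    f <- factor(cohort[[tm]])
    if (tm %in% names(.ref_levels) && .ref_levels[[tm]] %in% levels(f))
      f <- stats::relevel(f, .ref_levels[[tm]])
    mf[[tm]] <- f
  }
  mf
}

#' Fit the logistic incidence model
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares) of
#' `responsive ~ terms` with treatment-coded factors (reference levels
#' VIP / LI / K). Quasi-separation (fitted probabilities collapsing to 0/1)
#' is flagged rather than treated as an error; iterations are capped at 100.
#'
#' @param cohort Per-cell data frame with a logical `responsive` column and
#'   the predictor columns.
#' @param terms Character vector of predictor factors from
#'   `c("type", "layer", "solution")`; empty for the constant-only model.
#' @return A `glm_fit` list: `terms`, `fit` (the glm object), `coefficients`,
#'   `loglik`, `deviance`, `chisq_vs_constant`, `df`, `p_value`,
#'   `mcfadden_r2`, `separation` flag.
#' @export
fit_logistic <- function(cohort, terms = character()) {
  if (length(unique(cohort$responsive)) < 2L)
    stop("response must contain both classes")
  mf <- .model_frame(cohort, terms)
  fml <- if (length(terms))
    stats::as.formula(paste("responsive ~", paste(terms, collapse = " + ")))
  else stats::as.formula("responsive ~ 1")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = mf,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  # quasi-separation also shows as diverging linear predictors
  if (!separation && any(abs(stats::predict(fit, type = "link")) > 15))
    separation <- TRUE
  null_fit <- stats::glm(responsive ~ 1, family = stats::binomial(), data = mf)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  chisq <- 2 * (ll - ll0)
  df <- length(stats::coef(fit)) - 1L
  structure(list(
    terms = terms, fit = fit, coefficients = stats::coef(fit),
    loglik = ll, deviance = stats::deviance(fit),
    loglik_null = ll0, chisq_vs_constant = chisq, df = df,
    p_value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    mcfadden_r2 = if (ll0 != 0) 1 - ll / ll0 else NA_real_,
    separation = separation), class = "glm_fit")
}

#' McFadden's pseudo-R-squared
#'
#' `1 - LL_model / LL_null` for a fitted logistic model against the
#' constant-only fit on the same response.
#'
#' @param fit,null_fit `glm_fit` objects from [fit_logistic()]; `null_fit`
#'   must be the constant-only model.
#' @return Dimensionless value in `[0, 1)`; NA with a warning when the null
#'   log-likelihood is zero (all-identical response).
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  if (length(null_fit$terms)) stop("null_fit must be the constant-only model")
  if (null_fit$loglik == 0) {
    warning("null log-likelihood is zero; McFadden's R2 undefined")
    return(NA_real_)
  }
  1 - fit$loglik / null_fit$loglik
}

#' Stepwise term selection by deviance tests
#'
#' Starting from the constant-only model, alternately adds the candidate term
#' with the smallest likelihood-ratio p-value (if `<= p_enter`) and removes
#' any included term whose drop-test p-value exceeds `p_remove`, whole factors
#' at a time, until the model is stable. Reports the chi-squared test against
#' the constant model and McFadden's R-squared.
#'
#' @inheritParams fit_logistic
#' @param candidates Candidate factors (default `c("type","layer","solution")`
#'   intersected with the cohort's columns).
#' @param p_enter,p_remove Entry / removal thresholds for the deviance test
#'   (defaults 0.05 / 0.10).
#' @return The selected `glm_fit` (possibly the constant model), with a
#'   `selection` element recording the add/drop path.
#' @export
stepwise_select <- function(cohort,
                            candidates = intersect(c("type", "layer", "solution"),
                                                   names(cohort)),
                            p_enter = 0.05, p_remove = 0.10) {
  included <- character()
  path <- character()
  lrt_p <- function(small, big) {
    ch <- 2 * (big$loglik - small$loglik)
    df <- big$df - small$df
    if (df <= 0) return(1)
    stats::pchisq(max(ch, 0), df, lower.tail = FALSE)
  }
  current <- fit_logistic(cohort, included)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 20L) break  # cycle guard; cannot trigger with p_enter < p_remove
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      trial <- lapply(pool, function(tm) fit_logistic(cohort, c(included, tm)))
      pv <- vapply(trial, lrt_p, 0, small = current)
      if (any(pv <= p_enter)) {
        best <- which.min(pv)
        included <- c(included, pool[best])
        current <- trial[[best]]
        path <- c(path, paste0("+", pool[best]))
        changed <- TRUE
      }
    }
    # backward step
    if (length(included)) {
      pv <- vapply(included, function(tm) {
        lrt_p(fit_logistic(cohort, setdiff(included, tm)), current)
      }, 0)
      if (any(pv > p_remove)) {
        worst <- which.max(pv)
        path <- c(path, paste0("-", included[worst]))
        included <- setdiff(included, included[worst])
        current <- fit_logistic(cohort, included)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current$selection <- path
  current
}
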
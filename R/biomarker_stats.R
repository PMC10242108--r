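#' qPCR fold enrichment by the 2^-dCT method
#'
#' `fold = 2^-(ct_target - ct_reference)`, the expression of a target
#' miRNA normalized to an endogenous reference miRNA (hsa-miR-30d in the
#' intended assay). Vectorised.
#'
#' @param ct_target,ct_reference Ct values in cycles (finite).
#' @return Strictly positive fold enrichment(s).
#' @export
fold_enrichment <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite (non-amplified wells are treated as ",
         "missing samples and must be dropped, not imputed)")
  2^-(ct_target - ct_reference)
}

#' Predictor presets
#'
#' The multiplicative predictors combining fold enrichments of the three
#' plasma miRNAs of the signature: P1 = hsa-miR-4311 x hsa-let-7i-3p,
#' P2 = hsa-miR-5096 x hsa-let-7i-3p, P3 = hsa-miR-4311 x hsa-miR-5096,
#' and the ternary P combining all three.
#'
#' @format Named list of character vectors (component miRNAs).
#' @export
predictor_presets <- list(
  P1 = c("hsa-miR-4311", "hsa-let-7i-3p"),
  P2 = c("hsa-miR-5096", "hsa-let-7i-3p"),
  P3 = c("hsa-miR-4311", "hsa-miR-5096"),
  P  = c("hsa-miR-4311", "hsa-miR-5096", "hsa-let-7i-3p")
)

#' Reference single-miRNA cut-offs
#'
#' Published proposed cut-offs on the 2^-dCT scale for the three signature
#' miRNAs, shipped as documented constants (they derive from a patient
#' cohort and cannot be recomputed from synthetic data): hsa-miR-4311
#' 0.85, hsa-miR-5096 70, hsa-let-7i-3p 0.72.
#'
#' @format Named numeric vector.
#' @export
reference_cutoffs <- c("hsa-miR-4311" = 0.85,
                       "hsa-miR-5096" = 70,
                       "hsa-let-7i-3p" = 0.72)

#' Multiplicative predictor score
#'
#' Product of the fold enrichments of the component miRNAs;
#' order-invariant by construction.
#'
#' @param folds Named numeric vector of per-miRNA fold enrichments.
#' @param components Character vector of component miRNA names (>= 2,
#'   distinct), or the name of a preset in [predictor_presets].
#' @return Numeric score.
#' @export
predictor_score <- function(folds, components) {
  if (is.character(components) && length(components) == 1L &&
      components %in% names(predictor_presets))
    components <- predictor_presets[[components]]
  if (length(components) < 2L || anyDuplicated(components))
    stop("a predictor needs at least two distinct component miRNAs")
  missing <- setdiff(components, names(folds))
  if (length(missing))
    stop("missing fold enrichment for component(s): ",
         paste(missing, collapse = ", "))
  prod(folds[components])
}

#' Dichotomize a score at a cut-off
#'
#' `"high"` iff `score > cutoff` — strictly: a score equal to the cut-off
#' is `"low"` (the "> 70 vs <= 70" rule).
#'
#' @param score Numeric score(s).
#' @param cutoff Finite cut-off.
#' @return Character vector `"high"`/`"low"`.
#' @export
dichotomize <- function(score, cutoff) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite")
  ifelse(score > cutoff, "high", "low")
}

#' Empirical ROC curve with DeLong confidence interval
#'
#' Builds the empirical ROC over all distinct thresholds (classification
#' rule: positive iff score > threshold; thresholds at midpoints between
#' consecutive distinct scores, plus sentinels below and above). The AUC
#' is the trapezoidal area, identical to the pairwise concordance
#' probability with ties counted 1/2. The 95% CI uses the DeLong
#' structural-component variance estimator. Deterministic.
#'
#' @param scores Numeric marker values (higher = more positive).
#' @param labels Binary outcome (logical, or 0/1, or a two-level factor
#'   whose second level is the positive class).
#' @return A `roc_result`: list with `auc`, `ci95`, `se`, `curve`
#'   (`data.frame` threshold/tpr/fpr/sensitivity/specificity), `n_pos`,
#'   `n_neg`, and the structural components `v10`, `v01`.
#' @export
roc_analysis <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("scores and labels differ in length")
  ok <- is.finite(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  m <- sum(y == 1L); n <- sum(y == 0L)
  if (m < 2L || n < 2L)
    stop("need at least 2 samples in each outcome class (got ", m,
         " positive, ", n, " negative)")
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  # DeLong structural components: psi(X_i, Y_j) = 1, 1/2, 0
  v10 <- vapply(pos, function(x)
    mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(x)
    mean((pos > x) + 0.5 * (pos == x)), numeric(1))
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  curve <- data.frame(threshold = thr, sensitivity = sens,
                      specificity = spec, tpr = sens, fpr = 1 - spec)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  structure(list(auc = auc, ci95 = ci, se = se, curve = curve,
                 n_pos = m, n_neg = n, v10 = v10, v01 = v01,
                 scores = scores, labels = y),
            class = "roc_result")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels[!is.na(labels)]))
  if (is.numeric(labels) && all(u %in% c(0, 1))) return(as.integer(labels))
  if (length(u) == 2L) return(as.integer(labels == u[2]))
  stop("labels must be binary")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (95%% CI %.4f-%.4f), %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Select an operating cut-off on a ROC curve
#'
#' `youden` maximises sensitivity + specificity - 1; `liu` maximises
#' sensitivity x specificity. Ties break toward higher specificity, then
#' toward the higher threshold.
#'
#' @param roc A `roc_result` from [roc_analysis()].
#' @param method `"youden"` or `"liu"`.
#' @return List with `cutoff`, `sensitivity`, `specificity` and the
#'   criterion `value` at the optimum.
#' @export
select_cutoff <- function(roc, method = c("youden", "liu")) {
  method <- match.arg(method)
  cv <- roc$curve
  if (nrow(cv) < 2L || length(unique(roc$scores)) < 2L)
    stop("degenerate ROC curve: no threshold separates the scores")
  crit <- switch(method,
    youden = cv$sensitivity + cv$specificity - 1,
    liu = cv$sensitivity * cv$specificity)
  ord <- order(-crit, -cv$specificity, -cv$threshold)
  best <- cv[ord[1], ]
  list(cutoff = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, value = crit[ord[1]],
       method = method)
}

#' DeLong test comparing two AUCs
#'
#' Two-sided z-test on the AUC difference with DeLong (co)variance. In
#' paired mode both markers must be measured on the same samples (equal
#' class sizes and ordering); the covariance of the structural components
#' is then subtracted.
#'
#' @param roc_a,roc_b `roc_result` objects.
#' @param paired Logical; were both scores measured on the same samples?
#' @return List with `delta` (AUC_a - AUC_b), `se`, `z`, `p_value`.
#' @export
compare_auc <- function(roc_a, roc_b, paired = FALSE) {
  delta <- roc_a$auc - roc_b$auc
  if (paired) {
    if (roc_a$n_pos != roc_b$n_pos || roc_a$n_neg != roc_b$n_neg)
      stop("paired comparison requires identical sample sets under ",
           "both markers")
    m <- roc_a$n_pos; n <- roc_a$n_neg
    s10 <- stats::var(roc_a$v10 - roc_b$v10)
    s01 <- stats::var(roc_a$v01 - roc_b$v01)
    var_d <- s10 / m + s01 / n
  } else {
    var_d <- roc_a$se^2 + roc_b$se^2
  }
  if (var_d <= 0) {
    z <- if (abs(delta) < .Machine$double.eps) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_d)
  }
  list(delta = delta, se = sqrt(max(var_d, 0)), z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Read a long-format Ct table
#'
#' Expected CSV columns: `sample_id`, `group`, `mirna`, `ct_target`,
#' `ct_reference`. Rows with missing Ct (non-amplified wells) are dropped
#' with a message, never imputed.
#'
#' @param path CSV path, or a `data.frame` in the same layout.
#' @return Validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  ct <- if (is.data.frame(path)) path else read.csv(path,
                                                    stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "mirna", "ct_target", "ct_reference")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_reference) |
    ct$ct_target <= 0 | ct$ct_reference <= 0
  if (any(bad)) {
    message("dropping ", sum(bad), " well(s) with missing/invalid Ct")
    ct <- ct[!bad, , drop = FALSE]
  }
  ct
}

#' Per-sample fold enrichments and predictor scores from a Ct table
#'
#' @param ct Ct table (see [read_ct_table()]).
#' @param predictors Named list of component vectors (default
#'   [predictor_presets]); predictors whose components are absent from the
#'   table are skipped.
#' @return `data.frame`: one row per sample with `group`, one fold column
#'   per miRNA and one score column per computable predictor.
#' @export
score_ct_table <- function(ct, predictors = predictor_presets) {
  ct <- read_ct_table(ct)
  ct$fold <- fold_enrichment(ct$ct_target, ct$ct_reference)
  wide <- stats::reshape(
    ct[, c("sample_id", "group", "mirna", "fold")],
    idvar = c("sample_id", "group"), timevar = "mirna",
    direction = "wide")
  names(wide) <- sub("^fold\\.", "", names(wide))
  mirnas <- setdiff(names(wide), c("sample_id", "group"))
  for (p in names(predictors)) {
    if (!all(predictors[[p]] %in% mirnas)) next
    wide[[p]] <- apply(wide[, predictors[[p]], drop = FALSE], 1, prod)
  }
  rownames(wide) <- NULL
  wide
}
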
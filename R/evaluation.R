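# Agreement and accuracy: Cohen's kappa between the two models,
# sensitivity/specificity against gold-standard labels with exact
# Clopper-Pearson intervals, overall and stratified.

#' Confusion table of binary calls against gold labels
#'
#' Accepts either plain logical/0-1 vectors (paired positionally) or two
#' data frames keyed by `facility_id` (columns `damaged` and `gold_label`),
#' joined by key. Facilities without a gold label are excluded and listed
#' in the `"excluded"` attribute.
#'
#' @param calls Logical/0-1 vector, or tibble with `facility_id`,
#'   `damaged`.
#' @param gold Logical/0-1 vector, or tibble with `facility_id`,
#'   `gold_label`.
#' @return List of class `confusion_table` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(calls, gold) {
  if (is.data.frame(calls)) {
    stopifnot(is.data.frame(gold))
    m <- merge(as.data.frame(calls[c("facility_id", "damaged")]),
               as.data.frame(gold[c("facility_id", "gold_label")]),
               by = "facility_id")
    if (nrow(m) == 0L) stop("no facilities in common", call. = FALSE)
    excluded <- m$facility_id[is.na(m$gold_label)]
    m <- m[!is.na(m$gold_label), ]
    pred <- as.logical(m$damaged); truth <- m$gold_label == 1
  } else {
    stopifnot(length(calls) == length(gold))
    keep <- !is.na(gold)
    excluded <- which(!keep)
    pred <- as.logical(calls[keep]); truth <- as.logical(gold[keep])
  }
  out <- structure(
    list(tp = sum(pred & truth), fp = sum(pred & !truth),
         fn = sum(!pred & truth), tn = sum(!pred & !truth)),
    class = "confusion_table")
  attr(out, "excluded") <- excluded
  out
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Central exact interval obtained by inverting the binomial tail
#' probabilities, computed through the beta quantile identity:
#' `low = qbeta(alpha/2, k, n-k+1)` (0 when k = 0) and
#' `high = qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k Successes (vectorized), `0 <= k <= n`.
#' @param n Trials.
#' @param alpha Two-sided level in (0, 1). Default 0.05.
#' @return Two-column matrix with `low` and `high`.
#' @examples
#' round(100 * clopper_pearson(3, 7), 2)   # 9.90 to 81.59
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(all(k >= 0), all(k <= n), all(n >= 1), alpha > 0, alpha < 1)
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(low = low, high = high)
}

#' Sensitivity and specificity with exact intervals
#'
#' Sensitivity is the proportion of gold-positive units called damaged,
#' specificity the proportion of gold-negative units called undamaged;
#' both carry exact Clopper-Pearson intervals. A zero denominator flags
#' the corresponding estimate as undefined (NA) rather than erroring.
#'
#' @param table A [confusion()] table.
#' @param alpha Two-sided interval level.
#' @return List of class `accuracy_result`: `sensitivity`, `sens_ci`,
#'   `specificity`, `spec_ci`, `table`, `alpha`.
#' @export
sens_spec <- function(table, alpha = 0.05) {
  npos <- table$tp + table$fn
  nneg <- table$tn + table$fp
  sens <- if (npos >= 1) table$tp / npos else NA_real_
  spec <- if (nneg >= 1) table$tn / nneg else NA_real_
  sens_ci <- if (npos >= 1) clopper_pearson(table$tp, npos, alpha)[1L, ]
             else c(low = NA_real_, high = NA_real_)
  spec_ci <- if (nneg >= 1) clopper_pearson(table$tn, nneg, alpha)[1L, ]
             else c(low = NA_real_, high = NA_real_)
  structure(list(sensitivity = sens, sens_ci = sens_ci,
                 specificity = spec, spec_ci = spec_ci,
                 table = table, alpha = alpha),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  fmt <- function(est, ci) {
    if (is.na(est)) return("undefined")
    sprintf("%.2f%% (%.0f%% CI %.2f%% to %.2f%%)", 100 * est,
            100 * (1 - x$alpha), 100 * ci[1L], 100 * ci[2L])
  }
  cat("sensitivity:", fmt(x$sensitivity, x$sens_ci), "\n")
  cat("specificity:", fmt(x$specificity, x$spec_ci), "\n")
  invisible(x)
}

#' Cohen's kappa for paired binary raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with `po` the
#' observed agreement fraction and `pe` the expected agreement from the
#' marginal products. The default confidence interval uses the asymptotic
#' large-sample standard error `sqrt(po (1 - po) / (n (1 - pe)^2))`,
#' truncated to \[-1, 1\]; a nonparametric bootstrap is available. When
#' both raters are constant (`pe = 1`) kappa is undefined and flagged,
#' never silently 0 or 1.
#'
#' @param x,y Paired binary vectors (logical or 0/1) of equal length >= 2.
#' @param alpha Two-sided interval level.
#' @param ci_method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return List of class `agreement_result`: `kappa`, `se`, `ci_low`,
#'   `ci_high`, `n`, `po`, `pe`, `undefined`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
cohens_kappa <- function(x, y, alpha = 0.05,
                         ci_method = c("asymptotic", "bootstrap"),
                         n_boot = 2000L) {
  ci_method <- match.arg(ci_method)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  if (!all(x %in% c(0, 1, TRUE, FALSE)) || !all(y %in% c(0, 1, TRUE, FALSE))) {
    stop("entries must be binary", call. = FALSE)
  }
  x <- as.logical(x); y <- as.logical(y)
  n <- length(x)
  kappa_point <- function(x, y) {
    po <- mean(x == y)
    pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
    if (pe >= 1) return(c(NA_real_, po, pe))
    c((po - pe) / (1 - pe), po, pe)
  }
  kp <- kappa_point(x, y)
  if (is.na(kp[1L])) {
    return(structure(list(kappa = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, n = n,
                          po = kp[2L], pe = kp[3L], undefined = TRUE),
                     class = "agreement_result"))
  }
  po <- kp[2L]; pe <- kp[3L]; kappa <- kp[1L]
  if (ci_method == "asymptotic") {
    se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
    z <- stats::qnorm(1 - alpha / 2)
    lo <- max(kappa - z * se, -1); hi <- min(kappa + z * se, 1)
  } else {
    ks <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      kappa_point(x[idx], y[idx])[1L]
    }, 0)
    ks <- ks[!is.na(ks)]
    se <- stats::sd(ks)
    qs <- stats::quantile(ks, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- max(qs[1L], -1); hi <- min(qs[2L], 1)
  }
  structure(list(kappa = kappa, se = se, ci_low = lo, ci_high = hi, n = n,
                 po = po, pe = pe, undefined = FALSE),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("kappa: undefined (both raters constant; n=%d)\n", x$n))
  } else {
    cat(sprintf("kappa = %.3f (CI %.3f to %.3f), po = %.3f, pe = %.3f, n = %d\n",
                x$kappa, x$ci_low, x$ci_high, x$po, x$pe, x$n))
  }
  invisible(x)
}

#' Agreement and accuracy by stratum
#'
#' One row per value of each stratifying variable plus a pooled row.
#' Agreement (kappa) between the two models' calls is always computed;
#' accuracy (sensitivity/specificity per model) is added for facilities
#' with gold labels. Strata with undefined kappa are flagged, not dropped.
#'
#' @param calls_a,calls_b Call tibbles keyed by `facility_id`.
#' @param facilities Facility tibble with the stratum columns and
#'   (optionally) `gold_label`.
#' @param strata Character vector of facility columns to stratify by.
#'   Default `c("ftype", "city")`.
#' @param alpha Interval level.
#' @return Tibble with `stratum`, `level`, `n`, kappa fields, and per-model
#'   sensitivity/specificity (NA when no gold labels in the stratum).
#' @export
stratified_metrics <- function(calls_a, calls_b, facilities,
                               strata = c("ftype", "city"), alpha = 0.05) {
  bad <- setdiff(strata, names(facilities))
  if (length(bad)) stop("unknown stratum key: ", bad[1L], call. = FALSE)
  df <- facilities
  df$call_a <- calls_a$damaged[match(df$facility_id, calls_a$facility_id)]
  df$call_b <- calls_b$damaged[match(df$facility_id, calls_b$facility_id)]
  if (any(is.na(df$call_a)) || any(is.na(df$call_b))) {
    stop("calls missing for some facilities", call. = FALSE)
  }

  one_row <- function(sub, stratum, level) {
    kp <- if (nrow(sub) >= 2) {
      cohens_kappa(sub$call_a, sub$call_b, alpha = alpha)
    } else {  # a singleton stratum cannot support an agreement estimate
      list(kappa = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           undefined = TRUE)
    }
    row <- tibble::tibble(
      stratum = stratum, level = level, n = nrow(sub),
      kappa = kp$kappa, kappa_low = kp$ci_low, kappa_high = kp$ci_high,
      kappa_undefined = kp$undefined,
      sens_a = NA_real_, spec_a = NA_real_,
      sens_b = NA_real_, spec_b = NA_real_, n_gold = 0L)
    if ("gold_label" %in% names(sub) && any(!is.na(sub$gold_label))) {
      g <- sub[!is.na(sub$gold_label), ]
      acc_a <- sens_spec(confusion(g$call_a, g$gold_label), alpha)
      acc_b <- sens_spec(confusion(g$call_b, g$gold_label), alpha)
      row$sens_a <- acc_a$sensitivity; row$spec_a <- acc_a$specificity
      row$sens_b <- acc_b$sensitivity; row$spec_b <- acc_b$specificity
      row$n_gold <- nrow(g)
    }
    row
  }

  rows <- list(one_row(df, "pooled", "pooled"))
  for (s in strata) {
    for (lev in unique(df[[s]])) {
      rows[[length(rows) + 1L]] <- one_row(df[df[[s]] == lev, ], s, lev)
    }
  }
  dplyr::bind_rows(rows)
}
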
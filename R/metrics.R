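# Confusion-matrix statistics: Precision, Recall, NPV, Specificity,
# Balanced Accuracy and the Matthews Correlation Coefficient, plus their
# aggregation over repeated cross-validation cycles.

#' Confusion-matrix metrics
#'
#' Computes the six statistics from TP/FP/TN/FN counts:
#' \deqn{Precision = TP/(TP+FP)}
#' \deqn{Recall = TP/(TP+FN)}
#' \deqn{NPV = TN/(TN+FN)}
#' \deqn{Specificity = TN/(TN+FP)}
#' \deqn{BA = (Recall + Specificity)/2}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' A statistic whose denominator is zero is `NA` (undefined), never
#' silently 0; BA is `NA` if either of its terms is.
#'
#' @param TP,FP,TN,FN non-negative integer counts, total at least 1.
#' @return object of class `kp_metrics`: a list with the four counts and
#'   the six statistics.
#' @examples
#' m <- kp_compute_metrics(90, 20, 80, 10)
#' round(m$mcc, 4)   # 0.7035
#' @export
kp_compute_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("empty confusion matrix")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rate(TP, TP + FP)
  recall <- rate(TP, TP + FN)
  npv <- rate(TN, TN + FN)
  specificity <- rate(TN, TN + FP)
  ba <- if (is.na(recall) || is.na(specificity)) NA_real_
        else (recall + specificity) / 2
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) NA_real_
         else (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 precision = precision, recall = recall, npv = npv,
                 specificity = specificity, ba = ba, mcc = mcc),
            class = "kp_metrics")
}

#' @export
print.kp_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  for (m in .kp_metric_names)
    cat(sprintf("  %-11s %s\n", m,
                ifelse(is.na(x[[m]]), "undefined", formatC(x[[m]], digits = 2,
                                                           format = "f"))))
  invisible(x)
}

.kp_metric_names <- c("precision", "recall", "npv", "specificity", "ba", "mcc")

#' Metrics from predicted and true labels
#'
#' @param truth,predicted logical vectors (or factors coercible to logical
#'   with `TRUE` = active/positive).
#' @return a `kp_metrics`.
#' @export
kp_metrics_from_labels <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted))
  kp_compute_metrics(TP = sum(truth & predicted),
                     FP = sum(!truth & predicted),
                     TN = sum(!truth & !predicted),
                     FN = sum(truth & !predicted))
}

#' Summarize metrics across repeats
#'
#' Mean and population standard deviation of each statistic over repeated
#' evaluation cycles, the reporting convention behind "0.96 +/- 0.01"
#' tables. Undefined (`NA`) values are excluded with a recorded count.
#'
#' @param metrics_list non-empty list of `kp_metrics`.
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return object of class `kp_metric_summary`: data.frame `summary` with
#'   columns `metric`, `mean`, `sd`, `n_undefined`, plus the per-repeat
#'   table `repeats`.
#' @export
kp_summarize_repeats <- function(metrics_list, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!length(metrics_list)) stop("empty metrics list")
  stopifnot(all(vapply(metrics_list, inherits, logical(1), "kp_metrics")))
  rep_tab <- do.call(rbind, lapply(metrics_list, function(m)
    as.data.frame(m[c("TP", "FP", "TN", "FN", .kp_metric_names)])))
  summary <- do.call(rbind, lapply(.kp_metric_names, function(nm) {
    v <- rep_tab[[nm]]
    ok <- !is.na(v)
    n <- sum(ok)
    mu <- if (n) mean(v[ok]) else NA_real_
    sdv <- if (n > 0) {
      if (sd_type == "population") sqrt(mean((v[ok] - mu)^2))
      else if (n > 1) stats::sd(v[ok]) else 0
    } else NA_real_
    data.frame(metric = nm, mean = mu, sd = sdv, n_undefined = sum(!ok))
  }))
  structure(list(summary = summary, repeats = rep_tab,
                 n_repeats = length(metrics_list), sd_type = sd_type),
            class = "kp_metric_summary")
}

#' @export
print.kp_metric_summary <- function(x, ...) {
  cat(sprintf("Metric summary over %d repeats (sd: %s)\n",
              x$n_repeats, x$sd_type))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %s +/- %s%s\n", s$metric[i],
                ifelse(is.na(s$mean[i]), "undef", sprintf("%.2f", s$mean[i])),
                ifelse(is.na(s$sd[i]), "undef", sprintf("%.2f", s$sd[i])),
                if (s$n_undefined[i]) sprintf("  (%d undefined)", s$n_undefined[i])
                else ""))
  }
  invisible(x)
}

#' Mean value of one metric from a summary
#' @param summary a `kp_metric_summary`.
#' @param metric metric name.
#' @return numeric scalar (may be `NA`).
#' @export
kp_summary_mean <- function(summary, metric) {
  s <- summary$summary
  s$mean[match(metric, s$metric)]
}

#' Panel success rate
#'
#' Percentage of correct predictions: `100 * n_correct / n_total`.
#'
#' @param n_correct,n_total integers, `0 <= n_correct <= n_total`,
#'   `n_total >= 1`.
#' @return percentage in `[0, 100]`.
#' @examples
#' kp_success_rate(15, 20)  # 75
#' @export
kp_success_rate <- function(n_correct, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_correct < 0 || n_correct > n_total) stop("n_correct out of range")
  100 * n_correct / n_total
}

# Display rounding used in report tables (half-even, 2 d.p. like the
# published convention).
.kp_round2 <- function(x) round(x, 2)
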
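#' Mono-exponential ADC fit
#'
#' Least-squares line fit of ln S(b) against b; the apparent diffusion
#' coefficient is -slope, reported in 1e-3 mm^2/s (b in s/mm^2). Exact
#' inverse of [simulate_dwi_series()] at zero noise.
#'
#' @param dwi a `dwi_series`, or a list/data.frame with `b_values` and
#'   `signals`.
#' @return object of class `adc_result`: list with `adc` (1e-3 mm^2/s),
#'   `s0_fit`, `r_squared`, `unit`.
#' @export
fit_adc <- function(dwi) {
  b <- dwi$b_values; s <- dwi$signals
  if (length(b) < 2L) stop("need >= 2 b-values", call. = FALSE)
  if (any(s <= 0)) stop("nonpositive signal: log-linear ADC fit undefined",
                        call. = FALSE)
  fit <- stats::lm(log(s) ~ b)
  slope <- stats::coef(fit)[["b"]]
  sst <- sum((log(s) - mean(log(s)))^2)
  r2 <- if (sst < 1e-24) 1 else 1 - sum(stats::resid(fit)^2) / sst
  structure(list(adc = -slope * 1e3, s0_fit = exp(stats::coef(fit)[[1]]),
                 r_squared = min(max(r2, 0), 1), unit = "1e-3 mm^2/s"),
            class = "adc_result")
}

#' @export
print.adc_result <- function(x, ...) {
  cat(sprintf("ADC = %.4f %s (S0 = %.3f, R^2 = %.4f)\n",
              x$adc, x$unit, x$s0_fit, x$r_squared))
  invisible(x)
}

#' Enhancement metrics from a time-intensity curve
#'
#' From a dynamic contrast-enhancement TIC: the maximum enhancement ME
#' (peak signal after baseline correction) and the relative enhancement
#' ratio Er (peak-to-baseline signal ratio). The signal is corrected twice
#' before the peak is read: a baseline-offset subtraction and a linear
#' drift correction estimated from the pre-enhancement frames (a no-op when
#' only one pre-enhancement frame exists); both corrections are switchable.
#'
#' @param tic a `tic` object (or list with `times`, `signal`,
#'   `baseline_index`).
#' @param correct_baseline,correct_drift enable the two corrections.
#' @return object of class `enhancement_result`: list with `me`, `er`,
#'   `peak_index`, `baseline`.
#' @export
compute_me_er <- function(tic, correct_baseline = TRUE, correct_drift = TRUE) {
  s <- tic$signal; bi <- tic$baseline_index
  if (is.null(bi) || bi < 1L || bi >= length(s))
    stop("invalid baseline_index", call. = FALSE)
  baseline <- s[bi]
  if (baseline <= 0) stop("baseline signal must be > 0", call. = FALSE)
  corrected <- s
  if (correct_drift && bi >= 2L) {
    t <- tic$times
    drift <- stats::lm(s[seq_len(bi)] ~ t[seq_len(bi)])
    corrected <- corrected -
      (stats::coef(drift)[[2]] * (t - t[bi]))   # remove pre-enhancement trend
  }
  post <- corrected[(bi + 1L):length(corrected)]
  peak_rel <- which.max(post)
  peak <- max(post)
  er <- max(peak, baseline) / baseline          # flat curves give er = 1
  me <- if (correct_baseline) max(peak - baseline, 0) else peak
  structure(list(me = me, er = er, peak_index = bi + peak_rel,
                 baseline = baseline),
            class = "enhancement_result")
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf("ME = %.3f, Er = %.3f (peak frame %d, baseline %.3f)\n",
              x$me, x$er, x$peak_index, x$baseline))
  invisible(x)
}

#' ROC analysis of a two-group ADC table
#'
#' Sweeps thresholds over all midpoints of the observed ADC values,
#' computes sensitivity and specificity at each, the trapezoid AUC, and the
#' Youden-optimal operating threshold; sensitivity/specificity are also
#' reported at a caller-specified threshold (the clinical operating point).
#'
#' @param table data.frame with columns `group` and `adc`.
#' @param positive_group group label treated as positive (default
#'   "algorithm", the higher-ADC group).
#' @param direction "greater" if larger ADC indicates the positive group,
#'   "less" otherwise.
#' @param threshold optional clinical threshold (e.g. 1.25 1e-3 mm^2/s) at
#'   which sensitivity/specificity are additionally reported.
#' @return object of class `roc_curve`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `chosen_threshold`,
#'   `sens_at_chosen`, `spec_at_chosen`, and (when `threshold` is given)
#'   `threshold`, `sens_at_threshold`, `spec_at_threshold`.
#' @export
roc_analysis <- function(table, positive_group = "algorithm",
                         direction = c("greater", "less"),
                         threshold = NULL) {
  direction <- match.arg(direction)
  if (!all(c("group", "adc") %in% names(table)))
    stop("table must have `group` and `adc` columns", call. = FALSE)
  pos <- table$adc[table$group == positive_group]
  neg <- table$adc[table$group != positive_group]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both groups must be present", call. = FALSE)
  sc <- if (direction == "greater") 1 else -1
  pos <- sc * pos; neg <- sc * neg
  v <- sort(unique(c(pos, neg)))
  thr <- c(-Inf, if (length(v) > 1L) (v[-1] + v[-length(v)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), 1)
  spec <- vapply(thr, function(t) mean(neg < t), 1)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  j <- sens + spec - 1
  best <- which.max(j)                    # ties: first (lowest threshold)
  out <- list(thresholds = sc * thr, sensitivity = sens, specificity = spec,
              auc = auc,
              chosen_threshold = sc * thr[best],
              sens_at_chosen = sens[best], spec_at_chosen = spec[best],
              positive_group = positive_group, direction = direction)
  if (!is.null(threshold)) {
    tt <- sc * threshold
    out$threshold <- threshold
    out$sens_at_threshold <- mean(pos >= tt)
    out$spec_at_threshold <- mean(neg < tt)
  }
  structure(out, class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; Youden threshold %.4f (sens %.1f%%, spec %.1f%%)\n",
              x$auc, x$chosen_threshold, 100 * x$sens_at_chosen,
              100 * x$spec_at_chosen))
  if (!is.null(x$threshold))
    cat(sprintf("  at threshold %.4f: sens %.1f%%, spec %.1f%%\n",
                x$threshold, 100 * x$sens_at_threshold,
                100 * x$spec_at_threshold))
  invisible(x)
}

#' Diagnostic accuracy from confusion counts
#'
#' Integer-percent accuracy floor(100 * correct / total): truncation toward
#' zero is the reporting convention this package follows throughout
#' (46 correct / 3 errors -> 93, 41 correct / 8 errors -> 83).
#'
#' @param n_correct,n_error nonnegative integer counts (total >= 1).
#'   `n_correct` may also be a list with fields `n_correct` and `n_error`.
#' @return integer percentage.
#' @export
accuracy_from_counts <- function(n_correct, n_error = NULL) {
  if (is.list(n_correct)) {
    n_error <- n_correct$n_error
    n_correct <- n_correct$n_correct
  }
  if (n_correct < 0 || n_error < 0) stop("counts must be >= 0", call. = FALSE)
  total <- n_correct + n_error
  if (total < 1) stop("at least one case required", call. = FALSE)
  as.integer(100 * n_correct / total)     # integer division = truncation
}

#' Pooled-variance two-sample t test
#'
#' Independent-samples t with pooled variance; accepts raw sample vectors
#' or `(mean, sd, n)` summary lists interchangeably per side.
#'
#' @param a,b numeric vectors, or lists with `mean`, `sd`, `n`.
#' @return list with `t`, `df`, `p` (two-sided) and per-group summaries.
#' @export
two_sample_t <- function(a, b) {
  summarize <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(mean = x$mean, sd = x$sd, n = x$n)
    } else {
      if (length(x) < 2L) stop("need n >= 2 per group", call. = FALSE)
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  sa <- summarize(a); sb <- summarize(b)
  if (sa$n < 2L || sb$n < 2L) stop("need n >= 2 per group", call. = FALSE)
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  t <- (sa$mean - sb$mean) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       group_a = sa, group_b = sb)
}

#' Full cohort diagnostic report
#'
#' Per-group ADC summaries (mean, sd, min, max), per-group diagnostic
#' accuracy from the correctness flags, the pooled two-sample t test on
#' ADC, and the ROC analysis with sensitivity/specificity at the supplied
#' clinical threshold.
#'
#' @param table cohort data.frame with columns `patient_id`, `group`,
#'   `adc`, `correct`.
#' @param adc_threshold clinical operating threshold in 1e-3 mm^2/s
#'   (default 1.25).
#' @param positive_group,direction passed to [roc_analysis()].
#' @return object of class `cohort_report`: list with `groups` (data.frame,
#'   one row per group), `t_test`, `roc`.
#' @export
cohort_report <- function(table, adc_threshold = 1.25,
                          positive_group = "algorithm",
                          direction = "greater") {
  need <- c("group", "adc", "correct")
  if (!all(need %in% names(table)))
    stop(sprintf("table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  gs <- lapply(split(table, table$group, drop = TRUE), function(d) {
    data.frame(group = as.character(d$group[1]), n = nrow(d),
               adc_mean = mean(d$adc), adc_sd = stats::sd(d$adc),
               adc_min = min(d$adc), adc_max = max(d$adc),
               n_correct = sum(d$correct == 1),
               n_error = sum(d$correct != 1),
               accuracy_pct = accuracy_from_counts(sum(d$correct == 1),
                                                   sum(d$correct != 1)),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, gs)
  rownames(groups) <- NULL
  tt <- NULL
  if (nrow(groups) == 2L) {
    sp <- split(table$adc, table$group, drop = TRUE)
    tt <- two_sample_t(sp[[1]], sp[[2]])
  }
  roc <- if (nrow(groups) == 2L)
    roc_analysis(table, positive_group = positive_group,
                 direction = direction, threshold = adc_threshold) else NULL
  structure(list(groups = groups, t_test = tt, roc = roc,
                 adc_threshold = adc_threshold),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort diagnostic report\n")
  print(x$groups, row.names = FALSE)
  if (!is.null(x$t_test))
    cat(sprintf("t = %.3f, df = %d, p = %.3g\n",
                x$t_test$t, x$t_test$df, x$t_test$p))
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}
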
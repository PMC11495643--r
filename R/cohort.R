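#' Classify CRT response from outcome measurements
#'
#' Echocardiographic responders show a strictly greater than 10% reduction
#' in LV end-systolic volume at follow-up (`desv_lv > 10`). Clinical
#' responders improve by at least one NYHA class (`nyha_baseline -
#' nyha_followup >= 1`); a strict variant requiring more than one class is
#' available. A CRT (combined) responder satisfies both criteria. Rows
#' with missing outcomes get NA flags and are excluded from group
#' statistics downstream.
#'
#' @param records data frame with columns `desv_lv` (% reduction in LV
#'   end-systolic volume, positive = improvement), `nyha_baseline`,
#'   `nyha_followup` (NYHA classes I-IV coded 1-4).
#' @param strict_clinical logical; require an improvement of more than one
#'   NYHA class (default FALSE: at least one class).
#' @return `records` with logical columns `echo_responder`,
#'   `clinical_responder`, `crt_responder` appended.
#' @export
classify_response <- function(records, strict_clinical = FALSE) {
  stopifnot(all(c("desv_lv", "nyha_baseline", "nyha_followup") %in% names(records)))
  impr <- records$nyha_baseline - records$nyha_followup
  records$echo_responder <- records$desv_lv > 10
  records$clinical_responder <- if (strict_clinical) impr > 1 else impr >= 1
  records$crt_responder <- records$echo_responder & records$clinical_responder
  records
}

#' Two-group comparison of a work metric
#'
#' Two-sided Student's t-test with pooled variance (paired option for
#' within-patient LBBB-vs-CRT comparisons). Degenerate cases (fewer than
#' two observations per group, or zero variance everywhere) return t = 0,
#' p = 1 with `degenerate = TRUE`.
#'
#' @param values numeric vector of metric values.
#' @param group two-level grouping vector (ignored when `paired = TRUE`
#'   and `values`/`values2` are used).
#' @param paired logical; paired t-test of `values` vs `values2`.
#' @param values2 second sample for the paired test.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
group_compare <- function(values, group = NULL, paired = FALSE, values2 = NULL) {
  if (paired) {
    d <- values - values2
    if (length(d) < 2L || stats::sd(d) == 0)
      return(list(t = 0, p = 1, df = length(d) - 1L, degenerate = TRUE))
    tt <- stats::t.test(values, values2, paired = TRUE)
  } else {
    g <- factor(group)
    if (nlevels(g) != 2L) stop("group must have exactly two levels")
    a <- values[g == levels(g)[1]]
    b <- values[g == levels(g)[2]]
    if (length(a) < 2L || length(b) < 2L)
      stop("need at least 2 observations per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(list(t = 0, p = 1, df = length(values) - 2L, degenerate = TRUE))
    tt <- stats::t.test(a, b, var.equal = TRUE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Two-factor ANOVA of a work metric
#'
#' Fixed-effects two-way ANOVA (response group x physiologic state, with
#' interaction) via [stats::aov()].
#'
#' @param values metric values.
#' @param factor1,factor2 factors (e.g. responder status and LBBB/CRT).
#' @return The ANOVA summary table as a data frame.
#' @export
two_way_anova <- function(values, factor1, factor2) {
  d <- data.frame(y = values, f1 = factor(factor1), f2 = factor(factor2))
  as.data.frame(summary(stats::aov(y ~ f1 * f2, data = d))[[1]])
}

#' Regress reverse remodeling on a work metric
#'
#' Simple linear regression of outcome (dESV_LV) on a baseline work
#' metric. R^2 is the squared Pearson correlation and the p-value is that
#' of Pearson's correlation coefficient at n - 2 degrees of freedom.
#'
#' @param metric baseline metric values (predictor).
#' @param desv outcome values (% ESV reduction).
#' @return List of class `work_regression`: `slope`, `intercept`, `r2`,
#'   `p`, `n`.
#' @export
regress_outcome <- function(metric, desv) {
  ok <- is.finite(metric) & is.finite(desv)
  metric <- metric[ok]; desv <- desv[ok]
  n <- length(metric)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(metric) == 0) stop("zero variance in the predictor")
  fit <- stats::lm(desv ~ metric)
  r <- stats::cor(metric, desv)
  p <- if (stats::sd(desv) == 0) 1 else stats::cor.test(metric, desv)$p.value
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r^2, p = p, n = n),
            class = "work_regression")
}

#' @export
print.work_regression <- function(x, ...) {
  cat(sprintf("slope %.3g, intercept %.3g, R^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r2, x$p, x$n))
  invisible(x)
}

#' Read a cohort outcome table from CSV
#'
#' Expects one row per patient with at least `patient_id`, `desv_lv`,
#' `nyha_baseline`, `nyha_followup`; extra columns (age, EF, QRS duration,
#' ...) are kept.
#'
#' @param path CSV file path.
#' @return Data frame of patient records.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "desv_lv", "nyha_baseline", "nyha_followup")
  if (!all(need %in% names(d)))
    stop("cohort CSV must contain columns: ", paste(need, collapse = ", "))
  d
}
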
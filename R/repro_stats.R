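#' Paired measurement table
#'
#' Two repeated qT1 measurements per subject: either two observers
#' (interobserver design) or two sessions of one observer (intraobserver
#' design).
#'
#' @param value1,value2 positive qT1 values in ms, equal length, no
#'   missing entries.
#' @param subject optional subject identifiers (default `1..n`).
#' @param labels length-2 character naming the two columns.
#' @return A `data.frame` of class `measurement_table` with columns
#'   `subject`, `value1`, `value2`.
#' @export
measurement_table <- function(value1, value2, subject = seq_along(value1),
                              labels = c("rater1", "rater2")) {
  if (length(value1) != length(value2)) {
    stop("value columns have different lengths", call. = FALSE)
  }
  if (length(value1) < 1L) stop("table is empty", call. = FALSE)
  bad <- which(!is.finite(value1) | !is.finite(value2) |
                 value1 <= 0 | value2 <= 0)
  if (length(bad)) {
    stop(sprintf("missing or non-positive qT1 values in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(subject = subject, value1 = as.numeric(value1),
                    value2 = as.numeric(value2))
  attr(out, "labels") <- labels
  class(out) <- c("measurement_table", "data.frame")
  out
}

#' Pairwise inter/intraobserver error
#'
#' `|a - b| / ((a + b) / 2) * 100` percent: the absolute difference of the
#' two measurements relative to their mean. Vectorised.
#'
#' @param a,b positive paired measurements (ms).
#' @return Error in percent.
#' @export
pair_error <- function(a, b) {
  if (any(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)) {
    stop("measurements must be positive and finite", call. = FALSE)
  }
  abs(a - b) / ((a + b) / 2) * 100
}

#' Pairwise coefficient of variation
#'
#' Sample SD (n-1 denominator) of the two measurements divided by their
#' mean, in percent. Identically equal to [pair_error()] divided by
#' sqrt(2).
#'
#' @param a,b positive paired measurements (ms).
#' @return CoV in percent.
#' @export
pair_cov <- function(a, b) {
  if (any(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)) {
    stop("measurements must be positive and finite", call. = FALSE)
  }
  # sample SD of {a,b} is |a-b|/sqrt(2)
  (abs(a - b) / sqrt(2)) / ((a + b) / 2) * 100
}

icc_mean_squares <- function(v1, v2) {
  n <- length(v1)
  k <- 2L
  dat <- cbind(v1, v2)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((dat - grand)^2) - k * sum((row_means - grand)^2) -
    n * sum((col_means - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Average-measures intraclass correlation with 95% CI
#'
#' Default model is two-way random effects, absolute agreement, average
#' measures — ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n) — matching the
#' SPSS "two-way random, absolute agreement" convention. The confidence
#' interval uses the F-based method of McGraw & Wong: the single-measures
#' interval (Satterthwaite degrees of freedom) stepped up to average
#' measures by the Spearman-Brown relation. A two-way mixed consistency
#' model, ICC(3,k), is available behind the `model` flag.
#'
#' @param table a [measurement_table()] with at least 3 subjects.
#' @param model `"ICC2k"` (absolute agreement, default) or `"ICC3k"`
#'   (consistency).
#' @param conf confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `model`, `n`, `k`.
#' @export
icc_average <- function(table, model = c("ICC2k", "ICC3k"), conf = 0.95) {
  model <- match.arg(model)
  stopifnot(inherits(table, "measurement_table"))
  v1 <- table$value1
  v2 <- table$value2
  if (length(v1) < 3L) stop("need at least 3 subjects", call. = FALSE)
  ms <- icc_mean_squares(v1, v2)
  n <- ms$n; k <- ms$k; msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  alpha <- 1 - conf
  if (msr <= .Machine$double.eps * max(abs(c(v1, v2)), 1)) {
    warning("between-subject variance is (near) zero; ICC is degenerate")
  }
  if (model == "ICC2k") {
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    up1 <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    low <- low1 * k / (1 + (k - 1) * low1)
    up <- up1 * k / (1 + (k - 1) * up1)
  } else {
    icc <- (msr - mse) / msr
    f_obs <- msr / mse
    df2 <- (n - 1) * (k - 1)
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, df2)
    f_u <- f_obs * stats::qf(1 - alpha / 2, df2, n - 1)
    low <- 1 - 1 / f_l
    up <- 1 - 1 / f_u
  }
  list(icc = icc, ci_low = low, ci_high = up, model = model, n = n, k = k)
}

#' Bland-Altman agreement analysis with proportional-bias test
#'
#' Differences are oriented `value1 - value2` (observer 1 minus observer 2,
#' or first minus second session). Bias is the mean difference; limits of
#' agreement are bias +/- 1.96 sample SD of the differences. Proportional
#' bias is the Pearson correlation between the per-subject differences and
#' means, with its two-sided t-test p-value.
#'
#' @param table a [measurement_table()] with at least 3 subjects.
#' @return List with `bias`, `loa_low`, `loa_high` (ms), `sd_diff`,
#'   `r_prop`, `p_prop` (both `NA` with a warning when the differences or
#'   means are constant), and `n`.
#' @export
bland_altman <- function(table) {
  stopifnot(inherits(table, "measurement_table"))
  if (nrow(table) < 3L) stop("need at least 3 subjects", call. = FALSE)
  d <- table$value1 - table$value2
  m <- (table$value1 + table$value2) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  if (stats::sd(d) == 0 || stats::sd(m) == 0) {
    warning("constant differences or means; proportional bias undefined")
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(d, m)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  list(bias = bias, loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       sd_diff = sdd, r_prop = r, p_prop = p, n = nrow(table))
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided. Zero differences are dropped (Wilcoxon convention); the
#' exact null distribution is used when at most 25 non-zero differences
#' remain and their absolute values are untied, otherwise the normal
#' approximation with continuity correction.
#'
#' @param a,b paired value vectors of equal length.
#' @return Two-sided p-value. All-zero differences give `p = 1` with a
#'   warning; fewer than 5 non-zero differences is an error.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("unequal lengths", call. = FALSE)
  d <- a - b
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  if (length(nz) < 5L) {
    stop("need at least 5 non-zero differences", call. = FALSE)
  }
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE)$p.value
  )
}

#' Paired t-test p-value
#'
#' @param a,b paired value vectors.
#' @return Two-sided p-value.
#' @export
paired_t <- function(a, b) {
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Full agreement report for one measurement table
#'
#' Per-subject CoV and pairwise error, their means, the average-measures
#' ICC with CI, and the Bland-Altman battery.
#'
#' @param table a [measurement_table()].
#' @param label optional report label (e.g. "manual interobserver").
#' @param icc_model passed to [icc_average()].
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(table, label = "", icc_model = "ICC2k") {
  stopifnot(inherits(table, "measurement_table"))
  cov <- pair_cov(table$value1, table$value2)
  err <- pair_error(table$value1, table$value2)
  structure(
    list(label = label, n = nrow(table),
         cov = cov, error = err,
         mean_cov = mean(cov), mean_error = mean(err),
         icc = icc_average(table, model = icc_model),
         bland_altman = bland_altman(table)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  ba <- x$bland_altman
  cat(sprintf("<agreement_report> %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  mean CoV %.2f%%, mean error %.2f%%\n",
              x$mean_cov, x$mean_error))
  cat(sprintf("  ICC(%s) %.3f (%.3f-%.3f)\n", x$icc$model, x$icc$icc,
              x$icc$ci_low, x$icc$ci_high))
  cat(sprintf("  bias %.1f ms, LoA [%.1f, %.1f] ms, r_prop %.3f (p = %.3f)\n",
              ba$bias, ba$loa_low, ba$loa_high, ba$r_prop, ba$p_prop))
  invisible(x)
}

#' Compare manual and semiautomatic reproducibility
#'
#' Computes per-subject CoV and pairwise error for each method's table and
#' tests whether the semiautomatic method is more reproducible with the
#' Wilcoxon signed-rank test (plus a paired t-test) on the paired
#' per-subject values.
#'
#' @param manual_tbl,semi_tbl [measurement_table()]s over the same
#'   subjects (same order).
#' @return An object of class `method_comparison`: the two
#'   [agreement_report()]s plus `p_cov_wilcoxon`, `p_error_wilcoxon`,
#'   `p_cov_t`, `p_error_t`.
#' @export
compare_methods <- function(manual_tbl, semi_tbl) {
  stopifnot(inherits(manual_tbl, "measurement_table"),
            inherits(semi_tbl, "measurement_table"))
  if (nrow(manual_tbl) != nrow(semi_tbl) ||
      !all(manual_tbl$subject == semi_tbl$subject)) {
    stop("the two tables must cover the same subjects in the same order",
         call. = FALSE)
  }
  man <- agreement_report(manual_tbl, "manual")
  semi <- agreement_report(semi_tbl, "semiautomatic")
  p_cov <- withCallingHandlers(
    wilcoxon_signed_rank(man$cov, semi$cov),
    warning = function(w) invokeRestart("muffleWarning"))
  p_err <- withCallingHandlers(
    wilcoxon_signed_rank(man$error, semi$error),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(manual = man, semiauto = semi,
         p_cov_wilcoxon = p_cov,
         p_error_wilcoxon = p_err,
         p_cov_t = if (stats::sd(man$cov - semi$cov) > 0)
           paired_t(man$cov, semi$cov) else 1,
         p_error_t = if (stats::sd(man$error - semi$error) > 0)
           paired_t(man$error, semi$error) else 1),
    class = "method_comparison"
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  cat(sprintf("  manual:        mean CoV %.2f%%, mean error %.2f%%\n",
              x$manual$mean_cov, x$manual$mean_error))
  cat(sprintf("  semiautomatic: mean CoV %.2f%%, mean error %.2f%%\n",
              x$semiauto$mean_cov, x$semiauto$mean_error))
  cat(sprintf("  Wilcoxon p (CoV) = %.4g, p (error) = %.4g\n",
              x$p_cov_wilcoxon, x$p_error_wilcoxon))
  invisible(x)
}
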
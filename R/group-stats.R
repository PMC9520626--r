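#' One-way (univariate) ANOVA across groups
#'
#' Classical between/within sums-of-squares decomposition on a long data
#' frame of per-subject values, the omnibus test used for MI, band power and
#' morphometry comparisons. Degenerate inputs (zero within-group variance
#' everywhere but unequal means) report `p = 0` with the `degenerate` flag
#' rather than failing.
#'
#' @param data Data frame with one value per subject.
#' @param value,group Column names (strings) of the response and the group
#'   label (defaults `"value"`, `"group"`).
#' @return An `anova_fit` object; see [tidy()] / [glance()] for the group
#'   summary (mean, SD, SEM, n) and the omnibus row (`F`, dfs, `p`).
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 6),
#'                 value = c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 6, 8,
#'                           13, 9, 11, 8, 7, 12))
#' glance(oneway_anova(d))
#' @export
oneway_anova <- function(data, value = "value", group = "group") {
  v <- data[[value]]; g <- factor(data[[group]])
  if (any(!is.finite(v))) tg_stop("non-finite values", "tg_data_error")
  k <- nlevels(g)
  if (k < 2) tg_stop("need at least 2 groups", "tg_parameter_error")
  ns <- tabulate(g)
  if (any(ns < 2)) tg_stop("every group needs n >= 2", "tg_parameter_error")
  N <- length(v)
  means <- tapply(v, g, mean)
  gm <- mean(v)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((v - means[as.integer(g)])^2)
  df_b <- k - 1L; df_w <- N - k
  degenerate <- ss_w == 0 && ss_b > 0
  f <- if (degenerate) Inf else (ss_b / df_b) / (ss_w / df_w)
  p <- if (degenerate) 0 else stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(
    groups = tibble::tibble(
      group = levels(g), n = as.integer(ns),
      mean = as.numeric(means),
      sd = as.numeric(tapply(v, g, stats::sd)),
      sem = as.numeric(tapply(v, g, stats::sd)) / sqrt(ns)),
    F = f, df_between = df_b, df_within = df_w, p = p,
    ss_between = ss_b, ss_within = ss_w,
    mse = if (df_w > 0) ss_w / df_w else NA_real_,
    degenerate = degenerate,
    data = tibble::tibble(value = v, group = g)
  ), class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("<anova_fit> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @rdname oneway_anova
#' @param x An `anova_fit`.
#' @param ... Unused.
#' @method tidy anova_fit
#' @export
tidy.anova_fit <- function(x, ...) x$groups

#' @rdname oneway_anova
#' @method glance anova_fit
#' @export
glance.anova_fit <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df_between, df_within = x$df_within,
                 p = x$p, degenerate = x$degenerate)
}

#' Variance homogeneity test (Brown-Forsythe / median-centred Levene)
#'
#' One-way ANOVA on the absolute deviations from the group medians; at
#' `alpha = 0.05` the decision routes the post-hoc method: equal variances
#' use LSD, unequal variances Tamhane T2.
#'
#' @inheritParams oneway_anova
#' @param alpha Decision level (default 0.05).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p`, `equal_variances`.
#' @export
variance_homogeneity <- function(data, value = "value", group = "group",
                                 alpha = 0.05) {
  v <- data[[value]]; g <- factor(data[[group]])
  meds <- tapply(v, g, stats::median)
  z <- abs(v - meds[as.integer(g)])
  if (all(z == 0)) {
    return(tibble::tibble(statistic = 0, df1 = nlevels(g) - 1L,
                          df2 = length(v) - nlevels(g), p = 1,
                          equal_variances = TRUE))
  }
  fit <- oneway_anova(data.frame(value = z, group = g))
  tibble::tibble(statistic = fit$F, df1 = fit$df_between,
                 df2 = fit$df_within, p = fit$p,
                 equal_variances = fit$p >= alpha)
}

#' Pairwise post-hoc comparisons (LSD or Tamhane T2)
#'
#' LSD (equal-variance route): pairwise t tests using the pooled
#' within-group mean square and its degrees of freedom, unadjusted p.
#' Tamhane T2 (unequal-variance route): pairwise Welch t tests with a
#' Sidak-style conservative adjustment `p_adj = 1 - (1 - p)^m` over the
#' `m = k(k-1)/2` pairs.
#'
#' @param fit An `anova_fit` from [oneway_anova()].
#' @param method `"lsd"` or `"tamhane"`.
#' @return A tibble with one row per pair: `group1`, `group2`,
#'   `mean_difference`, `statistic`, `df`, `p` (adjusted for Tamhane;
#'   `p_unadjusted` also reported), `method`.
#' @export
posthoc <- function(fit, method = c("lsd", "tamhane")) {
  stopifnot(inherits(fit, "anova_fit"))
  method <- match.arg(method)
  gs <- fit$groups
  k <- nrow(gs)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- gs$mean[a] - gs$mean[b]
    if (method == "lsd") {
      se <- sqrt(fit$mse * (1 / gs$n[a] + 1 / gs$n[b]))
      df <- fit$df_within
    } else {
      va <- gs$sd[a]^2 / gs$n[a]; vb <- gs$sd[b]^2 / gs$n[b]
      se <- sqrt(va + vb)
      df <- if (se > 0)
        (va + vb)^2 / (va^2 / (gs$n[a] - 1) + vb^2 / (gs$n[b] - 1))
        else fit$df_within
    }
    tstat <- if (se > 0) diff / se else 0
    p_raw <- if (se > 0) 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
             else as.numeric(diff != 0)
    tibble::tibble(group1 = gs$group[a], group2 = gs$group[b],
                   mean_difference = diff, statistic = tstat, df = df,
                   p_unadjusted = p_raw)
  })
  rows$p <- if (method == "tamhane") pmin(1, 1 - (1 - rows$p_unadjusted)^m)
            else rows$p_unadjusted
  rows$method <- if (method == "tamhane") "TamhaneT2" else "LSD"
  rows
}

#' Pearson correlation with best-fit line
#'
#' Sample Pearson r with the two-sided t-based p value and the least-squares
#' regression line, the construction used to relate morphometry to coupling
#' strength across subjects.
#'
#' @param data Data frame holding the paired values.
#' @param x,y Column names (strings) of the paired variables.
#' @return A `correlation_fit`; `glance()` gives one row with `r`, `p`,
#'   `n`, `slope`, `intercept`.
#' @export
pearson_correlation <- function(data, x = "x", y = "y") {
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3)
    tg_stop("need at least 3 paired finite values", "tg_parameter_error")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    tg_stop("correlation undefined: zero variance", "tg_data_error")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  line <- stats::lm(yv ~ xv)
  structure(list(
    r = unname(ct$estimate), p = ct$p.value, n = n,
    slope = unname(coef(line)[2]), intercept = unname(coef(line)[1]),
    data = tibble::tibble(x = xv, y = yv)
  ), class = "correlation_fit")
}

#' @export
print.correlation_fit <- function(x, ...) {
  cat(sprintf("<correlation_fit> r = %.3f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  invisible(x)
}

#' @rdname pearson_correlation
#' @param x A `correlation_fit`.
#' @param ... Unused.
#' @method glance correlation_fit
#' @export
glance.correlation_fit <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n = x$n, slope = x$slope,
                 intercept = x$intercept)
}

#' @rdname pearson_correlation
#' @method tidy correlation_fit
#' @export
tidy.correlation_fit <- function(x, ...) glance.correlation_fit(x)

#' Full group-comparison report for one measure
#'
#' Omnibus ANOVA, homogeneity gate, and the post-hoc table the gate selects
#' (LSD under homogeneity, Tamhane T2 otherwise) - the standard comparison
#' chain for each readout.
#'
#' @inheritParams oneway_anova
#' @param alpha Gate level for the homogeneity decision (default 0.05).
#' @return List: `anova` (`anova_fit`), `homogeneity` (tibble),
#'   `posthoc` (tibble), `measure_summary` (tibble of group mean/SD/SEM).
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           alpha = 0.05) {
  fit <- oneway_anova(data, value = value, group = group)
  hom <- variance_homogeneity(data, value = value, group = group,
                              alpha = alpha)
  ph <- posthoc(fit, method = if (hom$equal_variances) "lsd" else "tamhane")
  list(anova = fit, homogeneity = hom, posthoc = ph,
       measure_summary = tidy(fit))
}
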
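# Re-methylation kinetics after 5-aza-2'-deoxycytidine.
#
# If recovery of methylation were driven purely by outgrowth of cells that
# escaped demethylation, every CGI's trajectory would be proportional to its
# starting level; after dividing by the day-0 value all CGIs then share one
# normalised trajectory. The alternative is that CGIs re-methylate at
# different rates. The two hypotheses are compared as nested linear mixed
# models on the normalised data:
#   null:        m ~ t + (1 | cgi)          (random intercept only)
#   alternative: m ~ t + (1 + t | cgi)      (random intercept and slope)
# fitted by maximum likelihood and compared via a likelihood-ratio test.

#' Build a methylation time-course table
#'
#' @param cgi Character vector of CGI ids.
#' @param day Numeric day of measurement.
#' @param beta Mean CGI methylation in \[0, 1\].
#' @param cell_line Optional label stored as an attribute.
#' @return A long `data.frame(cgi, day, beta)` of class `timecourse`.
#' @export
timecourse_table <- function(cgi, day, beta, cell_line = NULL) {
  check_prob(beta, "beta")
  x <- data.frame(cgi = as.character(cgi), day = as.numeric(day),
                  beta = as.numeric(beta), stringsAsFactors = FALSE)
  if (!0 %in% x$day) stop_bad("time course must include day 0")
  attr(x, "cell_line") <- cell_line
  class(x) <- c("timecourse", "data.frame")
  x
}

#' Normalise a time course to its day-0 methylation
#'
#' Each CGI's trajectory is divided by its own day-0 mean methylation, so
#' the normalised value is the fraction of the initial methylation level.
#' Only CGIs with day-0 methylation strictly above `day0_min` (default 0.5,
#' i.e. > 50%) are included; values above 1 after division are retained
#' unclipped.
#'
#' @param tc Time-course table (`cgi, day, beta`); day 0 required per CGI.
#' @param day0_min Day-0 inclusion threshold (strict inequality).
#' @return A `norm_timecourse` data.frame `(cgi, day, m_norm)` with
#'   attributes `included` and `excluded` (CGI ids) and `day0` (named
#'   vector of day-0 levels for included CGIs).
#' @export
normalise_timecourse <- function(tc, day0_min = 0.5) {
  stopifnot(all(c("cgi", "day", "beta") %in% names(tc)))
  d0 <- tc[tc$day == 0, , drop = FALSE]
  day0 <- tapply(d0$beta, d0$cgi, mean)
  missing_d0 <- setdiff(unique(tc$cgi), names(day0))
  if (length(missing_d0))
    stop_bad("no day-0 value for CGI(s): ", paste(head(missing_d0, 5), collapse = ", "))
  included <- names(day0)[day0 > day0_min]
  excluded <- setdiff(names(day0), included)
  if (any(day0[included] == 0))
    stop_bad("day-0 methylation of zero for an included CGI")  # unreachable given filter
  x <- tc[tc$cgi %in% included, , drop = FALSE]
  x$m_norm <- x$beta / day0[x$cgi]
  out <- data.frame(cgi = x$cgi, day = x$day, m_norm = x$m_norm,
                    stringsAsFactors = FALSE)
  attr(out, "included") <- included
  attr(out, "excluded") <- excluded
  attr(out, "day0") <- day0[included]
  class(out) <- c("norm_timecourse", "data.frame")
  out
}

subset_days <- function(ntc, t_min, t_max) {
  ntc[ntc$day >= t_min & ntc$day <= t_max, , drop = FALSE]
}

#' Test for heterogeneous re-methylation rates across CGIs
#'
#' Fits, by maximum likelihood on timepoints between `t_min` and `t_max`
#' inclusive (default days 3-22), a random-intercept null model
#' `m ~ t + (1 | cgi)` representing outgrowth-driven recovery, and a
#' random-intercept-and-slope alternative `m ~ t + (1 + t | cgi)` in which
#' each CGI recovers at its own rate. The likelihood-ratio statistic is
#' referred to a chi-square distribution with the difference in parameter
#' count as degrees of freedom. Because the null places the slope variance
#' on its boundary, this reference distribution is conservative.
#'
#' @param ntc Normalised time course from [normalise_timecourse()].
#' @param t_min,t_max Inclusive day range used for fitting.
#' @param correlated Model the random intercept and slope as correlated
#'   bivariate effects (default) or as independent effects.
#' @return An object of class `rate_heterogeneity` with log-likelihoods,
#'   the LR statistic, degrees of freedom, p-value, and the fitted models.
#' @export
test_rate_heterogeneity <- function(ntc, t_min = 3, t_max = 22, correlated = TRUE) {
  d <- subset_days(ntc, t_min, t_max)
  n_cgis <- length(unique(d$cgi))
  if (n_cgis < 2L)
    stop_bad("rate-heterogeneity test needs >= 2 CGIs (random effects unidentifiable)")
  if (length(unique(d$day)) < 3L)
    stop_bad("need >= 3 timepoints in [t_min, t_max]")
  dat <- data.frame(m = d$m_norm, t = d$day, cgi = factor(d$cgi))
  ctrl <- lme4::lmerControl(check.conv.grad = "ignore",
                            check.conv.singular = "ignore",
                            check.conv.hess = "ignore",
                            calc.derivs = FALSE)
  fit_null <- lme4::lmer(m ~ t + (1 | cgi), data = dat, REML = FALSE, control = ctrl)
  form_alt <- if (correlated) m ~ t + (1 + t | cgi) else m ~ t + (1 + t || cgi)
  fit_alt <- lme4::lmer(form_alt, data = dat, REML = FALSE, control = ctrl)
  ll0 <- as.numeric(stats::logLik(fit_null))
  # the alternative nests the null, so its ML log-likelihood cannot be
  # lower; when the optimizer stalls at the variance boundary, retry with
  # other optimizers and keep the best fit
  if (as.numeric(stats::logLik(fit_alt)) < ll0 - 1e-4) {
    for (optim in c("bobyqa", "Nelder_Mead")) {
      ctrl_i <- lme4::lmerControl(optimizer = optim,
                                  check.conv.grad = "ignore",
                                  check.conv.singular = "ignore",
                                  check.conv.hess = "ignore",
                                  calc.derivs = FALSE)
      refit <- tryCatch(
        lme4::lmer(form_alt, data = dat, REML = FALSE, control = ctrl_i),
        error = function(e) NULL)
      if (!is.null(refit) &&
          as.numeric(stats::logLik(refit)) > as.numeric(stats::logLik(fit_alt)))
        fit_alt <- refit
      if (as.numeric(stats::logLik(fit_alt)) >= ll0 - 1e-4) break
    }
  }
  ll1 <- as.numeric(stats::logLik(fit_alt))
  df0 <- attr(stats::logLik(fit_null), "df")
  df1 <- attr(stats::logLik(fit_alt), "df")
  lr <- 2 * (ll1 - ll0)
  df_diff <- df1 - df0
  # after the refit cascade any remaining deficit is numerical noise at the
  # boundary (the true statistic is >= 0); clamp it, but surface anything
  # that still looks like a failed fit
  if (lr < -0.05)
    warning("alternative fit remained below the null after optimizer retries ",
            "(LR = ", signif(lr, 3), "); statistic clamped to 0 (boundary null)")
  lr <- max(lr, 0)
  out <- list(loglik_null = ll0, loglik_alt = ll1, lr_statistic = lr,
              df_difference = df_diff,
              p_value = pchisq(lr, df = df_diff, lower.tail = FALSE),
              n_cgis = n_cgis, timepoints = sort(unique(d$day)),
              correlated = correlated,
              fit_null = fit_null, fit_alt = fit_alt)
  class(out) <- "rate_heterogeneity"
  out
}

#' @export
print.rate_heterogeneity <- function(x, ...) {
  cat("Test of heterogeneous re-methylation rates across CGIs\n")
  cat(sprintf("  null (outgrowth):  m ~ t + (1 | cgi),   logLik = %.3f\n", x$loglik_null))
  cat(sprintf("  alt  (per-CGI):    m ~ t + (1 + t %s cgi), logLik = %.3f\n",
              if (x$correlated) "|" else "||", x$loglik_alt))
  cat(sprintf("  LR = %.3f on %d df, p = %.3g  (%d CGIs, days %s)\n",
              x$lr_statistic, x$df_difference, x$p_value, x$n_cgis,
              paste(x$timepoints, collapse = ",")))
  invisible(x)
}

#' @export
summary.rate_heterogeneity <- function(object, ...) {
  print(object)
  cat("\nAlternative-model variance components:\n")
  print(lme4::VarCorr(object$fit_alt))
  invisible(object)
}

#' Per-CGI recovery rates by ordinary least squares
#'
#' Fits an individual linear model of normalised methylation on day, per
#' CGI, over timepoints between `t_min` and `t_max` inclusive. The slope is
#' the fraction of the day-0 methylation level recovered per day.
#'
#' @inheritParams test_rate_heterogeneity
#' @param groups Optional named vector mapping CGI id to a group label
#'   (e.g. `"H3K36me3"` vs `"other"`), attached to the output.
#' @return A `data.frame(cgi, slope, intercept, n_points, group)`; CGIs
#'   with fewer than 2 distinct timepoints in range are skipped and listed
#'   in attribute `skipped`.
#' @export
fit_cgi_recovery_rates <- function(ntc, t_min = 3, t_max = 22, groups = NULL) {
  d <- subset_days(ntc, t_min, t_max)
  ids <- unique(ntc$cgi)
  res <- lapply(ids, function(id) {
    di <- d[d$cgi == id, , drop = FALSE]
    if (length(unique(di$day)) < 2L) return(NULL)
    # closed-form OLS
    tbar <- mean(di$day); mbar <- mean(di$m_norm)
    slope <- sum((di$day - tbar) * (di$m_norm - mbar)) / sum((di$day - tbar)^2)
    data.frame(cgi = id, slope = slope, intercept = mbar - slope * tbar,
               n_points = nrow(di), stringsAsFactors = FALSE)
  })
  skipped <- ids[vapply(res, is.null, logical(1))]
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cgi = character(), slope = numeric(), intercept = numeric(),
                      n_points = integer(), stringsAsFactors = FALSE)
  out$group <- if (is.null(groups)) NA_character_ else unname(groups[out$cgi])
  attr(out, "skipped") <- skipped
  out
}

#' Compare recovery rates between two CGI groups
#'
#' Two-sided Wilcoxon rank-sum test on per-CGI slopes between two groups,
#' reporting group medians (e.g. H3K36me3-marked CGIs vs other CGIs).
#'
#' @param rates Output of [fit_cgi_recovery_rates()] with a `group` column.
#' @param group_a,group_b Group labels to compare.
#' @return A list with `median_a`, `median_b`, `p_value`, `n_a`, `n_b`.
#' @export
compare_rate_groups <- function(rates, group_a, group_b) {
  a <- rates$slope[rates$group %in% group_a]
  b <- rates$slope[rates$group %in% group_b]
  if (length(a) == 0L || length(b) == 0L) stop_bad("both groups must be non-empty")
  p <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
  list(median_a = median(a), median_b = median(b), p_value = p,
       n_a = length(a), n_b = length(b))
}

#' Plot normalised re-methylation trajectories
#'
#' Spaghetti plot of per-CGI normalised trajectories with the cross-CGI
#' mean overlaid; a visual companion to [test_rate_heterogeneity()].
#'
#' @param x Normalised time course.
#' @param max_cgis Cap on the number of individual trajectories drawn.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.norm_timecourse <- function(x, max_cgis = 100, ...) {
  ids <- unique(x$cgi)
  if (length(ids) > max_cgis) ids <- ids[seq_len(max_cgis)]
  days <- sort(unique(x$day))
  m <- sapply(ids, function(id) {
    xi <- x[x$cgi == id, ]
    xi$m_norm[match(days, xi$day)]
  })
  graphics::matplot(days, m, type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey40", 0.3),
                    xlab = "days after 5-aza-dC", ylab = "fraction of day-0 methylation",
                    ...)
  graphics::lines(days, rowMeans(m, na.rm = TRUE), col = "firebrick", lwd = 2)
  invisible(x)
}
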
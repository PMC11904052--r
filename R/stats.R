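# Inferential layer: standardized-beta regression, repeated-measures and
# mixed ANCOVA with type III sums of squares under sum-to-zero contrasts,
# partial eta squared with noncentral-F confidence limits, and
# within-subject condition intervals.

#' Round half away from zero
#'
#' Reported values are rounded half-away-from-zero to match the usual
#' reporting convention (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Linear regression with standardized coefficients
#'
#' Standardizes the response and all continuous predictors to unit sample
#' SD before an ordinary least-squares fit, so slopes are standardized
#' betas; factor covariates (e.g. a sample indicator) enter unstandardized.
#' Confidence intervals are t-based on the residual degrees of freedom.
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of continuous predictor columns.
#' @param covariates Character vector of covariate columns (factors such as
#'   the sample indicator are kept as factors).
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per predictor: `term`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(50))
#' d$y <- 0.5 * d$x + rnorm(50)
#' standardized_regression(d, "y", "x")
standardized_regression <- function(data, response, predictors,
                                    covariates = character(), level = 0.95) {
  cols <- c(response, predictors, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + length(covariates) + 1L) {
    stop("too few complete observations for the model")
  }
  scale1 <- function(x) as.numeric(scale(x))
  for (v in c(response, predictors)) {
    if (!is.numeric(d[[v]])) stop("column '", v, "' must be numeric")
    if (stats::sd(d[[v]]) == 0) stop("column '", v, "' has zero variance")
    d[[v]] <- scale1(d[[v]])
  }
  for (v in covariates) {
    if (is.character(d[[v]]) || is.logical(d[[v]])) d[[v]] <- factor(d[[v]])
  }
  fml <- stats::reformulate(c(predictors, covariates), response = response)
  fit <- stats::lm(fml, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design matrix; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  keep <- intersect(predictors, rownames(sm))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  tibble::tibble(
    term = keep,
    beta = sm[keep, "Estimate"],
    ci_low = sm[keep, "Estimate"] - tcrit * sm[keep, "Std. Error"],
    ci_high = sm[keep, "Estimate"] + tcrit * sm[keep, "Std. Error"],
    p = sm[keep, "Pr(>|t|)"],
    n = n
  )
}

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta_p^2 = F \, df_1 / (F \, df_1 + df_2)}.
#'
#' @param f F statistic (non-negative).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
#' @examples
#' partial_eta_sq(11, 1, 216)
partial_eta_sq <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  f * df1 / (f * df1 + df2)
}

#' Confidence interval for partial eta squared by noncentral-F inversion
#'
#' Finds the noncentrality parameters whose noncentral-F distribution
#' places the observed F at the upper and lower tail probabilities of the
#' interval, then maps them to partial eta squared via
#' \eqn{\lambda / (\lambda + df_1 + df_2 + 1)}. The lower bound is clipped
#' at 0 when the observed F falls below the corresponding central-F
#' quantile. 90% intervals are conventional for F-based effect sizes
#' because the F test is one-sided.
#'
#' @inheritParams partial_eta_sq
#' @param level Confidence level (default 0.90).
#' @param tol Convergence tolerance on the CDF scale for the bisection.
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' eta_sq_ci(21.78, 2, 432)
eta_sq_ci <- function(f, df1, df2, level = 0.90, tol = 1e-8) {
  stopifnot(f >= 0, df1 >= 1, df2 >= 1, level > 0, level < 1)
  tail <- (1 - level) / 2
  invert <- function(target) {
    # largest lambda with pf(f; df1, df2, lambda) >= target, by bisection
    g <- function(l) stats::pf(f, df1, df2, ncp = l) - target
    if (g(0) < 0) return(0)
    lo <- 0; hi <- max(4, 4 * f * df1)
    it <- 0
    while (g(hi) > 0) {
      hi <- hi * 2; it <- it + 1
      if (it > 60) stop("noncentrality inversion failed to bracket (F=", f, ")")
    }
    it <- 0
    while (hi - lo > tol * (1 + hi) && it < 200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
      it <- it + 1
    }
    mid <- (lo + hi) / 2
    if (abs(stats::pf(f, df1, df2, ncp = mid) - target) > 1e-4 && mid > tol) {
      stop("noncentrality inversion did not converge (F=", f,
           ", df=", df1, ",", df2, ", target=", target, ")")
    }
    mid
  }
  lam_hi <- invert(tail)        # CDF = 0.05 tail -> upper limit
  lam_lo <- invert(1 - tail)    # CDF = 0.95 -> lower limit
  eta <- function(l) l / (l + df1 + df2 + 1)
  c(low = eta(lam_lo), high = eta(lam_hi))
}

# type III F-test of a term by comparing the full OLS fit against the fit
# with that term's model-matrix columns removed (sum-to-zero contrasts)
drop_term_f <- function(y, mm, assign, term_idx) {
  fit_full <- stats::lm.fit(mm, y)
  rss_full <- sum(fit_full$residuals^2)
  df_res <- length(y) - fit_full$rank
  keep <- assign != term_idx
  fit_red <- stats::lm.fit(mm[, keep, drop = FALSE], y)
  rss_red <- sum(fit_red$residuals^2)
  q <- fit_full$rank - fit_red$rank
  num <- (rss_red - rss_full) / q
  f <- if (num <= 1e-12) 0 else num / (rss_full / df_res)
  list(f = f, df1 = q, df2 = df_res,
       p = stats::pf(f, q, df_res, lower.tail = FALSE))
}

anova_effect_row <- function(effect, ft, ci_level = 0.90) {
  eta <- partial_eta_sq(ft$f, ft$df1, ft$df2)
  ci <- eta_sq_ci(ft$f, ft$df1, ft$df2, level = ci_level)
  tibble::tibble(effect = effect, f = ft$f, df1 = ft$df1, df2 = ft$df2,
                 p = ft$p, eta_p_sq = eta,
                 eta_ci_low = ci[["low"]], eta_ci_high = ci[["high"]])
}

check_complete_wide <- function(data, participant, condition, value) {
  tab <- table(data[[participant]], data[[condition]])
  if (any(tab == 0)) stop("incomplete cases: some participants lack a condition")
}

#' Repeated-measures ANCOVA for a within-subject condition effect
#'
#' Tests the condition effect on participant-level condition means with
#' participant as a blocking factor, i.e. the classical univariate
#' repeated-measures decomposition: the condition F compares the full model
#' `value ~ participant + condition` against the participant-only model.
#' A between-subject covariate (such as the sample indicator) is constant
#' within participants and therefore absorbed by the participant factor;
#' it is accepted and recorded for interface symmetry. Sum-to-zero
#' contrasts are used throughout, making the drop-term tests type III.
#'
#' @param data Long-format data frame.
#' @param participant,condition,value Column names.
#' @param covariate Optional between-subject covariate column (absorbed).
#' @param ci_level Level for the partial-eta-squared interval.
#' @return A tibble of ANOVA effects (`effect`, `f`, `df1`, `df2`, `p`,
#'   `eta_p_sq`, `eta_ci_low`, `eta_ci_high`).
#' @export
rm_ancova <- function(data, participant = "participant_id",
                      condition = "condition", value = "value",
                      covariate = NULL, ci_level = 0.90) {
  stopifnot(all(c(participant, condition, value) %in% names(data)))
  d <- data[stats::complete.cases(data[c(participant, condition, value)]), ]
  pid <- factor(d[[participant]])
  cond <- factor(d[[condition]])
  if (nlevels(cond) < 2L) stop("need at least 2 conditions")
  check_complete_wide(d, participant, condition, value)
  y <- d[[value]]
  mm <- stats::model.matrix(~ pid + cond,
                            contrasts.arg = list(pid = "contr.sum",
                                                 cond = "contr.sum"))
  assign <- attr(mm, "assign")
  ft <- drop_term_f(y, mm, assign, term_idx = 2L)
  anova_effect_row("condition", ft, ci_level)
}

#' Mixed distance-by-domain ANCOVA (2 within x 3 between)
#'
#' Type III tests for a design with one within-subject factor (`distance`),
#' one between-subject factor (`domain`) and a between-subject covariate
#' (`sample`). The within-subject stratum models
#' `value ~ participant + distance + distance:domain` (the participant
#' factor absorbs all between-subject variation), giving the distance main
#' effect and the distance-by-domain interaction. The domain main effect is
#' tested in the between-subject stratum on participant means, adjusting
#' for the covariate. All factors are sum-to-zero coded.
#'
#' @param data Long-format data frame with two rows per participant
#'   (one per distance condition mean).
#' @param participant,distance,domain,value Column names.
#' @param covariate Optional between-subject covariate column name.
#' @param ci_level Level for the partial-eta-squared interval.
#' @return A tibble with rows `distance`, `domain`, `distance:domain`.
#' @export
mixed_ancova <- function(data, participant = "participant_id",
                         distance = "distance", domain = "domain",
                         value = "value", covariate = NULL,
                         ci_level = 0.90) {
  cols <- c(participant, distance, domain, value, covariate)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[cols]), ]
  pid <- factor(d[[participant]])
  dist <- factor(d[[distance]])
  dom <- factor(d[[domain]])
  if (any(table(dom) == 0)) stop("empty domain cell")
  if (nlevels(dist) != 2L) stop("distance factor must have 2 levels")
  check_complete_wide(d, participant, distance, value)
  pd <- unique(data.frame(pid = pid, dom = dom))
  if (anyDuplicated(pd$pid)) stop("participants must belong to exactly one domain")
  y <- d[[value]]

  # within-subject stratum; the domain main effect is constant within
  # participants and pivots out of the fit, leaving a properly sum-coded
  # distance:domain interaction block
  mm <- stats::model.matrix(~ pid + dist * dom,
                            contrasts.arg = list(pid = "contr.sum",
                                                 dist = "contr.sum",
                                                 dom = "contr.sum"))
  assign <- attr(mm, "assign")
  ft_dist <- drop_term_f(y, mm, assign, term_idx = 2L)
  ft_int <- drop_term_f(y, mm, assign, term_idx = 4L)

  # between-subject stratum: participant means adjusted for the covariate
  agg <- stats::aggregate(y, by = list(pid = pid), FUN = mean)
  pdat <- data.frame(pid = agg$pid, ybar = agg$x)
  meta <- d[!duplicated(pid), c(participant, domain, covariate), drop = FALSE]
  names(meta)[1] <- "pid"
  pdat <- merge(pdat, meta, by = "pid")
  rhs <- c(domain, covariate)
  for (v in rhs) if (!is.numeric(pdat[[v]])) pdat[[v]] <- factor(pdat[[v]])
  contr <- lapply(Filter(function(v) is.factor(pdat[[v]]), rhs),
                  function(v) "contr.sum")
  names(contr) <- Filter(function(v) is.factor(pdat[[v]]), rhs)
  mmb <- stats::model.matrix(stats::reformulate(rhs), data = pdat,
                             contrasts.arg = contr)
  ft_dom <- drop_term_f(pdat$ybar, mmb, attr(mmb, "assign"),
                        term_idx = which(rhs == domain))

  dplyr::bind_rows(
    anova_effect_row("distance", ft_dist, ci_level),
    anova_effect_row("domain", ft_dom, ci_level),
    anova_effect_row("distance:domain", ft_int, ci_level)
  )
}

#' Within-subject condition means with Morey-adjusted intervals
#'
#' Removes participant-level offsets (subtract each participant's mean, add
#' the grand mean), computes per-condition t-based intervals on the
#' normalized scores, and widens the half-width by \eqn{\sqrt{C/(C-1)}} for
#' C conditions to correct the variance deflation of the normalization.
#'
#' @param data Long-format data frame with complete cases.
#' @param participant,condition,value Column names.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `condition`, `mean`, `half_width`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
morey_within_ci <- function(data, participant = "participant_id",
                            condition = "condition", value = "value",
                            level = 0.95) {
  stopifnot(all(c(participant, condition, value) %in% names(data)))
  d <- data[stats::complete.cases(data[c(participant, condition, value)]), ]
  cond <- factor(d[[condition]])
  C <- nlevels(cond)
  if (C < 2L) stop("need at least 2 conditions")
  check_complete_wide(d, participant, condition, value)
  pid <- factor(d[[participant]])
  y <- d[[value]]
  pmean <- stats::ave(y, pid)
  ynorm <- y - pmean + mean(y)
  correction <- sqrt(C / (C - 1))
  out <- lapply(levels(cond), function(lv) {
    yy <- ynorm[cond == lv]
    n <- length(yy)
    se <- stats::sd(yy) / sqrt(n)
    hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se * correction
    tibble::tibble(condition = lv, mean = mean(y[cond == lv]),
                   half_width = hw, ci_low = mean(y[cond == lv]) - hw,
                   ci_high = mean(y[cond == lv]) + hw, n = n)
  })
  dplyr::bind_rows(out)
}
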
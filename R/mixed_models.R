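## Random-intercept linear mixed models (REML, Satterthwaite df) -- the
## inference engine behind segment fits, alpha-diversity trends and the
## edge-dynamics models. Estimation is delegated to lme4/lmerTest; this
## layer standardizes the interface, the error contract and the reported
## coefficient schema (term, b, SE, t, df, p).

#' Fit a random-intercept linear mixed model
#'
#' REML estimation with subject-level random intercepts;
#' fixed-effect t-tests use Satterthwaite's degrees-of-freedom method, so
#' fractional df are expected output. Degenerate designs fail loudly:
#' fewer than two groups, a singular fixed-effect design, or one
#' observation per group (random intercept unidentifiable) are errors, not
#' silently arbitrary fits.
#'
#' @param data data.frame with the response, covariates and grouping
#'   column.
#' @param formula fixed-effects formula, e.g. \code{value ~ day}.
#' @param group name of the grouping column (random-intercept factor).
#' @return list of class \code{lmmFit}: \code{coefficients} (data.frame
#'   term, b, SE, t, df, p), \code{sigma_intercept}, \code{sigma_resid},
#'   \code{logLik} (REML), \code{rmse} (conditional residuals),
#'   \code{n_obs}, \code{n_groups}, and the underlying \code{model}.
#' @export
fitLMM <- function(data, formula = value ~ day, group = "subject") {
  data <- as.data.frame(data)
  if (!group %in% colnames(data)) stop("no grouping column '", group, "'")
  g <- as.factor(data[[group]])
  if (nlevels(droplevels(g)) < 2)
    stop("need at least two groups for a random intercept")
  if (nrow(data) <= nlevels(droplevels(g)))
    stop("one observation per group: random intercept unidentifiable")
  mm <- stats::model.matrix(formula, data)
  if (qr(mm)$rank < ncol(mm)) stop("singular fixed-effect design")
  full <- stats::update(formula,
                        paste(". ~ . + (1 |", group, ")"))
  fit <- withCallingHandlers(
    lmerTest::lmer(full, data = data, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage"))
  smry <- suppressMessages(coef(summary(fit)))
  coefs <- data.frame(term = rownames(smry), b = smry[, "Estimate"],
                      SE = smry[, "Std. Error"], t = smry[, "t value"],
                      df = smry[, "df"], p = smry[, "Pr(>|t|)"],
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- residuals(fit)
  structure(list(
    coefficients = coefs,
    sigma_intercept = vc$sdcor[vc$grp == group][1],
    sigma_resid = vc$sdcor[vc$grp == "Residual"][1],
    logLik = as.numeric(logLik(fit)),
    rmse = sqrt(mean(res^2)),
    n_obs = nrow(data), n_groups = nlevels(droplevels(g)),
    model = fit), class = "lmmFit")
}

#' @export
print.lmmFit <- function(x, ...) {
  cat("Random-intercept LMM (REML):", x$n_obs, "obs,", x$n_groups,
      "groups\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat(sprintf("sigma(intercept) = %.4g, sigma(resid) = %.4g, RMSE = %.4g\n",
              x$sigma_intercept, x$sigma_resid, x$rmse))
  invisible(x)
}

#' Slope of a fixed effect from an lmmFit
#' @param fit an \code{lmmFit}.
#' @param term coefficient name (default \code{"day"}).
#' @return one coefficient row (term, b, SE, t, df, p).
#' @export
lmmCoef <- function(fit, term = "day") {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (!nrow(row)) stop("no coefficient named '", term, "'")
  row
}

#' Alpha-diversity time trend
#'
#' Fits \code{value ~ day} with subject random intercepts to a per-sample
#' alpha-diversity table (see \code{\link{alphaDiversity}}); the slope is
#' the per-day change in diversity.
#'
#' @param alpha data.frame with columns \code{value}, \code{day},
#'   \code{subject}.
#' @return an \code{lmmFit}.
#' @export
fitAlphaTrend <- function(alpha) {
  fitLMM(alpha, value ~ day, group = "subject")
}
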
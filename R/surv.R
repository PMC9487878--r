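#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over the product-limit estimator: censored subjects reduce
#' the at-risk count without producing steps.
#'
#' @param times non-negative follow-up times.
#' @param events logical (or 0/1) event indicators.
#' @return A [SurvivalCurve-class].
#' @examples
#' kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' @export
kmEstimate <- function(times, events) {
  if (!length(times)) stop("kmEstimate: empty input")
  if (length(times) != length(events))
    stop("times and events must have the same length")
  if (any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  new("SurvivalCurve", time = as.numeric(fit$time),
      surv = as.numeric(fit$surv),
      atRisk = as.numeric(fit$n.risk),
      nEvents = as.integer(sum(fit$n.event)),
      n = as.integer(length(times)))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic. When neither group has any event the
#' comparison is vacuous and `chi_square = 0`, `p_value = 1` is reported
#' rather than an error.
#'
#' @param timeA,eventA follow-up times and event indicators, group A.
#' @param timeB,eventB follow-up times and event indicators, group B.
#' @return list with `chi_square`, `p_value` and `df = 1`. Symmetric in the
#'   group labels.
#' @export
logrankTest <- function(timeA, eventA, timeB, eventB) {
  if (!length(timeA) || !length(timeB))
    stop("both groups must be non-empty")
  if (sum(eventA) + sum(eventB) == 0)
    return(list(chi_square = 0, p_value = 1, df = 1L))
  time <- c(timeA, timeB)
  event <- as.logical(c(eventA, eventB))
  group <- rep(c("A", "B"), c(length(timeA), length(timeB)))
  d <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- as.numeric(d$chisq)
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Pairwise log-rank tests with Bonferroni adjustment
#'
#' All pairwise two-group log-rank comparisons across the levels of
#' `group`, with Bonferroni-adjusted p-values.
#'
#' @param time,event follow-up times and event indicators.
#' @param group grouping factor (two or more levels).
#' @return data.frame: group_a, group_b, chi_square, p_value,
#'   p_adjusted (Bonferroni, capped at 1).
#' @export
pairwiseLogrank <- function(time, event, group) {
  group <- as.factor(group)
  lev <- levels(droplevels(group))
  if (length(lev) < 2) stop("need at least two groups")
  pairs <- utils::combn(lev, 2)
  nComp <- ncol(pairs)
  rows <- lapply(seq_len(nComp), function(k) {
    a <- group == pairs[1, k]
    b <- group == pairs[2, k]
    r <- logrankTest(time[a], event[a], time[b], event[b])
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               chi_square = r$chi_square, p_value = r$p_value,
               p_adjusted = min(1, r$p_value * nComp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards summary
#'
#' Partial-likelihood fit with the Efron tie approximation (clinical times
#' at day resolution produce ties). Hazard ratios are reported with 95%
#' confidence intervals. Collinear covariates are an error; monotone
#' likelihood / separation (diverging coefficients) is flagged, never
#' silent.
#'
#' @param records data.frame of patient records with endpoint columns
#'   `rfs_days`/`rfs_event` or `os_days`/`os_event` and the covariates.
#' @param covariates covariate column names (each needs at least two
#'   distinct values).
#' @param endpoint "RFS" or "OS".
#' @return data.frame: term, hazard_ratio, ci_low, ci_high, p_value,
#'   flagged (TRUE when the fit is suspect).
#' @export
coxPH <- function(records, covariates, endpoint = c("RFS", "OS")) {
  endpoint <- match.arg(endpoint)
  cols <- if (endpoint == "RFS") c("rfs_days", "rfs_event")
          else c("os_days", "os_event")
  requireColumns(records, c(cols, covariates), "patient record table")
  if (sum(records[[cols[2]]]) == 0) stop("no events for endpoint ", endpoint)
  for (cv in covariates)
    if (length(unique(records[[cv]])) < 2)
      stop("covariate ", cv, " has fewer than 2 distinct values")
  X <- data.matrix(records[, covariates, drop = FALSE])
  if (length(covariates) > 1 && qr(scale(X, scale = FALSE))$rank <
        length(covariates))
    stop("covariates are collinear")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", cols[1], ", ", cols[2], ") ~ ",
    paste(covariates, collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  coefs <- s$coefficients
  ci <- s$conf.int
  if (any(!is.finite(coefs[, "coef"])) || any(is.na(coefs[, "coef"])))
    stop("Cox fit failed (non-finite coefficient); check covariates")
  flagged <- flagged | abs(coefs[, "coef"]) > 10
  if (any(flagged))
    warning("possible separation / monotone likelihood in Cox fit")
  data.frame(term = rownames(coefs),
             hazard_ratio = unname(ci[, "exp(coef)"]),
             ci_low = unname(ci[, "lower .95"]),
             ci_high = unname(ci[, "upper .95"]),
             p_value = unname(coefs[, "Pr(>|z|)"]),
             flagged = unname(rep(flagged, length.out = nrow(coefs))),
             row.names = NULL)
}
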
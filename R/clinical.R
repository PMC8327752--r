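# Clinicopathological association tests, IHC score binning,
# Kaplan-Meier / log-rank / Cox survival analysis. The survival package
# provides the estimators; this module fixes the conventions (Pearson
# chi-square without continuity correction, Breslow ties, median
# dichotomization with ties to the low group).

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 matrix (or something coercible) of nonnegative counts.
#' @param correct apply the Yates continuity correction (default FALSE;
#'   the uncorrected statistic reproduces the published cohort table).
#' @return list: \code{statistic}, \code{p}, \code{df}.
#' @export
chisq2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative cell count")
  n <- sum(tab)
  if (n < 1) stop("empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal")
  expd <- outer(rs, cs) / n
  dev <- abs(tab - expd)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expd)
  list(statistic = stat, p = pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Bin an IHC percent-positive value into the ordinal score
#'
#' Score 1: < 25; score 2: [25, 50); score 3: [50, 75); score 4: >= 75.
#' Boundary percentages go to the higher score. Scores 1-2 are the
#' "low" expression class, 3-4 "high".
#'
#' @param percent numeric vector in [0, 100].
#' @param boundaryUp assign exact boundaries (25/50/75) to the higher
#'   score (default TRUE).
#' @return data.frame: \code{percent}, \code{score} (1-4),
#'   \code{class} ("low"/"high").
#' @export
binIHCScore <- function(percent, boundaryUp = TRUE) {
  if (any(percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]")
  cuts <- c(25, 50, 75)
  score <- if (boundaryUp) {
    1L + rowSums(outer(percent, cuts, `>=`))
  } else {
    1L + rowSums(outer(percent, cuts, `>`))
  }
  data.frame(percent = percent, score = as.integer(score),
             class = ifelse(score <= 2L, "low", "high"),
             stringsAsFactors = FALSE)
}

# internal: validate survival records
checkSurvivalRecords <- function(records) {
  if (!all(c("time", "event") %in% colnames(records)))
    stop("records need 'time' and 'event' columns")
  if (any(!is.finite(records$time) | records$time <= 0))
    stop("survival times must be positive and finite")
  if (any(!records$event %in% c(0, 1)))
    stop("event must be 0/1")
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records data.frame with \code{time} and \code{event}.
#' @return data.frame: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv} (one row per observed time).
#' @export
kmEstimate <- function(records) {
  checkSurvivalRecords(records)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance summed over event times, 1 df. Two identical groups give a
#' statistic of exactly 0 and p = 1.
#'
#' @param records data.frame with \code{time}, \code{event}.
#' @param groups two-level grouping vector aligned to records.
#' @return list: \code{statistic}, \code{p}.
#' @export
logrankTest <- function(records, groups) {
  checkSurvivalRecords(records)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("exactly 2 groups required")
  if (any(table(groups) == 0L)) stop("one group is empty")
  if (sum(records$event) < 1L) stop("need at least one event")
  df <- data.frame(time = records$time, event = records$event,
                   g = groups)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  stat <- sd2$chisq
  list(statistic = stat,
       p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Univariate mode fits one model per covariate; multivariate mode fits
#' the joint model. Hazard ratios, Wald 95% confidence intervals and
#' p-values per covariate, plus model log-likelihood and iteration
#' count. Non-convergence and infinite coefficients (complete
#' separation) are flagged rather than silently returned.
#'
#' @param records data.frame with \code{time}, \code{event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return data.frame: model, covariate, beta, HR, ci_low, ci_high, p,
#'   loglik, iterations, converged, separation.
#' @export
coxFit <- function(records, covariates,
                   mode = c("univariate", "multivariate"),
                   ties = c("breslow", "efron")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  checkSurvivalRecords(records)
  for (cv in covariates) {
    if (!cv %in% colnames(records)) stop("no such covariate: ", cv)
    v <- records[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate: ", cv)
  }
  fitOne <- function(cvs, label) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(sprintf("`%s`", cvs), collapse = " + ")))
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = records, ties = ties),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite",
                  conditionMessage(w)))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    co <- s$coefficients
    sep <- !is.finite(co[, "coef"]) | co[, "se(coef)"] > 1e3
    data.frame(model = label,
               covariate = rownames(co),
               beta = co[, "coef"],
               HR = exp(co[, "coef"]),
               ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
               ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
               p = co[, "Pr(>|z|)"],
               loglik = fit$loglik[2L],
               iterations = fit$iter,
               converged = converged,
               separation = sep,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(covariates, function(cv)
      fitOne(cv, "univariate")))
  } else {
    fitOne(covariates, "multivariate")
  }
  rownames(out) <- NULL
  out
}

#' Dichotomize a continuous expression vector
#'
#' \code{"median"}: values <= median go to "low" (ties at the median
#' are low by convention); \code{"ihc_score"}: IHC percent values are
#' binned via \code{\link{binIHCScore}}; \code{"threshold"}: explicit
#' cut, <= threshold is low.
#'
#' @param values numeric vector.
#' @param rule one of \code{"median"}, \code{"ihc_score"},
#'   \code{"threshold"}.
#' @param threshold explicit cut for rule \code{"threshold"}.
#' @return character vector of "low"/"high" labels.
#' @export
dichotomizeExpression <- function(values,
                                  rule = c("median", "ihc_score",
                                           "threshold"),
                                  threshold = NULL) {
  rule <- match.arg(rule)
  switch(rule,
    median = {
      m <- median(values)
      if (all(values == values[1L]))
        stop("constant values cannot be median-dichotomized")
      ifelse(values <= m, "low", "high")
    },
    ihc_score = binIHCScore(values)$class,
    threshold = {
      if (is.null(threshold)) stop("threshold rule needs a threshold")
      ifelse(values <= threshold, "low", "high")
    })
}

#' Clinicopathological association table
#'
#' For each covariate, cross-tabulates its two levels against a binary
#' expression class and reports the uncorrected Pearson chi-square
#' p-value -- the published cohort-table layout.
#'
#' @param clinical data.frame of per-patient covariates.
#' @param classes "low"/"high" labels aligned to rows.
#' @param covariates covariate column names (default: dictionary
#'   columns present).
#' @return data.frame: covariate, level, n, n_low, n_high, p (p on the
#'   first level row of each covariate).
#' @export
clinicalAssociationTable <- function(clinical, classes,
                                     covariates = NULL) {
  if (is.null(covariates))
    covariates <- intersect(names(clinicalLevelDictionary()),
                            colnames(clinical))
  out <- NULL
  for (cv in covariates) {
    v <- as.character(clinical[[cv]])
    lv <- unique(v)
    if (length(lv) != 2L)
      stop("covariate '", cv, "' is not two-level")
    lv <- sort(lv)
    tab <- rbind(
      c(sum(v == lv[1L] & classes == "low"),
        sum(v == lv[1L] & classes == "high")),
      c(sum(v == lv[2L] & classes == "low"),
        sum(v == lv[2L] & classes == "high")))
    p <- chisq2x2(tab)$p
    out <- rbind(out, data.frame(
      covariate = cv, level = lv, n = rowSums(tab),
      n_low = tab[, 1L], n_high = tab[, 2L],
      p = c(p, NA_real_), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
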
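#' Kaplan-Meier product-limit estimate
#'
#' Events and censorings tied at the same time are handled events-first
#' (the product-limit convention).
#'
#' @param time Non-negative follow-up times (months).
#' @param event 0/1 event indicators.
#' @return Object of class `km_curve`: data.frame (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`) plus a `median` attribute (the
#'   smallest time with survival <= 0.5, NA if never reached).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% 0:1))
  if (length(time) == 0L) stop("need at least one sample")
  fit <- survfit(Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  med <- if (any(curve$survival <= 0.5))
    min(curve$time[curve$survival <= 0.5]) else NA_real_
  structure(curve, class = c("km_curve", "data.frame"), median = med)
}

#' Median survival of a Kaplan-Meier curve
#' @param curve A `km_curve` from [km_estimate()].
#' @return Median survival time (NA if the curve never reaches 0.5).
#' @export
km_median <- function(curve) attr(curve, "median")

#' Two-group log-rank test
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level group labels.
#' @return List (`statistic`, `df`, `p_value`).
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (sum(event) == 0L) stop("log-rank undefined without any event")
  sd <- survdiff(Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron handling of tied event
#' times. Covariates named in `standardize` (e.g. expression values on
#' an arbitrary scale) are scaled to unit variance first, so their
#' hazard ratios read per standard deviation.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param covariates data.frame of covariates (numeric, logical, or
#'   factor), one row per sample. Rows with any missing value are
#'   dropped (pairwise-complete analysis).
#' @param standardize Character vector of numeric covariate names to
#'   scale to unit variance.
#' @return Object of class `cox_fit`: data.frame per model term
#'   (`term`, `hr`, `ci_lower`, `ci_upper`, `p_value`), with
#'   `loglik`, `n`, `n_events` attributes.
#' @export
cox_fit <- function(time, event, covariates, standardize = character()) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(time))
  keep <- complete.cases(covariates) & !is.na(time) & !is.na(event)
  time <- time[keep]
  event <- event[keep]
  covariates <- covariates[keep, , drop = FALSE]
  if (sum(event) < 1L) stop("Cox model undefined without any event")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v)) < 2L)
      stop("covariate '", nm, "' is constant")
    if (nm %in% standardize) {
      if (!is.numeric(v)) stop("cannot standardize non-numeric '", nm, "'")
      covariates[[nm]] <- v / sd(v)
    }
  }
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ ., data = covariates, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit)))
    stop("Cox fit dropped coefficient(s) (collinear covariates): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(out, class = c("cox_fit", "data.frame"),
            loglik = fit$loglik[2L], n = s$n, n_events = s$nevent)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d\n",
              attr(x, "n"), attr(x, "n_events")))
  df <- as.data.frame(x)
  df$hr <- sprintf("%.3f", df$hr)
  df$ci <- sprintf("(%.3f-%.3f)", x$ci_lower, x$ci_upper)
  df$p_value <- signif(df$p_value, 3)
  print(df[c("term", "hr", "ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Bivariate Cox scans with a fixed covariate
#'
#' Fits one two-covariate Cox model per candidate confounder, always
#' including the fixed covariate (e.g. KRAS LOH), and reports the fixed
#' covariate's hazard ratio from each model — a stability check of its
#' effect against potential confounders.
#'
#' @inheritParams cox_fit
#' @param fixed Name of the fixed covariate column in `covariates`.
#' @param others Names of candidate covariates (default: all other
#'   columns).
#' @return data.frame, one row per candidate: `other`, the fixed
#'   covariate's `fixed_hr`, `fixed_ci_lower`, `fixed_ci_upper`,
#'   `fixed_p`, plus `other_hr` and `other_p`.
#' @export
bivariate_scan <- function(time, event, covariates, fixed,
                           others = setdiff(names(covariates), fixed),
                           standardize = character()) {
  covariates <- as.data.frame(covariates)
  if (!fixed %in% names(covariates))
    stop("fixed covariate '", fixed, "' not found")
  empty <- data.frame(other = character(), fixed_hr = numeric(),
                      fixed_ci_lower = numeric(), fixed_ci_upper = numeric(),
                      fixed_p = numeric(), other_hr = numeric(),
                      other_p = numeric())
  if (length(others) == 0L) return(empty)
  rows <- lapply(others, function(nm) {
    sub <- covariates[c(fixed, nm)]
    a <- as.numeric(factor(sub[[1L]]))
    b <- as.numeric(factor(sub[[2L]]))
    ok <- !is.na(a) & !is.na(b)
    if (sd(a[ok]) > 0 && sd(b[ok]) > 0 &&
        abs(cor(a[ok], b[ok])) > 1 - 1e-12)
      stop("covariate '", nm, "' is collinear with '", fixed, "'")
    f <- cox_fit(time, event, sub,
                 standardize = intersect(standardize, names(sub)))
    fixed_row <- grep(paste0("^", fixed), f$term)[1L]
    other_row <- setdiff(seq_len(nrow(f)), fixed_row)[1L]
    data.frame(other = nm, fixed_hr = f$hr[fixed_row],
               fixed_ci_lower = f$ci_lower[fixed_row],
               fixed_ci_upper = f$ci_upper[fixed_row],
               fixed_p = f$p_value[fixed_row],
               other_hr = f$hr[other_row], other_p = f$p_value[other_row])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified Kaplan-Meier report with pairwise log-rank tests
#'
#' One KM curve per stratum (e.g. the four KRAS LOH x mutation
#' combinations), the overall log-rank p across strata, and pairwise
#' log-rank p-values. Empty strata are dropped with a warning.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param strata Per-sample stratum labels.
#' @return List: `curves` (named list of `km_curve`), `medians`,
#'   `overall_p`, `pairwise_p` (symmetric matrix).
#' @export
stratified_km_report <- function(time, event, strata) {
  if (!is.factor(strata)) strata <- factor(strata)
  empty <- setdiff(levels(strata), as.character(unique(strata[!is.na(strata)])))
  if (length(empty)) {
    warning("dropping empty stratum(s): ", paste(empty, collapse = ", "))
    strata <- droplevels(strata)
  }
  lv <- levels(strata)
  if (length(lv) < 2L) stop("need at least two non-empty strata")
  curves <- lapply(lv, function(s)
    km_estimate(time[strata == s], event[strata == s]))
  names(curves) <- lv
  overall <- logrank_test(time, event, strata)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    sel <- strata %in% lv[c(i, j)]
    p <- if (sum(event[sel]) == 0L) NA_real_
    else logrank_test(time[sel], event[sel], droplevels(strata[sel]))$p_value
    pw[i, j] <- pw[j, i] <- p
  }
  diag(pw) <- 1
  list(curves = curves,
       medians = vapply(curves, km_median, numeric(1)),
       overall_p = overall$p_value, pairwise_p = pw)
}
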
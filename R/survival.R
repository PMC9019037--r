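#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]: subjects censored at an event time are
#' counted at risk for that time, per the product-limit convention.
#'
#' @param records Data frame with columns `time` (positive) and `event`
#'   (1 event, 0 censored).
#' @return Data frame of class `"km_curve"` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric
#' variance summed over distinct event times (chi-square, 1 df,
#' two-sided), via [survival::survdiff()].
#'
#' @param records Data frame with columns `time`, `event` and the group
#'   column.
#' @param group Name of the grouping column (exactly 2 levels).
#' @return List of class `"logrank_result"`: `observed` and `expected`
#'   events per group, `chi_square`, `p`.
#' @export
logrank_test <- function(records, group = "group") {
  check_survival_records(records)
  if (!group %in% colnames(records)) {
    stop(sprintf("grouping column '%s' not found", group), call. = FALSE)
  }
  g <- as.character(records[[group]])
  if (length(unique(g)) != 2L) {
    stop("log-rank test requires exactly 2 groups", call. = FALSE)
  }
  records$..group <- g
  fit <- survival::survdiff(survival::Surv(time, event) ~ ..group,
                            data = records)
  chi <- unname(fit$chisq)
  structure(list(observed = setNames(as.numeric(fit$obs),
                                     sub("^\\.\\.group=", "", names(fit$n))),
                 expected = setNames(as.numeric(fit$exp),
                                     sub("^\\.\\.group=", "", names(fit$n))),
                 chi_square = chi,
                 p = pchisq(chi, df = 1L, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("log-rank test (2 groups, 1 df)\n")
  print(data.frame(observed = x$observed, expected = x$expected))
  cat(sprintf("chi-square = %.4g, p = %.4g\n", x$chi_square, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via [survival::coxph()] with Efron
#' tie handling by default (Breslow available), convergence tolerance
#' 1e-9 and at most 50 iterations. Wald 95% confidence intervals are
#' `exp(beta +/- 1.96 * SE)`. A monotone partial likelihood (complete
#' separation) is reported through the `converged` flag with the last
#' iterate retained.
#'
#' @param records Data frame with columns `time`, `event` and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List of class `"cox_result"`: `coefficients`,
#'   `hazard_ratios`, `ci_lower`, `ci_upper`, `se`, `score_chi_square`
#'   (the global score test), `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival_records(records)
  if (sum(records$event) < 1L) stop("need at least 1 event", call. = FALSE)
  missing <- setdiff(covariates, colnames(records))
  if (length(missing) > 0L) {
    stop("covariate(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)),
    warning = function(w) {
      if (grepl("converge|infinit|beta may be infinite", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  qr_ok <- qr(fit$var)$rank == length(beta)
  converged <- !warned && all(is.finite(beta)) && all(is.finite(se)) && qr_ok
  structure(list(coefficients = beta,
                 hazard_ratios = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 se = setNames(se, names(beta)),
                 score_chi_square = unname(fit$score),
                 converged = converged,
                 n = fit$n, n_events = fit$nevent),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (n = %d, events = %d)%s\n",
              x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                   ci_low = x$ci_lower, ci_high = x$ci_upper, se = x$se))
  invisible(x)
}

check_survival_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% colnames(records)))
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("times must be finite and positive", call. = FALSE)
  }
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  invisible(records)
}
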
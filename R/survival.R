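#' Univariate Cox proportional-hazards screen of one covariate
#'
#' Fits the Cox partial likelihood for a single covariate (Breslow handling
#' of tied event times by default; Efron available) and classifies the
#' signature: protective when the hazard ratio is below 1 with a two-sided
#' Wald p-value under `alpha`, high-risk when above 1, null otherwise.
#' Monotone likelihood (perfect separation of the risk ordering) makes the
#' estimate diverge; fits with `|log HR|` beyond a bound are flagged
#' non-estimable.
#'
#' @param time positive follow-up times.
#' @param event 0/1 indicator (1 = death observed).
#' @param covariate numeric vector.
#' @param alpha significance level for the classification, default 0.05.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param hr_bound flag threshold on `|log HR|`, default `log(1e6)`.
#' @return list with `log_hr`, `hr`, `se`, `p`, `classification`
#'   (`"protective"`, `"high_risk"`, `"null"` or `"non_estimable"`),
#'   `n`, `n_events`.
#' @export
cox_univariate <- function(time, event, covariate, alpha = 0.05,
                           ties = c("breslow", "efron"),
                           hr_bound = log(1e6)) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event),
            length(time) == length(covariate),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) stop("need at least one observed event")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ covariate,
                    ties = ties),
    error = function(e) NULL,
    warning = function(w) {
      # refit quietly; the divergence check below handles monotone cases
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ covariate,
                        ties = ties))
    })
  if (is.null(fit) || !is.finite(stats::coef(fit)) ||
      abs(stats::coef(fit)) > hr_bound) {
    return(list(log_hr = NA_real_, hr = NA_real_, se = NA_real_,
                p = NA_real_, classification = "non_estimable",
                n = length(time), n_events = sum(event)))
  }
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  cls <- if (p >= alpha) "null" else if (beta < 0) "protective"
         else "high_risk"
  list(log_hr = beta, hr = exp(beta), se = se, p = p,
       classification = cls, n = length(time), n_events = sum(event))
}

#' Cox screening of every expression feature against survival
#'
#' Applies [cox_univariate()] to each row of an expression matrix, matching
#' samples between the survival table and the expression columns.
#'
#' @param surv data frame with columns `sample`, `time`, `event`.
#' @param expr features x samples matrix.
#' @param alpha significance level, default 0.05.
#' @param ties tie handling, see [cox_univariate()].
#' @return data frame with `feature`, `log_hr`, `hr`, `p`,
#'   `classification`, sorted by p-value.
#' @export
cox_screen <- function(surv, expr, alpha = 0.05, ties = "breslow") {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  shared <- intersect(surv$sample, colnames(expr))
  if (length(shared) < 3)
    stop("fewer than 3 samples shared between survival and expression data")
  s <- surv[match(shared, surv$sample), ]
  rows <- lapply(rownames(expr), function(f) {
    r <- cox_univariate(s$time, s$event, expr[f, shared],
                        alpha = alpha, ties = ties)
    data.frame(feature = f, log_hr = r$log_hr, hr = r$hr, p = r$p,
               classification = r$classification)
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
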
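#' Simulate individual-patient survival data at trial scale
#'
#' Stands in for the calibration trial: overall survival (OS) and
#' time-to-progression (TTP) are drawn from independent Weibull processes,
#' TTP is then capped at OS (a patient who dies first is progression-
#' censored at death), and administrative censoring is applied. Patients
#' accrue uniformly over `accrual_weeks`, so with total study duration
#' `censor_time` the per-patient censoring time is
#' `censor_time - U(0, accrual_weeks)`.
#'
#' @param n Number of patients (>= 10); default 160, a phase-III-like arm.
#' @param os,ttp Generating `weibull_params`.
#' @param censor_time Total study duration in weeks (default 156, i.e.
#'   3 years); `Inf` disables censoring.
#' @param accrual_weeks Uniform accrual window in weeks (default 104);
#'   0 makes censoring purely administrative at `censor_time`.
#' @param seed Optional integer seed.
#' @return A data frame of class `ipd_table` with columns `id`,
#'   `os_weeks`, `os_event`, `ttp_weeks`, `ttp_event`.
#' @export
#' @examples
#' ipd <- simulate_ipd(n = 50, seed = 1)
#' all(ipd$ttp_weeks <= ipd$os_weeks)
simulate_ipd <- function(n = 160, os = default_os_params(),
                         ttp = default_ttp_params(), censor_time = 156,
                         accrual_weeks = 104, seed = NULL) {
  if (n < 10) stop("validation error: 'n' must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  os_t <- stats::rweibull(n, shape = os$shape, scale = os$scale)
  ttp_t <- stats::rweibull(n, shape = ttp$shape, scale = ttp$scale)
  cens <- if (is.finite(censor_time)) {
    censor_time - stats::runif(n, 0, min(accrual_weeks, censor_time))
  } else rep(Inf, n)
  os_obs <- pmin(os_t, cens)
  os_event <- as.integer(os_t <= cens)
  # progression observed only if it precedes both death and censoring
  ttp_obs <- pmin(ttp_t, os_obs)
  ttp_event <- as.integer(ttp_t <= os_obs)
  # guard against zero times (possible only at extreme censor_time)
  eps <- 1e-6
  d <- data.frame(id = seq_len(n), os_weeks = pmax(os_obs, eps),
                  os_event = os_event, ttp_weeks = pmax(ttp_obs, eps),
                  ttp_event = ttp_event)
  class(d) <- c("ipd_table", "data.frame")
  d
}

endpoint_surv <- function(ipd, endpoint = c("os", "ttp")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "os") {
    list(time = ipd$os_weeks, event = ipd$os_event)
  } else {
    list(time = ipd$ttp_weeks, event = ipd$ttp_event)
  }
}

as_fit_result <- function(fit, family, n_used, n_events) {
  if (family == "weibull") {
    est <- fit$res[c("shape", "scale"), ]
    out <- list(family = "weibull",
                shape = est["shape", "est"], scale = est["scale", "est"],
                se_shape = est["shape", "se"], se_scale = est["scale", "se"])
  } else {
    rate <- fit$res["rate", "est"]
    se_rate <- fit$res["rate", "se"]
    out <- list(family = "exponential", shape = 1, scale = 1 / rate,
                se_shape = 0, se_scale = se_rate / rate^2)
  }
  out$loglik <- fit$loglik
  out$AIC <- fit$AIC
  out$n_used <- n_used
  out$n_events <- n_events
  structure(out, class = "fit_result")
}

#' Fit a parametric survival model by censored maximum likelihood
#'
#' Fits an exponential or Weibull model to a right-censored endpoint of an
#' individual-patient table, maximising the usual censored log-likelihood
#' (events contribute the log density, censored records the log survival).
#' The two families are compared by AIC (`2k - 2 loglik`, k = 1 or 2).
#'
#' @param ipd An `ipd_table` (see [simulate_ipd()], [read_ipd()]).
#' @param endpoint `"os"` or `"ttp"`.
#' @param family `"weibull"` or `"exponential"`.
#' @return An object of class `fit_result`: `family`, `shape`, `scale`
#'   (weeks; shape fixed at 1 for the exponential), standard errors,
#'   `loglik`, `AIC`, `n_used`, `n_events`.
#' @export
fit_parametric <- function(ipd, endpoint = c("os", "ttp"),
                           family = c("weibull", "exponential")) {
  endpoint <- match.arg(endpoint)
  family <- match.arg(family)
  y <- endpoint_surv(ipd, endpoint)
  if (sum(y$event) < 2) {
    stop("fitting error: need at least 2 observed events for endpoint '",
         endpoint, "'")
  }
  dist <- if (family == "weibull") "weibull" else "exp"
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(y$time, y$event) ~ 1, dist = dist),
    error = function(e) {
      stop("fitting error: ", family, " fit did not converge: ",
           conditionMessage(e))
    }
  )
  as_fit_result(fit, family, n_used = length(y$time),
                n_events = sum(y$event))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s: shape %.3f (se %.3f), scale %.1f (se %.2f) weeks\n  loglik %.2f, AIC %.2f, %d/%d events\n",
    x$family, x$shape, x$se_shape, x$scale, x$se_scale, x$loglik, x$AIC,
    x$n_events, x$n_used))
  invisible(x)
}

#' Bootstrap the correlation between Weibull shape and scale
#'
#' Resamples patients with replacement, refits the Weibull model to each
#' resample and returns the Pearson correlation of the bootstrap (shape,
#' scale) estimates — the quantity that parameterises the joint
#' uncertainty distribution of the survival parameters.
#'
#' @param ipd An `ipd_table`.
#' @param endpoint `"os"` or `"ttp"`.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Optional integer seed.
#' @return A list with `correlation`, the bootstrap `estimates` data frame
#'   (shape, scale), and `n_failed`.
#' @export
bootstrap_shape_scale_corr <- function(ipd, endpoint = c("os", "ttp"),
                                       B = 1000, seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (B < 100) stop("validation error: 'B' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ipd)
  est <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("shape", "scale")))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- tryCatch(fit_parametric(ipd[idx, ], endpoint, "weibull"),
                  error = function(e) NULL)
    if (is.null(f)) failed <- failed + 1L else est[b, ] <- c(f$shape, f$scale)
  }
  if (failed > 0.05 * B) {
    stop("fitting error: ", failed, " of ", B, " bootstrap fits failed")
  }
  ok <- stats::complete.cases(est)
  list(correlation = stats::cor(est[ok, 1], est[ok, 2]),
       estimates = as.data.frame(est[ok, , drop = FALSE]),
       n_failed = failed)
}

#' Refit the Weibull model on survivors past a landmark
#'
#' Drops patients whose observed time is below the landmark and fits the
#' Weibull by a left-truncated (delayed-entry) likelihood with entry at
#' the landmark, keeping the model's original time origin. With
#' `landmark = 0` this is identical to [fit_parametric()].
#'
#' @param ipd An `ipd_table`.
#' @param endpoint `"os"` or `"ttp"`.
#' @param landmark Landmark time in weeks (default 9, about three full
#'   3-week cycles).
#' @return A `fit_result`.
#' @export
refit_conditional <- function(ipd, endpoint = "os", landmark = 9) {
  y <- endpoint_surv(ipd, endpoint)
  keep <- y$time >= landmark
  if (!any(keep)) stop("fitting error: empty risk set at landmark ", landmark)
  time <- y$time[keep]
  event <- y$event[keep]
  if (sum(event) < 2) {
    stop("fitting error: fewer than 2 events after landmark ", landmark)
  }
  if (landmark <= 0) {
    return(fit_parametric(ipd, endpoint, "weibull"))
  }
  entry <- rep(landmark, length(time))
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(entry, time, event) ~ 1,
                          dist = "weibull"),
    error = function(e) {
      stop("fitting error: left-truncated fit did not converge: ",
           conditionMessage(e))
    }
  )
  as_fit_result(fit, "weibull", n_used = length(time),
                n_events = sum(event))
}

#' Read / write individual-patient tables
#'
#' Plain comma-delimited format with header
#' `id, os_weeks, os_event, ttp_weeks, ttp_event`.
#'
#' @param file Path.
#' @return `read_ipd()`: an `ipd_table`.
#' @export
read_ipd <- function(file) {
  d <- utils::read.csv(file)
  need <- c("id", "os_weeks", "os_event", "ttp_weeks", "ttp_event")
  if (!all(need %in% names(d))) {
    stop("validation error: IPD file must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(d$ttp_weeks > d$os_weeks + 1e-9)) {
    stop("validation error: 'ttp_weeks' must not exceed 'os_weeks'")
  }
  if (!all(d$os_event %in% c(0, 1)) || !all(d$ttp_event %in% c(0, 1))) {
    stop("validation error: event flags must be 0/1")
  }
  class(d) <- c("ipd_table", "data.frame")
  d
}

#' @rdname read_ipd
#' @param ipd An `ipd_table`.
#' @export
write_ipd <- function(ipd, file) {
  utils::write.csv(
    ipd[, c("id", "os_weeks", "os_event", "ttp_weeks", "ttp_event")],
    file, row.names = FALSE
  )
  invisible(file)
}
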
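#' Incremental cost-effectiveness ratio between two strategies
#'
#' Computed on mean costs and QALYs (the convention for PSA-averaged
#' tables). Returns the ratio when the costlier strategy also gains QALYs,
#' or a dominance flag: `"dominated"` (more costly, no more effective),
#' `"dominant"` (cheaper and more effective), or `"equivalent"` when both
#' the QALY and cost differences are negligible (|dQALY| < 0.005 and
#' |dcost| < 100 EUR), which operationalises the treatment of strategies
#' whose difference is within model noise.
#'
#' @param costlier,cheaper `strategy_outcome`s (or any lists with
#'   `total_cost` and `qalys`), conventionally ordered by cost.
#' @return A list with `value` (EUR/QALY or `NA`), `status` (one of
#'   `"icer"`, `"dominated"`, `"dominant"`, `"equivalent"`), `d_cost`,
#'   `d_qalys`.
#' @export
#' @examples
#' icer(list(total_cost = 1000, qalys = 0.1), list(total_cost = 0, qalys = 0))
icer <- function(costlier, cheaper) {
  dc <- costlier$total_cost - cheaper$total_cost
  dq <- costlier$qalys - cheaper$qalys
  status <- if (abs(dq) < 0.005 && abs(dc) < 100) {
    "equivalent"
  } else if (dq > 0) {
    if (dc <= 0) "dominant" else "icer"
  } else {
    if (dc > 0) "dominated" else "icer"
  }
  value <- if (status == "icer") dc / dq else NA_real_
  list(value = value, status = status, d_cost = dc, d_qalys = dq)
}

#' Cost-effectiveness frontier with strict and extended dominance
#'
#' Orders strategies by mean cost, removes strictly dominated strategies
#' (some other strategy costs no more and yields no fewer QALYs, one
#' strictly), then iteratively removes extended- (weakly-) dominated
#' strategies, i.e. those whose incremental ICER exceeds that of the next
#' more expensive frontier point. ICERs along the resulting frontier are
#' strictly increasing.
#'
#' @param means Data frame with columns `strategy`, `total_cost` (or
#'   `mean_cost`) and `qalys` (or `mean_qalys`), e.g. the `summary` of a
#'   [run_psa()] result.
#' @param reference Optional name of the reference strategy for the
#'   `icer_vs_reference` column; defaults to the cheapest strategy.
#' @return An object of class `frontier_result`: data frame ordered by
#'   cost with columns `strategy`, `mean_cost`, `mean_qalys`, `status`
#'   (`reference`, `on_frontier`, `dominated`, `extended_dominated`),
#'   `icer_vs_previous` (vs the previous frontier point),
#'   `icer_vs_reference`, and `equivalent_to` (name of a frontier strategy
#'   this one is indistinguishable from, or `NA`).
#' @export
frontier <- function(means, reference = NULL) {
  cost <- if ("mean_cost" %in% names(means)) means$mean_cost else means$total_cost
  qaly <- if ("mean_qalys" %in% names(means)) means$mean_qalys else means$qalys
  stopifnot(length(cost) >= 2)
  d <- data.frame(strategy = means$strategy, mean_cost = cost,
                  mean_qalys = qaly, stringsAsFactors = FALSE)
  d <- d[order(d$mean_cost, d$mean_qalys), ]
  n <- nrow(d)
  status <- rep("on_frontier", n)

  # strict dominance
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dominated <- any(
      d$mean_cost[others] <= d$mean_cost[i] &
        d$mean_qalys[others] >= d$mean_qalys[i] &
        (d$mean_cost[others] < d$mean_cost[i] |
           d$mean_qalys[others] > d$mean_qalys[i])
    )
    if (dominated) status[i] <- "dominated"
  }

  # extended dominance on the remaining, cost-ordered strategies
  repeat {
    idx <- which(status == "on_frontier")
    if (length(idx) < 3) break
    ic <- diff(d$mean_cost[idx]) / diff(d$mean_qalys[idx])
    bad <- which(diff(ic) < 0)  # ICER not increasing => middle point weak
    if (!length(bad)) break
    status[idx[bad[1] + 1]] <- "extended_dominated"
  }

  idx <- which(status == "on_frontier")
  if (is.null(reference)) reference <- d$strategy[1]
  if (status[match(reference, d$strategy)] == "on_frontier" &&
      d$strategy[idx[1]] == reference) {
    status[idx[1]] <- "reference"
  } else if (length(idx)) {
    status[idx[1]] <- "reference"
  }

  front <- which(status %in% c("reference", "on_frontier"))
  icer_prev <- rep(NA_real_, n)
  if (length(front) > 1) {
    for (k in 2:length(front)) {
      i <- front[k]; j <- front[k - 1]
      icer_prev[i] <- (d$mean_cost[i] - d$mean_cost[j]) /
        (d$mean_qalys[i] - d$mean_qalys[j])
    }
  }
  ref_i <- match(reference, d$strategy)
  icer_ref <- (d$mean_cost - d$mean_cost[ref_i]) /
    (d$mean_qalys - d$mean_qalys[ref_i])
  icer_ref[ref_i] <- NA_real_

  equivalent_to <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (status[i] %in% c("reference", "on_frontier")) next
    for (j in front) {
      cmp <- icer(list(total_cost = d$mean_cost[i], qalys = d$mean_qalys[i]),
                  list(total_cost = d$mean_cost[j], qalys = d$mean_qalys[j]))
      if (cmp$status == "equivalent") {
        equivalent_to[i] <- d$strategy[j]
        break
      }
    }
  }
  structure(
    cbind(d, data.frame(status = status, icer_vs_previous = icer_prev,
                        icer_vs_reference = icer_ref,
                        equivalent_to = equivalent_to,
                        stringsAsFactors = FALSE)),
    class = c("frontier_result", "data.frame")
  )
}

#' Net monetary benefit
#'
#' `wtp * qalys - total_cost`: the monetary value of a strategy's health
#' gain at a given willingness to pay per QALY, minus its cost.
#'
#' @param outcome A `strategy_outcome` (or list with `total_cost`,
#'   `qalys`).
#' @param wtp Willingness to pay (EUR/QALY, >= 0); vectorised.
#' @return Net benefit in EUR.
#' @export
net_benefit <- function(outcome, wtp) {
  if (any(wtp < 0)) stop("domain error: 'wtp' must be >= 0")
  wtp * outcome$qalys - outcome$total_cost
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA runs in which
#' each strategy attains the highest net monetary benefit. Exact ties are
#' broken toward the lower-cost strategy.
#'
#' @param psa A `psa_results`.
#' @param wtp_grid Willingness-to-pay grid (EUR/QALY), default 0 to
#'   100 000 in steps of 1000.
#' @return An object of class `ceac_result`: data frame with column `wtp`
#'   and one probability column per strategy (rows sum to 1).
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(psa, "psa_results"))
  strategies <- unique(psa$draws$strategy)
  runs <- sort(unique(psa$draws$run))
  C <- Q <- matrix(NA_real_, length(runs), length(strategies),
                   dimnames = list(NULL, strategies))
  for (s in strategies) {
    d <- psa$draws[psa$draws$strategy == s, ]
    d <- d[order(d$run), ]
    C[, s] <- d$total_cost
    Q[, s] <- d$qalys
  }
  probs <- matrix(0, length(wtp_grid), length(strategies),
                  dimnames = list(NULL, strategies))
  # a vanishing cost penalty implements the lower-cost tie-break without
  # perturbing genuine net-benefit differences
  for (k in seq_along(wtp_grid)) {
    nmb <- wtp_grid[k] * Q - C - 1e-9 * C
    win <- max.col(nmb, ties.method = "first")
    tab <- tabulate(win, nbins = length(strategies))
    probs[k, ] <- tab / length(runs)
  }
  structure(data.frame(wtp = wtp_grid, probs, check.names = FALSE),
            class = c("ceac_result", "data.frame"))
}

#' Turning point of an acceptability curve set
#'
#' The smallest willingness-to-pay value at which the most probable
#' strategy differs from the most probable strategy at WTP 0 (the cheapest
#' strategy). Returns `NA` if no switch occurs on the grid.
#'
#' @param cc A `ceac_result`.
#' @return WTP in EUR/QALY, or `NA`.
#' @export
ceac_turning_point <- function(cc) {
  p <- as.matrix(cc[, setdiff(names(cc), "wtp"), drop = FALSE])
  lead <- max.col(p, ties.method = "first")
  sw <- which(lead != lead[1])
  if (!length(sw)) return(NA_real_)
  cc$wtp[sw[1]]
}

#' Rerun a scenario under a sensitivity-analysis variant
#'
#' Variants:
#' \describe{
#'   \item{`rr_1.2`, `rr_1.8` (aliases `rr12`, `rr18`)}{replace the
#'     relative risk of the discontinuation strategies (1.50 in the base
#'     case) by 1.2 or 1.8 on both endpoints;}
#'   \item{`rr_1.5`}{the no-op variant, identical to the base case;}
#'   \item{`conditional_9wk` (alias `cond9w`)}{replaces the
#'     overall-survival Weibull parameters by a left-truncated refit on
#'     patients surviving past a 9-week landmark, reflecting the later
#'     onset of hand-foot syndrome (~3 full cycles). The refit comes from
#'     [refit_conditional()] on supplied or freshly simulated
#'     individual-patient data.}
#' }
#'
#' @param scenario A `scenario_spec`.
#' @param settings A `model_settings`.
#' @param variant Variant name.
#' @param dists A `psa_distributions`.
#' @param n_runs,seed Passed to [run_psa()].
#' @param ipd Optional `data.frame` of individual-patient data for the
#'   `conditional_9wk` variant; simulated at the default emulation size if
#'   omitted.
#' @return A list with `variant`, `psa` (a `psa_results`), `frontier` and
#'   `ceac`.
#' @export
run_sensitivity <- function(scenario, settings, variant,
                            dists = psa_distributions(), n_runs = 1000,
                            seed = 20260317, ipd = NULL) {
  key <- c(rr12 = "rr_1.2", "rr_1.2" = "rr_1.2",
           rr15 = "rr_1.5", "rr_1.5" = "rr_1.5",
           rr18 = "rr_1.8", "rr_1.8" = "rr_1.8",
           cond9w = "conditional_9wk", conditional_9wk = "conditional_9wk")
  if (!variant %in% names(key)) {
    stop("unknown sensitivity variant: '", variant, "'")
  }
  variant <- unname(key[variant])
  if (startsWith(variant, "rr_")) {
    rr <- as.numeric(sub("rr_", "", variant))
    scenario$strategies <- lapply(scenario$strategies, function(s) {
      if (s$discontinuation) {
        s$rr_os <- rr
        s$rr_ttp <- rr
      }
      s
    })
  } else {
    if (is.null(ipd)) {
      ipd <- simulate_ipd(n = 160, seed = seed + 1L)
    }
    fit <- refit_conditional(ipd, endpoint = "os", landmark = 9)
    dists$os_mean <- c(fit$shape, fit$scale)
  }
  psa <- run_psa(scenario, settings, dists, n_runs = n_runs, seed = seed)
  fr <- frontier(psa$summary, reference = scenario$reference_strategy)
  cc <- ceac(psa)
  list(variant = variant, psa = psa, frontier = fr, ceac = cc)
}
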
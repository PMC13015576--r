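STATE_NAMES <- c("first_line", "progression", "second_line_treat",
                 "prog_no_treat", "death")

#' Discount factor for a given model week
#'
#' @param week Integer week (>= 0); vectorised.
#' @param annual_rate Annual discount rate (>= 0).
#' @param weeks_per_year Weeks per year.
#' @return `(1 + annual_rate)^(-week / weeks_per_year)`.
#' @export
#' @examples
#' discount_factor(0, 0.03)            # 1
#' discount_factor(365.25 / 7, 0.03)   # 1 / 1.03
discount_factor <- function(week, annual_rate, weeks_per_year = 365.25 / 7) {
  if (annual_rate < 0) stop("domain error: 'annual_rate' must be >= 0")
  (1 + annual_rate)^(-week / weeks_per_year)
}

#' Run the five-state weekly cohort model
#'
#' Follows a closed cohort from the moment of the treatment switch through
#' the states first-line treatment, progression (a single transient week),
#' second-line treatment, progression without treatment, and death. Within
#' each week death is evaluated first (so the cohort survival curve exactly
#' reproduces the fitted overall-survival distribution), then progression
#' among survivors of the first-line state; patients leaving the transient
#' progression state split `p_second_line : 1 - p_second_line` between the
#' two post-progression states. Death is absorbing and the same
#' overall-survival process (clock at the model start) drives death from
#' every alive state.
#'
#' @param strategy A `strategy_spec`.
#' @param settings A `model_settings`.
#' @param os,ttp `weibull_params` for overall survival and
#'   time-to-progression under the reference (capecitabine/5FU) treatment;
#'   the strategy's relative risks are applied on top.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (matrix, week 0..horizon by the five states, rows sum to 1) and
#'   `new_progressions` (fraction of the cohort entering the progression
#'   state each week).
#' @export
run_cohort <- function(strategy, settings, os = default_os_params(),
                       ttp = default_ttp_params()) {
  stopifnot(inherits(strategy, "strategy_spec"),
            inherits(settings, "model_settings"))
  H <- settings$horizon
  wk <- 0:(H - 1)
  pd <- weekly_transition_prob(wk, os, strategy$rr_os)
  pp <- weekly_transition_prob(wk, ttp, strategy$rr_ttp)
  if (any(!is.finite(pd)) || any(!is.finite(pp)) ||
      any(pd < 0 | pd > 1) || any(pp < 0 | pp > 1)) {
    stop("numerical-integrity error: weekly transition probabilities ",
         "outside [0, 1]")
  }
  # Death first, then progression among survivors: the combined weekly exit
  # probability pd + (1 - pd) * pp can never exceed 1, and alive mass
  # telescopes to the survival function.
  alive <- c(1, cumprod(1 - pd))            # A[t] = prod_{s<t} (1 - pd[s])
  progfree <- c(1, cumprod(1 - pp))         # share of alive still in 1st line
  first_line <- alive * progfree
  # inflow into the transient progression state, as fraction of alive mass
  inflow <- c(0, progfree[1:H] * pp)        # P[t] / alive[t]
  new_prog <- alive * inflow
  # post-progression occupancy accumulates the split inflow, thinned only by
  # death (which factors out through 'alive')
  settled <- c(0, cumsum(inflow[1:H]))      # sum_{s<t} inflow[s]
  second_line <- alive * settings$p_second_line * settled
  no_treat <- alive * (1 - settings$p_second_line) * settled
  occ <- cbind(first_line, new_prog, second_line, no_treat, 1 - alive)
  colnames(occ) <- STATE_NAMES
  rownames(occ) <- 0:H
  structure(
    list(occupancy = occ, new_progressions = new_prog,
         strategy = strategy$name, horizon = H),
    class = "cohort_trace"
  )
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Costs: weekly regimen cost times state occupancy, discounted at the cost
#' rate; the expected adverse-event cost is added once at week 0
#' (undiscounted, as the events occur immediately at first-line treatment).
#' QALYs: occupancy-weighted utilities divided by weeks-per-year,
#' discounted at the utility rate. During the adverse-event period the
#' first-line utility is reduced by the probability-weighted, additive
#' disutilities (floored at 0). The transient progression week and the
#' untreated post-progression state carry the no-treatment decrement; the
#' second-line state carries the treatment decrement.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param strategy The `strategy_spec` that produced it.
#' @param settings A `model_settings`.
#' @param utilities A `utility_set`.
#' @return An object of class `strategy_outcome` (also a one-row list):
#'   total and per-source discounted costs, QALYs, median OS and TTP in
#'   months, mean treatment cycles per line, percentage progressing.
#' @export
accrue <- function(trace, strategy, settings, utilities = utility_set()) {
  stopifnot(inherits(trace, "cohort_trace"))
  H <- trace$horizon
  occ <- trace$occupancy[1:H, , drop = FALSE]  # state occupied during week t
  wk <- 0:(H - 1)
  dfc <- discount_factor(wk, settings$discount_costs, settings$weeks_per_year)
  dfq <- discount_factor(wk, settings$discount_qalys, settings$weeks_per_year)

  wc_fl <- weekly_cost(strategy$first_line)
  wc_sl <- weekly_cost(strategy$second_line)
  cost_first <- sum(occ[, "first_line"] * wc_fl * dfc)
  cost_second <- sum(occ[, "second_line_treat"] * wc_sl * dfc)
  cost_ae <- expected_ae_cost(strategy$ae)

  u <- utilities
  u_second <- u$u_first_line - u$d_second_line
  u_not <- u$u_first_line - u$d_prog_no_treat
  if (min(u$u_first_line, u_second, u_not) < 0 ||
      max(u$u_first_line, u_second, u_not) > 1) {
    stop("validation error: state utility outside [0, 1] after decrements")
  }
  u_fl <- rep(u$u_first_line, H)
  ae_weeks <- seq_len(min(strategy$ae$duration, H))
  u_fl[ae_weeks] <- pmax(0, u$u_first_line - ae_disutility(strategy$ae))
  weekly_utility <- occ[, "first_line"] * u_fl +
    occ[, "progression"] * u_not +
    occ[, "second_line_treat"] * u_second +
    occ[, "prog_no_treat"] * u_not
  qalys <- sum(weekly_utility / settings$weeks_per_year * dfq)

  death <- trace$occupancy[, "death"]
  med_os_wk <- which(death >= 0.5)[1] - 1
  total_prog <- sum(trace$new_progressions)
  cum_prog <- cumsum(trace$new_progressions)
  med_ttp_wk <- if (total_prog > 0) {
    which(cum_prog >= total_prog / 2)[1] - 1
  } else NA_real_

  fl_weeks <- sum(occ[, "first_line"])
  sl_weeks <- sum(occ[, "second_line_treat"])
  mean_cycles_first <- if (is.null(strategy$first_line)) 0 else
    fl_weeks / strategy$first_line$cycle_length
  mean_cycles_second <- sl_weeks / strategy$second_line$cycle_length

  structure(
    list(
      strategy = strategy$name,
      total_cost = cost_first + cost_second + cost_ae,
      cost_first_line = cost_first,
      cost_second_line = cost_second,
      cost_ae = cost_ae,
      qalys = qalys,
      median_os = weeks_to_months(med_os_wk),
      median_ttp = weeks_to_months(med_ttp_wk),
      mean_cycles_first_line = mean_cycles_first,
      mean_cycles_second_line = mean_cycles_second,
      pct_progressed = 100 * total_prog
    ),
    class = "strategy_outcome"
  )
}

weeks_to_months <- function(w) w * 7 / 30.44

#' Run one strategy end to end at given parameter values
#'
#' Convenience wrapper: [run_cohort()] followed by [accrue()].
#' @inheritParams run_cohort
#' @inheritParams accrue
#' @return A `strategy_outcome`.
#' @export
run_strategy <- function(strategy, settings, os = default_os_params(),
                         ttp = default_ttp_params(),
                         utilities = utility_set()) {
  accrue(run_cohort(strategy, settings, os, ttp), strategy, settings,
         utilities)
}

#' Tabulate strategy outcomes
#'
#' Binds `strategy_outcome` objects into a data frame with columns in the
#' order of the published results tables (total costs, costs by source,
#' QALYs, medians, treatment cycles, percentage progressing).
#'
#' @param outcomes List of `strategy_outcome` objects.
#' @return A data frame, one row per strategy.
#' @export
outcomes_table <- function(outcomes) {
  stopifnot(length(outcomes) >= 1)
  do.call(rbind, lapply(outcomes, function(o) {
    data.frame(
      strategy = o$strategy, total_cost = o$total_cost,
      cost_first_line = o$cost_first_line,
      cost_second_line = o$cost_second_line, cost_ae = o$cost_ae,
      qalys = o$qalys, median_os = o$median_os, median_ttp = o$median_ttp,
      mean_cycles_first_line = o$mean_cycles_first_line,
      mean_cycles_second_line = o$mean_cycles_second_line,
      pct_progressed = o$pct_progressed,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write a cohort trace to a delimited file
#'
#' @param trace A `cohort_trace`.
#' @param file Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
write_trace <- function(trace, file) {
  d <- data.frame(week = 0:trace$horizon, trace$occupancy,
                  new_progressions = trace$new_progressions)
  names(d) <- c("week", paste0("s_", STATE_NAMES), "new_progressions")
  utils::write.csv(d, file, row.names = FALSE)
  invisible(d)
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf(
    "<strategy_outcome> %s\n  total %.0f EUR (1st %.0f, 2nd %.0f, AE %.0f)\n  %.2f QALYs | median OS %.1f mo | %.0f%% progressed\n",
    x$strategy, x$total_cost, x$cost_first_line, x$cost_second_line,
    x$cost_ae, x$qalys, x$median_os, x$pct_progressed))
  invisible(x)
}
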
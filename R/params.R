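#' Default per-cycle cost components (EUR, 2024-indexed)
#'
#' Point estimates for the medication and administration cost components of
#' the modelled regimens, per treatment cycle for an average body surface
#' area of 1.95 m2. Oral drugs (capecitabine, S-1) carry no administration
#' cost; short i.v. administration (~2 h, oxaliplatin or irinotecan) and long
#' i.v. administration (48+ h, 5FU) are costed separately.
#'
#' @return Named numeric vector of per-cycle costs in EUR.
#' @export
#' @examples
#' default_cost_table()["s1_mono"]
default_cost_table <- function() {
  c(
    s1_mono     = 398,  # S-1 monotherapy, 30 mg/m2
    s1_combo    = 331,  # S-1 in combination, 25 mg/m2
    cape_red    = 180,  # reduced-dose capecitabine, 1000 mg/m2
    oxaliplatin = 556,  # 130 mg/m2
    fu_lv       = 208,  # reduced 5FU + leucovorin
    iri_mono    = 677,  # irinotecan monotherapy, 350 mg/m2
    iri_combo   = 348,  # irinotecan in combination, 180 mg/m2
    admin_short = 335,  # 2-h i.v. administration
    admin_long  = 1288  # 48+-h i.v. administration
  )
}

#' Construct a regimen cost object
#'
#' A regimen is costed per treatment cycle and converted to a weekly cost by
#' [weekly_cost()]. Cycles last 3 weeks for oral and short-infusion regimens
#' and 2 weeks for i.v.-5FU-based regimens. A regimen may optionally record
#' the named cost components it is built from (see [default_cost_table()]);
#' component-based regimens can then be re-priced per probabilistic draw.
#'
#' @param name Regimen label.
#' @param drug_cost_per_cycle Medication cost per cycle (EUR, >= 0).
#' @param admin_cost_per_cycle Administration cost per cycle (EUR, >= 0).
#' @param cycle_length Cycle length in weeks, 2 or 3.
#' @param drug_components Optional character vector of component names from
#'   the cost table whose sum gives the drug cost.
#' @param admin_component Optional single component name for the
#'   administration cost, or `NA` for oral regimens.
#' @return An object of class `regimen_cost`.
#' @export
regimen_cost <- function(name, drug_cost_per_cycle, admin_cost_per_cycle,
                         cycle_length, drug_components = NULL,
                         admin_component = NA_character_) {
  if (!is.numeric(cycle_length) || !(cycle_length %in% c(2, 3))) {
    stop("configuration error: 'cycle_length' must be 2 or 3 (got ",
         deparse(cycle_length), ") for regimen '", name, "'")
  }
  if (!is.numeric(drug_cost_per_cycle) || drug_cost_per_cycle < 0 ||
      !is.finite(drug_cost_per_cycle)) {
    stop("configuration error: 'drug_cost_per_cycle' must be finite and >= 0 ",
         "for regimen '", name, "'")
  }
  if (!is.numeric(admin_cost_per_cycle) || admin_cost_per_cycle < 0 ||
      !is.finite(admin_cost_per_cycle)) {
    stop("configuration error: 'admin_cost_per_cycle' must be finite and >= 0 ",
         "for regimen '", name, "'")
  }
  structure(
    list(
      name = as.character(name),
      drug_cost_per_cycle = as.numeric(drug_cost_per_cycle),
      admin_cost_per_cycle = as.numeric(admin_cost_per_cycle),
      cycle_length = as.numeric(cycle_length),
      drug_components = drug_components,
      admin_component = admin_component
    ),
    class = "regimen_cost"
  )
}

#' Build a regimen from named cost components
#'
#' @param name Regimen label.
#' @param drug_components Character vector of component names (drug costs).
#' @param admin_component Single component name or `NA` (oral regimen).
#' @param cycle_length Cycle length in weeks (2 or 3).
#' @param cost_table Named vector of per-cycle component costs.
#' @return A `regimen_cost`.
#' @export
#' @examples
#' sox <- regimen_from_components("SOX", c("s1_combo", "oxaliplatin"),
#'                                "admin_short", 3)
#' weekly_cost(sox)  # ~407 EUR/week
regimen_from_components <- function(name, drug_components, admin_component,
                                    cycle_length,
                                    cost_table = default_cost_table()) {
  missing_comp <- setdiff(
    c(drug_components, admin_component[!is.na(admin_component)]),
    names(cost_table)
  )
  if (length(missing_comp)) {
    stop("configuration error: unknown cost component(s): ",
         paste(missing_comp, collapse = ", "))
  }
  admin <- if (length(admin_component) == 1 && !is.na(admin_component)) {
    unname(cost_table[admin_component])
  } else 0
  regimen_cost(
    name = name,
    drug_cost_per_cycle = sum(cost_table[drug_components]),
    admin_cost_per_cycle = admin,
    cycle_length = cycle_length,
    drug_components = drug_components,
    admin_component = admin_component
  )
}

#' Re-price a regimen against a (possibly sampled) cost table
#'
#' Regimens carrying component names are rebuilt from the supplied table;
#' regimens defined by direct costs are returned unchanged.
#'
#' @param regimen A `regimen_cost` or `NULL`.
#' @param cost_table Named vector of per-cycle component costs.
#' @return A `regimen_cost` (or `NULL`).
#' @keywords internal
reprice_regimen <- function(regimen, cost_table) {
  if (is.null(regimen) || is.null(regimen$drug_components)) return(regimen)
  regimen_from_components(regimen$name, regimen$drug_components,
                          regimen$admin_component, regimen$cycle_length,
                          cost_table = cost_table)
}

#' Weekly cost of a regimen
#'
#' Total per-cycle cost (medication + administration) divided by the cycle
#' length in weeks. Treatment discontinuation (a `NULL` regimen) costs zero.
#'
#' @param regimen A `regimen_cost`, or `NULL` for no treatment.
#' @return Cost in EUR per week.
#' @export
#' @examples
#' folfox <- regimen_cost("FOLFOX", 208 + 556, 1288, 2)
#' weekly_cost(folfox)  # 1026
weekly_cost <- function(regimen) {
  if (is.null(regimen)) return(0)
  stopifnot(inherits(regimen, "regimen_cost"))
  (regimen$drug_cost_per_cycle + regimen$admin_cost_per_cycle) /
    regimen$cycle_length
}

#' @export
print.regimen_cost <- function(x, ...) {
  cat(sprintf("<regimen_cost> %s: %.2f + %.2f EUR / %d-week cycle = %.2f EUR/week\n",
              x$name, x$drug_cost_per_cycle, x$admin_cost_per_cycle,
              as.integer(x$cycle_length), weekly_cost(x)))
  invisible(x)
}

#' Adverse-event profile of a first-line treatment switch
#'
#' Probabilities that a patient experiences recurrent hand-foot syndrome
#' (HFS, grade >= 2), recurrent cardiovascular toxicity (CVT, grade >= 1),
#' diarrhoea and anorexia after the switch, with the per-event management
#' costs for HFS/CVT and the common quality-of-life decrement. Adverse
#' events are assumed to occur at the start of first-line treatment and to
#' last `duration` weeks. Diarrhoea and anorexia carry disutility only; no
#' management cost is attached to them.
#'
#' @param p_hfs,p_cvt,p_diarrhoea,p_anorexia Event probabilities in `[0, 1]`.
#' @param cost_hfs,cost_cvt Per-event management cost (EUR, >= 0).
#' @param disutility Utility decrement applied while the events last.
#' @param duration Duration of the adverse-event period in weeks (>= 1).
#' @return An object of class `ae_profile`.
#' @export
adverse_event_profile <- function(p_hfs = 0, p_cvt = 0, p_diarrhoea = 0,
                                  p_anorexia = 0, cost_hfs = 50,
                                  cost_cvt = 200, disutility = 0.15,
                                  duration = 2) {
  probs <- c(p_hfs = p_hfs, p_cvt = p_cvt, p_diarrhoea = p_diarrhoea,
             p_anorexia = p_anorexia)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    stop("configuration error: '", names(probs)[bad][1],
         "' must be a probability in [0, 1] (got ", probs[bad][1], ")")
  }
  if (cost_hfs < 0 || cost_cvt < 0) {
    stop("configuration error: adverse-event costs must be >= 0")
  }
  if (disutility < 0 || disutility > 1) {
    stop("configuration error: 'disutility' must lie in [0, 1]")
  }
  if (duration < 1) stop("configuration error: 'duration' must be >= 1 week")
  structure(
    list(p_hfs = p_hfs, p_cvt = p_cvt, p_diarrhoea = p_diarrhoea,
         p_anorexia = p_anorexia, cost_hfs = cost_hfs, cost_cvt = cost_cvt,
         disutility = disutility, duration = duration),
    class = "ae_profile"
  )
}

#' Expected adverse-event cost per patient
#'
#' The cohort-level expectation of adverse-event management costs: each
#' recurrence probability multiplied by its cost. Only HFS and CVT carry a
#' cost; diarrhoea and anorexia enter the model through disutility alone.
#'
#' @param ae An `ae_profile`.
#' @return Expected cost in EUR per patient.
#' @export
#' @examples
#' expected_ae_cost(adverse_event_profile(p_hfs = 0.55, p_cvt = 0.40))  # 107.5
expected_ae_cost <- function(ae) {
  stopifnot(inherits(ae, "ae_profile"))
  ae$p_hfs * ae$cost_hfs + ae$p_cvt * ae$cost_cvt
}

#' Summed probability-weighted disutility of the adverse-event profile
#' @keywords internal
ae_disutility <- function(ae) {
  ae$disutility * (ae$p_hfs + ae$p_cvt + ae$p_diarrhoea + ae$p_anorexia)
}

# Canned AE profiles: continuation on capecitabine/i.v.-5FU vs switch to S-1.
# Recurrence probabilities after a toxicity-triggered switch.

#' @rdname adverse_event_profile
#' @export
ae_profile_fluoropyrimidine <- function() {
  adverse_event_profile(p_hfs = 0.55, p_cvt = 0.40)
}

#' @rdname adverse_event_profile
#' @export
ae_profile_s1 <- function() {
  adverse_event_profile(p_hfs = 0.05, p_cvt = 0.04)
}

#' Health-state utilities
#'
#' Utility of the first-line treatment state and the decrements applied to
#' the post-progression states. The transient progression week and the
#' no-treatment post-progression state carry the smaller decrement (no
#' burden of treatment); the second-line treatment state carries the larger
#' one. Death has utility zero.
#'
#' @param u_first_line Utility while on first-line treatment.
#' @param d_second_line Decrement for progressed disease on second-line
#'   treatment.
#' @param d_prog_no_treat Decrement for progressed disease without treatment.
#' @param u_death Utility of death (fixed 0).
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_first_line = 0.83, d_second_line = 0.15,
                        d_prog_no_treat = 0.10, u_death = 0) {
  if (u_death != 0) stop("configuration error: 'u_death' must be 0")
  for (u in c(u_first_line, u_first_line - d_second_line,
              u_first_line - d_prog_no_treat)) {
    if (u < 0 || u > 1) {
      stop("validation error: a state utility falls outside [0, 1] ",
           "after applying decrements")
    }
  }
  structure(
    list(u_first_line = u_first_line, d_second_line = d_second_line,
         d_prog_no_treat = d_prog_no_treat, u_death = u_death),
    class = "utility_set"
  )
}

#' Construct a treatment strategy
#'
#' A strategy pairs a first-line regimen (or discontinuation) with a
#' second-line regimen, the relative risks it implies on the weekly death
#' and progression probabilities, and its adverse-event profile. By
#' convention: continuing capecitabine/5FU at reduced dose has RR 1.0 on
#' both endpoints; switching to an S-1-based first line has RR 0.93 on
#' death and 1.0 on progression; discontinuing first-line treatment has
#' RR 1.50 on both.
#'
#' @param name Strategy identifier (unique within a scenario).
#' @param first_line A `regimen_cost`, or `NULL` for discontinuation.
#' @param second_line A `regimen_cost`.
#' @param rr_os Relative risk on the weekly death probability (> 0).
#' @param rr_ttp Relative risk on the weekly progression probability (> 0).
#' @param ae An `ae_profile`.
#' @param s1_based Logical; `TRUE` if the first line is S-1-based (its
#'   OS relative risk is then redrawn in probabilistic analyses).
#' @param discontinuation Logical; `TRUE` if first-line treatment stops
#'   (its relative risk is the lever of the discontinuation sensitivity
#'   analyses).
#' @param label Optional human-readable label (e.g. "SOX -> irinotecan").
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, first_line, second_line, rr_os, rr_ttp, ae,
                          s1_based = FALSE, discontinuation = is.null(first_line),
                          label = name) {
  if (!is.null(first_line)) stopifnot(inherits(first_line, "regimen_cost"))
  stopifnot(inherits(second_line, "regimen_cost"), inherits(ae, "ae_profile"))
  if (!is.numeric(rr_os) || rr_os <= 0 || !is.numeric(rr_ttp) || rr_ttp <= 0) {
    stop("configuration error: 'rr_os' and 'rr_ttp' must be > 0 for strategy '",
         name, "'")
  }
  if (discontinuation && !is.null(first_line)) {
    stop("configuration error: a discontinuation strategy cannot carry a ",
         "first-line regimen ('", name, "')")
  }
  structure(
    list(name = as.character(name), label = as.character(label),
         first_line = first_line, second_line = second_line,
         rr_os = rr_os, rr_ttp = rr_ttp, ae = ae,
         s1_based = isTRUE(s1_based), discontinuation = isTRUE(discontinuation)),
    class = "strategy_spec"
  )
}

#' Construct a treatment scenario
#'
#' A scenario fixes the clinical setting (the first-line treatment on which
#' toxicity occurred) and collects the 3-4 strategies available from the
#' moment of the switch onward.
#'
#' @param name Scenario identifier.
#' @param strategies List of `strategy_spec` objects (3 or 4).
#' @param reference_strategy Name of the reference (comparator) strategy.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, strategies, reference_strategy) {
  stopifnot(is.list(strategies), length(strategies) >= 2)
  nm <- vapply(strategies, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("configuration error: duplicate strategy names: ",
         paste(nm[duplicated(nm)], collapse = ", "))
  }
  if (!reference_strategy %in% nm) {
    stop("configuration error: 'reference_strategy' (", reference_strategy,
         ") is not among the strategies")
  }
  names(strategies) <- nm
  structure(
    list(name = as.character(name), strategies = strategies,
         reference_strategy = reference_strategy),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "-", length(x$strategies), "strategies\n")
  for (s in x$strategies) {
    cat(sprintf("  %-16s %s (rr_os %.2f, rr_ttp %.2f)%s\n", s$name, s$label,
                s$rr_os, s$rr_ttp,
                if (s$name == x$reference_strategy) "  [reference]" else ""))
  }
  invisible(x)
}

#' Global model settings
#'
#' Cycle length is fixed at 1 week. The default horizon of 780 weeks (~15
#' years) leaves a negligible fraction (< 0.1%) of the cohort alive under
#' the default survival parameters. Costs are discounted at 3% per year and
#' utilities at 1.5% per year.
#'
#' @param horizon Model horizon in weeks.
#' @param weeks_per_year Weeks per year used for discounting and QALY
#'   accrual (365.25 / 7).
#' @param discount_costs Annual discount rate for costs.
#' @param discount_qalys Annual discount rate for utilities.
#' @param p_second_line Proportion of progressed patients who start
#'   second-line treatment.
#' @param cohort_size Size of the hypothetical cohort (reporting only; the
#'   engine tracks fractions).
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(horizon = 780, weeks_per_year = 365.25 / 7,
                           discount_costs = 0.03, discount_qalys = 0.015,
                           p_second_line = 0.80, cohort_size = 1000) {
  if (horizon < 1) stop("configuration error: 'horizon' must be >= 1 week")
  if (p_second_line < 0 || p_second_line > 1) {
    stop("configuration error: 'p_second_line' must lie in [0, 1]")
  }
  if (discount_costs < 0 || discount_qalys < 0) {
    stop("configuration error: discount rates must be >= 0")
  }
  structure(
    list(cycle_length = 1, horizon = as.integer(horizon),
         weeks_per_year = weeks_per_year, discount_costs = discount_costs,
         discount_qalys = discount_qalys, p_second_line = p_second_line,
         cohort_size = cohort_size),
    class = "model_settings"
  )
}
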
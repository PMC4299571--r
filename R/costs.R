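#' Intervention cost summary
#'
#' Container for the cost structure of one intervention: a one-off start-up
#' cost plus three annual streams (implementation, maintenance, external
#' technical assistance), all in constant 2013 international dollars.
#'
#' @param intervention Label, e.g. `"CI"`, `"FI"` or `"FICI"`.
#' @param start_up One-off start-up cost ($).
#' @param annual_implementation Annual implementation cost ($/yr).
#' @param annual_maintenance Annual maintenance (recruitment/retraining) cost
#'   ($/yr).
#' @param annual_external Annual cost of external technical experts ($/yr).
#' @param arms_covered Number of trial arms the costs pertain to (1 or 2).
#'
#' @return An object of class `cost_summary`.
#' @seealso [annual_cost()], [trial_total_cost()], [combine_interventions()]
#' @export
#' @examples
#' cs <- cost_summary("CI", 362083, 2068997, 27250, 120067)
#' annual_cost(cs)
cost_summary <- function(intervention, start_up, annual_implementation,
                         annual_maintenance, annual_external,
                         arms_covered = 2L) {
  comps <- c(start_up = start_up,
             annual_implementation = annual_implementation,
             annual_maintenance = annual_maintenance,
             annual_external = annual_external)
  if (any(!is.finite(comps)) || any(comps < 0)) {
    stop("all cost components must be finite and non-negative", call. = FALSE)
  }
  if (!arms_covered %in% c(1L, 2L)) {
    stop("'arms_covered' must be 1 or 2", call. = FALSE)
  }
  structure(
    list(intervention = as.character(intervention),
         start_up = as.numeric(start_up),
         annual_implementation = as.numeric(annual_implementation),
         annual_maintenance = as.numeric(annual_maintenance),
         annual_external = as.numeric(annual_external),
         arms_covered = as.integer(arms_covered)),
    class = "cost_summary"
  )
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("Cost summary: %s (%d arm%s), constant 2013 international $\n",
              x$intervention, x$arms_covered,
              if (x$arms_covered > 1) "s" else ""))
  comp <- c("start-up (one-off)" = x$start_up,
            "implementation ($/yr)" = x$annual_implementation,
            "maintenance ($/yr)" = x$annual_maintenance,
            "external ($/yr)" = x$annual_external)
  for (nm in names(comp)) {
    cat(sprintf("  %-22s %s\n", nm, format(round(comp[[nm]]), big.mark = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.cost_summary <- function(x, ...) {
  data.frame(intervention = x$intervention,
             arms_covered = x$arms_covered,
             start_up = x$start_up,
             annual_implementation = x$annual_implementation,
             annual_maintenance = x$annual_maintenance,
             annual_external = x$annual_external,
             stringsAsFactors = FALSE)
}

#' Annualise a capital purchase by straight-line depreciation
#'
#' Capital items are spread over their expected lifespan assuming constant
#' linear depreciation and no interest.
#'
#' @param purchase_cost Purchase cost (any currency).
#' @param lifespan_years Expected lifespan in years; must be positive.
#'
#' @return Annual cost, same currency as `purchase_cost`.
#' @export
#' @examples
#' annualize_capital(1000, 4) # 250 per year
annualize_capital <- function(purchase_cost, lifespan_years) {
  if (any(!is.finite(lifespan_years)) || any(lifespan_years <= 0)) {
    stop("'lifespan_years' must be positive", call. = FALSE)
  }
  purchase_cost / lifespan_years
}

#' Joint-cost allocation rule
#'
#' Programme (joint) costs that cannot be attributed directly to the
#' community or facility intervention are split by fixed proportions; any
#' remainder is attributed to non-intervention trial activities and excluded
#' from intervention costs.
#'
#' @param fraction_ci Proportion of joint costs allocated to the community
#'   intervention.
#' @param fraction_fi Proportion allocated to the facility intervention.
#'
#' @return An object of class `joint_rule`.
#' @export
joint_rule <- function(fraction_ci = 0.5, fraction_fi = 0.5) {
  if (fraction_ci < 0 || fraction_fi < 0 || fraction_ci + fraction_fi > 1) {
    stop("joint fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  structure(list(fraction_ci = fraction_ci, fraction_fi = fraction_fi),
            class = "joint_rule")
}

#' Allocate joint costs between the two interventions
#'
#' @param joint_total Total joint cost ($/yr).
#' @param rule A [joint_rule()].
#'
#' @return A list with components `ci`, `fi` and `remainder`; the three sum
#'   exactly to `joint_total`.
#' @export
#' @examples
#' allocate_joint_costs(1000, joint_rule(0.5, 0.5))
allocate_joint_costs <- function(joint_total, rule = joint_rule()) {
  stopifnot(inherits(rule, "joint_rule"))
  ci <- joint_total * rule$fraction_ci
  fi <- joint_total * rule$fraction_fi
  list(ci = ci, fi = fi, remainder = joint_total - ci - fi)
}

#' Total annual cost of an intervention
#'
#' Recurring (implementation plus maintenance) plus external costs; the
#' per-year figure used for scale-up.
#'
#' @param summary A [cost_summary()].
#' @return Annual cost in $/yr.
#' @export
annual_cost <- function(summary) {
  stopifnot(inherits(summary, "cost_summary"))
  summary$annual_implementation + summary$annual_maintenance +
    summary$annual_external
}

#' Total cost over the trial period
#'
#' Start-up cost plus the annual cost accrued over the trial period. This is
#' the fixed cost entering the incremental cost-effectiveness ratio.
#'
#' @param summary A [cost_summary()].
#' @param trial_years Length of the trial period in years (default 2.25,
#'   i.e. 27 months).
#' @return Total cost in constant 2013 international $.
#' @export
#' @examples
#' trial_total_cost(cost_summary("CI", 362083, 2068997, 27250, 120067))
trial_total_cost <- function(summary, trial_years = 2.25) {
  stopifnot(inherits(summary, "cost_summary"))
  if (!is.finite(trial_years) || trial_years <= 0) {
    stop("'trial_years' must be positive", call. = FALSE)
  }
  summary$start_up + trial_years * annual_cost(summary)
}

#' Combine the community and facility cost structures
#'
#' The combined intervention is costed as the component-wise sum of the two
#' single interventions (no economies of scope), covering two arms. Halving
#' with [rescale_arms()] gives the one-arm cost.
#'
#' @param ci,fi [cost_summary()] objects for the community and facility
#'   interventions, covering the same number of arms.
#' @param intervention Label for the combined summary.
#' @return A `cost_summary` with `arms_covered = 2`.
#' @export
combine_interventions <- function(ci, fi, intervention = "FICI") {
  stopifnot(inherits(ci, "cost_summary"), inherits(fi, "cost_summary"))
  if (ci$arms_covered != fi$arms_covered) {
    stop("cannot combine summaries covering different arm widths",
         call. = FALSE)
  }
  cost_summary(intervention,
               ci$start_up + fi$start_up,
               ci$annual_implementation + fi$annual_implementation,
               ci$annual_maintenance + fi$annual_maintenance,
               ci$annual_external + fi$annual_external,
               arms_covered = 2L)
}

#' Rescale a cost summary to a different number of arms
#'
#' Costs are proportional to the covered population, so moving between one-
#' and two-arm coverage multiplies every component by the arm ratio.
#'
#' @param summary A [cost_summary()].
#' @param arms Target number of arms (1 or 2).
#' @return A rescaled `cost_summary`.
#' @export
rescale_arms <- function(summary, arms) {
  stopifnot(inherits(summary, "cost_summary"))
  arms <- as.integer(arms)
  f <- arms / summary$arms_covered
  cost_summary(summary$intervention,
               summary$start_up * f,
               summary$annual_implementation * f,
               summary$annual_maintenance * f,
               summary$annual_external * f,
               arms_covered = arms)
}

#' Read a cost ledger from CSV
#'
#' Expected header: `item,category,year,currency,amount,lifespan`.
#' `category` is one of `start_up`, `implementation`, `maintenance`,
#' `external`, `joint`; `lifespan` is empty for recurrent items and a
#' positive number of years for capital items.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A `data.frame` ledger.
#' @export
read_cost_ledger <- function(path) {
  led <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cost_ledger(led)
}

#' @rdname read_cost_ledger
#' @param ledger A ledger `data.frame` to validate.
#' @export
validate_cost_ledger <- function(ledger) {
  need <- c("item", "category", "year", "currency", "amount", "lifespan")
  miss <- setdiff(need, names(ledger))
  if (length(miss)) {
    stop("ledger is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok_cat <- c("start_up", "implementation", "maintenance", "external", "joint")
  bad <- setdiff(unique(ledger$category), ok_cat)
  if (length(bad)) {
    stop("unknown ledger categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(ledger$amount < 0, na.rm = TRUE)) {
    stop("ledger amounts must be non-negative", call. = FALSE)
  }
  ls <- ledger$lifespan
  if (any(!is.na(ls) & ls <= 0)) {
    stop("capital lifespans must be positive", call. = FALSE)
  }
  ledger
}

#' Build an intervention cost summary from a raw ledger
#'
#' Converts every line to constant 2013 international dollars, annualises
#' capital items over their lifespan, allocates joint lines by the given
#' rule, and averages annual categories over the calendar years present in
#' the ledger. Start-up lines are summed as a one-off total (capital
#' start-up items are *not* annualised: in a trial costing the full purchase
#' enters the start-up block, while their use during implementation would
#' appear as separate annualised lines).
#'
#' @param ledger A ledger `data.frame` (see [read_cost_ledger()]).
#' @param intervention Label for the resulting summary.
#' @param table A [currency_table()].
#' @param rule A [joint_rule()]; joint lines receive the fraction belonging
#'   to `intervention` (`fraction_ci` when the label contains "CI" alone,
#'   `fraction_fi` for "FI"); pass `joint_fraction` to override.
#' @param joint_fraction Optional explicit proportion of joint lines
#'   allocated to this intervention.
#' @param arms_covered Arms the ledger pertains to.
#' @return A [cost_summary()].
#' @export
build_cost_summary <- function(ledger, intervention,
                               table = currency_table(),
                               rule = joint_rule(),
                               joint_fraction = NULL,
                               arms_covered = 2L) {
  ledger <- validate_cost_ledger(ledger)
  if (is.null(joint_fraction)) {
    joint_fraction <- switch(toupper(intervention),
                             CI = rule$fraction_ci,
                             FI = rule$fraction_fi,
                             rule$fraction_ci + rule$fraction_fi)
  }
  usd <- mapply(convert_to_intl2013, ledger$amount, ledger$currency,
                ledger$year, MoreArgs = list(table = table))
  annualised <- usd
  capital <- !is.na(ledger$lifespan)
  if (any(capital)) {
    annualised[capital] <- annualize_capital(usd[capital],
                                             ledger$lifespan[capital])
  }
  cat_of <- ledger$category
  # joint lines: take this intervention's share, then treat as implementation
  share <- ifelse(cat_of == "joint", joint_fraction, 1)
  cat_of[cat_of == "joint"] <- "implementation"

  start_up <- sum(usd[cat_of == "start_up"] * share[cat_of == "start_up"])
  per_year <- function(cat) {
    sel <- cat_of == cat
    if (!any(sel)) return(0)
    yrs <- ledger$year[sel]
    sum(annualised[sel] * share[sel]) / length(unique(yrs))
  }
  cost_summary(intervention,
               start_up,
               per_year("implementation"),
               per_year("maintenance"),
               per_year("external"),
               arms_covered = arms_covered)
}

#' Tabulate cost summaries in the trial's reporting layout
#'
#' @param summaries A list of [cost_summary()] objects.
#' @param trial_years Trial period length used for the period total.
#' @return A `data.frame` with one row per intervention: the four cost
#'   components, the annual cost and the trial-period total.
#' @export
cost_table <- function(summaries, trial_years = 2.25) {
  rows <- lapply(summaries, function(s) {
    cbind(as.data.frame(s),
          annual_cost = annual_cost(s),
          trial_total = trial_total_cost(s, trial_years))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
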
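#' Cost-effectiveness analysis input
#'
#' One decision option: a fixed total cost (costs carry no sampling
#' uncertainty in the trial costing) paired with posterior draws of its
#' effect in DALYs averted. Per-draw costs are also accepted for reuse in
#' settings with uncertain costs.
#'
#' @param label Option name.
#' @param cost Total cost ($); scalar, or one value per draw.
#' @param effect_draws DALYs averted per posterior draw; a scalar is treated
#'   as a degenerate distribution.
#' @return An object of class `cea_input`.
#' @export
#' @examples
#' ci <- cea_input("CI", 5348791, rnorm(1000, 67361, 28750))
cea_input <- function(label, cost, effect_draws) {
  if (length(effect_draws) < 1 || anyNA(effect_draws)) {
    stop("'effect_draws' must be non-empty and free of NAs", call. = FALSE)
  }
  if (any(!is.finite(cost)) || any(cost < 0)) {
    stop("'cost' must be finite and non-negative", call. = FALSE)
  }
  if (!length(cost) %in% c(1L, length(effect_draws))) {
    stop("'cost' must be scalar or one value per draw", call. = FALSE)
  }
  structure(list(label = as.character(label),
                 cost = as.numeric(cost),
                 effect = as.numeric(effect_draws)),
            class = "cea_input")
}

#' The do-nothing comparator (current practice)
#'
#' Current practice has zero incremental cost and zero incremental effect by
#' construction.
#'
#' @param n_draws Draw count to match the other options.
#' @param label Option name.
#' @return A [cea_input()].
#' @export
do_nothing <- function(n_draws = 1, label = "current practice") {
  cea_input(label, 0, rep(0, n_draws))
}

mean_cost <- function(input) mean(input$cost)
mean_effect <- function(input) mean(input$effect)

# net-benefit draws at threshold k (scalar k)
nb_draws <- function(input, k, n = length(input$effect)) {
  eff <- rep_len(input$effect, n)
  cst <- rep_len(input$cost, n)
  k * eff - cst
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental mean cost over incremental mean effect of the reference
#' option relative to the comparator (default: do-nothing). Dominance is
#' flagged: the reference *dominates* when it is cheaper and more effective,
#' and is *dominated* when costlier and less effective. A zero incremental
#' effect leaves the ratio undefined; a warning of class
#' `mnhcea_undefined_icer` is signalled and the incremental cost is still
#' reported.
#'
#' @param reference,comparator [cea_input()] objects.
#' @return An object of class `icer`: list with `icer`, `delta_cost`,
#'   `delta_effect`, `status` (one of `"tradeoff"`, `"reference dominates"`,
#'   `"reference dominated"`, `"undefined"`).
#' @export
#' @examples
#' icer(cea_input("CI", 5348791, 67361))
icer <- function(reference, comparator = do_nothing()) {
  stopifnot(inherits(reference, "cea_input"),
            inherits(comparator, "cea_input"))
  dc <- mean_cost(reference) - mean_cost(comparator)
  de <- mean_effect(reference) - mean_effect(comparator)
  status <- if (de == 0) "undefined"
    else if (dc <= 0 && de > 0) "reference dominates"
    else if (dc >= 0 && de < 0) "reference dominated"
    else "tradeoff"
  val <- if (de == 0) NA_real_ else dc / de
  if (status == "undefined") {
    warning(structure(class = c("mnhcea_undefined_icer", "warning",
                                "condition"),
                      list(message = sprintf(
                        "undefined ICER: zero incremental effect (incremental cost %.2f)",
                        dc), call = sys.call())))
  }
  structure(list(icer = val, delta_cost = dc, delta_effect = de,
                 status = status,
                 reference = reference$label, comparator = comparator$label),
            class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  cat(sprintf("ICER %s vs %s: ", x$reference, x$comparator))
  if (x$status == "undefined") {
    cat(sprintf("undefined (zero incremental effect; incremental cost $%s)\n",
                format(round(x$delta_cost), big.mark = ",")))
  } else {
    cat(sprintf("$%.1f per DALY averted (%s)\n", x$icer, x$status))
  }
  invisible(x)
}

#' Expected incremental benefit
#'
#' `EIB(k) = k * (E1 - E0) - (C1 - C0)`: the monetised expected net benefit
#' of the option at willingness-to-pay `k` per DALY averted, relative to the
#' comparator. Exactly linear in `k`, and zero at `k = ICER` when the ICER
#' is a genuine trade-off.
#'
#' @param input A [cea_input()].
#' @param k Willingness-to-pay threshold(s), $ per DALY; vectorised.
#' @param comparator Comparator option (default do-nothing).
#' @return EIB in $, one value per `k`.
#' @export
#' @examples
#' eib(cea_input("CI", 5348791, 67361), k = 780)
eib <- function(input, k, comparator = do_nothing()) {
  stopifnot(inherits(input, "cea_input"), all(k >= 0))
  k * (mean_effect(input) - mean_effect(comparator)) -
    (mean_cost(input) - mean_cost(comparator))
}

#' Cost-effectiveness acceptability curve
#'
#' For each threshold `k`, the proportion of matched simulations in which
#' the reference option has strictly higher net benefit `k*E - C` than the
#' comparator; ties count as not more cost-effective.
#'
#' @param reference,comparator [cea_input()] objects with matched draws
#'   (equal draw counts, or a degenerate scalar effect).
#' @param k Threshold(s), vectorised.
#' @return Probability per `k`.
#' @export
ceac <- function(reference, comparator = do_nothing(), k) {
  stopifnot(inherits(reference, "cea_input"),
            inherits(comparator, "cea_input"))
  nr <- length(reference$effect)
  nc <- length(comparator$effect)
  if (nr != nc && nr > 1 && nc > 1) {
    stop("matched-draw CEAC needs equal draw counts (or a scalar option)",
         call. = FALSE)
  }
  n <- max(nr, nc)
  vapply(k, function(kk) {
    mean(nb_draws(reference, kk, n) > nb_draws(comparator, kk, n))
  }, numeric(1))
}

#' Expected value of perfect information
#'
#' `EVPI(k) = E[max_i NB_i] - max_i E[NB_i]` over matched draws, where the
#' net benefit of option i in draw j is `k*E_ij - C_i` and do-nothing has
#' net benefit identically zero. Population-level, in $; always
#' non-negative.
#'
#' @param inputs List of [cea_input()] objects; a do-nothing option is
#'   appended automatically unless `include_do_nothing = FALSE`.
#' @param k Threshold(s), vectorised.
#' @param include_do_nothing Append the zero-NB option?
#' @return EVPI in $, one value per `k`.
#' @export
#' @examples
#' evpi(list(cea_input("A", 0, c(10, 0)), cea_input("B", 0, c(0, 4))), k = 1)
evpi <- function(inputs, k, include_do_nothing = TRUE) {
  if (inherits(inputs, "cea_input")) inputs <- list(inputs)
  stopifnot(all(vapply(inputs, inherits, logical(1), "cea_input")))
  n <- max(vapply(inputs, function(z) length(z$effect), integer(1)))
  if (include_do_nothing) inputs <- c(inputs, list(do_nothing(n)))
  vapply(k, function(kk) {
    nb <- lapply(inputs, nb_draws, k = kk, n = n)
    mean(do.call(pmax, nb)) - max(vapply(nb, mean, numeric(1)))
  }, numeric(1))
}

#' Willingness-to-pay threshold grid
#'
#' @param kmax Upper end of the grid ($ per DALY).
#' @param step Grid spacing.
#' @param kref Reference threshold always included (default 780, Malawi's
#'   2013 per-capita GDP).
#' @return Ascending numeric vector starting at 0.
#' @export
threshold_grid <- function(kmax = 2500, step = 10, kref = 780) {
  sort(unique(c(seq(0, kmax, by = step), kref)))
}

#' Incremental analysis with dominance pruning
#'
#' Standard cost-effectiveness frontier over the options' mean costs and
#' effects (plus an implicit zero-cost, zero-effect origin): options that
#' are dominated (another option is at least as cheap and more effective)
#' or extendedly dominated (a convex combination of two others beats them)
#' are flagged; frontier ICERs are each option's ratio against the previous
#' frontier point.
#'
#' @param inputs List of [cea_input()] objects.
#' @return A `data.frame`: label, mean cost, mean effect, `status`
#'   (`"frontier"`, `"dominated"`, `"extended dominated"`), and
#'   `icer_vs_previous` for frontier options.
#' @export
ce_frontier <- function(inputs) {
  stopifnot(all(vapply(inputs, inherits, logical(1), "cea_input")))
  df <- data.frame(
    label = vapply(inputs, `[[`, character(1), "label"),
    cost = vapply(inputs, mean_cost, numeric(1)),
    effect = vapply(inputs, mean_effect, numeric(1)),
    stringsAsFactors = FALSE)
  df$status <- "frontier"
  # strict dominance (against the origin and every other option)
  for (i in seq_len(nrow(df))) {
    others <- rbind(df[-i, c("cost", "effect")], c(0, 0))
    if (any(others$cost <= df$cost[i] & others$effect >= df$effect[i] &
              (others$cost < df$cost[i] | others$effect > df$effect[i]))) {
      df$status[i] <- "dominated"
    }
  }
  # exact duplicates collapse to one frontier point
  for (i in seq_len(nrow(df))[-1]) {
    earlier <- seq_len(i - 1)
    if (df$status[i] == "frontier" &&
        any(df$status[earlier] == "frontier" &
              df$cost[earlier] == df$cost[i] &
              df$effect[earlier] == df$effect[i])) {
      df$status[i] <- "duplicate"
    }
  }
  # extended dominance: walk the cost-sorted candidates, require
  # increasing ICERs along the frontier
  repeat {
    cand <- df[df$status == "frontier", , drop = FALSE]
    cand <- cand[order(cand$cost, cand$effect), , drop = FALSE]
    pts <- rbind(data.frame(label = ".origin", cost = 0, effect = 0),
                 cand[c("label", "cost", "effect")])
    ic <- diff(pts$cost) / diff(pts$effect)
    bad <- which(diff(ic) < 0)  # ICER drops => previous point ext. dominated
    if (!length(bad)) break
    df$status[df$label == pts$label[bad[1] + 1]] <- "extended dominated"
  }
  cand <- df[df$status == "frontier", , drop = FALSE]
  cand <- cand[order(cand$cost), , drop = FALSE]
  df$icer_vs_previous <- NA_real_
  prev <- c(0, 0)
  for (i in seq_len(nrow(cand))) {
    lab <- cand$label[i]
    de <- cand$effect[i] - prev[2]
    df$icer_vs_previous[df$label == lab] <-
      if (de == 0) NA_real_ else (cand$cost[i] - prev[1]) / de
    prev <- c(cand$cost[i], cand$effect[i])
  }
  rownames(df) <- NULL
  df
}

#' Probabilistic cost-effectiveness analysis
#'
#' Full Bayesian decision analysis of one or more options against current
#' practice: per-option ICER and EIB, pairwise acceptability curve against
#' current practice, probability each option (including current practice)
#' has the strictly highest net benefit, EVPI, and the incremental frontier.
#'
#' @param inputs A [cea_input()] or list of them.
#' @param k Threshold grid (default [threshold_grid()]).
#' @param kref Reference threshold reported by `print`/`summary`.
#' @return An object of class `cea` with methods `print`, `summary`,
#'   `plot`. Components: `options`, `frontier`, `by_k` (data.frame with one
#'   row per option per k: `eib`, `ceac`, `prob_best`, `evpi`), `kref`.
#' @export
#' @examples
#' eff <- trial_effects()
#' pd <- emulate_posterior(eff[1, ], 5000, seed = 1)
#' p0 <- calibrate_p0(pd[, "baby_log_or"], 772, 108000)
#' od <- convert_draws(pd, baseline_rates(p0, 0.007))
#' res <- cea(cea_input("CI", 5348791, od$dalys_averted))
#' summary(res)
cea <- function(inputs, k = threshold_grid(), kref = 780) {
  if (inherits(inputs, "cea_input")) inputs <- list(inputs)
  stopifnot(all(vapply(inputs, inherits, logical(1), "cea_input")),
            all(diff(k) > 0), all(k >= 0))
  if (!kref %in% k) k <- sort(c(k, kref))
  n <- max(vapply(inputs, function(z) length(z$effect), integer(1)))
  all_opts <- c(inputs, list(do_nothing(n)))
  labels <- vapply(all_opts, `[[`, character(1), "label")

  icers <- lapply(inputs, function(z)
    suppressWarnings(icer(z, do_nothing())))
  ev <- evpi(inputs, k)
  rows <- list()
  for (kk_i in seq_along(k)) {
    kk <- k[kk_i]
    nb <- lapply(all_opts, nb_draws, k = kk, n = n)
    rowmax <- do.call(pmax, nb)
    n_at_max <- Reduce(`+`, lapply(nb, function(col) col == rowmax))
    for (oi in seq_along(inputs)) {
      rows[[length(rows) + 1]] <- data.frame(
        option = labels[oi], k = kk,
        eib = kk * mean_effect(inputs[[oi]]) - mean_cost(inputs[[oi]]),
        ceac = mean(nb[[oi]] > nb[[length(all_opts)]]),
        # strictly best: at the row maximum and no other option ties it
        prob_best = mean(nb[[oi]] == rowmax & n_at_max == 1),
        evpi = ev[kk_i])
    }
  }
  structure(list(options = inputs,
                 icers = icers,
                 frontier = ce_frontier(inputs),
                 by_k = do.call(rbind, rows),
                 k = k, kref = kref, n_draws = n),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis: %d option(s) vs current practice, %d draws\n",
              length(x$options), x$n_draws))
  print(summary(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cea <- function(object, kref = object$kref, ...) {
  at <- object$by_k[object$by_k$k == kref, ]
  data.frame(
    option = at$option,
    cost = vapply(object$options, mean_cost, numeric(1)),
    mean_dalys_averted = vapply(object$options, mean_effect, numeric(1)),
    icer = vapply(object$icers, `[[`, numeric(1), "icer"),
    status = vapply(object$icers, `[[`, character(1), "status"),
    eib = at$eib, ceac = at$ceac, prob_best = at$prob_best,
    evpi = at$evpi, k = kref,
    stringsAsFactors = FALSE)
}

#' Plot a cost-effectiveness analysis
#'
#' Four panels: the cost-effectiveness plane (effect draws against fixed
#' costs), EIB, acceptability curves against current practice, and EVPI,
#' all over the threshold grid.
#'
#' @param x A [cea()] object.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.cea <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- seq_along(x$options) + 1
  # (a) CE plane
  xr <- range(unlist(lapply(x$options, `[[`, "effect")))
  yr <- range(0, vapply(x$options, mean_cost, numeric(1)))
  plot(NA, xlim = xr, ylim = yr, xlab = "DALYs averted",
       ylab = "Incremental cost ($)", main = "CE plane", ...)
  for (i in seq_along(x$options)) {
    o <- x$options[[i]]
    graphics::points(o$effect, rep_len(o$cost, length(o$effect)),
                     col = grDevices::adjustcolor(cols[i], 0.15), pch = 16,
                     cex = 0.4)
  }
  graphics::abline(a = 0, b = 1 / x$kref, lty = 3)
  for (panel in c("eib", "ceac", "evpi")) {
    ylab <- c(eib = "EIB ($)", ceac = "P(cost-effective)",
              evpi = "EVPI ($)")[panel]
    plot(NA, xlim = range(x$k), ylim = range(x$by_k[[panel]], 0),
         xlab = "Willingness to pay ($/DALY)", ylab = ylab,
         main = toupper(panel), ...)
    for (i in seq_along(x$options)) {
      sel <- x$by_k$option == x$options[[i]]$label
      graphics::lines(x$by_k$k[sel], x$by_k[[panel]][sel], col = cols[i])
    }
    graphics::abline(v = x$kref, lty = 3)
    if (panel == "ceac") {
      graphics::legend("bottomright",
                       legend = vapply(x$options, `[[`, character(1),
                                       "label"),
                       col = cols, lty = 1, bty = "n", cex = 0.8)
    }
  }
  invisible(x)
}
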
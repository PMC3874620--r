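#' Constant fortification level
#'
#' The year-round fortification level (micrograms of vitamin D per 100 g of
#' carrier) that closes the gap between a recommended daily intake and the
#' actual daily intake from natural food and supplements:
#' \deqn{f_c = \max\left(0, \frac{(I_r - I_a) \cdot 100}{F_i}\right)}
#' Negative raw levels (actual intake already above the recommendation) are
#' floored to zero. Full precision is kept internally; rounding is a
#' reporting concern only.
#'
#' @param I_r recommended daily intake, micrograms/day.
#' @param I_a actual daily intake (natural food + supplements),
#'   micrograms/day.
#' @param F_i daily consumption of the carrier, grams/day (> 0).
#' @return fortification level, micrograms per 100 g.
#' @examples
#' constant_fortification(15, 3.4, 180)  # 6.44
#' @export
constant_fortification <- function(I_r, I_a, F_i) {
  check_positive_consumption(F_i)
  max(0, (I_r - I_a) * 100 / F_i)
}

#' Seasonally varying fortification levels
#'
#' Month-specific fortification levels that lift each month's baseline serum
#' 25(OH)D concentration to a flat target, via the linear intake-to-serum
#' conversion factor:
#' \deqn{f_v(m) = \max\left(0, \frac{(L_r - L_a(m)) \cdot 100}{c_f \cdot F_i}\right)}
#' Months whose baseline already exceeds the target are floored to level 0.
#'
#' @param L_r target serum concentration, nmol/L.
#' @param trajectory baseline [serum_trajectory()].
#' @param c_f [conversion_factor()] or positive scalar, nmol/L per
#'   microgram/day.
#' @param F_i daily carrier consumption, grams/day (> 0).
#' @return named numeric vector of 12 monthly levels, micrograms per 100 g.
#' @examples
#' traj <- generate_trajectory(seasonal_model())
#' round(varying_fortification(75, traj, 2.32, 180)["Jan"], 2)  # 11.3
#' @export
varying_fortification <- function(L_r, trajectory, c_f, F_i) {
  stopifnot(inherits(trajectory, "serum_trajectory"))
  c_f <- as.numeric(c_f)
  if (length(c_f) != 1L || is.na(c_f) || c_f <= 0) {
    stop("conversion factor must be a single positive number", call. = FALSE)
  }
  check_positive_consumption(F_i)
  pmax((L_r - trajectory$values) * 100 / (c_f * F_i), 0)
}

check_positive_consumption <- function(F_i) {
  if (!is.numeric(F_i) || length(F_i) != 1L || is.na(F_i) || F_i <= 0) {
    stop("carrier consumption F_i must be positive; this scenario has no ",
         "carrier consumption - use a nonzero-consumption scenario",
         call. = FALSE)
  }
  invisible(F_i)
}

#' Fortification plan
#'
#' Per-carrier fortification levels, either a single year-round level
#' (`mode = "constant"`, repeated across the 12 months) or month-specific
#' levels (`mode = "seasonal"`), together with the summer/winter clustering
#' produced by [cluster_plan()].
#'
#' @param carrier carrier label.
#' @param mode `"constant"` or `"seasonal"`.
#' @param monthly_levels 12 non-negative levels, micrograms per 100 g (a
#'   single value is recycled in constant mode).
#' @param clusters optional list with elements `summer` (month indices at
#'   level 0), `winter` (remaining month indices) and `winter_level`.
#' @param feasible whether the underlying scenario had positive carrier
#'   consumption.
#' @return an object of class `fortification_plan`.
#' @export
fortification_plan <- function(carrier, mode = c("constant", "seasonal"),
                               monthly_levels, clusters = NULL,
                               feasible = TRUE) {
  mode <- match.arg(mode)
  if (mode == "constant" && length(monthly_levels) == 1L) {
    monthly_levels <- rep(monthly_levels, 12L)
  }
  monthly_levels <- as.numeric(monthly_levels)
  if (length(monthly_levels) != 12L) {
    stop("monthly_levels must have 12 values", call. = FALSE)
  }
  if (feasible) {
    if (any(is.na(monthly_levels)) || any(monthly_levels < 0)) {
      stop("fortification levels must be non-negative", call. = FALSE)
    }
    if (mode == "constant" && diff(range(monthly_levels)) > 0) {
      stop("constant mode requires all 12 monthly levels equal", call. = FALSE)
    }
    if (!is.null(clusters) && length(clusters$summer) > 0 &&
        any(monthly_levels[clusters$summer] != 0)) {
      stop("summer-cluster months must have level 0", call. = FALSE)
    }
  }
  names(monthly_levels) <- month.abb
  structure(list(carrier = carrier, mode = mode,
                 monthly_levels = monthly_levels, clusters = clusters,
                 feasible = feasible),
            class = "fortification_plan")
}

#' Cluster monthly levels into summer and winter
#'
#' A monthly change of fortification intensity is impractical, so monthly
#' requirements are clustered into two blocks: the summer cluster is the
#' longest run of consecutive months (circularly, so December-January are
#' adjacent) whose requirement is zero, and all remaining months form the
#' winter cluster, which is assigned a single level. The default aggregation
#' is the maximum winter-month requirement - the only choice that never
#' undershoots the serum target in any winter month; the mean is available
#' behind a flag for cost-oriented planning.
#'
#' @param monthly_levels 12 non-negative monthly requirements, micrograms per
#'   100 g (e.g. from [varying_fortification()]).
#' @param carrier carrier label stored in the plan.
#' @param aggregate `"max"` (default, guarantees the target every winter
#'   month) or `"mean"`.
#' @return a seasonal [fortification_plan()] whose winter months all carry
#'   the aggregated level and whose summer months are 0.
#' @export
cluster_plan <- function(monthly_levels, carrier = "carrier",
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  monthly_levels <- as.numeric(monthly_levels)
  stopifnot(length(monthly_levels) == 12L, all(monthly_levels >= 0))

  zero <- monthly_levels == 0
  if (all(zero)) {
    summer <- 1:12
    winter <- integer(0)
    winter_level <- 0
  } else if (!any(zero)) {
    summer <- integer(0)
    winter <- 1:12
    winter_level <- if (aggregate == "max") max(monthly_levels)
                    else mean(monthly_levels)
  } else {
    summer <- longest_circular_run(zero)
    winter <- setdiff(1:12, summer)
    winter_level <- if (aggregate == "max") max(monthly_levels[winter])
                    else mean(monthly_levels[winter])
  }

  lv <- rep(0, 12L)
  lv[winter] <- winter_level
  fortification_plan(carrier, "seasonal", lv,
                     clusters = list(summer = summer, winter = winter,
                                     winter_level = winter_level))
}

# longest run of TRUE in a circular 12-vector; first such run on ties
longest_circular_run <- function(flag) {
  n <- length(flag)
  doubled <- rep(flag, 2L)
  r <- rle(doubled)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & starts <= n & r$lengths <= n
  if (!any(keep)) return(integer(0))
  i <- which(keep)[which.max(r$lengths[keep])]
  ((starts[i]:ends[i]) - 1L) %% n + 1L
}

#' Full three-axis scenario grid
#'
#' Enumerates every scenario cell of the fortification model: carrier x
#' carrier-consumption percentile (y-axis) x vitamin D intake percentile
#' (x-axis) x target (z-axis). Constant mode covers the intake targets
#' (IOM, DGE, UL); seasonal mode covers the serum targets (50 and 75 nmol/L;
#' the monthly levels depend on the baseline trajectory, not on the intake
#' percentile, which still determines the reported total intake). Cells
#' whose effective carrier consumption is zero (e.g. the juice 5th
#' percentile) are flagged infeasible rather than failing the grid.
#'
#' @param params a [load_parameters()] `parameter_set`.
#' @param trajectory baseline [serum_trajectory()]; default generated from
#'   `params$serum_model`.
#' @return an object of class `scenario_grid`: a list with `table` (a
#'   data.frame with columns carrier, mode, target_label, vitd_percentile,
#'   carrier_percentile, month, level_ug_per_100g, feasible) and `plans`
#'   (named list of [fortification_plan()] per cell).
#' @export
scenario_grid <- function(params, trajectory = NULL) {
  stopifnot(inherits(params, "parameter_set"))
  if (is.null(trajectory)) {
    trajectory <- generate_trajectory(do.call(seasonal_model,
                                              params$serum_model))
  }
  stopifnot(inherits(trajectory, "serum_trajectory"))

  kinds <- vapply(params$targets, function(t) t$kind, character(1))
  rows <- list()
  plans <- list()

  for (carrier in names(params$carriers)) {
    profile <- params$carriers[[carrier]]
    for (cp in PERCENTILES) {
      F_i <- effective_carrier_intake(profile, cp)
      for (vp in PERCENTILES) {
        I_a <- effective_vitd_intake(params$intake, vp)
        for (tg in params$targets) {
          key <- paste(carrier, cp, vp, tg$label, sep = ".")
          mode <- if (tg$kind == "intake") "constant" else "seasonal"
          if (F_i <= 0) {
            plan <- fortification_plan(carrier, mode, rep(NA_real_, 12L),
                                       feasible = FALSE)
            rows[[key]] <- grid_row(carrier, mode, tg$label, vp, cp, "all",
                                    NA_real_, FALSE)
          } else if (mode == "constant") {
            lvl <- constant_fortification(tg$value, I_a, F_i)
            plan <- fortification_plan(carrier, "constant", lvl)
            rows[[key]] <- grid_row(carrier, mode, tg$label, vp, cp, "all",
                                    lvl, TRUE)
          } else {
            req <- varying_fortification(tg$value, trajectory,
                                         params$conversion_factor, F_i)
            plan <- cluster_plan(req, carrier = carrier)
            rows[[key]] <- grid_row(carrier, mode, tg$label, vp, cp,
                                    month.abb, unname(plan$monthly_levels),
                                    TRUE)
          }
          plans[[key]] <- plan
        }
      }
    }
  }

  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, plans = plans, trajectory = trajectory),
            class = "scenario_grid")
}

grid_row <- function(carrier, mode, target_label, vp, cp, month, level,
                     feasible) {
  data.frame(carrier = carrier, mode = mode, target_label = target_label,
             vitd_percentile = vp, carrier_percentile = cp, month = month,
             level_ug_per_100g = level, feasible = feasible,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.scenario_grid <- function(x, ...) x$table

#' @export
print.scenario_grid <- function(x, ...) {
  tab <- x$table
  cat("<scenario_grid>", length(x$plans), "cells (",
      sum(tab$mode == "constant"), "constant rows,",
      sum(tab$mode == "seasonal"), "seasonal month-rows;",
      sum(!tab$feasible), "infeasible )\n")
  invisible(x)
}

#' @export
print.fortification_plan <- function(x, ...) {
  cat("<fortification_plan>", x$carrier, "-", x$mode,
      if (!x$feasible) "(infeasible)" else "", "\n")
  if (x$feasible) {
    if (x$mode == "constant") {
      cat("  level:", round(x$monthly_levels[1L], 2), "ug per 100 g\n")
    } else {
      print(round(x$monthly_levels, 2))
      if (!is.null(x$clusters)) {
        cat("  summer (level 0):",
            if (length(x$clusters$summer)) {
              paste(month.abb[x$clusters$summer], collapse = " ")
            } else "none", "\n")
        cat("  winter level:", round(x$clusters$winter_level, 2),
            "ug per 100 g\n")
      }
    }
  }
  invisible(x)
}
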
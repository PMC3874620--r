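#' Forward-model the serum response to a fortification plan
#'
#' Predicts the new monthly 25(OH)D concentration under a plan from the
#' baseline trajectory and the linear conversion factor:
#' \deqn{L_{n}(m) = L_{a}(m) + c_f \cdot F_i \cdot f(m) / 100}
#' and the corresponding total daily vitamin D intake per month
#' (fortified-carrier contribution plus natural food and supplements).
#'
#' @param trajectory baseline [serum_trajectory()].
#' @param plan a feasible [fortification_plan()] covering the same 12 months.
#' @param F_i daily carrier consumption of the modelled individual,
#'   grams/day (>= 0; 0 reproduces the baseline exactly).
#' @param c_f [conversion_factor()] or positive scalar.
#' @param I_a daily vitamin D intake from natural food and supplements,
#'   micrograms/day.
#' @param ul_intake daily intake limit used for flagging, micrograms/day.
#' @param intox_threshold serum intoxication threshold used for flagging,
#'   nmol/L.
#' @return an object of class `response_result` with elements
#'   `new_trajectory` (a [serum_trajectory()]), `total_intake_by_month`
#'   (micrograms/day) and `flags` (from [ul_flags()]).
#' @examples
#' traj <- generate_trajectory(seasonal_model())
#' plan <- cluster_plan(varying_fortification(75, traj, 2.32, 180), "bread")
#' resp <- apply_fortification(traj, plan, 180, 2.32, I_a = 3.4)
#' round(resp$new_trajectory$values["Jan"], 1)  # 75
#' @export
apply_fortification <- function(trajectory, plan, F_i, c_f, I_a = 0,
                                ul_intake = 100, intox_threshold = 500) {
  stopifnot(inherits(trajectory, "serum_trajectory"),
            inherits(plan, "fortification_plan"))
  if (!plan$feasible) {
    stop("plan for carrier '", plan$carrier, "' is infeasible (zero carrier ",
         "consumption scenario)", call. = FALSE)
  }
  if (length(plan$monthly_levels) != length(trajectory$values)) {
    stop("plan and trajectory must cover the same 12 months", call. = FALSE)
  }
  c_f <- as.numeric(c_f)
  stopifnot(length(F_i) == 1L, F_i >= 0, c_f > 0, I_a >= 0)

  new_vals <- trajectory$values + c_f * F_i * plan$monthly_levels / 100
  total <- total_daily_intake(plan$monthly_levels, F_i, I_a)
  res <- structure(list(
    new_trajectory = serum_trajectory(new_vals, region = trajectory$region),
    baseline = trajectory,
    total_intake_by_month = total,
    plan = plan, F_i = F_i, I_a = I_a),
    class = "response_result")
  res$flags <- ul_flags(res, ul_intake = ul_intake,
                        intox_threshold = intox_threshold)
  res
}

#' Total daily vitamin D intake under fortification
#'
#' Fortified-carrier contribution (`level * F_i / 100`) plus intake from
#' natural food sources and supplements.
#'
#' @param level fortification level(s), micrograms per 100 g.
#' @param F_i daily carrier consumption, grams/day.
#' @param I_a daily intake from natural food and supplements, micrograms/day.
#' @return total daily intake, micrograms/day (vectorized over `level`).
#' @examples
#' total_daily_intake(11.3, 180, 3.4)  # 23.74
#' @export
total_daily_intake <- function(level, F_i, I_a) {
  stopifnot(all(level >= 0), F_i >= 0, I_a >= 0)
  level * F_i / 100 + I_a
}

#' Risk envelope for extreme consumers
#'
#' Applies a plan sized for the mean consumer to the two extreme consumer
#' profiles: the upper envelope combines 95th-percentile carrier consumption
#' with 95th-percentile vitamin D intake, the lower envelope combines the
#' 5th percentiles. Both responses carry upper-intake-level and intoxication
#' flags. A zero 5th-percentile consumption (juice) yields a lower envelope
#' identical to the baseline.
#'
#' @param params a `parameter_set`; must contain the plan's carrier.
#' @param trajectory baseline [serum_trajectory()].
#' @param plan a [fortification_plan()] computed at the mean-carrier
#'   scenario.
#' @return list with elements `upper` and `lower`, both `response_result`s.
#' @export
risk_envelope <- function(params, trajectory, plan) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(plan, "fortification_plan"))
  profile <- params$carriers[[plan$carrier]]
  if (is.null(profile)) {
    stop("unknown carrier '", plan$carrier, "' in parameter set",
         call. = FALSE)
  }
  envelope <- function(pct) {
    apply_fortification(
      trajectory, plan,
      F_i = effective_carrier_intake(profile, pct),
      c_f = params$conversion_factor,
      I_a = effective_vitd_intake(params$intake, pct),
      ul_intake = params$thresholds$ul_intake,
      intox_threshold = params$thresholds$intoxication_serum)
  }
  list(upper = envelope("p95"), lower = envelope("p5"))
}

#' Intake multipliers across consumption percentiles
#'
#' How much more fortified-carrier vitamin D a high consumer takes in than a
#' low one. Because the fortified-carrier intake is `level * F_i / 100`, the
#' fortification level cancels in the ratio and the multipliers reduce to
#' consumption ratios. Ratios are given per gender and for the scenario-
#' selected consumption (p95/mean use the higher-consuming gender, p5 the
#' lower). A zero denominator (e.g. the juice 5th percentile) yields `NA`
#' with `undefined = TRUE` rather than an error.
#'
#' @param profile a [carrier_profile()].
#' @return data.frame with columns `gender` (`men`, `women`, `selected`),
#'   `mean_over_p5`, `p95_over_p5`, `p95_over_mean`, and `undefined`
#'   (TRUE when a zero denominator made at least one ratio undefined).
#' @examples
#' params <- load_parameters()
#' intake_multipliers(params$carriers$bread)
#' @export
intake_multipliers <- function(profile) {
  stopifnot(inherits(profile, "carrier_profile"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  one <- function(p5, mn, p95) {
    c(mean_over_p5 = ratio(mn, p5), p95_over_p5 = ratio(p95, p5),
      p95_over_mean = ratio(p95, mn))
  }
  m <- profile$consumption
  rows <- rbind(
    men = one(m["p5", "men"], m["mean", "men"], m["p95", "men"]),
    women = one(m["p5", "women"], m["mean", "women"], m["p95", "women"]),
    selected = one(min(m["p5", ]), max(m["mean", ]), max(m["p95", ]))
  )
  out <- data.frame(gender = rownames(rows), rows, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$undefined <- apply(rows, 1L, function(r) any(is.na(r)))
  out
}

#' Safety flags for a serum response
#'
#' Month-wise boolean flags: total daily intake strictly above the tolerable
#' upper intake level (default 100 micrograms/day) and serum concentration
#' strictly above the intoxication threshold (default 500 nmol/L). Boundary
#' equality does not flag: the limits are stated as limits, not exceedances.
#'
#' @param result a `response_result`.
#' @param ul_intake intake limit, micrograms/day.
#' @param intox_threshold serum threshold, nmol/L.
#' @return list with logical 12-vectors `ul_intake_exceeded` and
#'   `intoxication`.
#' @export
ul_flags <- function(result, ul_intake = 100, intox_threshold = 500) {
  stopifnot(inherits(result, "response_result"),
            ul_intake > 0, intox_threshold > 0)
  list(ul_intake_exceeded = result$total_intake_by_month > ul_intake,
       intoxication = result$new_trajectory$values > intox_threshold)
}

#' @export
print.response_result <- function(x, ...) {
  cat("<response_result>", x$plan$carrier, "- F_i", x$F_i, "g/day, I_a",
      x$I_a, "ug/day\n")
  df <- data.frame(baseline = round(x$baseline$values, 1),
                   new = round(x$new_trajectory$values, 1),
                   intake_ug = round(x$total_intake_by_month, 1),
                   ul = x$flags$ul_intake_exceeded,
                   intox = x$flags$intoxication)
  print(df)
  invisible(x)
}
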
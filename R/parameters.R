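PERCENTILES <- c("p5", "mean", "p95")
GENDERS <- c("men", "women")

#' Carrier consumption profile
#'
#' Daily consumption (grams) of a fortifiable carrier foodstuff at the 5th
#' percentile, mean and 95th percentile of the population, split by gender.
#'
#' @param name carrier label, e.g. `"bread"`, `"milk"`, `"juice"` or a custom
#'   name.
#' @param consumption numeric matrix with rows `p5`, `mean`, `p95` and columns
#'   `men`, `women`, in grams/day.
#' @return an object of class `carrier_profile`.
#' @examples
#' cp <- carrier_profile("bread", matrix(c(46, 180, 377, 43, 134, 270), 3, 2,
#'   dimnames = list(c("p5", "mean", "p95"), c("men", "women"))))
#' effective_carrier_intake(cp, "mean")
#' @export
carrier_profile <- function(name, consumption) {
  consumption <- as.matrix(consumption)
  if (!all(PERCENTILES %in% rownames(consumption)) ||
      !all(GENDERS %in% colnames(consumption))) {
    stop("carrier '", name, "': consumption must have rows p5/mean/p95 and ",
         "columns men/women", call. = FALSE)
  }
  consumption <- consumption[PERCENTILES, GENDERS, drop = FALSE]
  storage.mode(consumption) <- "double"
  validate_percentile_table(consumption, paste0("carrier '", name, "'"))
  structure(list(name = name, consumption = consumption),
            class = "carrier_profile")
}

#' Dietary vitamin D intake profile
#'
#' Daily vitamin D intake from natural food sources by percentile and gender,
#' plus a population-mean supplement intake. Supplement intake is applied
#' identically in all percentile scenarios (no supplement percentiles are
#' modelled).
#'
#' @param dietary numeric matrix (rows `p5`, `mean`, `p95`; columns `men`,
#'   `women`), micrograms/day.
#' @param supplement_mean mean daily supplement intake, micrograms/day.
#' @return an object of class `intake_profile`.
#' @export
intake_profile <- function(dietary, supplement_mean = 0) {
  dietary <- as.matrix(dietary)
  if (!all(PERCENTILES %in% rownames(dietary)) ||
      !all(GENDERS %in% colnames(dietary))) {
    stop("intake$dietary must have rows p5/mean/p95 and columns men/women",
         call. = FALSE)
  }
  dietary <- dietary[PERCENTILES, GENDERS, drop = FALSE]
  storage.mode(dietary) <- "double"
  validate_percentile_table(dietary, "intake$dietary")
  if (!is.numeric(supplement_mean) || length(supplement_mean) != 1L ||
      is.na(supplement_mean) || supplement_mean < 0) {
    stop("intake$supplement_mean must be a single non-negative number",
         call. = FALSE)
  }
  structure(list(dietary = dietary, supplement_mean = supplement_mean),
            class = "intake_profile")
}

validate_percentile_table <- function(m, what) {
  if (any(is.na(m))) stop(what, ": missing value", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(what, ": negative value at ", rownames(m)[bad[1L]], "/",
         colnames(m)[bad[2L]], call. = FALSE)
  }
  for (g in colnames(m)) {
    if (!(m["p5", g] <= m["mean", g] && m["mean", g] <= m["p95", g])) {
      stop(what, ": percentile ordering violated for ", g,
           " (need p5 <= mean <= p95)", call. = FALSE)
    }
  }
  invisible(m)
}

#' Intake or serum target
#'
#' A fortification goal on the scenario grid's z-axis: either a daily intake
#' recommendation (micrograms/day; e.g. IOM 15, DGE 20, tolerable upper level
#' 100) or a target 25(OH)D serum concentration (nmol/L; 50 or 75).
#'
#' @param kind `"intake"` or `"serum"`.
#' @param value target value (> 0), micrograms/day or nmol/L.
#' @param label short label (`"IOM"`, `"DGE"`, `"UL"`, `"serum50"`,
#'   `"serum75"`, or custom).
#' @param ul the tolerable upper intake level used to sanity-check intake
#'   targets, micrograms/day.
#' @return an object of class `target_spec`.
#' @export
target_spec <- function(kind = c("intake", "serum"), value, label = "custom",
                        ul = 100) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop("target value must be a single positive number", call. = FALSE)
  }
  if (kind == "intake" && label != "UL" && value > ul) {
    stop("intake target '", label, "' (", value,
         ") exceeds the upper intake level (", ul, ")", call. = FALSE)
  }
  structure(list(kind = kind, value = value, label = label),
            class = "target_spec")
}

#' Intake-to-serum conversion factor
#'
#' Expected rise in serum 25(OH)D (nmol/L) per 1 microgram of daily vitamin D
#' from fortified food. The model treats it as linear and season-independent.
#'
#' @param cf positive scalar, nmol/L per microgram/day. Default 2.32.
#' @return an object of class `conversion_factor` (a validated scalar).
#' @export
conversion_factor <- function(cf = 2.32) {
  if (!is.numeric(cf) || length(cf) != 1L || is.na(cf) || cf <= 0) {
    stop("conversion_factor must be a single positive number", call. = FALSE)
  }
  structure(cf, class = "conversion_factor")
}

#' Load and validate model parameters
#'
#' Reads a YAML (or JSON) configuration mirroring the packaged default file
#' `table1_defaults.yaml`, validates every field and returns a `parameter_set`
#' holding carrier profiles, the intake profile, intake/serum targets, the
#' conversion factor, the baseline serum model settings and the risk
#' thresholds. With no argument the packaged defaults are returned.
#'
#' @param config path to a YAML/JSON file, or an already-parsed nested list
#'   with the same structure. `NULL` loads the packaged defaults.
#' @return an object of class `parameter_set`.
#' @examples
#' params <- load_parameters()
#' effective_carrier_intake(params$carriers$bread, "p95")
#' @export
load_parameters <- function(config = NULL) {
  if (is.null(config)) config <- default_config_path()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a file path or a list",
                             call. = FALSE)
  for (key in c("carriers", "intake", "targets", "conversion_factor")) {
    if (is.null(config[[key]])) {
      stop("config is missing required key '", key, "'", call. = FALSE)
    }
  }

  carriers <- lapply(names(config$carriers), function(nm) {
    carrier_profile(nm, percentile_matrix(config$carriers[[nm]],
                                          paste0("carriers$", nm)))
  })
  names(carriers) <- names(config$carriers)

  sup <- config$intake$supplement_mean
  if (is.null(sup)) sup <- 0
  intake <- intake_profile(percentile_matrix(config$intake$dietary,
                                             "intake$dietary"), sup)

  cf <- conversion_factor(as.numeric(config$conversion_factor))

  ul <- config$targets$intake$UL
  if (is.null(ul)) ul <- 100
  targets <- c(
    lapply(names(config$targets$intake), function(nm) {
      target_spec("intake", as.numeric(config$targets$intake[[nm]]), nm, ul)
    }),
    lapply(names(config$targets$serum), function(nm) {
      target_spec("serum", as.numeric(config$targets$serum[[nm]]), nm)
    })
  )
  names(targets) <- c(names(config$targets$intake), names(config$targets$serum))

  sm <- config$serum_model
  serum_model_args <- list(
    annual_mean = if (is.null(sm$annual_mean)) 45 else as.numeric(sm$annual_mean),
    amplitude = if (is.null(sm$amplitude)) 17.2 else as.numeric(sm$amplitude),
    trough_month = if (is.null(sm$trough_month)) 1L else as.integer(sm$trough_month),
    region_offset = if (is.null(sm$region_offset)) 0 else as.numeric(sm$region_offset),
    region = if (is.null(sm$region)) "germany" else as.character(sm$region)
  )

  th <- config$thresholds
  thresholds <- list(
    ul_intake = if (is.null(th$ul_intake)) 100 else as.numeric(th$ul_intake),
    intoxication_serum = if (is.null(th$intoxication_serum)) 500
                         else as.numeric(th$intoxication_serum)
  )

  structure(list(carriers = carriers, intake = intake, targets = targets,
                 conversion_factor = cf, serum_model = serum_model_args,
                 thresholds = thresholds),
            class = "parameter_set")
}

percentile_matrix <- function(x, what) {
  if (is.null(x)) stop("config is missing required key '", what, "'",
                       call. = FALSE)
  m <- matrix(NA_real_, 3L, 2L, dimnames = list(PERCENTILES, GENDERS))
  for (p in PERCENTILES) {
    for (g in GENDERS) {
      v <- x[[p]][[g]]
      if (is.null(v)) stop("config is missing required key '", what, "$", p,
                           "$", g, "'", call. = FALSE)
      m[p, g] <- as.numeric(v)
    }
  }
  m
}

default_config_path <- function() {
  system.file("extdata", "table1_defaults.yaml", package = "fortiplan",
              mustWork = TRUE)
}

#' Write a parameter set back to YAML
#'
#' Inverse of [load_parameters()]: serializes a `parameter_set` to a YAML
#' document with the same structure as the packaged defaults, so that a
#' round trip reproduces every value exactly.
#'
#' @param params a `parameter_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  cfg <- as_config_list(params)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

as_config_list <- function(params) {
  mat_to_list <- function(m) {
    out <- lapply(PERCENTILES, function(p) {
      setNames(as.list(unname(m[p, GENDERS])), GENDERS)
    })
    setNames(out, PERCENTILES)
  }
  tk <- vapply(params$targets, function(t) t$kind, character(1))
  list(
    carriers = lapply(params$carriers, function(cp) mat_to_list(cp$consumption)),
    intake = list(dietary = mat_to_list(params$intake$dietary),
                  supplement_mean = params$intake$supplement_mean),
    targets = list(
      intake = lapply(params$targets[tk == "intake"], function(t) t$value),
      serum = lapply(params$targets[tk == "serum"], function(t) t$value)
    ),
    conversion_factor = as.numeric(params$conversion_factor),
    serum_model = params$serum_model,
    thresholds = params$thresholds
  )
}

#' Effective carrier consumption for a scenario
#'
#' Applies the gender-selection convention: the high (`p95`) and mean
#' scenarios use the higher-consuming gender so that fortification levels err
#' on the conservative (low) side, while the low (`p5`) scenario uses the
#' lower-consuming gender so that 95% of the population at least reaches the
#' target. For bread and juice the p5 minimum is women; for milk it is men,
#' who consume less milk at the 5th percentile.
#'
#' @param profile a [carrier_profile()].
#' @param scenario `"p5"`, `"mean"` or `"p95"`.
#' @return consumption in grams/day (the quantity `F_i`).
#' @export
effective_carrier_intake <- function(profile, scenario) {
  stopifnot(inherits(profile, "carrier_profile"))
  scenario <- check_percentile(scenario)
  row <- profile$consumption[scenario, ]
  if (scenario == "p5") min(row) else max(row)
}

#' Effective vitamin D intake for a scenario
#'
#' Gender-averaged (unweighted mean of men and women) dietary vitamin D intake
#' at the scenario percentile, plus the mean supplement intake. This is the
#' quantity `I_a` entering the constant-fortification formula.
#'
#' @param profile an [intake_profile()].
#' @param scenario `"p5"`, `"mean"` or `"p95"`.
#' @return intake in micrograms/day.
#' @export
effective_vitd_intake <- function(profile, scenario) {
  stopifnot(inherits(profile, "intake_profile"))
  scenario <- check_percentile(scenario)
  mean(profile$dietary[scenario, ]) + profile$supplement_mean
}

check_percentile <- function(scenario) {
  if (length(scenario) != 1L || !scenario %in% PERCENTILES) {
    stop("unknown scenario '", paste(scenario, collapse = ","),
         "'; must be one of p5, mean, p95", call. = FALSE)
  }
  scenario
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  carriers:", paste(names(x$carriers), collapse = ", "), "\n")
  cat("  dietary means (men/women):",
      paste(x$intake$dietary["mean", ], collapse = "/"), "ug/day;",
      "supplements", x$intake$supplement_mean, "ug/day\n")
  cat("  targets:", paste(vapply(x$targets, function(t)
    sprintf("%s=%g", t$label, t$value), character(1)), collapse = ", "), "\n")
  cat("  conversion factor:", as.numeric(x$conversion_factor),
      "nmol/L per ug/day\n")
  invisible(x)
}

#' @export
print.carrier_profile <- function(x, ...) {
  cat("<carrier_profile>", x$name, "(g/day)\n")
  print(x$consumption)
  invisible(x)
}
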
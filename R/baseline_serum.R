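#' Seasonal baseline 25(OH)D model
#'
#' A single-harmonic cosine description of the monthly baseline serum
#' 25(OH)D trajectory of an average individual:
#' \deqn{L_a(m) = \mu + o - A \cos\left(2\pi (m - m_0)/12\right)}
#' with annual mean \eqn{\mu}, additive regional offset \eqn{o}, amplitude
#' \eqn{A} and trough month \eqn{m_0}. The default calibration (mean 45
#' nmol/L, amplitude 17.2 nmol/L, trough in January, so January is about
#' 27.8 nmol/L) is chosen so that the packaged defaults reproduce the
#' January bread worked example end-to-end; the January figure is derived
#' from that example, not an observed value. Any observed 12-month vector
#' can be supplied directly via [serum_trajectory()] instead.
#'
#' @param annual_mean annual mean serum 25(OH)D, nmol/L.
#' @param amplitude seasonal half-range, nmol/L (>= 0).
#' @param trough_month calendar month (1 = January) at which the minimum is
#'   attained.
#' @param region_offset additive regional offset, nmol/L.
#' @param region region label carried through to trajectories.
#' @param noise_sd standard deviation of optional Gaussian month-to-month
#'   noise, nmol/L; 0 (the default) gives the deterministic trajectory.
#' @return an object of class `seasonal_model`.
#' @seealso [generate_trajectory()], [calibrate_amplitude()]
#' @export
seasonal_model <- function(annual_mean = 45, amplitude = 17.2,
                           trough_month = 1L, region_offset = 0,
                           region = "germany", noise_sd = 0) {
  stopifnot(is.numeric(annual_mean), length(annual_mean) == 1L,
            is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(region_offset), length(region_offset) == 1L,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  trough_month <- as.integer(trough_month)
  if (is.na(trough_month) || trough_month < 1L || trough_month > 12L) {
    stop("trough_month must be a month index 1-12", call. = FALSE)
  }
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (annual_mean + region_offset - amplitude <= 0) {
    stop("annual_mean + region_offset - amplitude must be positive ",
         "(serum concentrations stay positive)", call. = FALSE)
  }
  structure(list(annual_mean = annual_mean, amplitude = amplitude,
                 trough_month = trough_month, region_offset = region_offset,
                 region = region, noise_sd = noise_sd),
            class = "seasonal_model")
}

#' Monthly baseline serum trajectory
#'
#' Twelve monthly baseline 25(OH)D concentrations (nmol/L), January-first,
#' with a region label. This is the container for the quantity `L_a(m)`;
#' it can hold either a synthetic trajectory from [generate_trajectory()]
#' or observed monthly values.
#'
#' @param values numeric vector of exactly 12 positive concentrations,
#'   nmol/L, ordered January to December.
#' @param region region label.
#' @return an object of class `serum_trajectory`.
#' @export
serum_trajectory <- function(values, region = "unspecified") {
  values <- as.numeric(values)
  if (length(values) != 12L) {
    stop("a serum trajectory needs exactly 12 monthly values, got ",
         length(values), call. = FALSE)
  }
  if (any(is.na(values)) || any(values <= 0)) {
    stop("all monthly serum values must be positive", call. = FALSE)
  }
  names(values) <- month.abb
  structure(list(values = values, region = region),
            class = "serum_trajectory")
}

#' Generate a synthetic baseline trajectory
#'
#' Evaluates a [seasonal_model()] at the 12 calendar months. The arithmetic
#' mean of the generated values equals `annual_mean + region_offset` (the
#' cosine integrates to zero over a full period) and the minimum is attained
#' at the trough month. If `noise_sd > 0`, independent Gaussian noise is
#' added to each month; pass `seed` for reproducibility.
#'
#' @param model a [seasonal_model()].
#' @param seed optional integer seed used only when `noise_sd > 0`.
#' @return a [serum_trajectory()].
#' @examples
#' traj <- generate_trajectory(seasonal_model())
#' round(traj$values[c("Jan", "Jul")], 1)  # 27.8 and 62.2
#' @export
generate_trajectory <- function(model = seasonal_model(), seed = NULL) {
  stopifnot(inherits(model, "seasonal_model"))
  m <- 1:12
  vals <- model$annual_mean + model$region_offset -
    model$amplitude * cos(2 * pi * (m - model$trough_month) / 12)
  if (model$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + stats::rnorm(12L, sd = model$noise_sd)
    vals <- pmax(vals, .Machine$double.eps)
  }
  serum_trajectory(vals, region = model$region)
}

#' Calibrate the seasonal amplitude from one anchor month
#'
#' Solves the cosine model for the amplitude that makes the trajectory pass
#' exactly through a known monthly value:
#' \deqn{A = (\mu - L_{anchor}) / \cos(2\pi (m_{anchor} - m_0)/12)}
#' The anchor must not sit at a zero of the cosine (a quarter-period from
#' the trough), where the amplitude is unidentifiable.
#'
#' @param annual_mean annual mean, nmol/L.
#' @param anchor_month month index 1-12 of the known value.
#' @param anchor_value serum concentration at the anchor month, nmol/L.
#' @param trough_month month index 1-12 of the seasonal minimum.
#' @return the amplitude, nmol/L.
#' @examples
#' calibrate_amplitude(45, 1, 27.8, 1)  # 17.2
#' @export
calibrate_amplitude <- function(annual_mean, anchor_month, anchor_value,
                                trough_month) {
  co <- cos(2 * pi * (anchor_month - trough_month) / 12)
  if (abs(co) < 1e-9) {
    stop("anchor month is a quarter-period from the trough: the cosine is ",
         "zero there and the amplitude is unidentifiable", call. = FALSE)
  }
  (annual_mean - anchor_value) / co
}

#' Read / write trajectories as CSV
#'
#' Trajectories are exchanged as plain CSV with columns `month` (1-12),
#' `region` and `value_nmol_per_L`.
#'
#' @param path CSV file path.
#' @return `read_trajectory_csv()` returns a [serum_trajectory()];
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "region", "value_nmol_per_L")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$month), ]
  if (!identical(as.integer(df$month), 1:12)) {
    stop("trajectory CSV must contain months 1-12 exactly once", call. = FALSE)
  }
  serum_trajectory(df$value_nmol_per_L, region = df$region[1L])
}

#' @rdname read_trajectory_csv
#' @param trajectory a [serum_trajectory()].
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "serum_trajectory"))
  df <- data.frame(month = 1:12, region = trajectory$region,
                   value_nmol_per_L = signif(unname(trajectory$values), 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.serum_trajectory <- function(x, ...) {
  cat("<serum_trajectory> region:", x$region, "(nmol/L)\n")
  print(round(x$values, 2))
  invisible(x)
}

#' @export
print.seasonal_model <- function(x, ...) {
  cat(sprintf(
    "<seasonal_model> mean %g + offset %g nmol/L, amplitude %g, trough %s%s\n",
    x$annual_mean, x$region_offset, x$amplitude, month.abb[x$trough_month],
    if (x$noise_sd > 0) sprintf(", noise sd %g", x$noise_sd) else ""))
  invisible(x)
}
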
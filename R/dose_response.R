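#' Fit a four-parameter logistic (4PL) dose-response curve and estimate IC50
#'
#' Raw plate readings are first normalized to percent survival with the
#' vehicle-control mean set to 100%, then fitted by bounded least squares
#' (Levenberg-Marquardt, multi-start) to
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`
#' on the log-concentration axis, with `bottom` in \[0, 100\], `top` in
#' \[50, 150\] and `hill > 0`. An IC50 outside the tested concentration range
#' is reported but flagged as extrapolated.
#'
#' @param plate Tibble of treated wells with columns `concentration`
#'   (positive, molar) and `reading` (raw signal); replicates are extra rows.
#'   At least 4 distinct concentrations are required.
#' @param vehicle Numeric vector of vehicle-control readings.
#' @param compound,cell_line Optional labels carried into the result.
#' @return A one-row tibble: `compound`, `cell_line`, `bottom`, `top`,
#'   `hill`, `ic50`, `extrapolated`, `converged`, `rss`, `n_points`. The
#'   attribute `"viability"` holds the normalized per-well data.
#' @export
fit_ic50 <- function(plate, vehicle, compound = NA_character_,
                     cell_line = NA_character_) {
  plate <- tibble::as_tibble(plate)
  stopifnot(all(c("concentration", "reading") %in% names(plate)))
  if (length(vehicle) == 0 || any(!is.finite(vehicle))) {
    stop("vehicle readings must be present and finite", call. = FALSE)
  }
  if (any(plate$concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  concs <- sort(unique(plate$concentration))
  if (length(concs) < 4) {
    stop("at least 4 distinct concentrations are required for a 4PL fit",
         call. = FALSE)
  }

  v0 <- mean(vehicle)
  viability <- tibble::tibble(
    concentration = plate$concentration,
    viability = 100 * plate$reading / v0
  )

  lx <- log10(viability$concentration)
  y <- viability$viability
  model <- function(bottom, top, hill, lic50, x) {
    bottom + (top - bottom) / (1 + 10^(hill * (x - lic50)))
  }

  lo <- c(bottom = 0, top = 50, hill = 1e-3,
          lic50 = min(lx) - 3)
  hi <- c(bottom = 100, top = 150, hill = 10,
          lic50 = max(lx) + 3)
  starts <- expand.grid(
    bottom = max(0, min(y)),
    top = min(150, max(50, max(y))),
    hill = c(0.5, 1, 2),
    lic50 = seq(min(lx), max(lx), length.out = 5)
  )

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model(bottom, top, hill, lic50, lx),
        start = as.list(starts[i, ]),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    out <- tibble::tibble(
      compound = compound, cell_line = cell_line,
      bottom = NA_real_, top = NA_real_, hill = NA_real_, ic50 = NA_real_,
      extrapolated = NA, converged = FALSE, rss = NA_real_,
      n_points = nrow(plate)
    )
  } else {
    cf <- stats::coef(best$fit)
    ic50 <- 10^cf[["lic50"]]
    out <- tibble::tibble(
      compound = compound, cell_line = cell_line,
      bottom = cf[["bottom"]], top = cf[["top"]], hill = cf[["hill"]],
      ic50 = ic50,
      extrapolated = ic50 < min(concs) || ic50 > max(concs),
      converged = TRUE, rss = best$rss, n_points = nrow(plate)
    )
  }
  attr(out, "viability") <- viability
  out
}

#' Simulate a viability plate from a 4PL curve
#'
#' Synthetic plate generator for validating [fit_ic50()]: readings are drawn
#' from the 4PL model (in percent-survival units, with a vehicle signal of
#' 100) plus optional Gaussian noise.
#'
#' @param bottom,top,hill,ic50 Generating 4PL parameters (`ic50` in the same
#'   units as `concentrations`).
#' @param concentrations Tested concentrations (positive).
#' @param n_replicates Replicate wells per concentration.
#' @param noise_sd Gaussian noise standard deviation in percent-survival
#'   units (0 = noise-free).
#' @param n_vehicle Number of vehicle wells.
#' @param seed Integer seed.
#' @return List with `plate` (tibble `concentration`, `replicate`, `reading`)
#'   and `vehicle` (numeric readings).
#' @export
simulate_plate <- function(bottom = 0, top = 100, hill = 1, ic50 = 1e-7,
                           concentrations = 10^seq(-9, -5, length.out = 8),
                           n_replicates = 3, noise_sd = 0, n_vehicle = 6,
                           seed = 1L) {
  stopifnot(all(concentrations > 0), ic50 > 0, hill > 0)
  set.seed(derive_seed(seed, 6))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      concentration = concentrations)
  mu <- bottom + (top - bottom) / (1 + (grid$concentration / ic50)^hill)
  reading <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  vehicle <- 100 + stats::rnorm(n_vehicle, 0, noise_sd)
  list(
    plate = tibble::tibble(concentration = grid$concentration,
                           replicate = grid$replicate,
                           reading = reading),
    vehicle = vehicle
  )
}
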
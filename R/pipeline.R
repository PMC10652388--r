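#' Read a triaxial signal from CSV
#'
#' Dialect: comma-separated, UTF-8, `.` decimal, header exactly
#' `time,ax,ay,az`; one file per measurement location. The record is passed
#' through [validate_signal()], so a non-uniform time base is rejected.
#'
#' @param path CSV file path.
#' @param location measurement location label for the returned signal.
#' @return a [triaxial_signal()].
#' @export
read_signal_csv <- function(path, location = "chest") {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expected <- c("time", "ax", "ay", "az")
  if (!identical(trimws(header), expected)) {
    bad <- setdiff(expected, trimws(header))
    stop_wheelride(paste0("bad signal header; expected 'time,ax,ay,az'",
                          if (length(bad)) paste0(" (missing: ", paste(bad, collapse = ", "), ")")),
                   "wheelride_parse_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_signal(raw, location = location)
}

#' Write a triaxial signal to CSV
#'
#' Inverse of [read_signal_csv()]; full double precision is kept so that a
#' write-read round trip reproduces the samples.
#'
#' @param signal a [triaxial_signal()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  df <- as.data.frame(signal)
  lines <- c("time,ax,ay,az",
             sprintf("%.15g,%.15g,%.15g,%.15g", df$time, df$ax, df$ay, df$az))
  writeLines(lines, path)
  invisible(path)
}

#' Comfort and annoyance report over measurement locations
#'
#' Runs the full evaluation chain for each supplied signal: frequency
#' weighting, per-axis weighted RMS, total vibration, comfort class, and
#' the annoyance rate of the resulting av. Optionally appends a stability
#' summary (rollover/pitch/slip limit angles) when plants are given.
#' A location whose record fails to evaluate is recorded with its error
#' message rather than aborting the whole report.
#'
#' @param signals named list of [triaxial_signal()]s (names are free; each
#'   signal carries its own location label).
#' @param spec a [weighting_spec()].
#' @param model an [annoyance_model()].
#' @param roll,pitch optional [roll_plant()] / [pitch_plant()] for the
#'   stability summary.
#' @param seed integer recorded in the provenance block (the evaluation
#'   itself is deterministic).
#' @return object of class `evaluation_report`.
#' @export
run_report <- function(signals, spec = weighting_spec(),
                       model = annoyance_model(), roll = NULL, pitch = NULL,
                       seed = NA_integer_) {
  if (!length(signals))
    stop_wheelride("no signals supplied", "wheelride_bad_input")
  locations <- lapply(signals, function(sig) {
    tryCatch({
      cr <- evaluate_comfort(sig, spec)
      list(location = cr$location,
           awx = cr$awx, awy = cr$awy, awz = cr$awz,
           av = cr$av, label = cr$label, C = cr$C,
           annoyance_rate_pct = 100 * annoyance_rate(cr$av, model),
           error = NULL)
    }, error = function(e) list(location = sig$location, error = conditionMessage(e)))
  })
  if (all(vapply(locations, function(l) !is.null(l$error), logical(1))))
    stop_wheelride("all locations failed to evaluate", "wheelride_bad_input")
  stability <- NULL
  if (!is.null(roll) || !is.null(pitch)) {
    deg <- 180 / pi
    stability <- list()
    if (!is.null(roll))
      stability$alpha1_deg <- as.numeric(roll_limit_angle(roll)) * deg
    if (!is.null(pitch)) {
      stability$beta_lim_deg <- pitch_limit_angle(pitch) * deg
      stability$beta1_deg <- as.numeric(uphill_slip_angle(pitch)) * deg
      stability$beta2_deg <- as.numeric(downhill_slip_angle(pitch)) * deg
    }
  }
  structure(list(
    schema = "wheelride-report/1",
    locations = locations,
    stability = stability,
    provenance = list(
      package_version = as.character(utils::packageVersion("wheelride")),
      weighting = spec$weighting,
      annoyance = list(r1 = model$r1, r2 = model$r2, a = model$a, b = model$b,
                       delta = model$delta, umin = model$umin),
      seed = seed)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Ride comfort evaluation\n")
  for (l in x$locations) {
    if (!is.null(l$error)) {
      cat(sprintf("  %-6s FAILED: %s\n", l$location, l$error))
    } else {
      cat(sprintf("  %-6s av = %.4f m/s^2  %s (C = %.1f)  annoyance = %.2f%%\n",
                  l$location, l$av, l$label, l$C, l$annoyance_rate_pct))
    }
  }
  if (!is.null(x$stability)) {
    s <- x$stability
    cat("Stability limits (deg):",
        if (!is.null(s$alpha1_deg)) sprintf("alpha1 = %.2f", s$alpha1_deg),
        if (!is.null(s$beta_lim_deg)) sprintf("beta_lim = %.2f", s$beta_lim_deg),
        if (!is.null(s$beta1_deg)) sprintf("beta1 = %.2f", s$beta1_deg),
        if (!is.null(s$beta2_deg)) sprintf("beta2 = %.2f", s$beta2_deg), "\n")
  }
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' The serialization carries no timestamp, so identical inputs (including
#' the recorded seed) produce byte-identical files.
#'
#' @param report an `evaluation_report` from [run_report()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
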
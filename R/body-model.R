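#' Evaluate a GeBOD-style anthropometric regression
#'
#' Body-segment parameter generators of the GeBOD family predict a shape,
#' mass or inertia quantity from weight, height and age through a linear
#' regression `Y = B0 + B1*X1 + B2*X2 + B3*X3` with X1 = weight (kg),
#' X2 = height (mm), X3 = age (years). Coefficient sets are supplied by the
#' caller; none are invented here.
#'
#' @param B0,B1,B2,B3 regression coefficients.
#' @param weight body weight (kg).
#' @param height standing height (mm).
#' @param age age (years).
#' @return predicted quantity in the units of the coefficient set.
#' @export
gebod_regression <- function(B0, B1, B2, B3, weight, height, age) {
  stopifnot(is.finite(c(B0, B1, B2, B3, weight, height, age)))
  B0 + B1 * weight + B2 * height + B3 * age
}

#' Total mass of a body-segment set
#'
#' @param segments data.frame with a `mass_kg` column, one row per segment.
#' @return total mass (kg).
#' @export
total_body_mass <- function(segments) {
  if (!nrow(segments)) stop_wheelride("empty segment table", "wheelride_bad_input")
  sum(segments$mass_kg)
}

#' Convert segment inertias from kg*mm^2 to kg*m^2
#'
#' Segment tables are shipped in kg*mm^2 as published; SI dynamics code
#' wants kg*m^2.
#'
#' @param x inertia values (kg*mm^2).
#' @return inertia values (kg*m^2).
#' @export
kgmm2_to_kgm2 <- function(x) x * 1e-6

#' Load the packaged anthropometric fixture tables
#'
#' Returns the 18-segment mass/inertia table and the 31-dimension body
#' measurement table for the reference occupant (50th-percentile adult,
#' 1800 mm standing height, 65 kg). Values are the published model outputs,
#' transcribed verbatim; known quirks are preserved rather than repaired:
#' the dimension list contains two distinct "Ankle circumference" entries,
#' and the segment masses sum to about 59.6 kg although the subject is
#' nominally 65 kg.
#'
#' @return list with `segments` (name, mass_kg, Ixx/Iyy/Izz in kg*mm^2) and
#'   `anthropometry` (dimension, value_mm) data.frames, plus `profile`
#'   (height_mm, weight_kg, percentile).
#' @export
load_fixture_tables <- function() {
  seg_path <- system.file("extdata", "gebod_segments.csv", package = "wheelride",
                          mustWork = TRUE)
  ant_path <- system.file("extdata", "gebod_anthropometry.csv", package = "wheelride",
                          mustWork = TRUE)
  segments <- utils::read.csv(seg_path, stringsAsFactors = FALSE)
  anthropometry <- utils::read.csv(ant_path, stringsAsFactors = FALSE)
  list(segments = segments, anthropometry = anthropometry,
       profile = list(height_mm = 1800, weight_kg = 65, percentile = 50))
}
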
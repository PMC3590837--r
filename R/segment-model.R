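#' Scale segment inertial parameters to a participant
#'
#' Builds the rigid-link inertial model of the throwing arm (humerus,
#' forearm, hand) from published anthropometric fractions scaled to the
#' participant's height and mass: segment mass is a fixed fraction of body
#' mass, segment length a fixed fraction of height, the centre-of-mass
#' position a fixed fraction of segment length from the proximal end, and
#' the principal radii of gyration fixed fractions of segment length. The
#' bundled reference table carries the adjusted Zatsiorsky fractions of
#' de Leva (1996) with Drillis-Contini length fractions. The torso is used
#' kinematically only and carries no inertial parameters here.
#'
#' @param height_cm standing height, cm.
#' @param mass_kg body mass, kg.
#' @param ball_mass_kg mass of the carried ball, kg (regulation baseball
#'   0.145 kg); the ball rides in the hand until ball release.
#' @param reference reference-table identifier; only `"deleva1996"` is
#'   bundled.
#' @return an object of class `segment_model`: list with `segments` (a
#'   data.frame with one row per segment: `mass_kg`, `length_m`,
#'   `com_fraction`, `rg_sagittal_m`, `rg_transverse_m`,
#'   `rg_longitudinal_m`), `ball_mass_kg`, `height_cm`, `mass_kg`.
#' @examples
#' scale_segment_parameters(142.6, 41.1)
#' @export
scale_segment_parameters <- function(height_cm, mass_kg, ball_mass_kg = 0.145,
                                     reference = "deleva1996") {
  if (!is.numeric(height_cm) || length(height_cm) != 1L || !is.finite(height_cm) || height_cm <= 0)
    stop("height_cm must be a single positive number")
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || !is.finite(mass_kg) || mass_kg <= 0)
    stop("mass_kg must be a single positive number")
  if (!is.numeric(ball_mass_kg) || ball_mass_kg < 0)
    stop("ball_mass_kg must be >= 0")
  reference <- match.arg(reference, "deleva1996")
  tab <- segment_reference_table()
  h_m <- height_cm / 100
  seg <- data.frame(
    segment = tab$segment,
    mass_kg = tab$mass_fraction * mass_kg,
    length_m = tab$length_fraction * h_m,
    com_fraction = tab$com_fraction,
    rg_sagittal_m = tab$rg_sagittal * tab$length_fraction * h_m,
    rg_transverse_m = tab$rg_transverse * tab$length_fraction * h_m,
    rg_longitudinal_m = tab$rg_longitudinal * tab$length_fraction * h_m,
    stringsAsFactors = FALSE
  )
  structure(
    list(segments = seg, ball_mass_kg = ball_mass_kg,
         height_cm = height_cm, mass_kg = mass_kg, reference = reference),
    class = "segment_model"
  )
}

segment_reference_table <- function() {
  path <- system.file("extdata", "segment_inertia.csv", package = "pitchload")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "segment_inertia.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

segment_mass <- function(model, segment) {
  i <- match(segment, model$segments$segment)
  if (is.na(i)) stop("segment '", segment, "' missing from segment model")
  model$segments$mass_kg[i]
}

segment_row <- function(model, segment) {
  i <- match(segment, model$segments$segment)
  if (is.na(i)) stop("segment '", segment, "' missing from segment model")
  model$segments[i, ]
}

#' @export
print.segment_model <- function(x, ...) {
  cat("Segment inertial model (", x$reference, ") for ",
      x$height_cm, " cm, ", x$mass_kg, " kg\n", sep = "")
  print(x$segments, row.names = FALSE)
  cat("ball mass:", x$ball_mass_kg, "kg\n")
  invisible(x)
}
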
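#' @title Additive background correction for fluorescence fold changes
#' @name correction
#' @keywords internal
NULL

#' Background model for quantitative immunofluorescence
#'
#' Cell autofluorescence and nonspecific secondary-antibody binding add a
#' constant, condition-independent offset to the measured cytoplasmic
#' signal. The model parameterises it as a fraction `b` of the
#' vehicle-condition mean cytoplasmic signal (measured defaults:
#' autofluorescence alone ~0.35; combined with nonspecific binding ~0.45).
#'
#' @param autofluorescence_fraction Fraction of the vehicle mean
#'   contributed by autofluorescence alone (default 0.35).
#' @param combined_fraction Autofluorescence plus nonspecific binding
#'   (default 0.45); must be `>= autofluorescence_fraction` and `< 1`.
#' @return Object of class `background_model`.
#' @export
background_model <- function(autofluorescence_fraction = 0.35,
                             combined_fraction = 0.45) {
  stopifnot(autofluorescence_fraction >= 0,
            combined_fraction >= autofluorescence_fraction,
            combined_fraction < 1)
  structure(list(autofluorescence_fraction = autofluorescence_fraction,
                 combined_fraction = combined_fraction),
            class = "background_model")
}

#' Correct a measured fold change for constant additive background
#'
#' A constant background equal to `b` times the vehicle mean inflates the
#' denominator and numerator of a fold change equally; subtracting it from
#' both gives the background-free fold `(f - b) / (1 - b)`. For a true
#' increase (`f > 1`) the corrected fold is strictly larger than the
#' measured one, and grows with `b`.
#'
#' @param f Measured fold change (> 0), treated mean over vehicle mean.
#' @param b Background fraction of the vehicle mean, in `[0, 1)`.
#' @return Corrected fold change. If `f < b` the measured signal lies
#'   below the background level and the (non-positive) value is returned
#'   with a warning.
#' @examples
#' corrected_fold(3.5, 0.45)  # 5.545...
#' @export
corrected_fold <- function(f, b) {
  stopifnot(is.numeric(f), is.numeric(b))
  if (any(b < 0) || any(b >= 1)) stop("'b' must lie in [0, 1)")
  if (any(f <= 0)) stop("'f' must be positive")
  if (any(f < b)) {
    warning("measured fold below background fraction; corrected fold is <= 0")
  }
  (f - b) / (1 - b)
}

#' Background-corrected fold from group means
#'
#' Subtracts the same constant background (`b` times the vehicle mean)
#' from both group means before forming their ratio; algebraically equal
#' to `corrected_fold(treated_mean / vehicle_mean, b)`.
#'
#' @param vehicle_mean,treated_mean Group means (vehicle mean > 0).
#' @param b Background fraction of the vehicle mean, in `[0, 1)`.
#' @return Corrected fold change.
#' @examples
#' corrected_fold_from_means(700, 2485, 0.45)  # ~5.64
#' @export
corrected_fold_from_means <- function(vehicle_mean, treated_mean, b) {
  stopifnot(is.numeric(vehicle_mean), is.numeric(treated_mean))
  if (any(vehicle_mean <= 0)) stop("vehicle mean must be positive")
  corrected_fold(treated_mean / vehicle_mean, b)
}
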
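#' Intensity class labels
#'
#' Ordered from sedentary to vigorous. MVPA is the union of `MPA` and `VPA`.
#' @return character vector of the four class labels
#' @export
intensity_levels <- function() c("SB", "LPA", "MPA", "VPA")

#' Vertical-axis count cut-points for intensity classification
#'
#' Cut-points are three ordered count boundaries defined at a reference epoch
#' length: `sed_max` (counts at or below are sedentary), `mod_min` (counts at
#' or above are at least moderate) and `vig_min` (counts at or above are
#' vigorous). The defaults are the widely used vertical-axis thresholds for
#' children in counts per 15 s; they can be replaced by any calibration study's
#' values. Boundaries are rescaled to other epoch lengths with
#' [scale_cutpoints()].
#'
#' @param sed_max,mod_min,vig_min count boundaries at the reference epoch
#' @param reference_epoch_s epoch length the boundaries are defined at
#' @param epoch_s epoch length the set currently applies to (defaults to the
#'   reference; changed by [scale_cutpoints()])
#' @return an object of class `cutpoint_set`
#' @export
#' @examples
#' cp <- cutpoint_set()
#' scale_cutpoints(cp, 10)
cutpoint_set <- function(sed_max = 25, mod_min = 574, vig_min = 1003,
                         reference_epoch_s = 15, epoch_s = reference_epoch_s) {
  if (!(sed_max < mod_min && mod_min < vig_min)) {
    abort("cut-point boundaries must satisfy sed_max < mod_min < vig_min")
  }
  if (reference_epoch_s <= 0 || epoch_s <= 0) {
    abort("epoch lengths must be positive")
  }
  structure(
    list(sed_max = sed_max, mod_min = mod_min, vig_min = vig_min,
         reference_epoch_s = reference_epoch_s, epoch_s = epoch_s),
    class = "cutpoint_set"
  )
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_set> at %g s epochs (reference %g s)\n  SB <= %.2f < LPA < %.2f <= MPA < %.2f <= VPA (counts/epoch)\n",
    x$epoch_s, x$reference_epoch_s, x$sed_max, x$mod_min, x$vig_min))
  invisible(x)
}

#' Rescale cut-points to a different epoch length
#'
#' Boundaries defined at the reference epoch are multiplied by
#' `target_epoch_s / reference_epoch_s` (linear rescaling, matching the usual
#' practice of adjusting published cut-points to shorter epochs). Order is
#' preserved because the factor is positive.
#'
#' @param cutpoints a [cutpoint_set()]
#' @param target_epoch_s positive epoch length in seconds
#' @return a `cutpoint_set` applying at `target_epoch_s`
#' @export
#' @examples
#' scale_cutpoints(cutpoint_set(25, 574, 1003, reference_epoch_s = 15), 10)
scale_cutpoints <- function(cutpoints, target_epoch_s) {
  stopifnot(inherits(cutpoints, "cutpoint_set"))
  if (!is.numeric(target_epoch_s) || length(target_epoch_s) != 1 || target_epoch_s <= 0) {
    abort("target_epoch_s must be a single positive number")
  }
  f <- target_epoch_s / cutpoints$reference_epoch_s
  cutpoint_set(
    sed_max = cutpoints$sed_max * f,
    mod_min = cutpoints$mod_min * f,
    vig_min = cutpoints$vig_min * f,
    reference_epoch_s = cutpoints$reference_epoch_s,
    epoch_s = target_epoch_s
  )
}

#' Classify epoch counts into intensity classes
#'
#' Wear epochs are labelled `SB` when `counts <= sed_max`, `LPA` strictly
#' between `sed_max` and `mod_min`, `MPA` from `mod_min` (inclusive) up to
#' `vig_min` (exclusive), and `VPA` at or above `vig_min`. Non-wear epochs get
#' `NA`. The cut-point set must already be scaled to the stream's epoch
#' length; a mismatch is an error rather than a silent misclassification.
#'
#' @param epochs tibble with columns `time`, `counts` and logical `wear`
#'   (add one with [detect_nonwear()]); a missing `wear` column is treated as
#'   all-worn with a warning
#' @param cutpoints a [cutpoint_set()] scaled to the stream's epoch length
#' @param epoch_len_s epoch length of the stream; inferred from timestamps by
#'   default
#' @return `epochs` with a factor column `intensity`
#' @export
classify_intensity <- function(epochs, cutpoints = scale_cutpoints(cutpoint_set(), epoch_len_s),
                               epoch_len_s = infer_epoch_len(epochs$time)) {
  stopifnot(inherits(cutpoints, "cutpoint_set"))
  if (!"counts" %in% names(epochs)) abort("epochs must have a `counts` column")
  if (any(epochs$counts < 0, na.rm = TRUE)) abort("counts must be nonnegative")
  if (abs(cutpoints$epoch_s - epoch_len_s) > 1e-9) {
    abort(sprintf(
      "cut-point set applies at %g s epochs but the stream is at %g s; call scale_cutpoints() first",
      cutpoints$epoch_s, epoch_len_s))
  }
  if (!"wear" %in% names(epochs)) {
    warn("no `wear` column; assuming all epochs worn")
    epochs$wear <- TRUE
  }
  cls <- with(cutpoints, ifelse(
    epochs$counts <= sed_max, "SB",
    ifelse(epochs$counts < mod_min, "LPA",
           ifelse(epochs$counts < vig_min, "MPA", "VPA"))))
  cls[!epochs$wear] <- NA_character_
  epochs$intensity <- factor(cls, levels = intensity_levels())
  epochs
}
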
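#' Percentage of mislabelled pixels
#'
#' Region-based segmentation accuracy: with `R_b` the ground-truth object
#' pixels and `R_s` the extracted object pixels,
#' `P_mp = (|R_b \ R_s| + |R_s \ R_b|) / (|R_b| + |R_s|) * 100`.
#' Zero iff the two sets are equal; 100 for disjoint non-empty sets; symmetric
#' in its arguments.
#'
#' @param truth ground-truth object mask (logical/0-1 matrix).
#' @param predicted extracted object mask, or a fitted `fuzzy_ac` model (its
#'   mask is used).
#' @return scalar percentage.
#' @examples
#' a <- matrix(FALSE, 4, 5); a[2:3, 2:4] <- TRUE
#' p_mp(a, a)  # 0
#' @export
p_mp <- function(truth, predicted) {
  if (inherits(predicted, "fuzzy_ac")) predicted <- predicted$mask
  truth <- truth > 0.5
  predicted <- predicted > 0.5
  if (!identical(dim(truth), dim(predicted)))
    stop("masks must have the same dimensions", call. = FALSE)
  nb <- sum(truth)
  ns <- sum(predicted)
  if (nb + ns == 0L)
    stop("undefined score: both masks are empty", call. = FALSE)
  mis <- sum(truth & !predicted) + sum(predicted & !truth)
  100 * mis / (nb + ns)
}
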
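#' Parameters of the T-RFLP alignment algorithm
#'
#' All knobs of the peak-table processing chain in one validated object.
#' Defaults put fragment size (bp) and relative area/height (both in
#' [0, 1] after relativization) on comparable scales, and set the gap
#' cost so that a candidate match is preferred over leaving both peaks
#' unmatched whenever its dissimilarity is below `2 * gap_cost = 1.5`.
#'
#' @param merge_window Peaks closer than this (bp) within one profile are
#'   merged as double/shoulder peaks (default 0.5).
#' @param max_drift Maximum size difference (bp) at which two peaks may
#'   be matched across profiles (default 1.0; must be >= `merge_window`).
#' @param w_size Dissimilarity weight per bp of size difference.
#' @param w_area,w_height Dissimilarity weights per unit of relative area
#'   and height difference.
#' @param gap_cost Cost of leaving one peak unmatched in a pairwise
#'   alignment; also the per-missing-sample penalty of a bin in the
#'   overall alignment score.
#' @param noise_k Multiple of the baseline standard deviation a peak must
#'   exceed to count as signal (default 3).
#' @param noise_rule `"and"` (default): a signal peak must exceed the
#'   threshold in both relative area and relative height; `"or"`: either
#'   suffices.
#' @param max_refine_iters Hard cap on leave-one-out refinement passes.
#' @return An object of class `align_params`.
#' @examples
#' align_params(max_drift = 0.8)
#' @export
align_params <- function(merge_window = 0.5,
                         max_drift = 1.0,
                         w_size = 1.0,
                         w_area = 1.0,
                         w_height = 1.0,
                         gap_cost = 0.75,
                         noise_k = 3.0,
                         noise_rule = c("and", "or"),
                         max_refine_iters = 20) {
  noise_rule <- match.arg(noise_rule)
  num <- c(
    merge_window = merge_window, max_drift = max_drift, w_size = w_size,
    w_area = w_area, w_height = w_height, gap_cost = gap_cost,
    noise_k = noise_k, max_refine_iters = max_refine_iters
  )
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("All alignment parameters must be positive and finite.")
  }
  if (max_drift < merge_window) {
    abort("`max_drift` must be at least `merge_window`.")
  }
  structure(
    list(
      merge_window = merge_window, max_drift = max_drift,
      w_size = w_size, w_area = w_area, w_height = w_height,
      gap_cost = gap_cost, noise_k = noise_k, noise_rule = noise_rule,
      max_refine_iters = as.integer(max_refine_iters)
    ),
    class = "align_params"
  )
}

.as_align_params <- function(params) {
  if (inherits(params, "align_params")) params else abort("`params` must come from align_params().")
}
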
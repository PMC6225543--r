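#' Merge double and shoulder peaks within each profile
#'
#' Within every (sample, gene, enzyme) profile, repeatedly merges the
#' closest pair of peaks whose size difference is below the merge window
#' until no such pair remains. A merged peak takes the area-weighted mean
#' size, the summed area, and the maximum height of its parents; when a
#' `truth_label` column is present the label of the larger-area parent is
#' kept. Merging is performed on raw (unrelativized) peak tables.
#'
#' @param peaks Long peak table with columns `sample_id`, `gene`,
#'   `enzyme`, `size_bp`, `area`, `height` (optionally `truth_label`).
#' @param params An [align_params()] object (uses `merge_window`).
#' @return The peak table with merged profiles, re-sorted by size within
#'   each profile.
#' @examples
#' p <- tibble::tibble(
#'   sample_id = "S1", gene = "nirK", enzyme = "HaeIII",
#'   size_bp = c(100.0, 100.3), area = c(10, 2), height = c(8, 1)
#' )
#' smooth_peaks(p)
#' @export
smooth_peaks <- function(peaks, params = align_params()) {
  params <- .as_align_params(params)
  check_columns(peaks, c("sample_id", "gene", "enzyme", "size_bp", "area", "height"))
  if (nrow(peaks) == 0) {
    return(as_tibble(peaks))
  }
  peaks %>%
    group_by(.data$sample_id, .data$gene, .data$enzyme) %>%
    dplyr::group_modify(~ .merge_profile(.x, params$merge_window)) %>%
    ungroup()
}

.merge_profile <- function(df, delta) {
  df <- df[order(df$size_bp), , drop = FALSE]
  has_label <- "truth_label" %in% names(df)
  repeat {
    if (nrow(df) < 2) break
    gaps <- diff(df$size_bp)
    if (all(gaps >= delta)) break
    i <- which.min(gaps) # closest pair; leftmost on ties
    a <- df$area[i] + df$area[i + 1]
    merged <- df[i, , drop = FALSE]
    merged$size_bp <- if (a > 0) {
      (df$area[i] * df$size_bp[i] + df$area[i + 1] * df$size_bp[i + 1]) / a
    } else {
      mean(df$size_bp[i:(i + 1)])
    }
    merged$area <- a
    merged$height <- max(df$height[i:(i + 1)])
    if (has_label) {
      dominant <- if (df$area[i + 1] > df$area[i]) i + 1 else i
      merged$truth_label <- df$truth_label[dominant]
    }
    df <- dplyr::bind_rows(
      df[seq_len(i - 1), , drop = FALSE], merged,
      df[setdiff(seq_len(nrow(df)), seq_len(i + 1)), , drop = FALSE]
    )
    df <- df[order(df$size_bp), , drop = FALSE]
  }
  df
}

#' Relativize peak areas and heights within each profile
#'
#' Divides every peak's area by the profile's total area and its height
#' by the profile's total height, so that areas and heights each sum to 1
#' within one (sample, gene, enzyme) profile. Idempotent.
#'
#' @inheritParams smooth_peaks
#' @return The peak table with relative areas and heights.
#' @export
relativize_peaks <- function(peaks) {
  check_columns(peaks, c("sample_id", "gene", "enzyme", "size_bp", "area", "height"))
  out <- peaks %>%
    group_by(.data$sample_id, .data$gene, .data$enzyme) %>%
    mutate(.ta = sum(.data$area), .th = sum(.data$height)) %>%
    ungroup()
  if (any(out$.ta <= 0) || any(out$.th <= 0)) {
    abort("Profiles with all-zero area or height cannot be relativized.")
  }
  out %>%
    mutate(area = .data$area / .data$.ta, height = .data$height / .data$.th) %>%
    dplyr::select(-".ta", -".th")
}

#' Classify peaks into signal and noise
#'
#' Iterative baseline method applied to relativized profiles, pooled over
#' all samples of each (gene, enzyme): the standard deviation of relative
#' areas about a theoretical baseline of zero, `sqrt(sum(a^2) / n)`, is
#' computed over all peaks not yet flagged as signal (and likewise for
#' heights); every pooled peak exceeding `noise_k` times both baselines
#' (default rule `"and"`; see [align_params()]) is flagged as signal and
#' removed from the pool; the baselines are recomputed and the process
#' iterates until no new peak is flagged. Remaining peaks are noise and
#' are discarded before alignment.
#'
#' The result does not depend on the input row order.
#'
#' @param peaks Relativized peak table (see [relativize_peaks()]).
#' @param params An [align_params()] object (uses `noise_k`,
#'   `noise_rule`).
#' @return The peak table with an added `peak_class` column
#'   (`"signal"`/`"noise"`).
#' @export
classify_peaks <- function(peaks, params = align_params()) {
  params <- .as_align_params(params)
  check_columns(peaks, c("sample_id", "gene", "enzyme", "size_bp", "area", "height"))
  if (nrow(peaks) == 0) {
    return(mutate(as_tibble(peaks), peak_class = character()))
  }
  peaks %>%
    group_by(.data$gene, .data$enzyme) %>%
    mutate(peak_class = .classify_pool(
      .data$area, .data$height, params$noise_k, params$noise_rule
    )) %>%
    ungroup()
}

.classify_pool <- function(area, height, k, rule) {
  cls <- rep("noise", length(area))
  pool <- rep(TRUE, length(area))
  repeat {
    n <- sum(pool)
    if (n == 0) break
    sigma_a <- sqrt(sum(area[pool]^2) / n)
    sigma_h <- sqrt(sum(height[pool]^2) / n)
    hit_a <- area >= k * sigma_a
    hit_h <- height >= k * sigma_h
    newly <- pool & if (rule == "and") hit_a & hit_h else hit_a | hit_h
    if (!any(newly)) break
    cls[newly] <- "signal"
    pool <- pool & !newly
  }
  cls
}

#' Fraction of labelled noise peaks removed by classification
#'
#' Scoring helper for synthetic data: among peaks whose `truth_label` is
#' `"noise"`, the fraction classified as noise by [classify_peaks()].
#'
#' @param classified A peak table carrying `truth_label` and
#'   `peak_class` columns.
#' @return A fraction in [0, 1] (`NaN` if no labelled noise peaks).
#' @export
noise_discard_rate <- function(classified) {
  check_columns(classified, c("truth_label", "peak_class"))
  is_noise <- classified$truth_label == "noise"
  mean(classified$peak_class[is_noise] == "noise")
}
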
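#' Ground-truth description of a synthetic T-RFLP community
#'
#' Bundles the true terminal restriction fragments (T-RFs) of one or more
#' (gene, enzyme) digests together with the error model used to emit
#' Peak Scanner-style peak tables: per-sample fragment-size jitter
#' (size-calling error), spurious low-intensity noise peaks, and shoulder
#' peaks riding on true peaks.
#'
#' @param fragments A data frame with columns `gene`, `enzyme`,
#'   `fragment_id`, `size_bp` (>= 50), `mean_log_area` (mean of the
#'   log-normal raw peak area). Within one (gene, enzyme), fragment sizes
#'   must be separated by more than `3 * jitter_sd` so that true
#'   co-binning is well defined.
#' @param jitter_sd Standard deviation of the per-sample size-calling
#'   error (bp, > 0).
#' @param noise_rate Expected number of spurious peaks per profile
#'   (Poisson mean, >= 0). Noise areas fall below 10% of the smallest
#'   true peak in the same profile.
#' @param shoulder_prob Probability that a true peak spawns a shoulder
#'   peak offset +0.3 bp carrying at most 25% of the parent area.
#' @param area_sdlog Log-normal sdlog of per-sample area variation about
#'   each fragment's mean log-area.
#' @param height_ratio,height_sdlog Heights are generated as
#'   `height_ratio * area` times multiplicative log-normal noise with
#'   sdlog `height_sdlog` (peak tables report both, correlated in
#'   practice).
#'
#' @return An object of class `trflp_truth`.
#' @examples
#' truth <- trflp_truth()
#' truth$fragments
#' @seealso [sim_trflp_profiles()], [default_fragment_panel()]
#' @export
trflp_truth <- function(fragments = default_fragment_panel(),
                        jitter_sd = 0.2,
                        noise_rate = 30,
                        shoulder_prob = 0.2,
                        area_sdlog = 0.3,
                        height_ratio = 0.35,
                        height_sdlog = 0.15) {
  check_columns(fragments, c("gene", "enzyme", "fragment_id", "size_bp", "mean_log_area"))
  if (!is.numeric(jitter_sd) || jitter_sd <= 0) abort("`jitter_sd` must be > 0.")
  if (noise_rate < 0) abort("`noise_rate` must be >= 0.")
  if (shoulder_prob < 0 || shoulder_prob > 1) abort("`shoulder_prob` must be in [0, 1].")
  if (any(fragments$size_bp < 50)) {
    abort("True fragment sizes must be >= 50 bp (below that is primer/dye artifact range).")
  }
  min_sep <- fragments %>%
    group_by(.data$gene, .data$enzyme) %>%
    summarise(sep = if (n() > 1) min(diff(sort(.data$size_bp))) else Inf, .groups = "drop")
  if (any(min_sep$sep <= 3 * jitter_sd)) {
    abort(sprintf(
      "Fragment sizes within one (gene, enzyme) must be separated by > 3 * jitter_sd = %.2f bp.",
      3 * jitter_sd
    ))
  }
  structure(
    list(
      fragments = as_tibble(fragments),
      jitter_sd = jitter_sd,
      noise_rate = noise_rate,
      shoulder_prob = shoulder_prob,
      area_sdlog = area_sdlog,
      height_ratio = height_ratio,
      height_sdlog = height_sdlog
    ),
    class = "trflp_truth"
  )
}

#' Default true-fragment panel for synthetic T-RFLP profiles
#'
#' Evenly spaced fragment sizes across the sizing-standard range with mean
#' relative abundances following a geometric series spanning one order of
#' magnitude — a dominant-to-rare abundance structure typical of community
#' fingerprints, and the spread the iterative baseline noise classifier
#' relies on. Abundance rank is decoupled from fragment size.
#'
#' @param n_fragments Number of true fragments (default 15).
#' @param gene,enzyme Labels for the digest.
#' @param size_range Range (bp) over which fragments are evenly spaced.
#' @param abundance_ratio Ratio of the most to the least abundant
#'   fragment's mean area.
#' @param base_area Raw fluorescence area (RFU units) of the least
#'   abundant fragment.
#' @return A tibble usable as the `fragments` field of [trflp_truth()].
#' @export
default_fragment_panel <- function(n_fragments = 15,
                                   gene = "nirK",
                                   enzyme = "HaeIII",
                                   size_range = c(60, 480),
                                   abundance_ratio = 10,
                                   base_area = 2000) {
  stopifnot(n_fragments >= 1, abundance_ratio >= 1, base_area > 0)
  sizes <- seq(size_range[1], size_range[2], length.out = n_fragments)
  abund <- abundance_ratio^(seq(0, 1, length.out = max(n_fragments, 2))[seq_len(n_fragments)])
  # interleave ranks so neighbouring fragments differ in abundance
  ord <- order(rep_len(c(1, 3, 2), n_fragments), seq_len(n_fragments))
  tibble(
    gene = gene,
    enzyme = enzyme,
    fragment_id = sprintf("%s_%s_F%02d", gene, enzyme, seq_len(n_fragments)),
    size_bp = sizes,
    mean_log_area = log(base_area * abund[ord])
  )
}

#' Simulate Peak Scanner-style T-RFLP peak tables with known truth
#'
#' Emits one peak table per sample and (gene, enzyme) digest: every true
#' fragment appears at its size plus Gaussian size-calling jitter with
#' log-normal area (and correlated height); shoulder peaks appear +0.3 bp
#' from their parent with at most 25% of its area; spurious noise peaks
#' (Poisson count) carry areas below 10% of the profile's smallest true
#' peak. Every emitted peak is labelled with its true fragment id,
#' `"shoulder"`, or `"noise"`, so that downstream bin recovery and noise
#' discard can be scored exactly.
#'
#' @param truth A [trflp_truth()] object.
#' @param n_samples Number of samples (>= 1).
#' @param seed Optional integer seed; fixed seed gives identical tables.
#' @return A tibble with columns `sample_id`, `gene`, `enzyme`, `size_bp`,
#'   `area`, `height`, `truth_label`, sorted by sample, gene, enzyme and
#'   size.
#' @examples
#' peaks <- sim_trflp_profiles(trflp_truth(), n_samples = 3, seed = 1)
#' dplyr::count(peaks, truth_label == "noise")
#' @export
sim_trflp_profiles <- function(truth, n_samples, seed = NULL) {
  if (!inherits(truth, "trflp_truth")) abort("`truth` must be a `trflp_truth` object.")
  if (n_samples < 1) abort("`n_samples` must be >= 1.")

  with_seed_if(seed, {
    out <- purrr::map_dfr(seq_len(n_samples), function(s) {
      sample_id <- sprintf("S%02d", s)
      purrr::map_dfr(
        split(truth$fragments, paste(truth$fragments$gene, truth$fragments$enzyme)),
        function(fr) .sim_one_profile(fr, truth, sample_id)
      )
    })
    out %>% arrange(.data$sample_id, .data$gene, .data$enzyme, .data$size_bp)
  })
}

.sim_one_profile <- function(fr, truth, sample_id) {
  k <- nrow(fr)
  true_peaks <- tibble(
    sample_id = sample_id,
    gene = fr$gene,
    enzyme = fr$enzyme,
    size_bp = fr$size_bp + rnorm(k, 0, truth$jitter_sd),
    area = rlnorm(k, meanlog = fr$mean_log_area, sdlog = truth$area_sdlog),
    truth_label = fr$fragment_id
  )
  true_peaks$height <- truth$height_ratio * true_peaks$area *
    rlnorm(k, 0, truth$height_sdlog)

  is_shoulder <- runif(k) < truth$shoulder_prob
  shoulders <- if (any(is_shoulder)) {
    parent <- true_peaks[is_shoulder, ]
    frac <- runif(nrow(parent), 0.05, 0.25)
    tibble(
      sample_id = sample_id,
      gene = parent$gene,
      enzyme = parent$enzyme,
      size_bp = parent$size_bp + 0.3,
      area = frac * parent$area,
      height = frac * parent$height,
      truth_label = "shoulder"
    )
  } else {
    NULL
  }

  n_noise <- rpois(1, truth$noise_rate)
  noise <- if (n_noise > 0) {
    lo <- max(50, min(fr$size_bp) - 20)
    hi <- max(fr$size_bp) + 20
    area <- runif(n_noise, 0.01, 0.10) * min(true_peaks$area)
    tibble(
      sample_id = sample_id,
      gene = fr$gene[1],
      enzyme = fr$enzyme[1],
      size_bp = runif(n_noise, lo, hi),
      area = area,
      height = truth$height_ratio * area * rlnorm(n_noise, 0, truth$height_sdlog),
      truth_label = "noise"
    )
  } else {
    NULL
  }

  bind_rows(true_peaks[, c(
    "sample_id", "gene", "enzyme", "size_bp", "area", "height", "truth_label"
  )], shoulders, noise)
}
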
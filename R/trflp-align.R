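#' Random-order incremental multiple alignment of T-RFLP profiles
#'
#' Builds a multiple alignment of all de-noised profiles of one
#' (gene, enzyme) digest. Two profiles are drawn at random (seeded) and
#' aligned pairwise; the aligned set is then represented as a consensus
#' profile of bin-average peak size, area, and height, and each remaining
#' profile is added in random order by aligning it against the current
#' consensus with [align_pair()]. Matched peaks join the corresponding
#' bin (updating its averages and occupancy); unmatched peaks open new
#' bins. The overall alignment score is the sum over all member peaks of
#' their dissimilarity to their bin's consensus, plus `gap_cost` for
#' every (bin, sample) combination where the sample contributes no peak.
#'
#' @param peaks De-noised, relativized peak table of one (gene, enzyme):
#'   columns `sample_id`, `size_bp`, `area`, `height` (a `peak_class`
#'   column, if present, is filtered to `"signal"`; `truth_label` is
#'   carried through for scoring). At least 2 samples.
#' @param params An [align_params()] object.
#' @param seed Integer seed controlling the random insertion order.
#' @return An object of class `trflp_alignment`; see
#'   [tidy.trflp_alignment()], [augment.trflp_alignment()],
#'   [alignment_score()].
#' @examples
#' peaks <- sim_trflp_profiles(trflp_truth(noise_rate = 0, shoulder_prob = 0), 4, seed = 1)
#' aln <- peaks |> relativize_peaks() |> align_profiles(seed = 1)
#' glance(aln)
#' @export
align_profiles <- function(peaks, params = align_params(), seed = 1) {
  params <- .as_align_params(params)
  check_columns(peaks, c("sample_id", "size_bp", "area", "height"))
  if ("peak_class" %in% names(peaks)) {
    peaks <- filter(peaks, .data$peak_class == "signal")
  }
  gene <- if ("gene" %in% names(peaks)) unique(peaks$gene) else NA_character_
  enzyme <- if ("enzyme" %in% names(peaks)) unique(peaks$enzyme) else NA_character_
  if (length(gene) > 1 || length(enzyme) > 1) {
    abort("`peaks` must contain a single (gene, enzyme); split before aligning.")
  }
  profiles <- .split_profiles(peaks)
  if (length(profiles) < 2) abort("At least 2 samples are required for an alignment.")

  members <- with_seed_if(seed, {
    ord <- sample(names(profiles))
    mem <- .seed_bins(profiles[[ord[1]]], ord[1])
    for (s in ord[-1]) {
      mem <- .add_profile(mem, profiles[[s]], s, params)
    }
    mem
  })
  .finalize_alignment(members,
    params = params, samples = names(profiles),
    gene = gene, enzyme = enzyme, seed = seed
  )
}

#' Leave-one-out refinement of a multiple alignment
#'
#' Iteratively improves an alignment: in each pass every sample is, in
#' seeded random order, removed from the alignment (bin averages are
#' recomputed without it and emptied bins dropped) and realigned against
#' the remaining consensus. After a full pass the overall score is
#' recomputed; the pass is kept only if the score strictly decreased,
#' otherwise the previous alignment is restored and refinement stops.
#' At most `max_refine_iters` passes are attempted.
#'
#' @param aln A `trflp_alignment` from [align_profiles()].
#' @param seed Integer seed for the per-pass removal order.
#' @return A `trflp_alignment` whose `score_history` records the initial
#'   score followed by the score after each accepted pass (strictly
#'   decreasing).
#' @export
refine_alignment <- function(aln, seed = 1) {
  stopifnot(inherits(aln, "trflp_alignment"))
  params <- aln$params
  members <- aln$members
  best_members <- members
  best_score <- aln$score
  history <- aln$score_history
  n_samples <- length(aln$samples)

  with_seed_if(seed, {
    for (pass in seq_len(params$max_refine_iters)) {
      for (s in sample(aln$samples)) {
        own <- members[members$sample_id == s, , drop = FALSE]
        rest <- members[members$sample_id != s, , drop = FALSE]
        prof <- own[order(own$size_bp), c("sample_id", "size_bp", "area", "height",
          intersect("truth_label", names(own))), drop = FALSE]
        members <- .add_profile(rest, prof, s, params)
      }
      sc <- .score_members(members, n_samples, params)
      if (sc < best_score - 1e-12) {
        best_score <- sc
        best_members <- members
        history <- c(history, sc)
      } else {
        members <- best_members
        break
      }
    }
  })
  .finalize_alignment(best_members,
    params = params, samples = aln$samples,
    gene = aln$gene, enzyme = aln$enzyme, seed = aln$seed,
    score_history = history
  )
}

#' Recompute the overall score of an alignment from its membership
#'
#' Sum over member peaks of the dissimilarity to their bin's consensus
#' (size/area/height averages over current members), plus `gap_cost` for
#' every missing (bin, sample) combination. Equals the stored `score`.
#'
#' @param aln A `trflp_alignment`.
#' @return The overall alignment score (non-negative scalar).
#' @export
alignment_score <- function(aln) {
  stopifnot(inherits(aln, "trflp_alignment"))
  .score_members(aln$members, length(aln$samples), aln$params)
}

#' Combine the alignments of two enzyme digests
#'
#' Column-wise concatenation of the sample-by-bin relative-area matrices
#' of the same gene digested with two different restriction enzymes, with
#' enzyme-prefixed bin ids — the combined fingerprint used for community
#' statistics.
#'
#' @param aln_a,aln_b `trflp_alignment` objects covering the same sample
#'   set.
#' @param value Which peak attribute to tabulate.
#' @return A wide tibble: `sample_id` plus one column per bin of both
#'   alignments.
#' @export
combine_enzymes <- function(aln_a, aln_b, value = c("area", "height")) {
  value <- match.arg(value)
  stopifnot(inherits(aln_a, "trflp_alignment"), inherits(aln_b, "trflp_alignment"))
  if (!setequal(aln_a$samples, aln_b$samples)) {
    abort("The two alignments must cover the same samples.")
  }
  a <- as_bin_matrix(aln_a, value = value, prefix = aln_a$enzyme)
  b <- as_bin_matrix(aln_b, value = value, prefix = aln_b$enzyme)
  b <- b[match(a$sample_id, b$sample_id), , drop = FALSE]
  dplyr::bind_cols(a, b[, -1, drop = FALSE])
}

#' Sample-by-bin matrix of an alignment
#'
#' @param aln A `trflp_alignment`.
#' @param value Peak attribute to tabulate (relative area or height);
#'   absent (sample, bin) combinations are 0.
#' @param prefix Optional prefix for bin column names (e.g. the enzyme).
#' @return A wide tibble, one row per sample, bins ordered by consensus
#'   size.
#' @export
as_bin_matrix <- function(aln, value = c("area", "height"), prefix = NULL) {
  value <- match.arg(value)
  stopifnot(inherits(aln, "trflp_alignment"))
  bins <- aln$bins$bin_id
  cols <- if (is.null(prefix) || is.na(prefix)) bins else paste(prefix, bins, sep = "_")
  wide <- aln$members %>%
    dplyr::select("sample_id", "bin_id", value = dplyr::all_of(value)) %>%
    tidyr::pivot_wider(
      names_from = "bin_id", values_from = "value", values_fill = 0
    )
  missing_bins <- setdiff(bins, names(wide))
  for (b in missing_bins) wide[[b]] <- 0
  wide <- wide[, c("sample_id", bins)]
  names(wide) <- c("sample_id", cols)
  wide[order(wide$sample_id), , drop = FALSE]
}

#' Truth-cohort bin recovery of a synthetic alignment
#'
#' For every true fragment (members labelled with a fragment id rather
#' than `"noise"`/`"shoulder"`), finds the bin holding the plurality of
#' its peaks and reports how many of the fragment's peaks landed there.
#' `bin_purity()` summarizes this as the overall fraction of true peaks
#' co-binned with their truth cohort.
#'
#' @param aln A `trflp_alignment` whose members carry `truth_label`.
#' @return `bin_recovery()`: a tibble `fragment_id`, `n_peaks`,
#'   `modal_bin`, `n_cobinned`. `bin_purity()`: a single fraction.
#' @export
bin_recovery <- function(aln) {
  stopifnot(inherits(aln, "trflp_alignment"))
  check_columns(aln$members, "truth_label", arg = "aln$members")
  aln$members %>%
    filter(!.data$truth_label %in% c("noise", "shoulder")) %>%
    group_by(fragment_id = .data$truth_label) %>%
    summarise(
      n_peaks = n(),
      modal_bin = names(which.max(table(.data$bin_id))),
      n_cobinned = max(table(.data$bin_id)),
      .groups = "drop"
    )
}

#' @rdname bin_recovery
#' @export
bin_purity <- function(aln) {
  rec <- bin_recovery(aln)
  sum(rec$n_cobinned) / sum(rec$n_peaks)
}

# ---- internals -------------------------------------------------------------

.split_profiles <- function(peaks) {
  keep <- intersect(
    c("sample_id", "size_bp", "area", "height", "truth_label"),
    names(peaks)
  )
  peaks <- peaks[, keep, drop = FALSE]
  out <- split(as_tibble(peaks), peaks$sample_id)
  lapply(out, function(df) df[order(df$size_bp), , drop = FALSE])
}

# every peak of the first profile opens its own bin
.seed_bins <- function(prof, sample_id) {
  prof$bin_key <- seq_len(nrow(prof))
  prof$sample_id <- sample_id
  prof
}

.consensus <- function(members) {
  cons <- members %>%
    group_by(.data$bin_key) %>%
    summarise(
      size_bp = mean(.data$size_bp),
      area = mean(.data$area),
      height = mean(.data$height),
      .groups = "drop"
    ) %>%
    arrange(.data$size_bp)
  cons
}

# align one profile against the consensus of `members` and absorb it
.add_profile <- function(members, prof, sample_id, params) {
  prof <- prof[order(prof$size_bp), , drop = FALSE]
  prof$sample_id <- sample_id
  if (nrow(members) == 0) {
    return(.seed_bins(prof, sample_id))
  }
  cons <- .consensus(members)
  pa <- align_pair(cons, prof, params)
  prof$bin_key <- NA_integer_
  if (nrow(pa$pairs) > 0) {
    prof$bin_key[pa$pairs$j] <- cons$bin_key[pa$pairs$i]
  }
  if (length(pa$unmatched_q) > 0) {
    next_key <- max(members$bin_key) + seq_along(pa$unmatched_q)
    prof$bin_key[pa$unmatched_q] <- next_key
  }
  bind_rows(members, prof)
}

.score_members <- function(members, n_samples, params) {
  cons <- .consensus(members)
  idx <- match(members$bin_key, cons$bin_key)
  # raw weighted dissimilarity (feasibility was enforced at match time)
  d <- params$w_size * abs(members$size_bp - cons$size_bp[idx]) +
    params$w_area * abs(members$area - cons$area[idx]) +
    params$w_height * abs(members$height - cons$height[idx])
  occ <- tabulate(idx, nbins = nrow(cons))
  sum(d) + params$gap_cost * sum(n_samples - occ)
}

.finalize_alignment <- function(members, params, samples, gene, enzyme, seed,
                                score_history = NULL) {
  cons <- .consensus(members)
  cons$bin_id <- sprintf("B%03d", seq_len(nrow(cons)))
  members$bin_id <- cons$bin_id[match(members$bin_key, cons$bin_key)]
  occ <- members %>%
    group_by(.data$bin_id) %>%
    summarise(occupancy = dplyr::n_distinct(.data$sample_id), .groups = "drop")
  bins <- cons %>%
    dplyr::select("bin_id", consensus_size = "size_bp", mean_area = "area",
      mean_height = "height") %>%
    dplyr::left_join(occ, by = "bin_id")
  score <- .score_members(members, length(samples), params)
  structure(
    list(
      bins = bins,
      members = as_tibble(members),
      score = score,
      score_history = if (is.null(score_history)) score else score_history,
      params = params,
      samples = sort(samples),
      gene = gene,
      enzyme = enzyme,
      seed = seed
    ),
    class = "trflp_alignment"
  )
}

#' @export
print.trflp_alignment <- function(x, ...) {
  cat(sprintf(
    "<trflp_alignment> %s/%s: %d samples, %d bins, score %.4f\n",
    x$gene, x$enzyme, length(x$samples), nrow(x$bins), x$score
  ))
  invisible(x)
}

#' Bin table of a T-RFLP alignment
#'
#' @param x A `trflp_alignment`.
#' @param ... Unused.
#' @return A tibble of bins: `bin_id`, `consensus_size` (bp, mean of
#'   member sizes), `mean_area`, `mean_height`, `occupancy` (number of
#'   samples contributing a peak).
#' @export
tidy.trflp_alignment <- function(x, ...) {
  x$bins
}

#' One-row summary of a T-RFLP alignment
#'
#' @param x A `trflp_alignment`.
#' @param ... Unused.
#' @return A one-row tibble: `gene`, `enzyme`, `n_samples`, `n_bins`,
#'   `score`, `n_refine_passes`.
#' @export
glance.trflp_alignment <- function(x, ...) {
  tibble(
    gene = x$gene, enzyme = x$enzyme,
    n_samples = length(x$samples), n_bins = nrow(x$bins),
    score = x$score, n_refine_passes = length(x$score_history) - 1L
  )
}

#' Member peaks of a T-RFLP alignment
#'
#' @param x A `trflp_alignment`.
#' @param ... Unused.
#' @return The member peak table with each peak's `bin_id` assignment.
#' @export
augment.trflp_alignment <- function(x, ...) {
  dplyr::select(x$members, -"bin_key")
}

#' False-gel image of an alignment
#'
#' @param object A `trflp_alignment`.
#' @param ... Unused.
#' @return A ggplot tile plot: samples on the x axis, bin consensus size
#'   on the y axis, fill mapped to relative peak area — the classic
#'   false-gel view used to eyeball fragment binning.
#' @export
autoplot.trflp_alignment <- function(object, ...) {
  df <- dplyr::left_join(
    object$members, object$bins[, c("bin_id", "consensus_size")],
    by = "bin_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$consensus_size, fill = .data$area
  )) +
    ggplot2::geom_tile(height = 4) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "black") +
    ggplot2::labs(
      x = "Sample", y = "Fragment size (bp)", fill = "Rel. area",
      title = sprintf("%s / %s false-gel image", object$gene, object$enzyme)
    ) +
    ggplot2::theme_minimal()
}
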
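#' End-to-end T-RFLP processing of a raw peak table
#'
#' Runs the full fingerprint chain on a Peak Scanner-style peak table
#' covering any number of (gene, enzyme) digests: shoulder-peak merging,
#' relativization, iterative noise classification, and per-digest
#' multiple alignment with optional leave-one-out refinement.
#'
#' @param peaks Raw long peak table (`sample_id`, `gene`, `enzyme`,
#'   `size_bp`, `area`, `height`, optionally `truth_label`).
#' @param params An [align_params()] object.
#' @param seed Integer seed; per-digest alignment seeds are derived from
#'   it deterministically.
#' @param refine Run [refine_alignment()] on each digest's alignment.
#' @return A list with elements `alignments` (named list of
#'   `trflp_alignment`, one per `gene_enzyme`) and `classified` (the
#'   relativized peak table with `peak_class`).
#' @examples
#' peaks <- sim_trflp_profiles(trflp_truth(), n_samples = 5, seed = 1)
#' res <- align_trflp(peaks, seed = 1)
#' glance(res$alignments[[1]])
#' @export
align_trflp <- function(peaks, params = align_params(), seed = 1, refine = TRUE) {
  params <- .as_align_params(params)
  classified <- peaks %>%
    smooth_peaks(params) %>%
    relativize_peaks() %>%
    classify_peaks(params)
  digests <- classified %>%
    filter(.data$peak_class == "signal") %>%
    dplyr::group_split(.data$gene, .data$enzyme)
  alignments <- purrr::imap(digests, function(d, i) {
    aln <- align_profiles(d, params, seed = seed + i)
    if (refine) aln <- refine_alignment(aln, seed = seed + i + 1000L)
    aln
  })
  names(alignments) <- purrr::map_chr(
    digests, ~ paste(.x$gene[1], .x$enzyme[1], sep = "_")
  )
  list(alignments = alignments, classified = classified)
}
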
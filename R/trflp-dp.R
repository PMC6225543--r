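#' Dissimilarity between two peaks
#'
#' Weighted L1 dissimilarity combining fragment-size, relative-area, and
#' relative-height differences:
#' `d = w_size * |ds| + w_area * |da| + w_height * |dh|`.
#' Peaks whose sizes differ by more than `max_drift` are infeasible
#' matches and receive `Inf`.
#'
#' @param size_p,area_p,height_p,size_q,area_q,height_q Peak attributes
#'   (relativized area/height); vectorized.
#' @param params An [align_params()] object.
#' @return Numeric dissimilarities (`Inf` for infeasible pairs).
#' @examples
#' peak_dissimilarity(100.0, 0.2, 0.1, 100.4, 0.25, 0.12)
#' @export
peak_dissimilarity <- function(size_p, area_p, height_p,
                               size_q, area_q, height_q,
                               params = align_params()) {
  params <- .as_align_params(params)
  ds <- abs(size_p - size_q)
  d <- params$w_size * ds + params$w_area * abs(area_p - area_q) +
    params$w_height * abs(height_p - height_q)
  d[ds > params$max_drift] <- Inf
  d
}

#' Pairwise dynamic-programming alignment of two peak profiles
#'
#' Global alignment of two size-sorted peak sequences minimizing the sum
#' of match dissimilarities plus `gap_cost` per unmatched peak. Matches
#' are restricted to pairs within `max_drift` bp and must be non-crossing
#' in size order (Needleman-Wunsch-style recursion over the two
#' sequences). Ties are broken deterministically: a match is preferred
#' over a gap, then a gap in the second profile over one in the first.
#'
#' @param p,q Data frames with columns `size_bp`, `area`, `height`,
#'   sorted ascending by `size_bp` (relativized). `p` may also be a bin
#'   consensus profile.
#' @param params An [align_params()] object.
#' @return A list with elements `pairs` (tibble `i`, `j`, `cost` of
#'   matched row indices into `p` and `q`), `unmatched_p`, `unmatched_q`
#'   (integer row indices), and `cost` (the total alignment cost).
#' @examples
#' p <- tibble::tibble(size_bp = c(100, 150), area = 0.5, height = 0.5)
#' align_pair(p, p)$cost
#' @export
align_pair <- function(p, q, params = align_params()) {
  params <- .as_align_params(params)
  check_columns(p, c("size_bp", "area", "height"), arg = "p")
  check_columns(q, c("size_bp", "area", "height"), arg = "q")
  if (is.unsorted(p$size_bp, strictly = FALSE) || is.unsorted(q$size_bp, strictly = FALSE)) {
    abort("Profiles must be sorted ascending by `size_bp`.")
  }
  n <- nrow(p)
  m <- nrow(q)
  g <- params$gap_cost

  # cost matrix of the DP over prefixes; move matrix encodes traceback:
  # 1 = match, 2 = gap in q (skip p_i), 3 = gap in p (skip q_j)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- (0:n) * g
  M[1, ] <- (0:m) * g
  mv <- matrix(0L, n + 1, m + 1)
  mv[-1, 1] <- 2L
  mv[1, -1] <- 3L

  if (n > 0 && m > 0) {
    D <- outer(seq_len(n), seq_len(m), function(i, j) {
      peak_dissimilarity(
        p$size_bp[i], p$area[i], p$height[i],
        q$size_bp[j], q$area[j], q$height[j],
        params
      )
    })
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        cand <- c(M[i, j] + D[i, j], M[i, j + 1] + g, M[i + 1, j] + g)
        best <- which.min(cand) # prefers match, then gap-in-q, on ties
        M[i + 1, j + 1] <- cand[best]
        mv[i + 1, j + 1] <- best
      }
    }
  }

  # traceback
  i <- n
  j <- m
  pi <- integer(0)
  pj <- integer(0)
  up <- integer(0)
  uq <- integer(0)
  while (i > 0 || j > 0) {
    step <- mv[i + 1, j + 1]
    if (step == 1L) {
      pi <- c(i, pi)
      pj <- c(j, pj)
      i <- i - 1
      j <- j - 1
    } else if (step == 2L) {
      up <- c(i, up)
      i <- i - 1
    } else {
      uq <- c(j, uq)
      j <- j - 1
    }
  }
  pairs <- tibble(
    i = pi, j = pj,
    cost = if (length(pi)) {
      peak_dissimilarity(
        p$size_bp[pi], p$area[pi], p$height[pi],
        q$size_bp[pj], q$area[pj], q$height[pj],
        params
      )
    } else {
      numeric(0)
    }
  )
  list(pairs = pairs, unmatched_p = up, unmatched_q = uq, cost = M[n + 1, m + 1])
}
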
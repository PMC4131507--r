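# Shadowed-sets three-way thresholding of a fuzzy set and the narrow band
# (approximation region) built from it.
#
# A shadowed set trades the membership detail of a fuzzy set for a three-way
# partition: degrees below a threshold alpha are reduced to 0 (exclusion),
# degrees above U_max - alpha are elevated to full membership (core), and the
# rest form the shadow, where the uncertainty is retained.  The threshold
# balances the membership mass lost and gained against the size of the
# shadow.

#' Shadowed-sets balance objective
#'
#' `V(alpha) = | psi1 + psi2 - psi3 |` with
#' `psi1 = sum of u over {u <= alpha}` (membership reduced to 0),
#' `psi2 = sum of (U_max - u) over {u >= U_max - alpha}` (membership elevated
#' to `U_max`), and `psi3 = #{alpha < u < U_max - alpha}` (shadow
#' cardinality). The optimal threshold makes the total membership mass moved
#' out of the tails balance the cardinality of the shadow region where
#' uncertainty is retained; a sum of all three terms would be monotone in
#' `alpha` (every value crossing the threshold contributes `u - 1 < 0`) and
#' could never balance anything, so the shadow term enters with a minus sign.
#'
#' @param values membership degrees in `[0, 1]` (any numeric vector/matrix).
#' @param alpha candidate threshold.
#' @return scalar objective value.
#' @export
shadow_objective <- function(values, alpha) {
  values <- as.vector(values)
  if (length(values) == 0L) stop("empty membership set", call. = FALSE)
  umax <- max(values)
  psi1 <- sum(values[values <= alpha])
  psi2 <- sum(umax - values[values >= umax - alpha])
  psi3 <- sum(values > alpha & values < umax - alpha)
  abs(psi1 + psi2 - psi3)
}

#' Optimal shadowed-sets threshold
#'
#' Exhaustive search of [shadow_objective()] over the grid
#' `{U_min, U_min + step, ..., (U_max + U_min)/2}` (both endpoints included);
#' ties are broken toward the smallest threshold, which keeps the shadow
#' region large (conservative updates).
#'
#' The search is evaluated with sorted cumulative sums, so it is exact over
#' the stated grid at `O((n + G) log n)` cost.
#'
#' @param values membership degrees in `[0, 1]`.
#' @param step grid step (default 0.001).
#' @return list with `alpha_opt`, `v_value`, `u_max`, `u_min`, and the
#'   searched `grid`.
#' @export
shadow_threshold <- function(values, step = 0.001) {
  values <- as.vector(values)
  if (length(values) == 0L) stop("empty membership set", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("membership degrees must lie in [0, 1]", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  umin <- min(values)
  umax <- max(values)
  hi <- (umax + umin) / 2
  grid <- seq(umin, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)

  sv <- sort(values)
  cs <- cumsum(sv)
  n <- length(sv)
  # psi1: sum of values <= alpha
  i1 <- findInterval(grid, sv)                      # count of sv <= alpha
  psi1 <- ifelse(i1 > 0, cs[pmax(i1, 1L)], 0)
  # psi2: sum of (umax - v) over v >= umax - alpha
  thr <- umax - grid
  i2 <- findInterval(thr, sv, left.open = TRUE)     # count of sv < thr
  tail_n <- n - i2
  tail_sum <- cs[n] - ifelse(i2 > 0, cs[pmax(i2, 1L)], 0)
  psi2 <- tail_n * umax - tail_sum
  # psi3: count of alpha < v < umax - alpha
  lo_n <- findInterval(grid, sv)                    # v <= alpha
  hi_n <- findInterval(thr, sv, left.open = TRUE)   # v < umax - alpha
  psi3 <- pmax(hi_n - lo_n, 0L)

  v <- abs(psi1 + psi2 - psi3)
  best <- which.min(v)   # first minimum = smallest alpha
  list(alpha_opt = grid[best], v_value = v[best],
       u_max = umax, u_min = umin, grid = grid)
}

#' Shadowed-sets narrow band around the contour
#'
#' Thresholds the object fuzzy set (the membership map) and the background
#' fuzzy set (its complement) independently and returns the union of their
#' shadow regions:
#' `S1 = {a1 < u < max(u) - a1}`, `S2 = {a2 < 1-u < max(1-u) - a2}`,
#' `R_a = S1 U S2`. The strict inequalities exclude the extreme degrees, so a
#' crisp map yields an empty band (a legal result; the caller decides the
#' fallback).
#'
#' @param membership membership map in `[0, 1]`.
#' @param step threshold-search grid step.
#' @return logical band mask.
#' @export
boundary_band <- function(membership, step = 0.001) {
  check_membership(membership)
  u <- membership
  t1 <- shadow_threshold(u, step)
  t2 <- shadow_threshold(1 - u, step)
  s1 <- u > t1$alpha_opt & u < t1$u_max - t1$alpha_opt
  s2 <- (1 - u) > t2$alpha_opt & (1 - u) < t2$u_max - t2$alpha_opt
  s1 | s2
}
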
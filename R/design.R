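#' Maximin Latin hypercube design over the input box
#'
#' Generates `n_restarts` random Latin hypercubes (via [lhs::randomLHS()])
#' and keeps the one maximizing the minimum pairwise Euclidean distance on
#' the unit-cube scale, so that dimensions with small natural magnitude
#' (such as the interaction rate) do not dominate the criterion. Best-of-
#' restarts selection is fully reproducible given the seed and adequate in
#' three dimensions.
#'
#' @param n Number of design points (>= 2).
#' @param ranges Named list of per-dimension `(lower, upper)` bounds,
#'   default [lvpp_ranges()].
#' @param seed Integer seed.
#' @param n_restarts Number of candidate hypercubes (default 50).
#' @param wave Wave label stored with the design.
#' @return A `design_matrix`: data frame of points on the natural scale with
#'   attributes `ranges`, `wave`, `seed`, `min_dist`.
#' @export
maximin_lhs <- function(n, ranges = lvpp_ranges(), seed = 1,
                        n_restarts = 50, wave = 1L) {
  check_ranges(ranges)
  if (n < 2) stop("n must be at least 2")
  set.seed(seed)
  d <- length(ranges)
  best <- NULL
  best_crit <- -Inf
  for (r in seq_len(n_restarts)) {
    u <- lhs::randomLHS(n, d)
    crit <- min(stats::dist(u))
    if (crit > best_crit) {
      best <- u
      best_crit <- crit
    }
  }
  design_from_unit(best, ranges, wave = wave, seed = seed,
                   min_dist = best_crit)
}

check_ranges <- function(ranges) {
  if (!is.list(ranges) || !length(ranges))
    stop("ranges must be a non-empty named list of (lower, upper) bounds")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop(sprintf("degenerate or invalid range for %s", nm))
  }
  invisible(ranges)
}

design_from_unit <- function(u, ranges, wave, seed, min_dist = NA_real_) {
  pts <- as.data.frame(mapply(function(col, r) r[1] + col * (r[2] - r[1]),
                              as.data.frame(u), ranges, SIMPLIFY = FALSE),
                       col.names = names(ranges))
  names(pts) <- names(ranges)
  structure(pts, class = c("design_matrix", "data.frame"),
            ranges = ranges, wave = wave, seed = seed, min_dist = min_dist)
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> wave %s, %d points in %d dimensions\n",
              attr(x, "wave"), nrow(x), ncol(x)))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# rescale a design (or any points matrix) to the unit cube of its ranges
to_unit_cube <- function(points, ranges) {
  m <- as.matrix(points[, names(ranges), drop = FALSE])
  for (j in seq_along(ranges)) {
    r <- ranges[[j]]
    m[, j] <- (m[, j] - r[1]) / (r[2] - r[1])
  }
  m
}

#' Rejection-sample candidate points under an acceptance predicate
#'
#' Draws points uniformly over the box and keeps those accepted by
#' `acceptor` until `n_target` points are accepted or `max_draws` draws are
#' exhausted. Used to generate the next wave of inputs satisfying an
#' implausibility threshold under a refined discrepancy specification.
#'
#' @param n_target Number of accepted points wanted.
#' @param ranges Per-dimension bounds.
#' @param acceptor Predicate taking a numeric input point, returning `TRUE`
#'   to keep it.
#' @param seed Integer seed.
#' @param max_draws Cap on total uniform draws (default `200 * n_target`).
#' @param wave Wave label for the returned design.
#' @return A `design_matrix` of the accepted points (possibly fewer than
#'   `n_target` if the cap is hit with at least one acceptance) with
#'   attribute `acceptance_rate`.
#' @export
rejection_sample_candidates <- function(n_target, ranges = lvpp_ranges(),
                                        acceptor, seed = 1,
                                        max_draws = 200 * n_target,
                                        wave = NULL) {
  check_ranges(ranges)
  if (!is.function(acceptor)) stop("acceptor must be a function")
  set.seed(seed)
  d <- length(ranges)
  lower <- vapply(ranges, `[`, numeric(1), 1L)
  upper <- vapply(ranges, `[`, numeric(1), 2L)
  kept <- matrix(numeric(0), ncol = d)
  drawn <- 0L
  while (nrow(kept) < n_target && drawn < max_draws) {
    batch <- min(max(n_target, 100L), max_draws - drawn)
    u <- matrix(runif(batch * d), ncol = d)
    pts <- sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`)
    ok <- apply(pts, 1L, function(p) isTRUE(acceptor(p)))
    kept <- rbind(kept, pts[ok, , drop = FALSE])
    drawn <- drawn + batch
  }
  rate <- nrow(kept) / drawn
  if (nrow(kept) == 0L)
    stop(sprintf(paste0("no candidates accepted after %d draws ",
                        "(acceptance rate 0); review the discrepancy ",
                        "specification or threshold"), drawn))
  kept <- kept[seq_len(min(n_target, nrow(kept))), , drop = FALSE]
  colnames(kept) <- names(ranges)
  structure(as.data.frame(kept),
            class = c("design_matrix", "data.frame"),
            ranges = ranges, wave = wave, seed = seed,
            min_dist = NA_real_, acceptance_rate = rate)
}
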
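#' Fit linear-regression emulators for simulator or discrepancy outputs
#'
#' One emulator per output column: a least-squares fit of an intercept plus
#' linear terms in each input, after rescaling every input dimension to
#' `[-1, 1]` for conditioning. The residual process is summarized by its
#' variance (residual mean square); with `interpolate = TRUE` a stationary
#' residual process with Gaussian correlation
#' `exp(-(x - x')' Sigma (x - x'))` is added and predictions are adjusted
#' through the training residuals (second-order Bayes linear update), so
#' training outputs are reproduced.
#'
#' @param design A `design_matrix` (or data frame with a `ranges`
#'   attribute, or supply `ranges`).
#' @param responses Numeric matrix (points x outputs) or vector.
#' @param ranges Per-dimension bounds used for rescaling; defaults to the
#'   design's own ranges.
#' @param interpolate Enable the residual-process adjustment.
#' @param theta Residual correlation scale (diagonal of `Sigma`, unit-cube
#'   scale). If `NULL` and `interpolate = TRUE`, chosen from a small grid
#'   of candidates by leave-one-out error.
#' @return An object of class `lv_emulator` with per-output coefficients,
#'   coefficient covariances, residual variances `sigma2`, and `r_squared`
#'   (defined as 0, and flagged, for constant responses).
#' @export
fit_linear_emulator <- function(design, responses, ranges = NULL,
                                interpolate = FALSE, theta = NULL) {
  if (is.null(ranges)) ranges <- attr(design, "ranges")
  if (is.null(ranges)) stop("ranges must be supplied or carried by design")
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n != nrow(design)) stop("design and responses disagree in length")
  U <- 2 * to_unit_cube(design, ranges) - 1
  colnames(U) <- names(ranges)
  X <- cbind(`(Intercept)` = 1, U)
  p <- ncol(X)
  if (n < p + 2) stop("need at least p + 2 design points")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("rank-deficient basis; collinear terms: %s",
                 paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(X, responses)
  B <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  rss <- colSums(res^2)
  tss <- colSums(sweep(responses, 2L, colMeans(responses))^2)
  sigma2 <- rss / (n - p)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  XtXinv <- chol2inv(qr.R(qrX))
  em <- structure(list(
    coefficients = B, xtx_inv = XtXinv, sigma2 = sigma2,
    r_squared = setNames(r2, colnames(responses)),
    degenerate = tss <= 0,
    ranges = ranges, n = n, p = p,
    train_u = U, train_resid = res,
    interpolate = interpolate, theta = NULL, kinv = NULL),
    class = "lv_emulator")
  if (interpolate) {
    if (is.null(theta)) theta <- choose_theta(U, res)
    em$theta <- theta
    K <- corr_gauss(U, U, theta)
    diag(K) <- diag(K) + 1e-8
    Ki <- chol2inv(chol(K))
    # generalized-least-squares coefficients under the correlated residual
    # process, so the interpolating predictor is the universal-kriging mean
    XtKiX <- t(X) %*% Ki %*% X
    em$coefficients <- solve(XtKiX, t(X) %*% Ki %*% responses)
    em$xtx_inv <- solve(XtKiX)
    em$train_resid <- responses - X %*% em$coefficients
    em$kinv <- Ki
  }
  em
}

# Gaussian correlation between row sets, diagonal Sigma = theta (recycled)
corr_gauss <- function(u1, u2, theta) {
  theta <- rep_len(theta, ncol(u1))
  d2 <- outer(rowSums(sweep(u1^2, 2L, theta, `*`)),
              rowSums(sweep(u2^2, 2L, theta, `*`)), `+`) -
    2 * (sweep(u1, 2L, theta, `*`) %*% t(u2))
  exp(-pmax(d2, 0))
}

# small documented candidate grid for the residual correlation scale,
# scored by leave-one-out squared error of the adjusted predictor
choose_theta <- function(U, res, candidates = c(0.25, 0.5, 1, 2, 4, 8)) {
  score <- vapply(candidates, function(th) {
    K <- corr_gauss(U, U, th)
    diag(K) <- diag(K) + 1e-8
    Ki <- tryCatch(chol2inv(chol(K)), error = function(e) NULL)
    if (is.null(Ki)) return(Inf)
    # LOO residual of the kriging smoother: (Ki r) / diag(Ki)
    sum((sweep(Ki %*% res, 1L, diag(Ki), `/`))^2)
  }, numeric(1))
  candidates[which.min(score)]
}

#' Predict from a linear emulator
#'
#' Predictive mean is the fitted basis surface (plus the residual-process
#' adjustment in interpolating mode); predictive variance is the
#' basis-coefficient uncertainty term plus the residual variance. Points
#' outside the training ranges are flagged as extrapolation.
#'
#' @param object An `lv_emulator`.
#' @param x Input point(s): vector, matrix or data frame on the natural
#'   scale.
#' @param ... Unused.
#' @return List with `mean` and `var` (points x outputs matrices) and
#'   `extrapolating` (logical per point).
#' @export
predict.lv_emulator <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.data.frame(x)
  names(x) <- names(object$ranges)
  Unew <- 2 * to_unit_cube(x, object$ranges) - 1
  extrap <- apply(abs(Unew) > 1 + 1e-9, 1L, any)
  X <- cbind(1, Unew)
  mu <- X %*% object$coefficients
  basis_var <- rowSums((X %*% object$xtx_inv) * X)
  v <- outer(basis_var, object$sigma2) +
    matrix(object$sigma2, nrow(X), length(object$sigma2), byrow = TRUE)
  if (!is.null(object$extra_coef_var))  # reified: added coefficient variance
    v <- v + X^2 %*% object$extra_coef_var
  if (isTRUE(object$interpolate)) {
    cc <- corr_gauss(Unew, object$train_u, object$theta)
    mu <- mu + cc %*% object$kinv %*% object$train_resid
    shrink <- pmax(1 - rowSums((cc %*% object$kinv) * cc), 0)
    v <- outer(basis_var, object$sigma2) + outer(shrink, object$sigma2)
  }
  dimnames(mu) <- list(NULL, names(object$r_squared))
  dimnames(v) <- dimnames(mu)
  list(mean = mu, var = v, extrapolating = extrap)
}

#' @export
print.lv_emulator <- function(x, ...) {
  cat(sprintf("<lv_emulator> %d outputs, %d training points, basis: %s\n",
              length(x$sigma2), x$n,
              paste(rownames(x$coefficients), collapse = " + ")))
  cat(sprintf("  R^2: min %.3f  median %.3f  (%d degenerate outputs)\n",
              min(x$r_squared[!x$degenerate]),
              median(x$r_squared[!x$degenerate]), sum(x$degenerate)))
  invisible(x)
}

#' @export
summary.lv_emulator <- function(object, ...) {
  data.frame(output = names(object$r_squared),
             r_squared = unname(object$r_squared),
             sigma = sqrt(unname(object$sigma2)),
             degenerate = unname(object$degenerate), row.names = NULL)
}

#' Augment a simulator or emulator with internal-discrepancy fields
#'
#' Builds the discrepancy-augmented representation
#' `fI(x) = f(x) + muI(x) + sigmaI(x) eps`, where the bias field `muI` and
#' scale field `sigmaI` come from emulators of the internal-discrepancy
#' bias and sd summaries, and `eps` has zero mean, unit variance and the
#' output-output correlation measured in the experiments.
#'
#' @param base Either a function `x -> named output vector` (direct
#'   simulator evaluation, the default mode for fast models) or an
#'   `lv_emulator`.
#' @param bias_em,sd_em Emulators of the bias and sd fields over the same
#'   output indexing (note: `muI = -bias` by the sign convention of
#'   [discrepancy_mean_from_bias()]).
#' @param corr Output correlation matrix (`NA` entries treated as 0).
#' @return An object of class `augmented_emulator`; predict with
#'   [predict_augmented()].
#' @export
augment_with_internal <- function(base, bias_em, sd_em, corr = NULL) {
  stopifnot(inherits(bias_em, "lv_emulator"), inherits(sd_em, "lv_emulator"))
  structure(list(base = base, bias_em = bias_em, sd_em = sd_em,
                 corr = corr, n_floored = 0L),
            class = "augmented_emulator")
}

#' @rdname augment_with_internal
#' @param aug An `augmented_emulator`.
#' @param x A single input point.
#' @return `predict_augmented`: list with `mean` (vector), `cov` (output
#'   covariance), `base_mean`, `base_var`, `sigma_i`, `n_floored` (count of
#'   negative sd-field predictions floored at zero).
#' @export
predict_augmented <- function(aug, x) {
  if (is.function(aug$base)) {
    base_mean <- aug$base(x)
    base_var <- rep(0, length(base_mean))
  } else {
    pr <- predict(aug$base, x)
    base_mean <- drop(pr$mean)
    base_var <- drop(pr$var)
  }
  bias <- drop(predict(aug$bias_em, x)$mean)
  sig <- drop(predict(aug$sd_em, x)$mean)
  n_floored <- sum(sig < 0)
  sig <- pmax(sig, 0)
  R <- length(base_mean)
  corr <- aug$corr
  if (is.null(corr)) corr <- diag(R)
  corr[is.na(corr)] <- 0
  diag(corr) <- 1
  cov <- diag(base_var, R) + (sig %o% sig) * corr
  mean_out <- base_mean + discrepancy_mean_from_bias(bias)
  list(mean = mean_out, cov = cov, base_mean = base_mean,
       base_var = base_var, sigma_i = sig, n_floored = n_floored)
}

#' Direct-reification specification and transform
#'
#' A reified emulator treats the simulator as informative for a notional
#' improved model: coefficients are linked as `a* = c a + nu` with known
#' links `c` and added uncertainties `nu`, and the residual process as
#' `u* = gamma u + delta u'` plus an extra-input process `u**`, with `u'`
#' and `u**` independent of `u`. With the identity specification the
#' reified moments equal the base emulator's.
#'
#' @param c_link Coefficient link factors (recycled over coefficients),
#'   default 1.
#' @param nu_var Added coefficient variances, default 0.
#' @param gamma,delta Residual links, default 1 and 0.
#' @param uprime_var Variance of the independent residual `u'`, default:
#'   the base residual variance (so `delta` rebalances like-for-like).
#' @param ustar2_var Variance of the extra-input process `u**`, default 0.
#' @return An object of class `reified_spec`.
#' @export
reified_spec <- function(c_link = 1, nu_var = 0, gamma = 1, delta = 0,
                         uprime_var = NULL, ustar2_var = 0) {
  structure(list(c_link = c_link, nu_var = nu_var, gamma = gamma,
                 delta = delta, uprime_var = uprime_var,
                 ustar2_var = ustar2_var),
            class = "reified_spec")
}

#' @rdname reified_spec
#' @param em An `lv_emulator`.
#' @param spec A `reified_spec`.
#' @return `reify_emulator`: an `lv_emulator` whose second-order moments
#'   are the reified ones, with attribute `residual_corr_with_base`, the
#'   correlation between reified and base residual processes.
#' @export
reify_emulator <- function(em, spec = reified_spec()) {
  stopifnot(inherits(em, "lv_emulator"), inherits(spec, "reified_spec"))
  out <- em
  cl <- matrix(rep_len(spec$c_link, length(em$coefficients)),
               nrow(em$coefficients))
  nu <- matrix(rep_len(spec$nu_var, length(em$coefficients)),
               nrow(em$coefficients))
  out$coefficients <- cl * em$coefficients
  out$extra_coef_var <- nu
  upv <- if (is.null(spec$uprime_var)) em$sigma2 else
    rep_len(spec$uprime_var, length(em$sigma2))
  out$sigma2 <- spec$gamma^2 * em$sigma2 + spec$delta^2 * upv +
    rep_len(spec$ustar2_var, length(em$sigma2))
  denom <- sqrt(em$sigma2 * out$sigma2)
  attr(out, "residual_corr_with_base") <-
    ifelse(denom > 0, spec$gamma * em$sigma2 / denom, 0)
  out$reified <- TRUE
  out
}
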
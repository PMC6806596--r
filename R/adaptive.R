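#' Coefficients of the adaptive guided-filter model
#'
#' The window size and regularization of the guided filter are predicted
#' from three scan statistics by a pair of affine models:
#' `|omega| = a1*N1 + b1*N2 + c1*sigma2 + d1` and
#' `eps = a2*N1 + b2*N2 + c2*sigma2 + d2`, where `N1` is the total number
#' of scan points, `N2` the number of points whose band variance exceeds
#' the threshold (1000 by default), and `sigma2` a scalar summary of the
#' band-variance map.
#'
#' @param a1,b1,c1,d1 window-size model coefficients.
#' @param a2,b2,c2,d2 regularization model coefficients.
#' @return An object of class `adaptive_coefficients`.
#' @export
adaptive_coefficients <- function(a1, b1, c1, d1, a2, b2, c2, d2) {
  v <- c(a1 = a1, b1 = b1, c1 = c1, d1 = d1,
         a2 = a2, b2 = b2, c2 = c2, d2 = d2)
  if (any(!is.finite(v))) stop("coefficients must be finite")
  structure(as.list(v), class = "adaptive_coefficients")
}

#' @export
print.adaptive_coefficients <- function(x, ...) {
  cat(sprintf("adaptive_coefficients:\n  |omega| = %g*N1 + %g*N2 + %g*s2 + %g\n  eps     = %g*N1 + %g*N2 + %g*s2 + %g\n",
              x$a1, x$b1, x$c1, x$d1, x$a2, x$b2, x$c2, x$d2))
  invisible(x)
}

#' Built-in adaptive model coefficients
#'
#' The default coefficient matrix fitted on the reference instrument data:
#' `[a1 a2] = [0.0113 -0.0797]`, `[b1 b2] = [-0.0056 0.1210]`,
#' `[c1 c2] = [0.0001 -0.0001]`, `[d1 d2] = [3.1181 44.2304]`.
#'
#' @return An [adaptive_coefficients()] object.
#' @export
builtin_adaptive_coefficients <- function() {
  adaptive_coefficients(a1 = 0.0113, b1 = -0.0056, c1 = 0.0001, d1 = 3.1181,
                        a2 = -0.0797, b2 = 0.1210, c2 = -0.0001, d2 = 44.2304)
}

#' Adaptive guided-filter parameters from scan statistics
#'
#' Evaluates the affine models (see [adaptive_coefficients()]) and derives
#' the integer window radius.  The window width is the odd integer nearest
#' to `omega` (floored at 3 so the filter is never an accidental no-op).
#' The raw `eps` is in squared gray units on the 0-255 scale; since the
#' filter operates on \[0, 1\]-normalized gray, the applied value is
#' `eps / 255^2`, floored at 1e-4.
#'
#' @param N1 total number of scan points (>= 1).
#' @param N2 number of points with band variance above the threshold
#'   (`0 <= N2 <= N1`).
#' @param sigma2 scalar band-variance summary (>= 0), see
#'   [summarize_sigma2()].
#' @param coef an [adaptive_coefficients()] object.
#' @return An object of class `guided_params`: list with `omega` (raw model
#'   output), `width`, `r`, `eps` (raw model output, floored positive),
#'   `eps01` (value applied on the \[0, 1\] scale).
#' @export
adaptive_params <- function(N1, N2, sigma2,
                            coef = builtin_adaptive_coefficients()) {
  stopifnot(inherits(coef, "adaptive_coefficients"))
  if (N1 < 0 || N2 < 0 || sigma2 < 0) stop("N1, N2, sigma2 must be >= 0")
  if (N2 > N1) stop("N2 cannot exceed N1")
  omega <- coef$a1 * N1 + coef$b1 * N2 + coef$c1 * sigma2 + coef$d1
  eps <- coef$a2 * N1 + coef$b2 * N2 + coef$c2 * sigma2 + coef$d2
  width <- max(3L, 2L * as.integer(round((omega - 1) / 2)) + 1L)
  eps01 <- max(eps / 255^2, 1e-4)
  structure(list(omega = omega, width = width, r = (width - 1L) %/% 2L,
                 eps = max(eps, 1e-4 * 255^2), eps01 = eps01),
            class = "guided_params")
}

#' @export
print.guided_params <- function(x, ...) {
  cat(sprintf(
    "guided_params: omega %.4f -> width %d (r = %d), eps %.4f (%.6f on [0,1])\n",
    x$omega, x$width, x$r, x$eps, x$eps01))
  invisible(x)
}

#' Fit the adaptive model by least squares
#'
#' Solves the two independent linear systems for the window-size and
#' regularization targets over a design matrix `[N1 N2 sigma2 1]`.  On a
#' rank-deficient design the minimum-norm solution is returned with a
#' warning.
#'
#' @param data data.frame with columns `N1`, `N2`, `sigma2`, `omega`,
#'   `eps`; at least 4 rows and `N2 <= N1` everywhere.
#' @return An [adaptive_coefficients()] object.
#' @export
fit_coefficients <- function(data) {
  req <- c("N1", "N2", "sigma2", "omega", "eps")
  if (!all(req %in% names(data)))
    stop("data needs columns ", paste(req, collapse = ", "))
  if (nrow(data) < 4L)
    stop("underdetermined: at least 4 rows are required to fit 4 unknowns")
  if (any(data$N2 > data$N1)) stop("N2 cannot exceed N1")
  X <- cbind(data$N1, data$N2, data$sigma2, 1)
  qrX <- qr(X)
  deficient <- qrX$rank < 4L
  if (deficient)
    warning("rank-deficient design; returning the minimum-norm solution")
  solve_ls <- function(y) {
    if (deficient) {
      sv <- svd(X)
      pos <- sv$d > max(sv$d) * 1e-12
      drop(sv$v[, pos, drop = FALSE] %*%
             ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
    } else {
      qr.coef(qrX, y)
    }
  }
  co <- solve_ls(data$omega)
  ce <- solve_ls(data$eps)
  adaptive_coefficients(a1 = co[1L], b1 = co[2L], c1 = co[3L], d1 = co[4L],
                        a2 = ce[1L], b2 = ce[2L], c2 = ce[3L], d2 = ce[4L])
}
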
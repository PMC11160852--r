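#' Random i.i.d. feedback matrix
#'
#' Samples a feedback matrix `B` with entries i.i.d. Gaussian, mean 0 and
#' variance `1/n_rows`, so that `E[B'B] = I`. With `n_rows = Nbar` much
#' larger than `n_cols = N_{l+1}` (small aspect ratio `lambda =
#' n_cols/n_rows`), `B'B` concentrates around the identity, which is what
#' makes the product pathway `RB` track the forward weights.
#'
#' @param n_rows,n_cols Matrix dimensions (rows index the intermediate
#'   population).
#' @param seed Optional integer seed.
#' @return An `n_rows x n_cols` matrix.
#' @export
init_iid_feedback <- function(n_rows, n_cols, seed = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n_rows * n_cols, sd = 1 / sqrt(n_rows)), n_rows, n_cols)
}

#' Semi-orthogonal feedback matrix
#'
#' Returns a tall matrix with exactly orthonormal columns (`B'B = I`),
#' obtained from the QR decomposition of a Gaussian matrix; the column space
#' is Haar-distributed. Requires `n_rows >= n_cols`.
#'
#' @inheritParams init_iid_feedback
#' @return An `n_rows x n_cols` matrix with `B'B = I` to machine precision.
#' @export
init_semi_orthogonal <- function(n_rows, n_cols, seed = NULL) {
  if (n_rows < n_cols) {
    stop("semi-orthogonality requires n_rows >= n_cols (got ",
         n_rows, " < ", n_cols, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  qrG <- qr(G)
  Q <- qr.Q(qrG)
  # fix the sign ambiguity of QR so the distribution is Haar
  Q %*% diag(sign(diag(qr.R(qrG))), n_cols)
}

#' Marchenko-Pastur support edges
#'
#' Support `[lambda_minus, lambda_plus]` of the limiting eigenvalue density
#' of `B'B` for an i.i.d. `B` with aspect ratio `lambda = N_{l+1}/Nbar` and
#' entry variance `1/Nbar`: `lambda_pm = (1 +/- sqrt(lambda))^2`. As
#' `lambda -> 0` both edges tend to 1 and the spectrum collapses onto the
#' identity.
#'
#' @param lambda Aspect ratio in (0, 1].
#' @return Named numeric vector `c(lower, upper)`.
#' @export
mp_support <- function(lambda) {
  stopifnot(lambda > 0, lambda <= 1)
  c(lower = (1 - sqrt(lambda))^2, upper = (1 + sqrt(lambda))^2)
}

#' Marchenko-Pastur density
#'
#' Density `mu(v) = sqrt((lambda_plus - v)(v - lambda_minus)) / (2 pi lambda
#' v)` on the support returned by [mp_support()], and 0 outside it.
#'
#' @param v Evaluation points.
#' @param lambda Aspect ratio in (0, 1].
#' @return Density values, same length as `v`.
#' @export
mp_density <- function(v, lambda) {
  edges <- mp_support(lambda)
  out <- numeric(length(v))
  inside <- v >= edges[1] & v <= edges[2] & v > 0
  vi <- v[inside]
  out[inside] <- sqrt((edges[2] - vi) * (vi - edges[1])) / (2 * pi * lambda * vi)
  out
}

#' Empirical spectrum of B'B
#'
#' Eigenvalues of `B'B` for a feedback matrix, paired with the analytic
#' Marchenko-Pastur support for the matrix's aspect ratio.
#'
#' @param B Feedback matrix (`Nbar x N`, `Nbar >= N`).
#' @return An object of class `spectrum_result`: a list with sorted
#'   `eigenvalues`, the aspect ratio `lambda`, `support_edges`, and the
#'   analytic `density` function.
#' @export
empirical_spectrum <- function(B) {
  stopifnot(is.matrix(B))
  lambda <- ncol(B) / nrow(B)
  ev <- sort(eigen(crossprod(B), symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)  # clip tiny negative round-off; B'B is PSD
  structure(
    list(eigenvalues = ev, lambda = lambda,
         support_edges = mp_support(min(lambda, 1)),
         density = function(v) mp_density(v, min(lambda, 1))),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result: %d eigenvalues, lambda = %.4g, support [%.4g, %.4g]>\n",
              length(x$eigenvalues), x$lambda,
              x$support_edges[1], x$support_edges[2]))
  invisible(x)
}

#' @rdname empirical_spectrum
#' @param x A `spectrum_result`.
#' @param ... Unused.
#' @export
tidy.spectrum_result <- function(x, ...) {
  tibble::tibble(eigenvalue = x$eigenvalues, lambda = x$lambda,
                 support_lower = x$support_edges[1],
                 support_upper = x$support_edges[2])
}

#' @rdname empirical_spectrum
#' @param object A `spectrum_result`.
#' @export
autoplot.spectrum_result <- function(object, ...) {
  df <- tidy(object)
  edges <- object$support_edges
  grid <- seq(max(edges[1], 1e-6), edges[2], length.out = 400)
  dens <- tibble::tibble(v = grid, mu = object$density(grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvalue)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_line(data = dens, ggplot2::aes(x = .data$v, y = .data$mu),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "eigenvalue of B'B", y = "density",
                  title = sprintf("Empirical spectrum vs Marchenko-Pastur (lambda = %.3g)",
                                  object$lambda)) +
    ggplot2::theme_minimal()
}

#' Path-alignment angle as a function of the expansion ratio
#'
#' For each expansion ratio `1/lambda`, samples a random forward weight `W`
#' and sets the plastic feedback to its post-training fixed point `R' = BW`
#' (the configuration reached once weight decay has washed out the
#' initializations), then measures the angle between `vec(W')` and
#' `vec(RB)`. The mean angle decreases towards 0 as the expansion ratio
#' grows, because `B'B` concentrates at the identity; at ratio 10 it sits
#' near `acos(1/sqrt(1.1)) ~ 17.5` degrees.
#'
#' @param ratios Expansion ratios `1/lambda` to test.
#' @param n_out,n_in Dimensions of the forward weight `W` (`n_out x n_in`).
#' @param n_seeds Replicates per ratio.
#' @param seed Master seed.
#' @return A tibble with columns `ratio`, `seed`, `angle_deg`.
#' @export
angle_vs_ratio <- function(ratios = c(1, 2, 5, 10, 50), n_out = 50, n_in = 50,
                           n_seeds = 20, seed = 1) {
  res <- list()
  for (r in ratios) {
    for (s in seq_len(n_seeds)) {
      set.seed((seed * 1009 + s * 97 + round(r * 13)) %% .Machine$integer.max)
      W <- matrix(stats::rnorm(n_out * n_in), n_out, n_in)
      nbar <- as.integer(ceiling(r * n_out))
      B <- init_iid_feedback(nbar, n_out)
      R <- t(B %*% W)                       # R' = BW
      ang <- alignment_angle(t(W), R %*% B)
      res[[length(res) + 1]] <- tibble::tibble(ratio = r, seed = s,
                                               angle_deg = ang)
    }
  }
  dplyr::bind_rows(res)
}
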
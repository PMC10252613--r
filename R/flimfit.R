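# Bi-exponential NAD(P)H decay fitting. The decay model is
#   mu_i = A * (a1 * q_i(tau1) + a2 * q_i(tau2)),  a1 = 1 - a2,
# where q_i(tau) is the probability mass of bin i for an exponential
# lifetime truncated to the acquisition window. a1 + a2 = 1 is enforced by
# the parameterization (amplitude, a2, tau1, tau2), not by renormalization.

#' Amplitude-weighted mean fluorescence lifetime
#'
#' `tau_m = a1 * tau1 + a2 * tau2`, the standard summary of a bi-exponential
#' NAD(P)H decay, where the short component is free and the long component
#' protein-bound NAD(P)H.
#'
#' @param a1,a2 fractional amplitudes, must sum to 1 within 1e-6.
#' @param tau1_ns,tau2_ns component lifetimes, ns.
#' @return mean lifetime in ns.
#' @examples
#' mean_lifetime(0.8, 0.4, 0.2, 2.5)  # 0.82 ns
#' @export
mean_lifetime <- function(a1, tau1_ns, a2, tau2_ns) {
  if (any(abs(a1 + a2 - 1) > 1e-6)) {
    stop("a1 + a2 must equal 1 (within 1e-6)")
  }
  a1 * tau1_ns + a2 * tau2_ns
}

#' Fit a bi-exponential model to a time-binned decay
#'
#' Poisson-weighted nonlinear least squares (Levenberg-Marquardt) on the bin
#' counts. Lifetimes are box-bounded to the standard NAD(P)H ranges
#' (`tau1` in \[0.1, 1\] ns free, `tau2` in \[1, 6\] ns bound), which also
#' enforces `tau1 <= tau2`. Several starting values of `a2` are tried and
#' the best converged fit returned.
#'
#' @param decay a [generate_decay()] `decay_curve`, or any list with
#'   `bin_edges_ns` and `counts`.
#' @param init optional named list overriding starting values
#'   (`a2`, `tau1`, `tau2`).
#' @param bounds list with elements `tau1` and `tau2`, each `c(lower, upper)`.
#' @return object of class `biexp_fit`: `a1`, `a2`, `tau1_ns`, `tau2_ns`,
#'   `tau_m_ns`, `residual_norm` (sqrt of the summed Poisson-weighted squared
#'   residuals), `converged`.
#' @export
fit_biexponential <- function(decay, init = NULL,
                              bounds = list(tau1 = c(0.1, 1.0), tau2 = c(1.0, 6.0))) {
  y <- as.numeric(decay$counts)
  edges <- decay$bin_edges_ns
  if (length(y) != length(edges) - 1L) stop("counts and bin edges disagree")
  nonempty <- sum(y > 0)
  if (nonempty < 4L) {
    stop("fit failure: need at least 4 non-empty bins, got ", nonempty)
  }
  if (max(y) == sum(y)) {
    stop("fit failure: degenerate decay (all counts in one bin)")
  }
  w <- 1 / sqrt(pmax(y, 1))  # Poisson weighting
  model_mu <- function(p) {
    p[1L] * ((1 - p[2L]) * decay_bin_probs(edges, p[3L]) +
               p[2L] * decay_bin_probs(edges, p[4L]))
  }
  resid_fn <- function(p) (y - model_mu(p)) * w
  lower <- c(1e-3, 0, bounds$tau1[1L], bounds$tau2[1L])
  upper <- c(Inf, 1, bounds$tau1[2L], bounds$tau2[2L])
  a2_starts <- if (is.null(init$a2)) c(0.2, 0.5, 0.8) else init$a2
  tau1_0 <- if (is.null(init$tau1)) 0.5 else init$tau1
  tau2_0 <- if (is.null(init$tau2)) 2.5 else init$tau2
  best <- NULL
  for (a2_0 in a2_starts) {
    p0 <- pmin(pmax(c(sum(y), a2_0, tau1_0, tau2_0), lower), pmin(upper, 1e12))
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) stop("fit failure: optimizer did not converge")
  p <- best$fit$par
  structure(list(
    a1 = 1 - p[2L], a2 = p[2L],
    tau1_ns = p[3L], tau2_ns = p[4L],
    tau_m_ns = mean_lifetime(1 - p[2L], p[3L], p[2L], p[4L]),
    amplitude = p[1L],
    residual_norm = best$rn,
    converged = best$fit$info %in% 1:4
  ), class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> a2 = %.3f, tau1 = %.3f ns, tau2 = %.3f ns, tau_m = %.3f ns (resid %.3g)\n",
    x$a2, x$tau1_ns, x$tau2_ns, x$tau_m_ns, x$residual_norm))
  invisible(x)
}

#' Build a per-pixel a2 map from decay data
#'
#' Three input forms are accepted: an existing FLIM `image_field` (returned
#' unchanged, the passthrough used when a2 maps are simulated directly); a
#' 3-D array of bin counts with dimensions (time, row, col) plus shared
#' `bin_edges_ns`; or a list of `decay_curve` objects in row-major order with
#' `ny`/`nx` supplied. Pixels whose total photon count falls below
#' `min_photons` are marked background (a2 = 0 and a TRUE entry in the
#' `background` attribute).
#'
#' @param x input (see above).
#' @param bin_edges_ns bin edges for the array form.
#' @param ny,nx map size for the list form.
#' @param min_photons minimum photons per pixel for fitting (default 100).
#' @param tau_mode `"per_pixel"` fits all four parameters per pixel;
#'   `"global"` fixes the two lifetimes (`tau1_ns`, `tau2_ns`) and solves a
#'   fast non-negative two-component amplitude problem per pixel.
#' @param tau1_ns,tau2_ns lifetimes used in `"global"` mode.
#' @param ... passed on to [fit_biexponential()].
#' @return `image_field` with modality `"FLIM_A2"`; pixel values in \[0, 1\],
#'   attribute `background` a logical matrix.
#' @export
build_a2_map <- function(x, bin_edges_ns = NULL, ny = NULL, nx = NULL,
                         min_photons = 100,
                         tau_mode = c("per_pixel", "global"),
                         tau1_ns = 0.4, tau2_ns = 2.5, ...) {
  tau_mode <- match.arg(tau_mode)
  if (inherits(x, "image_field")) {
    if (x$modality != "FLIM_A2") stop("passthrough requires a FLIM_A2 field")
    return(x)
  }
  if (is.list(x) && !is.array(x)) {
    if (is.null(ny) || is.null(nx)) stop("ny and nx required for list input")
    if (length(x) != ny * nx) stop("need ny * nx decay curves")
    ref <- x[[1L]]$bin_edges_ns
    same <- vapply(x, function(d) isTRUE(all.equal(d$bin_edges_ns, ref)),
                   logical(1))
    if (!all(same)) stop("mixed bin axes: all decays must share the time-bin axis")
    arr <- array(0, dim = c(length(ref) - 1L, ny, nx))
    for (i in seq_along(x)) {
      r <- ((i - 1L) %% ny) + 1L
      cc <- ((i - 1L) %/% ny) + 1L
      arr[, r, cc] <- x[[i]]$counts
    }
    x <- arr
    bin_edges_ns <- ref
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("x must be a 3-D array (time, row, col), a list of decay curves, ",
         "or an image_field")
  }
  if (is.null(bin_edges_ns)) stop("bin_edges_ns required for array input")
  d <- dim(x)
  a2 <- matrix(0, d[2L], d[3L])
  bg <- matrix(TRUE, d[2L], d[3L])
  q1 <- decay_bin_probs(bin_edges_ns, tau1_ns)
  q2 <- decay_bin_probs(bin_edges_ns, tau2_ns)
  for (r in seq_len(d[2L])) {
    for (cc in seq_len(d[3L])) {
      cnt <- x[, r, cc]
      if (sum(cnt) < min_photons) next
      bg[r, cc] <- FALSE
      if (tau_mode == "per_pixel") {
        fit <- fit_biexponential(
          list(bin_edges_ns = bin_edges_ns, counts = cnt), ...)
        a2[r, cc] <- fit$a2
      } else {
        a2[r, cc] <- fit_amplitudes_nnls(cnt, q1, q2)
      }
    }
  }
  structure(list(pixels = a2, modality = "FLIM_A2",
                 width = d[3L], height = d[2L], day = NA_integer_,
                 seed = NA_integer_,
                 ground_truth = NULL, background = bg),
            class = "image_field")
}

# Two-component non-negative weighted least squares for fixed lifetimes;
# returns a2 = c2 / (c1 + c2).
#' @keywords internal
fit_amplitudes_nnls <- function(counts, q1, q2) {
  w <- 1 / pmax(counts, 1)
  xtx <- matrix(c(sum(w * q1 * q1), sum(w * q1 * q2),
                  sum(w * q1 * q2), sum(w * q2 * q2)), 2L, 2L)
  xty <- c(sum(w * q1 * counts), sum(w * q2 * counts))
  cf <- tryCatch(solve(xtx, xty), error = function(e) c(NA_real_, NA_real_))
  if (anyNA(cf) || any(cf < 0)) {
    # active-set fallback: best single-component solution
    c1 <- max(0, sum(w * q1 * counts) / sum(w * q1 * q1))
    c2 <- max(0, sum(w * q2 * counts) / sum(w * q2 * q2))
    r1 <- sum(w * (counts - c1 * q1)^2)
    r2 <- sum(w * (counts - c2 * q2)^2)
    cf <- if (r1 <= r2) c(c1, 0) else c(0, c2)
  }
  if (sum(cf) <= 0) return(0)
  cf[2L] / sum(cf)
}
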
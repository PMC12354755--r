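#' Plausible-values sample correlations
#'
#' For every MCMC draw, computes the Pearson correlation between the
#' draw's per-participant atomoxetine effects on a natural-scale
#' parameter (atomoxetine minus placebo, computed inside the draw, never
#' from point estimates) and an observed per-participant covariate. The
#' resulting distribution of "plausible" correlation coefficients
#' propagates the estimation uncertainty of the participant-level
#' parameters into the correlation analysis.
#'
#' @param samples A crossover `ql_posterior`.
#' @param covariate Named numeric vector, one finite value per
#'   participant (names matching the fit's participant ids; an unnamed
#'   vector in fit order is accepted).
#' @param parameter `"alpha"` or `"beta"`.
#' @return An object of class `plausible_correlation`: list with
#'   `sample_level` (one r per usable draw), `n_participants`,
#'   `n_dropped` (draws with zero-variance effects, excluded), `parameter`,
#'   `summary` (median, 89% HDI, p_dir of the r distribution).
#' @export
plausible_sample_correlations <- function(samples, covariate,
                                          parameter = c("alpha", "beta")) {
  parameter <- match.arg(parameter)
  ids <- samples$metadata$participants
  if (length(covariate) != length(ids)) {
    stop("covariate must have one value per participant", call. = FALSE)
  }
  if (!is.null(names(covariate))) {
    if (!all(ids %in% names(covariate))) {
      stop("covariate names must match participant ids", call. = FALSE)
    }
    covariate <- covariate[ids]
  }
  if (!all(is.finite(covariate))) {
    stop("covariate must be finite", call. = FALSE)
  }
  if (sd(covariate) == 0) stop("zero-variance covariate", call. = FALSE)
  if (length(ids) < 3L) stop("need at least 3 participants", call. = FALSE)

  eff <- participant_natural_draws(samples, parameter, "atomoxetine") -
    participant_natural_draws(samples, parameter, "placebo")
  sds <- apply(eff, 1, sd)
  ok <- is.finite(sds) & sds > 0
  r <- as.numeric(cor(t(eff[ok, , drop = FALSE]), covariate))
  structure(list(sample_level = r,
                 n_participants = length(ids),
                 n_dropped = sum(!ok),
                 parameter = parameter,
                 covariate = covariate,
                 summary = list(median = median(r), hdi = hdi(r),
                                p_dir = probability_of_direction(r))),
            class = "plausible_correlation")
}

# Gauss hypergeometric 2F1(1/2, 1/2; c; z) by series, vectorised over z.
# Converges for z < 1; with c = n - 1/2 the terms decay fast for the
# sample sizes used here.
.hyp2f1_half <- function(c_par, z, tol = 1e-12, max_terms = 500L) {
  term <- rep(1, length(z))
  out <- term
  for (k in 0:(max_terms - 1L)) {
    term <- term * ((0.5 + k)^2 / ((c_par + k) * (k + 1))) * z
    out <- out + term
    if (max(abs(term)) < tol) break
  }
  out
}

#' Posterior density of a population correlation given an observed r
#'
#' Unnormalised posterior density of the population Pearson correlation
#' `rho` given a sample correlation `r` from `n` bivariate-normal
#' observations, under a uniform prior on (-1, 1): the sampling density
#' of r as a function of rho,
#' `(1 - rho^2)^((n - 1) / 2) (1 - rho r)^(-(n - 3 / 2))
#'  2F1(1/2, 1/2; n - 1/2; (rho r + 1) / 2)`.
#'
#' @param rho Grid of population correlation values in (-1, 1).
#' @param r Observed sample correlation in (-1, 1).
#' @param n Number of participants (>= 4).
#' @return Unnormalised density values over `rho`.
#' @export
rho_posterior_density <- function(rho, r, n) {
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  exp(((n - 1) / 2) * log1p(-rho^2) -
        (n - 1.5) * log1p(-rho * r)) *
    .hyp2f1_half(n - 0.5, (rho * r + 1) / 2)
}

#' Population posterior of the correlation from plausible values
#'
#' Averages, across MCMC draws, the analytic posterior density of the
#' population correlation given each draw's sample correlation: each
#' per-draw posterior is evaluated on an equally spaced grid of rho
#' values, normalised (trapezoid rule), and the normalised densities are
#' averaged. The mean posterior supports inference on the latent
#' correlation in the population, complementing the sample-level
#' distribution of plausible r values.
#'
#' @param r Numeric vector of per-draw sample correlations (a
#'   `plausible_correlation` is also accepted).
#' @param n_participants Number of participants underlying each r (>= 4).
#' @param grid_resolution Number of equally spaced grid points on
#'   (-0.999, 0.999); default 1999.
#' @return An object of class `population_correlation_posterior`: list
#'   with `rho` (grid), `density` (mean normalised posterior), `summary`
#'   (median, 89% HDI, p_dir, all computed from the density), `n_clipped`
#'   (draws with |r| = 1, clipped to 1 - 1e-9).
#' @export
population_correlation_posterior <- function(r, n_participants,
                                             grid_resolution = 1999L) {
  if (inherits(r, "plausible_correlation")) {
    n_participants <- r$n_participants
    r <- r$sample_level
  }
  if (n_participants < 4L) stop("need n_participants >= 4", call. = FALSE)
  if (grid_resolution < 9L) stop("grid too coarse", call. = FALSE)
  clip <- abs(r) >= 1
  r[clip] <- sign(r[clip]) * (1 - 1e-9)

  rho <- seq(-0.999, 0.999, length.out = grid_resolution)
  drho <- rho[2] - rho[1]
  # density matrix grid x draws, built draw-blockwise to bound memory
  dens <- numeric(length(rho))
  block <- 500L
  n_draws <- length(r)
  base <- ((n_participants - 1) / 2) * log1p(-rho^2)
  for (s in seq(1L, n_draws, by = block)) {
    idx <- s:min(n_draws, s + block - 1L)
    z <- outer(rho, r[idx])           # rho * r
    m <- exp(base - (n_participants - 1.5) * log1p(-z)) *
      .hyp2f1_half(n_participants - 0.5, (z + 1) / 2)
    # trapezoid normalisation per draw (column)
    w <- drho * (colSums(m) - 0.5 * (m[1, ] + m[nrow(m), ]))
    dens <- dens + rowSums(sweep(m, 2, w, "/"))
  }
  dens <- dens / n_draws

  cum <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * drho))
  total <- cum[length(cum)]
  cdf <- cum / total
  med <- stats::approx(cdf, rho, xout = 0.5, ties = "ordered")$y
  mass_pos <- 1 - stats::approx(rho, cdf, xout = 0, ties = "ordered")$y
  p_dir <- 100 * max(mass_pos, 1 - mass_pos)
  hdi_int <- .density_hdi(rho, dens / total, mass = 0.89)

  structure(list(rho = rho, density = dens / total,
                 summary = list(median = med, hdi = hdi_int,
                                p_dir = p_dir),
                 n_participants = n_participants,
                 n_clipped = sum(clip)),
            class = "population_correlation_posterior")
}

# Narrowest grid interval holding `mass`, from a normalised density on an
# equally spaced grid: include points from highest density downward.
.density_hdi <- function(x, dens, mass = 0.89) {
  dx <- x[2] - x[1]
  ord <- order(dens, decreasing = TRUE)
  cm <- cumsum(dens[ord] * dx)
  k <- which(cm >= mass)[1]
  inc <- sort(ord[seq_len(k)])
  c(lower = x[inc[1]], upper = x[inc[length(inc)]])
}

#' @export
print.population_correlation_posterior <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Population correlation posterior (n = %d): median = %.3f, 89%% HDI [%.3f, %.3f], p_dir = %.1f%%\n",
    x$n_participants, s$median, s$hdi[1], s$hdi[2], s$p_dir))
  invisible(x)
}
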
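#' Simulate the optimal (alpha, beta) combination for a task
#'
#' Grid simulation of mean hit rate over the joint parameter space: for
#' every (alpha, beta) cell, `n_agents_per_cell` Q-learning agents are
#' forward-simulated on freshly drawn schedules of the given condition and
#' their hit rates averaged. "Optimal" is the grid argmax of the mean
#' hit-rate surface. In a stable probabilistic reward environment the
#' optimal inverse temperature sits at the top of its range (here 10).
#'
#' @param condition `"gain"` or `"loss"` (payoffs +0.5/0 or 0/-0.5; the
#'   hit-rate definition -- choose the advantageous option -- is shared).
#' @param alpha_step,beta_step Grid steps over \[0, 1\] and \[0, 10\]
#'   (defaults 0.02 and 0.25).
#' @param n_agents_per_cell Simulated agents per cell (default 1000).
#' @param n_trials Trials per simulated agent (default 48).
#' @param contingency Probability that the advantageous option carries the
#'   better outcome (default 0.75).
#' @param seed Optional integer seed.
#' @return An object of class `optimal_point`: list with `alpha_star`,
#'   `beta_star`, `hit_rate_surface` (matrix alpha x beta with dimnames),
#'   `alpha_grid`, `beta_grid`, `condition`.
#' @examples
#' opt <- simulate_optimal_grid("gain", alpha_step = 0.25, beta_step = 2.5,
#'                              n_agents_per_cell = 50, seed = 1)
#' opt$beta_star
#' @export
simulate_optimal_grid <- function(condition = c("gain", "loss"),
                                  alpha_step = 0.02, beta_step = 0.25,
                                  n_agents_per_cell = 1000L,
                                  n_trials = 48L, contingency = 0.75,
                                  seed = NULL) {
  condition <- match.arg(condition)
  if (alpha_step <= 0 || alpha_step > 1 || beta_step <= 0 ||
      beta_step > 10) {
    stop("degenerate grid steps", call. = FALSE)
  }
  if (n_agents_per_cell < 1L) stop("n_agents_per_cell must be >= 1",
                                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alphas <- seq(0, 1, by = alpha_step)
  betas <- seq(0, 10, by = beta_step)
  if (condition == "gain") {
    pay_good <- 0.5; pay_bad <- 0
  } else {
    pay_good <- 0; pay_bad <- -0.5
  }
  surf <- cpp_grid_hitrate(alphas, betas, as.integer(n_agents_per_cell),
                           as.integer(n_trials), contingency,
                           pay_good, pay_bad)
  dimnames(surf) <- list(alpha = formatC(alphas), beta = formatC(betas))
  idx <- arrayInd(which.max(surf), dim(surf))
  structure(list(alpha_star = alphas[idx[1]], beta_star = betas[idx[2]],
                 hit_rate_surface = surf, alpha_grid = alphas,
                 beta_grid = betas, condition = condition),
            class = "optimal_point")
}

#' @export
print.optimal_point <- function(x, ...) {
  cat(sprintf(
    "Optimal %s-condition parameters: alpha* = %.3g, beta* = %.3g (max hit rate %.3f)\n",
    x$condition, x$alpha_star, x$beta_star, max(x$hit_rate_surface)))
  invisible(x)
}

#' Joint-parameter-space distance posterior
#'
#' For each MCMC draw, the Euclidean distance between the group-level
#' natural-scale means (alpha, beta) and the optimal point, in raw natural
#' units (alpha in \[0, 1\], beta in \[0, 10\]; beta therefore dominates
#' the distance, mirroring the joint-space axes). For crossover fits the
#' drug contrast `distance(atomoxetine) - distance(placebo)` is also
#' returned; negative values mean atomoxetine is closer to optimal.
#'
#' @param samples A `ql_posterior`.
#' @param optimal An `optimal_point` from [simulate_optimal_grid()].
#' @param drug_state Drug states to evaluate; defaults to both for
#'   crossover fits.
#' @param normalise If `TRUE`, axes are rescaled to \[0, 1\] before the
#'   distance (alpha unchanged, beta / 10). Off by default.
#' @return A list with per-state distance vectors (`placebo`,
#'   `atomoxetine` as applicable) and, for crossover fits, `contrast`.
#' @export
joint_distance_posterior <- function(samples, optimal,
                                     drug_state = NULL,
                                     normalise = FALSE) {
  stopifnot(inherits(samples, "ql_posterior"),
            inherits(optimal, "optimal_point"))
  crossover <- samples$metadata$model == "crossover"
  if (is.null(drug_state)) {
    drug_state <- if (crossover) c("placebo", "atomoxetine") else "placebo"
  }
  sc <- if (normalise) 10 else 1
  out <- list()
  for (st in drug_state) {
    a <- group_natural_draws(samples, "alpha", st)
    b <- group_natural_draws(samples, "beta", st)
    out[[st]] <- sqrt((a - optimal$alpha_star)^2 +
                        ((b - optimal$beta_star) / sc)^2)
  }
  if (all(c("placebo", "atomoxetine") %in% names(out))) {
    out$contrast <- out$atomoxetine - out$placebo
  }
  out
}
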
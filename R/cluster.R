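#' Paired cluster-mass permutation test over time
#'
#' Compares two within-subject conditions of a time-resolved signal
#' (e.g., the z-scored pupil temporal derivative averaged per participant)
#' with cluster-based permutation inference. Per timepoint a paired
#' t-statistic is computed across participants; contiguous runs of
#' |t| above a cluster-forming threshold are clusters (separately per
#' sign), with cluster mass statistic (CMS) the sum of t within the run.
#' The null distribution is the maximum |CMS| per permutation under
#' random within-participant condition-label flips (family-wise control
#' across time); two-sided inference pools both signs into one null.
#' Cluster p-values are `(1 + #(null >= |CMS|)) / (1 + n_permutations)`,
#' so they can never fall below `1 / (1 + n_permutations)`.
#'
#' @param matrix_a,matrix_b Numeric matrices (participants x timepoints),
#'   same participants in the same row order (paired design).
#' @param n_permutations Number of sign-flip permutations (default 2000).
#' @param seed Optional integer seed.
#' @param threshold Cluster-forming threshold on |t|; default is the
#'   two-sided 0.05 critical value of the t distribution with
#'   `nrow - 1` degrees of freedom.
#' @param times Optional vector of timepoint labels (e.g., ms) used to
#'   report cluster extents; defaults to column indices.
#' @return An object of class `cluster_result`: data frame `clusters`
#'   with `start`, `end` (in `times` units), `start_idx`, `end_idx`,
#'   `cms`, `p_value`, `direction` (`"a>b"`/`"b>a"`), plus fields
#'   `n_permutations`, `threshold`, `t` (observed t series).
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(10 * 50), 10)
#' b <- matrix(rnorm(10 * 50), 10)
#' cluster_permutation_test(a, b, n_permutations = 200, seed = 1)
#' @export
cluster_permutation_test <- function(matrix_a, matrix_b,
                                     n_permutations = 2000L,
                                     seed = NULL, threshold = NULL,
                                     times = NULL) {
  stopifnot(is.matrix(matrix_a), is.matrix(matrix_b))
  if (!all(dim(matrix_a) == dim(matrix_b))) {
    stop("matrices must have identical dimensions (paired design)",
         call. = FALSE)
  }
  n <- nrow(matrix_a)
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(threshold)) threshold <- qt(0.975, df = n - 1L)
  if (is.null(times)) times <- seq_len(ncol(matrix_a))

  d <- matrix_a - matrix_b
  t_obs <- .paired_t(d)

  # observed clusters per sign
  clusters <- .find_clusters(t_obs, threshold)

  # permutation null: sign flips; SS per timepoint is flip-invariant
  ss <- colSums(d^2)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  m <- (signs %*% d) / n
  v <- sweep(-n * m^2, 2, ss, "+") / (n - 1)
  tmat <- m / sqrt(v / n)
  tmat[!is.finite(tmat)] <- 0
  null_max <- cpp_max_cms(tmat, threshold)

  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$cms, function(cm) {
      (1 + sum(null_max >= abs(cm))) / (1 + n_permutations)
    }, numeric(1))
    clusters$start <- times[clusters$start_idx]
    clusters$end <- times[clusters$end_idx]
    clusters$direction <- ifelse(clusters$cms > 0, "a>b", "b>a")
    clusters <- clusters[c("start", "end", "start_idx", "end_idx",
                           "cms", "p_value", "direction")]
  } else {
    clusters <- data.frame(start = numeric(0), end = numeric(0),
                           start_idx = integer(0), end_idx = integer(0),
                           cms = numeric(0), p_value = numeric(0),
                           direction = character(0))
  }
  structure(list(clusters = clusters, n_permutations = n_permutations,
                 threshold = threshold, t = t_obs,
                 null_max = null_max),
            class = "cluster_result")
}

.paired_t <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- 0  # zero-variance timepoints count as no effect
  t
}

.find_clusters <- function(t, threshold) {
  lab <- ifelse(t > threshold, 1L, ifelse(t < -threshold, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0L)
  if (!length(keep)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      cms = numeric(0)))
  }
  data.frame(
    start_idx = starts[keep], end_idx = ends[keep],
    cms = vapply(keep, function(k) sum(t[starts[k]:ends[k]]), numeric(1)))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: threshold |t| > %.3f, %d permutations\n",
              x$threshold, x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters) else cat("no suprathreshold clusters\n")
  invisible(x)
}
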
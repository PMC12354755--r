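#' Read / write posterior samples
#'
#' Loss-free round trip of a `ql_posterior` through plain text: a
#' long-format CSV (`chain, iteration, parameter, value`, values printed
#' at full precision) plus a JSON metadata sidecar (`<path>.json`).
#'
#' @param samples A `ql_posterior`.
#' @param path CSV file path; metadata goes to `paste0(path, ".json")`.
#' @return `read_posterior_samples` returns a `ql_posterior`;
#'   `write_posterior_samples` returns `path` invisibly.
#' @export
write_posterior_samples <- function(samples, path) {
  stopifnot(inherits(samples, "ql_posterior"))
  nd <- nrow(samples$draws)
  np <- ncol(samples$draws)
  iter_within <- stats::ave(seq_len(nd), samples$chain, FUN = seq_along)
  long <- data.frame(
    chain = rep(samples$chain, np),
    iteration = rep(iter_within, np),
    parameter = rep(colnames(samples$draws), each = nd),
    value = sprintf("%.17g", as.numeric(samples$draws)))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(samples$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior_samples
#' @export
read_posterior_samples <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  md <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pars <- unique(long$parameter)
  ord <- order(long$chain, long$iteration)
  first <- long[long$parameter == pars[1], ]
  first <- first[order(first$chain, first$iteration), ]
  draws <- vapply(pars, function(p) {
    v <- long[long$parameter == p, ]
    as.numeric(v$value[order(v$chain, v$iteration)])
  }, numeric(nrow(first)))
  colnames(draws) <- pars
  structure(list(draws = draws, chain = first$chain, metadata = md),
            class = "ql_posterior")
}

#' Write a JSON report for a posterior contrast
#'
#' Median, 89% HDI, probability of direction, ROPE percentage and the
#' accept/reject/undecided label, in one JSON object.
#'
#' @param x Numeric vector of per-draw contrast values.
#' @param group_sd Positive SD point estimate defining the ROPE.
#' @param path Output JSON path.
#' @param label Contrast label recorded in the report.
#' @return The summary list, invisibly.
#' @export
write_contrast_summary <- function(x, group_sd, path, label = "contrast") {
  s <- summarize_contrast(x, group_sd)
  report <- list(label = label, median = s$median,
                 hdi_89 = as.list(s$hdi), p_dir = s$p_dir,
                 rope_pct = s$rope_pct, decision = s$decision)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
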
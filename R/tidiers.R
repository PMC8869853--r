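# broom-style accessors for comparison objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a routed comparison
#'
#' @param x An `shg_comparison` from [compare_paired()] or
#'   [compare_unpaired()].
#' @param ... Unused.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`, `n`,
#'   `route`, `flags`.
#' @exportS3Method generics::tidy
tidy.shg_comparison <- function(x, ...) {
  tibble::tibble(
    test_name = x$test_name,
    statistic = x$statistic,
    p_value = x$p_value,
    n = max(x$n),
    route = x$route$route,
    flags = if (length(x$flags)) paste(x$flags, collapse = ";") else ""
  )
}

#' Group summaries of a routed comparison
#'
#' @param x An `shg_comparison`.
#' @param ... Unused.
#' @return Tibble of per-group `n`, `mean`, `sem` (the form in which group
#'   results are conventionally reported), plus the test and p-value.
#' @exportS3Method generics::glance
glance.shg_comparison <- function(x, ...) {
  x$summaries |>
    dplyr::mutate(test_name = x$test_name, p_value = x$p_value)
}

#' @export
print.shg_comparison <- function(x, ...) {
  cat(sprintf("<%s> (%s route)\n", x$test_name, x$route$route))
  cat(sprintf("  statistic = %.4g, p = %.4g, n = %s\n",
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n",
                s$group[i], s$mean[i], s$sem[i], s$n[i]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.shg_scene <- function(x, ...) {
  cat(sprintf("<shg_scene> %d x %d", nrow(x$B), ncol(x$B)))
  if (!is.null(x$truth)) {
    cat(sprintf(", %d fibers, %d labeled pixels",
                length(x$truth$fibers), sum(x$truth$label > 0)))
  }
  cat("\n")
  invisible(x)
}
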
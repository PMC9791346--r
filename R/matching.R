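#' Match groups on auditory-only performance by iterative pair removal
#'
#' Equates mean auditory-only morph level between the CI and NH groups by
#' iteratively removing pairs consisting of the lowest-performing CI user
#' (largest morph level, since lower levels mean better performance) and the
#' highest-performing NH user (smallest morph level), until the absolute
#' difference in group mean morph level is minimal.
#'
#' With `strategy = "global"` every admissible removal count
#' k = 0, ..., n - min_group_size is evaluated and the smallest k attaining
#' the global minimum is returned (ties broken toward retaining more
#' participants). `strategy = "greedy"` stops at the first local minimum:
#' the largest k before the trace first increases.
#'
#' Ties among equal morph levels within a group are broken deterministically
#' by removing the participant with the lexicographically larger id first.
#'
#' @param ci_ml,nh_ml Numeric vectors of auditory-only mean morph levels;
#'   equal length >= `min_group_size`.
#' @param min_group_size Smallest admissible subgroup size (>= 2).
#' @param strategy `"global"` (default) or `"greedy"`.
#' @param ci_ids,nh_ids Optional participant ids (default `"CI1"...`,
#'   `"NH1"...`).
#' @return Object of class `match_result`: list with `removals` (k),
#'   `kept_ci`, `kept_nh`, `removed_ci`, `removed_nh` (id vectors),
#'   `mean_diff_trace` (|mean CI - mean NH| for k = 0..k_max),
#'   `achieved_diff` and `strategy`.
#' @export
#' @examples
#' m <- match_groups(c(140, 120, 100, 90), c(60, 80, 95, 100))
#' m$removals      # 2
#' m$achieved_diff # 2.5
match_groups <- function(ci_ml, nh_ml, min_group_size = 2L,
                         strategy = c("global", "greedy"),
                         ci_ids = NULL, nh_ids = NULL) {
  strategy <- match.arg(strategy)
  n <- length(ci_ml)
  if (length(nh_ml) != n) stop("groups must have equal size", call. = FALSE)
  if (min_group_size < 2) stop("min_group_size must be >= 2", call. = FALSE)
  if (n < min_group_size) stop("groups smaller than min_group_size", call. = FALSE)
  if (is.null(ci_ids)) ci_ids <- paste0("CI", seq_len(n))
  if (is.null(nh_ids)) nh_ids <- paste0("NH", seq_len(n))
  ci_ids <- as.character(ci_ids)
  nh_ids <- as.character(nh_ids)

  # removal order: CI worst-first (largest ML), NH best-first (smallest ML);
  # ML ties resolved by removing the larger id first
  ci_ord <- order(-ci_ml, ci_ids, method = "radix",
                  decreasing = c(FALSE, TRUE))
  nh_ord <- order(nh_ml, nh_ids, method = "radix",
                  decreasing = c(FALSE, TRUE))

  k_max <- n - min_group_size
  trace <- vapply(0:k_max, function(k) {
    keep_ci <- ci_ord[seq.int(k + 1L, n)]
    keep_nh <- nh_ord[seq.int(k + 1L, n)]
    abs(mean(ci_ml[keep_ci]) - mean(nh_ml[keep_nh]))
  }, numeric(1))

  k <- if (strategy == "global") {
    which.min(trace) - 1L # which.min returns the first (smallest k) minimum
  } else {
    up <- which(diff(trace) >= 0) # first k after which removal stops helping
    if (length(up)) up[1] - 1L else k_max
  }

  keep_ci <- ci_ord[seq.int(k + 1L, n)]
  keep_nh <- nh_ord[seq.int(k + 1L, n)]
  structure(
    list(
      removals = as.integer(k),
      kept_ci = sort(ci_ids[keep_ci]),
      kept_nh = sort(nh_ids[keep_nh]),
      removed_ci = ci_ids[ci_ord[seq_len(k)]],
      removed_nh = nh_ids[nh_ord[seq_len(k)]],
      mean_diff_trace = trace,
      achieved_diff = trace[k + 1L],
      strategy = strategy
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("Performance-matched subgroups (", x$strategy, " strategy)\n", sep = "")
  cat("  pairs removed:", x$removals, "\n")
  cat("  subgroup size:", length(x$kept_ci), "per group\n")
  cat("  achieved |mean CI - mean NH|:", format(x$achieved_diff, digits = 4), "\n")
  invisible(x)
}

#' Serialise a match result to JSON
#'
#' @param x A `match_result`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to file).
#' @export
match_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "match_result"))
  obj <- unclass(x)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
}
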
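# Exact piecewise-linear stage segmentation of pressurisation curves via
# dynamic programming.

.segment_sse_table <- function(x, y) {
  # SSE of the least-squares line over every contiguous window [i, j],
  # computed from running sums in O(n^2).
  n <- length(x)
  sse <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sx <- sy <- sxx <- sxy <- syy <- 0
    for (j in i:n) {
      sx <- sx + x[j]; sy <- sy + y[j]
      sxx <- sxx + x[j]^2; sxy <- sxy + x[j] * y[j]; syy <- syy + y[j]^2
      m <- j - i + 1
      vx <- sxx - sx * sx / m
      cxy <- sxy - sx * sy / m
      vy <- syy - sy * sy / m
      sse[i, j] <- if (vx > 1e-12) max(0, vy - cxy^2 / vx) else max(0, vy)
    }
  }
  sse
}

#' Segment a pressurisation curve into stages
#'
#' Fits `n_segments` contiguous least-squares lines to the
#' (particle count, RMSD) curve, choosing the breakpoints that minimise
#' the total squared error exactly (dynamic programming over all
#' partitions). Pressurisation runs typically show four stages:
#' cavity filling, side-chain rearrangement, expansion into free volume,
#' and late protein distension.
#'
#' @param curve Data frame whose first two columns are the x (e.g.
#'   `particle_count`) and y (e.g. `rmsd`) values, ordered in x.
#' @param n_segments Number of stages (default 4). Needs at least
#'   `2 * n_segments` points.
#' @return List of class `stage_segmentation`: `breakpoints` (x values of
#'   the last point in each of the first `n_segments - 1` segments),
#'   `segments` tibble (`segment`, `x_start`, `x_end`, `slope`,
#'   `intercept`, `sse`, `n_points`), and `total_sse`.
#' @export
segment_stages <- function(curve, n_segments = 4) {
  curve <- as.data.frame(curve)
  x <- as.numeric(curve[[1]]); y <- as.numeric(curve[[2]])
  n <- length(x)
  if (n < 2 * n_segments) {
    abort(paste0("segment_stages needs at least ", 2 * n_segments, " points"))
  }
  if (is.unsorted(x)) abort("curve must be ordered in its x column")
  sse <- .segment_sse_table(x, y)

  # dp[s, j]: minimal SSE covering points 1..j with s segments
  dp <- matrix(Inf, n_segments, n)
  back <- matrix(0L, n_segments, n)
  dp[1, ] <- sse[1, ]
  if (n_segments > 1) {
    for (s in 2:n_segments) {
      for (j in s:n) {
        # previous segment ends at e (>= s-1), current covers (e+1)..j
        e <- (s - 1):(j - 1)
        tot <- dp[s - 1, e] + sse[cbind(e + 1, j)]
        b <- which.min(tot)
        dp[s, j] <- tot[b]
        back[s, j] <- e[b]
      }
    }
  }
  ends <- integer(n_segments)
  ends[n_segments] <- n
  if (n_segments > 1) {
    for (s in n_segments:2) ends[s - 1] <- back[s, ends[s]]
  }
  starts <- c(1L, head(ends, -1) + 1L)
  segs <- purrr::map2(starts, ends, function(i, j) {
    xi <- x[i:j]; yi <- y[i:j]
    if (length(xi) > 1 && stats::var(xi) > 1e-12) {
      fit <- stats::lm.fit(cbind(1, xi), yi)
      cf <- fit$coefficients
    } else {
      cf <- c(mean(yi), 0)
    }
    tibble(x_start = x[i], x_end = x[j], slope = cf[2], intercept = cf[1],
           sse = sse[i, j], n_points = j - i + 1L)
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(segment = dplyr::row_number(), .before = 1)
  structure(list(breakpoints = x[head(ends, -1)],
                 breakpoint_index = head(ends, -1),
                 segments = segs, total_sse = dp[n_segments, n],
                 n_segments = n_segments),
            class = "stage_segmentation")
}

#' @export
print.stage_segmentation <- function(x, ...) {
  cat("<stage_segmentation> ", x$n_segments, " stages; breakpoints at x = ",
      paste(signif(x$breakpoints, 6), collapse = ", "),
      "; total SSE ", signif(x$total_sse, 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.stage_segmentation <- function(x, ...) x$segments

#' @export
glance.stage_segmentation <- function(x, ...) {
  tibble(n_segments = x$n_segments, total_sse = x$total_sse,
         breakpoints = paste(signif(x$breakpoints, 6), collapse = ","))
}
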
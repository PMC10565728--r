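#' Adaptive-landscape frames along a trajectory
#'
#' Evaluates the G-function on a strategy grid at every `stride`-th
#' recorded sample, once per distinct evolvability present among the
#' extant species at that time (the landscapes of two `k` values differ by
#' the constant `d * (k_1 - k_2)`, so the slow evolver's landscape always
#' lies above the fast evolver's).  Each frame also carries the marker
#' positions `(u_i, G(u_i))` of the extant species on their own landscape.
#'
#' @param trajectory An `evodyn_trajectory`.
#' @param v_grid Strategy grid; defaults to `[-12, 12]` in steps of 0.05,
#'   widened if needed to cover the observed strategies plus a margin of 2.
#' @param stride Evaluate every `stride`-th sample (default 50).
#' @return A list of frames (class `evodyn_landscape_series`); each frame
#'   has `time`, `v`, `G` (matrix, one row per `k`, row names the `k`
#'   values) and `markers` (data frame `id`, `k`, `u`, `x`, `G_u`).
#' @export
landscape_series <- function(trajectory, v_grid = NULL, stride = 50) {
  stopifnot(inherits(trajectory, "evodyn_trajectory"),
            "stride must be >= 1" = stride >= 1)
  params <- trajectory$params
  if (is.null(v_grid)) {
    lo <- min(-12, floor(min(trajectory$strategy, na.rm = TRUE)) - 2)
    hi <- max(12, ceiling(max(trajectory$strategy, na.rm = TRUE)) + 2)
    v_grid <- seq(lo, hi, by = 0.05)
  }
  rows <- seq(1, length(trajectory$times), by = stride)
  comm_tpl <- trajectory$community
  frames <- lapply(rows, function(r) {
    x <- trajectory$density[r, ]
    u <- trajectory$strategy[r, ]
    alive <- !is.na(x) & x > 0
    comm <- data.frame(id = comm_tpl$id, k = comm_tpl$k, u = u, x = x,
                       extant = alive, stringsAsFactors = FALSE)
    class(comm) <- c("evodyn_community", "data.frame")
    gamma <- trajectory$gamma[r]
    ks <- sort(unique(comm_tpl$k[alive]))
    if (!length(ks)) ks <- sort(unique(comm_tpl$k))
    G <- t(vapply(ks, function(k)
      fitness(v_grid, k, comm, gamma, params), numeric(length(v_grid))))
    rownames(G) <- as.character(ks)
    markers <- if (any(alive)) {
      data.frame(
        id = comm$id[alive], k = comm$k[alive], u = u[alive], x = x[alive],
        G_u = vapply(which(alive), function(i)
          fitness(u[i], comm$k[i], comm, gamma, params), numeric(1)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(id = character(0), k = numeric(0), u = numeric(0),
                 x = numeric(0), G_u = numeric(0))
    }
    structure(list(time = trajectory$times[r], v = v_grid, G = G,
                   k_values = ks, gamma = gamma, markers = markers),
              class = "evodyn_landscape_frame")
  })
  structure(frames, class = "evodyn_landscape_series")
}

#' @export
print.evodyn_landscape_series <- function(x, ...) {
  cat(sprintf("adaptive-landscape series: %d frames, t in [%g, %g], %d grid points\n",
              length(x), x[[1]]$time, x[[length(x)]]$time, length(x[[1]]$v)))
  invisible(x)
}
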
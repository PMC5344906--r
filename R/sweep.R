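#' Define a parameter sweep grid
#'
#' A sweep evaluates the model independently at every point of a 1- or 2-axis
#' parameter grid: each point is simulated from the deterministic default
#' initial state (no state carry-over between points, so results cannot depend
#' on the direction of parameter change) and the requested measures are
#' computed from that point's trajectory.
#'
#' @param axes named list of 1 or 2 numeric vectors of parameter values, e.g.
#'   `list(g_sd = seq(0.15, 0.40, by = 0.0025))`. Names must be valid
#'   [hb_params()] fields.
#' @param fixed named list of parameter overrides applied everywhere.
#' @param measures subset of `"rate"`, `"pattern"`, `"mle"`, `"isile"`, `"lz"`,
#'   `"n_isi_clusters"`.
#' @param duration recorded ms per point. Default 150,000, or 1,000,000 when
#'   `isile`/`lz` are requested (long series stabilize the embedding and
#'   complexity estimates); override for faster scans.
#' @param dt,equilibration integration protocol per point (ms).
#' @param slow_only sweep the 4-variable slow subsystem.
#' @param seed grid seed; each point derives its own seed from it and its row
#'   index, so results are reproducible and independent of worker count.
#' @return An `hb_sweep_grid` object.
#' @export
sweep_grid <- function(axes, fixed = list(),
                       measures = c("rate", "pattern"),
                       duration = NULL, dt = 0.025, equilibration = 30000,
                       slow_only = FALSE, seed = 1L) {
  stopifnot(is.list(axes), length(axes) %in% 1:2, !is.null(names(axes)))
  all_measures <- c("rate", "pattern", "mle", "isile", "lz", "n_isi_clusters")
  measures <- match.arg(measures, all_measures, several.ok = TRUE)
  valid <- names(hb_params())
  bad <- setdiff(c(names(axes), names(fixed)), valid)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(duration))
    duration <- if (any(c("isile", "lz") %in% measures)) 1e6 else 150000
  structure(list(axes = axes, fixed = fixed, measures = measures,
                 duration = duration, dt = dt, equilibration = equilibration,
                 slow_only = slow_only, seed = as.integer(seed)),
            class = "hb_sweep_grid")
}

point_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(idx) * 16807) %% 2147483647)
}

#' Run a parameter sweep
#'
#' Simulates every grid point independently and returns one row per point. A
#' point whose integration blows up is reported with `status = "failed"`
#' rather than aborting the sweep. With `workers > 1` points are distributed
#' over forked processes; per-point seeds depend only on the grid seed and the
#' point's index, so the table is identical for any worker count.
#'
#' @param grid an [sweep_grid()] object.
#' @param workers number of parallel workers (forked; default 1).
#' @return An `hb_sweep` tibble: axis columns, `status`, `n_spikes`, `rate`,
#'   `code`, `spikes_per_burst`, `mle`, `mle_significant`, `isile`,
#'   `isile_significant`, `lz`, `n_isi_clusters` (measures not requested are
#'   `NA`).
#' @export
run_sweep <- function(grid, workers = 1L) {
  stopifnot(inherits(grid, "hb_sweep_grid"))
  pts <- expand.grid(grid$axes, KEEP.OUT.ATTRS = FALSE)
  run1 <- function(i) sweep_point(grid, pts[i, , drop = FALSE], i)
  rows <- if (workers > 1) {
    parallel::mclapply(seq_len(nrow(pts)), run1, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(pts)), run1)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hb_sweep", class(out))
  out
}

sweep_point <- function(grid, pt, idx) {
  ax <- tibble::as_tibble(pt)
  base <- c(as.list(pt), grid$fixed)
  empty <- tibble::tibble(
    status = "ok", n_spikes = NA_real_, rate = NA_real_,
    code = NA_integer_, spikes_per_burst = NA_integer_,
    mle = NA_real_, mle_significant = NA,
    isile = NA_real_, isile_significant = NA,
    lz = NA_real_, n_isi_clusters = NA_real_
  )
  res <- tryCatch({
    params <- do.call(hb_params, base)
    stride <- max(1L, as.integer(round(0.25 / grid$dt)))  # ~0.25 ms trace sampling
    tr <- simulate_hb(params, duration = grid$duration, dt = grid$dt,
                      equilibration = grid$equilibration,
                      slow_only = grid$slow_only, record_stride = stride)
    train <- detect_spikes(tr)
    iv <- isi(train)
    m <- empty
    m$n_spikes <- length(train$times)
    if ("rate" %in% grid$measures) m$rate <- firing_rate(train)
    if ("pattern" %in% grid$measures) {
      cl <- classify_pattern(tr, train)
      m$code <- cl$code
      m$spikes_per_burst <- cl$spikes_per_burst
    }
    if ("mle" %in% grid$measures) {
      le <- mle_ode(params, total_time = min(grid$duration, 200000),
                    dt = grid$dt, slow_only = grid$slow_only,
                    equilibration = grid$equilibration,
                    seed = point_seed(grid$seed, idx))
      m$mle <- le$value
      m$mle_significant <- !le$saturated
    }
    if ("isile" %in% grid$measures) {
      m$isile_significant <- FALSE
      m$isile <- 0
      if (length(iv) >= 200) {
        le <- tryCatch(isi_lyapunov(iv), error = function(e) NULL)
        if (!is.null(le)) {
          m$isile <- le$value
          m$isile_significant <- le$chaotic
        }
      }
    }
    if ("lz" %in% grid$measures && length(iv) >= 2)
      m$lz <- lz_complexity(train)$normalized
    if ("n_isi_clusters" %in% grid$measures && length(iv) >= 10)
      m$n_isi_clusters <- count_distinct_intervals(iv)
    m
  }, error = function(e) {
    m <- empty
    m$status <- paste0("failed: ", conditionMessage(e))
    m
  })
  dplyr::bind_cols(ax, res)
}

#' ISI bifurcation diagram along one parameter
#'
#' Runs a single-axis sweep and emits every inter-spike interval observed at
#' every parameter value (long format, for scatter-style bifurcation plots),
#' together with the point's ISI-series Lyapunov exponent for coloring.
#'
#' @param grid a 1-axis [sweep_grid()].
#' @param min_isi_for_le minimum ISI count to attempt the Lyapunov fit.
#' @return Tibble with columns `param`, `value`, `isi`, `le`,
#'   `le_significant`, one row per interval.
#' @export
isi_bifurcation <- function(grid, min_isi_for_le = 200) {
  stopifnot(inherits(grid, "hb_sweep_grid"), length(grid$axes) == 1)
  pname <- names(grid$axes)[1]
  vals <- grid$axes[[1]]
  rows <- lapply(seq_along(vals), function(i) {
    base <- c(stats::setNames(list(vals[i]), pname), grid$fixed)
    params <- do.call(hb_params, base)
    tr <- simulate_hb(params, duration = grid$duration, dt = grid$dt,
                      equilibration = grid$equilibration,
                      slow_only = grid$slow_only,
                      record_stride = max(1L, as.integer(round(1 / grid$dt))))
    iv <- isi(detect_spikes(tr))
    if (!length(iv))
      return(tibble::tibble(param = pname, value = vals[i], isi = NA_real_,
                            le = NA_real_, le_significant = NA))
    le <- 0; sig <- FALSE
    if (length(iv) >= min_isi_for_le) {
      fit <- tryCatch(isi_lyapunov(iv), error = function(e) NULL)
      if (!is.null(fit)) { le <- fit$value; sig <- fit$chaotic }
    }
    tibble::tibble(param = pname, value = vals[i], isi = iv,
                   le = le, le_significant = sig)
  })
  dplyr::bind_rows(rows)
}
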
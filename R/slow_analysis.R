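#' Equilibria of the slow subsystem
#'
#' With the fast spiking pair removed (g_d = g_r = 0, a_r = 0) the
#' 4-dimensional slow subsystem's equilibria reduce to a scalar problem in V:
#' at rest each gate sits on its steady-state curve and the calcium proxy on
#' its nullcline `a_sr = -eta * I_sd / kappa`, so the equilibrium condition is
#' that the total membrane current vanish. The voltage axis is scanned on
#' `[-90, 20]` mV at 0.01 mV resolution for sign changes, each bracketed root
#' is polished with [stats::uniroot()], and stability is read from the
#' eigenvalues of the 4 x 4 numerical Jacobian.
#'
#' @param params an [hb_params()] object; `g_d`/`g_r` are forced to 0.
#' @param v_range voltage scan interval (mV).
#' @param v_step scan resolution (mV).
#' @return An `hb_equilibria` tibble, one row per equilibrium: `V_eq`, `a_sd`,
#'   `a_sr`, `a_h`, `stable`, `max_re_eigen`, and list-columns `eigenvalues`
#'   and `state`.
#' @export
find_equilibrium <- function(params, v_range = c(-90, 20), v_step = 0.01) {
  stopifnot(inherits(params, "hb_params"))
  p <- params
  p$g_d <- 0; p$g_r <- 0

  tf <- temperature_factors(p$temperature)
  rho <- tf[["rho"]]
  f <- function(V) {
    a_sd <- steady_state_activation(V, p$s_sd, p$V0_sd)
    I_sd <- rho * p$g_sd * a_sd * (V - p$E_sd)
    a_sr <- -p$eta * I_sd / p$kappa
    a_h <- steady_state_activation(V, p$s_h, p$V0_h)
    sr_gate <- a_sr^2 / (a_sr^2 + p$K_sr)
    I_sr <- rho * p$g_sr * sr_gate * (V - p$E_sr)
    I_h <- rho * p$g_h * a_h * (V - p$E_h)
    I_l <- rho * p$g_l * (V - p$E_l)
    I_sd + I_sr + I_h + I_l
  }
  vs <- seq(v_range[1], v_range[2], by = v_step)
  fv <- f(vs)
  sgn <- sign(fv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(fv == 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(f, c(vs[i], vs[i + 1]), tol = 1e-12)$root, numeric(1))
  roots <- sort(unique(c(roots, vs[exact])))
  if (!length(roots))
    stop("no equilibrium found in V range [", v_range[1], ", ", v_range[2], "] mV",
         call. = FALSE)

  rows <- lapply(roots, function(V) {
    a_sd <- steady_state_activation(V, p$s_sd, p$V0_sd)
    I_sd <- rho * p$g_sd * a_sd * (V - p$E_sd)
    st <- hb_state(V = V, a_r = 0, a_sd = a_sd,
                   a_sr = -p$eta * I_sd / p$kappa,
                   a_h = steady_state_activation(V, p$s_h, p$V0_h))
    J <- numeric_jacobian(st, p, slow_only = TRUE)
    ev <- eigen(J, only.values = TRUE)$values
    tibble::tibble(V_eq = V, a_sd = st[["a_sd"]], a_sr = st[["a_sr"]],
                   a_h = st[["a_h"]],
                   stable = max(Re(ev)) < 0,
                   max_re_eigen = max(Re(ev)),
                   eigenvalues = list(ev), state = list(st))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hb_equilibria", class(out))
  out
}

#' Return intervals through the equilibrium voltage
#'
#' Intervals between successive upward (positive-slope) crossings of a voltage
#' level, typically the slow subsystem's equilibrium voltage `V_eq` at the same
#' parameter point. Crossing times are interpolated; an empty result is valid
#' (e.g. a trajectory converging to a stable equilibrium).
#'
#' @param trajectory an `hb_trajectory` (normally `slow_only = TRUE`).
#' @param v_eq crossing level in mV. If the trajectory was simulated with
#'   `monitor = v_eq` the full-resolution crossings are used.
#' @return Numeric vector of intervals (ms).
#' @export
return_intervals <- function(trajectory, v_eq) {
  stopifnot(inherits(trajectory, "hb_trajectory"))
  times <- if (isTRUE(trajectory$monitor == v_eq)) {
    trajectory$monitor_times
  } else {
    upward_crossings(trajectory$trace$t, trajectory$trace$V, v_eq)
  }
  if (length(times) < 2) return(numeric(0))
  diff(times)
}

#' Count distinct interval values
#'
#' Greedy fixed-width grouping on the real line: the sorted intervals are
#' walked left to right and a new group starts whenever the current value lies
#' more than `tol` times the median interval above the start of the current
#' group. Two intervals count as "the same value" only when they differ by less
#' than that width, so a periodic series with small jitter counts its true
#' period while a continuous (aperiodic) band produces many groups. Series with
#' more than 32 groups are reported as `Inf` ("many"), the signature of chaos.
#' Used to detect period-doubling cascades (counts 1 -> 2 -> 4 -> ... -> many).
#'
#' @param intervals numeric vector of at least 10 intervals (ms).
#' @param tol relative width tolerance (default 0.02).
#' @return Number of distinct values (numeric; `Inf` when above 32).
#' @examples
#' count_distinct_intervals(rep(c(80, 120), 10))  # 2
#' @export
count_distinct_intervals <- function(intervals, tol = 0.02) {
  x <- as.numeric(intervals)
  if (length(x) < 10)
    stop("need at least 10 intervals to count distinct values", call. = FALSE)
  xs <- sort(x)
  thr <- tol * stats::median(xs)
  k <- 1L
  base <- xs[1]
  for (v in xs) {
    if (v - base > thr) {
      k <- k + 1L
      base <- v
      if (k > 32L) return(Inf)
    }
  }
  k
}

#' Equilibrium branch with Hopf and limit-point markers
#'
#' Sweeps one parameter and tracks the slow-subsystem equilibria found by
#' [find_equilibrium()] at every value (each point solved from scratch via the
#' voltage grid scan, so no branch seeding is required and folds are seen as
#' changes in the number of roots). Two event types are marked and refined by
#' bisection to `refine_tol` in the parameter: `HB` where the leading complex
#' eigenvalue pair of a tracked branch crosses the imaginary axis (Hopf
#' bifurcation: birth/death of a periodic orbit), and `LP` where the number of
#' equilibria changes (saddle-node / limit point).
#'
#' @param params base [hb_params()] (g_d/g_r forced to 0).
#' @param sweep_param parameter name to vary (e.g. `"g_sd"`).
#' @param from,to,step sweep range and step.
#' @param refine_tol bisection tolerance on the event parameter value.
#' @return An `hb_branch` tibble, one row per (parameter value, equilibrium):
#'   `param`, `value`, `V_eq`, `stable`, `max_re_eigen`, `max_re_complex`,
#'   `n_roots`; events in `attr(., "events")`, a tibble with `type`, `value`,
#'   `V_eq`.
#' @export
equilibrium_branch <- function(params, sweep_param, from, to, step,
                               refine_tol = 1e-5) {
  stopifnot(inherits(params, "hb_params"), step > 0, to > from)
  if (!sweep_param %in% names(params))
    stop("unknown parameter: ", sweep_param, call. = FALSE)
  at <- function(v) {
    p <- params
    p[[sweep_param]] <- v
    find_equilibrium(p)
  }
  values <- seq(from, to, by = step)
  eqs <- lapply(values, at)

  max_re_complex <- function(eq_row) {
    ev <- eq_row$eigenvalues[[1]]
    cx <- ev[abs(Im(ev)) > 1e-9]
    if (length(cx)) max(Re(cx)) else NA_real_
  }
  rows <- dplyr::bind_rows(lapply(seq_along(values), function(i) {
    e <- eqs[[i]]
    tibble::tibble(param = sweep_param, value = values[i], V_eq = e$V_eq,
                   stable = e$stable, max_re_eigen = e$max_re_eigen,
                   max_re_complex = vapply(seq_len(nrow(e)), function(r)
                     max_re_complex(e[r, ]), numeric(1)),
                   n_roots = nrow(e))
  }))

  events <- list()
  # principal branch: root closest in V to the previous principal root
  principal <- numeric(length(values))
  vprev <- NULL
  hq <- numeric(length(values))  # max Re of complex pair on principal branch
  for (i in seq_along(values)) {
    e <- eqs[[i]]
    j <- if (is.null(vprev)) which.min(abs(e$V_eq - stats::median(e$V_eq))) else which.min(abs(e$V_eq - vprev))
    vprev <- e$V_eq[j]
    principal[i] <- vprev
    hq[i] <- max_re_complex(e[j, ])
  }
  hq_at <- function(v) {
    e <- at(v)
    j <- which.min(abs(e$V_eq - stats::approx(values, principal, v, rule = 2)$y))
    max_re_complex(e[j, ])
  }
  for (i in seq_len(length(values) - 1)) {
    a <- hq[i]; b <- hq[i + 1]
    if (!is.na(a) && !is.na(b) && a * b < 0) {
      lo <- values[i]; hi <- values[i + 1]; fa <- a
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        fm <- hq_at(mid)
        if (is.na(fm)) break
        if (fa * fm <= 0) hi <- mid else { lo <- mid; fa <- fm }
      }
      vstar <- (lo + hi) / 2
      events[[length(events) + 1]] <-
        tibble::tibble(type = "HB", value = vstar,
                       V_eq = stats::approx(values, principal, vstar, rule = 2)$y)
    }
    nr_a <- nrow(eqs[[i]]); nr_b <- nrow(eqs[[i + 1]])
    if (nr_a != nr_b) {
      lo <- values[i]; hi <- values[i + 1]
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        if (nrow(at(mid)) == nr_a) lo <- mid else hi <- mid
      }
      vstar <- (lo + hi) / 2
      events[[length(events) + 1]] <-
        tibble::tibble(type = "LP", value = vstar,
                       V_eq = stats::approx(values, principal, vstar, rule = 2)$y)
    }
  }
  ev_tbl <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(type = character(), value = numeric(), V_eq = numeric())
  attr(rows, "events") <- ev_tbl
  class(rows) <- c("hb_branch", class(rows))
  rows
}

#' Events of an equilibrium branch
#'
#' @param branch an `hb_branch` from [equilibrium_branch()].
#' @return Tibble of bifurcation events (`type`, `value`, `V_eq`).
#' @export
branch_events <- function(branch) attr(branch, "events")
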
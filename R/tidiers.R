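#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for chaos-measure results
#'
#' Broom-style accessors. `tidy()` returns the per-component table of a fitted
#' result (per embedding dimension for an ISI Lyapunov fit, per equilibrium
#' for an equilibria table); `glance()` returns a one-row summary.
#'
#' @param x an `hb_isile`, `hb_mle` or `hb_lz` object.
#' @param ... unused.
#' @return A tibble.
#' @name hb-tidiers
NULL

#' @rdname hb-tidiers
#' @method tidy hb_isile
#' @export
tidy.hb_isile <- function(x, ...) x$per_dim

#' @rdname hb-tidiers
#' @method glance hb_isile
#' @export
glance.hb_isile <- function(x, ...) {
  tibble::tibble(value = x$value, significant = x$significant,
                 chaotic = x$chaotic,
                 n_dims_kept = sum(x$per_dim$kept),
                 advance = x$config$advance)
}

#' @rdname hb-tidiers
#' @method tidy hb_mle
#' @export
tidy.hb_mle <- function(x, ...) {
  tibble::tibble(value = x$value, value_per_s = x$value_per_s,
                 sat_fraction = x$sat_fraction, saturated = x$saturated,
                 n_renorm = x$n_renorm, system = x$system)
}

#' @rdname hb-tidiers
#' @method glance hb_mle
#' @export
glance.hb_mle <- function(x, ...) tidy.hb_mle(x, ...)

#' @rdname hb-tidiers
#' @method tidy hb_lz
#' @export
tidy.hb_lz <- function(x, ...) {
  tibble::tibble(c_n = x$c_n, b_n = x$b_n, normalized = x$normalized,
                 n = x$n, bin_width = x$bin_width)
}

#' @rdname hb-tidiers
#' @method glance hb_lz
#' @export
glance.hb_lz <- function(x, ...) tidy.hb_lz(x, ...)
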
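#' Surrogate interval series with known structure
#'
#' Generators for benchmark series used to validate the chaos estimators:
#' a constant series (degenerate, zero distances everywhere), a periodic
#' pattern (non-chaotic, should never yield a significant exponent), and a
#' logistic-map-driven series whose Lyapunov exponent is known analytically
#' (ln 2 per step at r = 4, mapped affinely into a positive ISI range so the
#' exponent is unchanged).
#'
#' @param n series length.
#' @param value interval value (ms) for the constant series.
#' @param pattern vector of interval values recycled periodically.
#' @param r logistic map parameter (default 4, the fully chaotic case).
#' @param x0 initial map state in (0, 1); `NULL` draws it from `seed`.
#' @param seed integer seed used when `x0` is `NULL`.
#' @param range target ISI range (ms) the unit interval is mapped onto.
#' @param burn_in discarded initial iterates.
#' @return Numeric vector of length `n`.
#' @examples
#' isi_periodic(6, c(10, 50))
#' @export
isi_constant <- function(n, value = 100) rep(value, n)

#' @rdname isi_constant
#' @export
isi_periodic <- function(n, pattern) rep_len(pattern, n)

#' @rdname isi_constant
#' @export
isi_logistic <- function(n, r = 4, x0 = NULL, seed = NULL,
                         range = c(10, 110), burn_in = 100) {
  if (is.null(x0)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    x0 <- stats::runif(1, 0.1, 0.9)
  }
  x <- numeric(n + burn_in)
  x[1] <- x0
  for (i in 2:(n + burn_in)) x[i] <- r * x[i - 1] * (1 - x[i - 1])
  range[1] + (range[2] - range[1]) * x[(burn_in + 1):(burn_in + n)]
}
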
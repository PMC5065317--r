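# Ordinary least-squares line plus Pearson correlation, used for pH
# slopes (mV per pH unit) and V_PEAK vs V_THR comparisons.

#' Linear fit with Pearson correlation
#'
#' @param x,y Paired observations (>= 2 points; >= 3 for a meaningful r).
#' @return A `linear_fit`: `slope`, `intercept`, `pearson_r`, `n`.
#' @examples
#' fit_line(c(5.5, 6.5, 7.5), c(66.3, 25.0, -15.7))  # ~ -41 mV/pH unit
#' @export
fit_line <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) .hv_err("need at least 2 points")
  if (stats::var(x) == 0) .hv_err("x has zero variance")
  cf <- stats::coef(stats::lm(y ~ x))
  r <- if (length(x) >= 3L && stats::var(y) > 0) stats::cor(x, y)
       else if (stats::var(y) == 0) NA_real_
       else sign(cf[[2]])
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 pearson_r = unname(r), n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(fit_summary_line(x), "\n")
  invisible(x)
}
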
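#' Moving windows along the latitude gradient
#'
#' Samples are sorted by ascending latitude (ties broken by sample id,
#' stable), and contiguous windows of `window_size` samples advance by one
#' sample, giving `n - window_size + 1` windows.
#'
#' @param metadata a [sample_metadata()].
#' @param window_size window length (>= 3, <= number of samples); the survey
#'   design uses 30 and 40.
#' @return Object of class `window_set`: `window_size`, `n_windows`,
#'   `order` (sample ids in gradient order), `windows` (list of index
#'   vectors into `order`).
#' @export
make_windows <- function(metadata, window_size) {
  stopifnot(inherits(metadata, "sample_metadata"))
  n <- nrow(metadata)
  if (window_size < 3 || window_size > n) {
    stop("window_size must be between 3 and the number of samples (", n, ")")
  }
  ord <- order(metadata$latitude, metadata$sample_id)
  nw <- n - window_size + 1
  structure(list(window_size = window_size,
                 n_windows = nw,
                 order = metadata$sample_id[ord],
                 windows = lapply(seq_len(nw), function(i) i:(i + window_size - 1))),
            class = "window_set")
}

#' Per-window BEF slopes and stochasticity ratios
#'
#' For every window: the standardized OLS slope of multifunctionality on
#' diversity (both z-scored within the window) together with the raw slope,
#' and the stochasticity ratio of the window's community subtable. A window
#' with zero diversity variance gets an undefined slope and is excluded from
#' the trend, which is a polynomial fit of slope against ST computed when at
#' least 10 usable windows exist.
#'
#' @param ws a [make_windows()] result.
#' @param diversity named per-sample diversity vector (names = sample ids).
#' @param mf named per-sample multifunctionality vector.
#' @param table [community_table()] or abundance matrix with sample
#'   rownames; the subcommunity whose assembly is being probed (default use:
#'   the rare pooled table).
#' @param n_null randomizations per window.
#' @param seed master seed; per-window seeds are derived deterministically.
#' @param trend_degree polynomial degree for the slope-vs-ST trend
#'   (2 by default; 1 gives plain linear fits).
#' @return Object of class `window_result`: `per_window` data frame
#'   (window, start, end, slope, standardized_slope, st, flagged), `trend`.
#' @export
window_bef_st <- function(ws, diversity, mf, table, n_null = 100, seed,
                          trend_degree = 2) {
  stopifnot(inherits(ws, "window_set"))
  m <- as_abundance_matrix(table)
  ids <- ws$order
  miss <- setdiff(ids, Reduce(intersect, list(names(diversity), names(mf), rownames(m))))
  if (length(miss)) stop("samples missing from inputs: ", paste(utils::head(miss, 5), collapse = ", "))
  per_window <- do.call(rbind, lapply(seq_along(ws$windows), function(w) {
    sel <- ids[ws$windows[[w]]]
    x <- diversity[sel]; y <- mf[sel]
    flagged <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (flagged) {
      slope <- NA_real_; std_slope <- NA_real_
    } else {
      fit <- bef_regression(x, y)
      slope <- fit$slope; std_slope <- fit$standardized_slope
    }
    sub <- m[sel, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    st <- stochasticity_ratio(sub, n_null = n_null, seed = derive_seed(seed, w))
    data.frame(window = w, start = ws$windows[[w]][1],
               end = ws$windows[[w]][ws$window_size],
               slope = slope, standardized_slope = std_slope,
               st = st$ST, flagged = flagged)
  }))
  ok <- !per_window$flagged
  trend <- NULL
  if (sum(ok) >= 10 && stats::sd(per_window$st[ok]) > 0) {
    trend <- polynomial_trend(per_window$st[ok], per_window$standardized_slope[ok],
                              degree = trend_degree)
  }
  structure(list(per_window = per_window, trend = trend,
                 window_size = ws$window_size),
            class = "window_result")
}

#' Polynomial least-squares trend
#'
#' OLS fit of `y = b0 + b1 x + ... + bd x^d` (default second order, the form
#' used for the ST trends) with two-sided coefficient p-values, overall
#' F-test p-value and R-squared.
#'
#' @param x predictor (not constant), length >= degree + 2.
#' @param y response.
#' @param degree polynomial degree (1 or 2 in practice).
#' @return List with `coefficients` (b0..bd), `p_values`, `r_squared`,
#'   `overall_p`, `n`, `degree`.
#' @export
polynomial_trend <- function(x, y, degree = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < degree + 2) stop("need at least degree + 2 points")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  sm <- summary(fit)
  coefs <- stats::setNames(as.numeric(stats::coef(fit)), paste0("b", 0:degree))
  pv <- stats::setNames(sm$coefficients[, 4], paste0("b", 0:degree))
  fstat <- sm$fstatistic
  overall_p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(coefficients = coefs, p_values = pv, r_squared = sm$r.squared,
       overall_p = unname(overall_p), n = length(x), degree = degree)
}
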
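#' Fit a power-law degree distribution
#'
#' Fits `p(k) ~ k^-gamma` to an observed degree sequence.  Degree-zero
#' nodes are excluded (p(0) is undefined on a log scale) and only degrees
#' with nonzero observed frequency enter the fit.
#'
#' Methods:
#' * `"wls"` (default): least squares of `log p(k)` on `log k`, weighted
#'   by the observed count at each degree.  Unweighted log-log regression
#'   gives every degree value one vote, so the long sparse tail — where a
#'   degree is typically seen once — dominates and drags the slope down;
#'   count weighting removes that bias while staying a transparent
#'   straight-line fit of the empirical frequencies.
#' * `"ls"`: the classic unweighted log-log regression.
#' * `"mle"`: maximum likelihood for the discrete power law truncated to
#'   the observed degree range (normalized over `1..max(k)`), via
#'   one-dimensional optimization.
#'
#' @param degrees Integer vector of node degrees (e.g. from
#'   [node_degrees()]).
#' @param method Fitting method, see above.
#' @return A `power_law_fit`: list with `gamma` (degree exponent > 0),
#'   `r_squared` (goodness of the log-log line; NA for `"mle"`),
#'   `fit_range` (degrees used), `method`, and `data` (tibble of degree,
#'   count, frequency).
#' @examples
#' set.seed(1)
#' k <- sample(1:50, 2000, replace = TRUE, prob = (1:50)^-2.5)
#' fit_power_law(k)$gamma
#' @export
fit_power_law <- function(degrees, method = c("wls", "ls", "mle")) {
  method <- match.arg(method)
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 3) {
    rlang::abort("need at least 3 distinct positive degrees to fit a power law")
  }
  freq <- cnt / sum(cnt)
  r2 <- NA_real_
  if (method == "mle") {
    kmax <- max(k)
    nll <- function(g) {
      q <- (seq_len(kmax))^(-g)
      q <- q / sum(q)
      -sum(cnt * log(q[k]))
    }
    gamma <- stats::optimize(nll, c(0.01, 10))$minimum
  } else {
    w <- if (method == "wls") cnt else rep(1, length(k))
    fit <- stats::lm(log(freq) ~ log(k), weights = w)
    gamma <- -unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  if (gamma <= 0) {
    rlang::warn("fitted degree exponent is not positive; degree distribution is not power-law-like")
  }
  structure(
    list(gamma = gamma, r_squared = r2, fit_range = range(k),
         method = method,
         data = tibble::tibble(degree = k, count = cnt, frequency = freq)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> gamma = ", signif(x$gamma, 5),
      " (", x$method, ", degrees ", x$fit_range[1], "..", x$fit_range[2],
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = "gamma", estimate = x$gamma)
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma,
    r_squared = x$r_squared,
    n_degrees = nrow(x$data),
    k_min = x$fit_range[1],
    k_max = x$fit_range[2],
    method = x$method
  )
}

#' Plot an observed degree distribution with its power-law fit
#'
#' Log-log scatter of empirical degree frequencies with the fitted
#' `k^-gamma` line.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$data
  # anchor the fitted line through the weighted fit on the plotted scale
  c0 <- exp(mean(log(d$frequency) + object$gamma * log(d$degree)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_function(
      fun = function(k) c0 * k^(-object$gamma),
      colour = "firebrick"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "degree k", y = "p(k)",
      title = sprintf("Degree distribution (gamma = %.2f)", object$gamma)
    )
}
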
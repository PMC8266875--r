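#' Parametric distribution specifications
#'
#' A `dist_spec` names one of the five stochastic input families used in the
#' exposure model -- point mass, uniform, triangular, normal, lognormal --
#' together with its parameters and an optional truncation interval. Every
#' stochastic quantity in the risk engine (concentration, intake rate,
#' exposure frequency and duration, body weight) is described by one of these
#' specs, so sampling, moments and quantiles all flow through a single,
#' seed-stable code path.
#'
#' Truncation is applied by restricting the quantile function to the truncated
#' CDF range (inverse-CDF truncation), never by rejection sampling, so a draw
#' of `n` values always has length exactly `n` and is reproducible under a
#' seed regardless of how tight the truncation is.
#'
#' @param value Point-mass location.
#' @param low,high Uniform bounds, `low < high`.
#' @param min,mode,max Triangular parameters, `min <= mode <= max`, `min < max`.
#' @param mean,sd Normal mean and standard deviation (`sd > 0`).
#' @param meanlog,sdlog Lognormal log-scale mean and standard deviation
#'   (`sdlog > 0`).
#' @param truncate Optional length-2 numeric `c(lower, upper)` truncation
#'   bounds; use `-Inf`/`Inf` for one-sided truncation. The interval must
#'   intersect the support with positive probability.
#'
#' @return An object of class `dist_spec`.
#' @examples
#' dist_triangular(1.12, 2.54, 3.87)
#' dist_normal(65, 12, truncate = c(0, Inf))
#' @name dist_spec
NULL

new_dist_spec <- function(family, params, truncate = NULL) {
  spec <- structure(
    list(family = family, params = params, truncate = truncate),
    class = "dist_spec"
  )
  validate_dist_spec(spec)
  spec
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  new_dist_spec("point", list(value = as.numeric(value)))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(low, high, truncate = NULL) {
  new_dist_spec("uniform", list(low = as.numeric(low), high = as.numeric(high)),
                truncate)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max, truncate = NULL) {
  new_dist_spec(
    "triangular",
    list(min = as.numeric(min), mode = as.numeric(mode), max = as.numeric(max)),
    truncate
  )
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, truncate = NULL) {
  new_dist_spec("normal", list(mean = as.numeric(mean), sd = as.numeric(sd)),
                truncate)
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog, truncate = NULL) {
  new_dist_spec(
    "lognormal",
    list(meanlog = as.numeric(meanlog), sdlog = as.numeric(sdlog)),
    truncate
  )
}

dist_families <- c("point", "uniform", "triangular", "normal", "lognormal")

validate_dist_spec <- function(spec) {
  if (!inherits(spec, "dist_spec")) {
    rlang::abort("`spec` must be a `dist_spec` object.", class = "fluorisk_error_spec")
  }
  fam <- spec$family
  if (!fam %in% dist_families) {
    rlang::abort(paste0("Unknown distribution family: ", fam),
                 class = "fluorisk_error_spec")
  }
  p <- spec$params
  bad <- function(msg) rlang::abort(msg, class = "fluorisk_error_spec")
  if (any(!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    bad(paste0(fam, " parameters must be finite numbers."))
  }
  switch(fam,
    point = NULL,
    uniform = if (p$low >= p$high) bad("uniform requires low < high."),
    triangular = {
      if (p$min > p$mode || p$mode > p$max) {
        bad("triangular requires min <= mode <= max.")
      }
      if (p$min >= p$max) bad("triangular requires min < max.")
    },
    normal = if (p$sd <= 0) bad("normal requires sd > 0."),
    lognormal = if (p$sdlog <= 0) bad("lognormal requires sdlog > 0.")
  )
  tr <- spec$truncate
  if (!is.null(tr)) {
    if (fam == "point") bad("point distributions cannot be truncated.")
    if (!is.numeric(tr) || length(tr) != 2 || anyNA(tr)) {
      bad("`truncate` must be numeric c(lower, upper).")
    }
    if (tr[1] >= tr[2]) bad("truncation bounds must satisfy lower < upper.")
    mass <- base_cdf(spec, tr[2]) - base_cdf(spec, tr[1])
    if (mass <= 0) {
      bad("truncation interval has zero probability under the distribution.")
    }
  }
  invisible(spec)
}

#' @export
format.dist_spec <- function(x, ...) {
  ps <- paste(names(x$params), signif(unlist(x$params), 6), sep = " = ",
              collapse = ", ")
  out <- paste0(x$family, "(", ps, ")")
  if (!is.null(x$truncate)) {
    out <- paste0(out, " truncated to [", x$truncate[1], ", ", x$truncate[2], "]")
  }
  out
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

# Untruncated CDF / quantile per family. Triangular uses its piecewise closed
# form; the others delegate to stats.
base_cdf <- function(spec, x) {
  p <- spec$params
  switch(spec$family,
    point = as.numeric(x >= p$value),
    uniform = stats::punif(x, p$low, p$high),
    triangular = ptri(x, p$min, p$mode, p$max),
    normal = stats::pnorm(x, p$mean, p$sd),
    lognormal = stats::plnorm(x, p$meanlog, p$sdlog)
  )
}

base_quantile <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, length(q)),
    uniform = stats::qunif(q, p$low, p$high),
    triangular = qtri(q, p$min, p$mode, p$max),
    normal = stats::qnorm(q, p$mean, p$sd),
    lognormal = stats::qlnorm(q, p$meanlog, p$sdlog)
  )
}

ptri <- function(x, a, c, b) {
  out <- numeric(length(x))
  out[x <= a] <- 0
  out[x >= b] <- 1
  i <- x > a & x < c
  out[i] <- (x[i] - a)^2 / ((b - a) * (c - a))
  # x == c falls through to the upper branch, which evaluates to (c-a)/(b-a)
  j <- x >= c & x < b
  out[j] <- 1 - (b - x[j])^2 / ((b - a) * (b - c))
  out
}

qtri <- function(q, a, c, b) {
  fc <- (c - a) / (b - a)
  out <- numeric(length(q))
  lo <- q <= fc
  out[lo] <- a + sqrt(q[lo] * (b - a) * (c - a))
  out[!lo] <- b - sqrt((1 - q[!lo]) * (b - a) * (b - c))
  out
}

trunc_range <- function(spec) {
  if (is.null(spec$truncate)) return(c(0, 1))
  c(base_cdf(spec, spec$truncate[1]), base_cdf(spec, spec$truncate[2]))
}

#' Distribution CDF and quantile function
#'
#' Closed-form cumulative distribution and inverse CDF for a [dist_spec],
#' honouring any truncation interval (the quantile function maps `[0, 1]`
#' onto the truncated support).
#'
#' @param spec A [dist_spec].
#' @param x Numeric vector of evaluation points.
#' @param q Numeric vector of probabilities in `[0, 1]`.
#' @return Numeric vector.
#' @export
dist_cdf <- function(spec, x) {
  validate_dist_spec(spec)
  r <- trunc_range(spec)
  p <- (base_cdf(spec, x) - r[1]) / (r[2] - r[1])
  pmin(pmax(p, 0), 1)
}

#' @rdname dist_cdf
#' @export
dist_quantile <- function(spec, q) {
  validate_dist_spec(spec)
  if (any(q < 0 | q > 1, na.rm = TRUE)) {
    rlang::abort("quantile probabilities must lie in [0, 1].",
                 class = "fluorisk_error_domain")
  }
  r <- trunc_range(spec)
  base_quantile(spec, r[1] + q * (r[2] - r[1]))
}

#' Draw a reproducible sample from a distribution specification
#'
#' Draws `n` independent values by inverse-CDF transform of uniforms, so a
#' truncated spec still yields exactly `n` values. When `seed` is supplied the
#' draw is bit-reproducible and the caller's RNG state is left untouched.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws (positive integer).
#' @param seed Optional integer seed for a reproducible stream.
#' @return Numeric vector of length `n`.
#' @examples
#' dist_sample(dist_triangular(0, 1, 2), 5, seed = 42)
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  validate_dist_spec(spec)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    rlang::abort("`n` must be a positive integer.", class = "fluorisk_error_domain")
  }
  if (spec$family == "point") return(rep(spec$params$value, n))
  u <- if (is.null(seed)) {
    stats::runif(n)
  } else {
    withr::with_seed(as.integer(seed), stats::runif(n))
  }
  dist_quantile(spec, u)
}

# Deterministic substream seed from (root seed, parameter name): adding or
# renaming one parameter never perturbs another parameter's draws. Kept below
# 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(root_seed, name) {
  codes <- utf8ToInt(name)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 2147483563
  as.integer((as.numeric(root_seed) %% 2147483563 * 37 + h + 1) %% 2147483562 + 1)
}

#' Closed-form mean and variance of a distribution specification
#'
#' Exact moments for every untruncated family, and for truncated uniform,
#' normal and lognormal specs. Truncated triangular moments are not
#' implemented (no closed form is used anywhere in the pipeline); a truncation
#' interval that does not actually bind (covers the whole support) is ignored.
#'
#' @param spec A [dist_spec].
#' @return A list with elements `mean` and `variance`.
#' @examples
#' dist_mean_var(dist_triangular(0, 1, 2)) # mean 1, variance 1/6
#' @export
dist_mean_var <- function(spec) {
  validate_dist_spec(spec)
  p <- spec$params
  r <- trunc_range(spec)
  binds <- !is.null(spec$truncate) && (r[1] > 0 || r[2] < 1)
  if (!binds) {
    return(switch(spec$family,
      point = list(mean = p$value, variance = 0),
      uniform = list(mean = (p$low + p$high) / 2,
                     variance = (p$high - p$low)^2 / 12),
      triangular = {
        a <- p$min; c <- p$mode; b <- p$max
        list(mean = (a + b + c) / 3,
             variance = (a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18)
      },
      normal = list(mean = p$mean, variance = p$sd^2),
      lognormal = list(
        mean = exp(p$meanlog + p$sdlog^2 / 2),
        variance = (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
      )
    ))
  }
  lo <- spec$truncate[1]; hi <- spec$truncate[2]
  switch(spec$family,
    uniform = {
      l <- max(p$low, lo); h <- min(p$high, hi)
      list(mean = (l + h) / 2, variance = (h - l)^2 / 12)
    },
    normal = {
      a <- (lo - p$mean) / p$sd
      b <- (hi - p$mean) / p$sd
      Z <- stats::pnorm(b) - stats::pnorm(a)
      da <- stats::dnorm(a); db <- stats::dnorm(b)
      m <- p$mean + p$sd * (da - db) / Z
      aT <- if (is.finite(a)) a * da else 0
      bT <- if (is.finite(b)) b * db else 0
      v <- p$sd^2 * (1 + (aT - bT) / Z - ((da - db) / Z)^2)
      list(mean = m, variance = v)
    },
    lognormal = {
      # partial expectations of the lognormal over [lo, hi]
      mu <- p$meanlog; s <- p$sdlog
      a <- if (lo <= 0) -Inf else (log(lo) - mu) / s
      b <- if (is.infinite(hi)) Inf else (log(hi) - mu) / s
      Z <- stats::pnorm(b) - stats::pnorm(a)
      m1 <- exp(mu + s^2 / 2) * (stats::pnorm(b - s) - stats::pnorm(a - s)) / Z
      m2 <- exp(2 * mu + 2 * s^2) *
        (stats::pnorm(b - 2 * s) - stats::pnorm(a - 2 * s)) / Z
      list(mean = m1, variance = m2 - m1^2)
    },
    rlang::abort(
      paste0("Closed-form moments for a truncated ", spec$family,
             " distribution are not implemented."),
      class = "fluorisk_error_not_implemented"
    )
  )
}

#' Fit a triangular distribution to a sample
#'
#' A deterministic moment-matching fit emulating the distribution-fitting step
#' commercial risk software applies to sparse environmental concentration
#' data: the endpoints are pinned at the sample minimum and maximum and the
#' mode is solved from the sample mean via `mode = 3 * mean - min - max`
#' (the triangular mean is `(min + mode + max) / 3`), clamped into
#' `[min, max]` so the returned spec is always valid.
#'
#' @param x Numeric sample, at least 3 values, not all identical.
#' @return A triangular [dist_spec].
#' @examples
#' fit_triangular(c(1.12, 2.54, 3.87))
#' @export
fit_triangular <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) rlang::abort("`x` must not contain NA.", class = "fluorisk_error_domain")
  if (length(x) < 3) {
    rlang::abort("triangular fitting needs at least 3 values.",
                 class = "fluorisk_error_insufficient_data")
  }
  a <- min(x); b <- max(x)
  if (a == b) {
    rlang::abort(
      "all values identical: zero range; use dist_point() instead.",
      class = "fluorisk_error_degenerate"
    )
  }
  cc <- 3 * mean(x) - a - b
  dist_triangular(a, min(max(cc, a), b), b)
}

#' Serialize a distribution specification to and from JSON
#'
#' The JSON fragment carries the family, its named parameters and the
#' truncation interval (`null` bounds mean unbounded), e.g.
#' `{"family":"triangular","min":1.12,"mode":2.54,"max":3.87,"truncate":[0,null]}`.
#'
#' @param spec A [dist_spec].
#' @param json A JSON string or a list already parsed from one.
#' @return `dist_to_json()` a JSON string; `dist_from_json()` a [dist_spec].
#' @export
dist_to_json <- function(spec) {
  validate_dist_spec(spec)
  x <- c(list(family = spec$family), spec$params)
  if (!is.null(spec$truncate)) {
    tr <- as.list(spec$truncate)
    tr[vapply(spec$truncate, is.infinite, logical(1))] <- list(NULL)
    x$truncate <- tr
  }
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA))
}

#' @rdname dist_to_json
#' @export
dist_from_json <- function(json) {
  x <- if (is.character(json)) jsonlite::fromJSON(json, simplifyVector = FALSE) else json
  fam <- x$family
  tr <- NULL
  if (!is.null(x$truncate)) {
    lo <- x$truncate[[1]]; hi <- if (length(x$truncate) > 1) x$truncate[[2]] else NULL
    tr <- c(if (is.null(lo)) -Inf else as.numeric(lo),
            if (is.null(hi)) Inf else as.numeric(hi))
  }
  switch(fam,
    point = dist_point(x$value),
    uniform = dist_uniform(x$low, x$high, tr),
    triangular = dist_triangular(x$min, x$mode, x$max, tr),
    normal = dist_normal(x$mean, x$sd, tr),
    lognormal = dist_lognormal(x$meanlog, x$sdlog, tr),
    rlang::abort(paste0("Unknown distribution family: ", fam),
                 class = "fluorisk_error_spec")
  )
}
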
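# Nonparametric (binned, Laplace-smoothed) emission components.

#' Estimate a binned feature distribution
#'
#' The nonparametric representation used for every emission component: a
#' histogram over fixed bins with pseudocount smoothing,
#' `mass_i = (count_i + pseudocount) / (N + B * pseudocount)`, so every bin
#' has strictly positive mass. Spacing `d` uses unit bins `1 ... D_cens`
#' (the last bin absorbing all censored values); `c` and `a` use `bins`
#' equal-width bins on `[0, 1]` (value 1 falls in the last bin).
#'
#' @param values Numeric observations (>= 1 required).
#' @param feature One of `"d"`, `"c"`, `"a"`.
#' @param bins Number of bins for `c`/`a` (ignored for `d`).
#' @param pseudocount Smoothing pseudocount (> 0).
#' @param D_cens Spacing censoring threshold (for `feature = "d"`).
#' @param stratum Optional stratum label carried for provenance.
#' @return An object of class `feature_distribution`.
#' @export
estimate_distribution <- function(values, feature = c("d", "c", "a"),
                                  bins = 20L, pseudocount = 1,
                                  D_cens = 30L, stratum = "ALL") {
  feature <- match.arg(feature)
  stopifnot(pseudocount > 0)
  values <- values[!is.na(values)]
  if (length(values) < 1) abort("estimate_distribution needs at least one value")
  if (feature == "d") {
    if (any(values < 1 | values > D_cens | values != floor(values))) {
      abort(sprintf("spacing values must be integers in [1, %d]", D_cens))
    }
    B <- as.integer(D_cens)
    idx <- as.integer(values)
    breaks <- seq(0.5, D_cens + 0.5, by = 1)
  } else {
    if (any(values < 0 | values > 1)) {
      abort(sprintf("'%s' values must lie in [0, 1]", feature))
    }
    B <- as.integer(bins)
    idx <- pmin(floor(values * B) + 1L, B)
    breaks <- seq(0, 1, length.out = B + 1L)
  }
  counts <- tabulate(idx, nbins = B)
  mass <- (counts + pseudocount) / (length(values) + B * pseudocount)
  structure(
    list(feature = feature, breaks = breaks, mass = mass,
         n = length(values), pseudocount = pseudocount, stratum = stratum,
         D_cens = if (feature == "d") as.integer(D_cens) else NULL),
    class = "feature_distribution"
  )
}

# Bin index of values under a feature_distribution.
fd_bin <- function(fd, values) {
  B <- length(fd$mass)
  if (fd$feature == "d") {
    if (any(values < 1 | values > B, na.rm = TRUE)) {
      abort("spacing value outside the binned range")
    }
    as.integer(values)
  } else {
    if (any(values < 0 | values > 1, na.rm = TRUE)) {
      abort(sprintf("'%s' value outside [0, 1]", fd$feature))
    }
    pmin(floor(values * B) + 1L, B)
  }
}

# Natural-log mass of each value's bin.
fd_logmass <- function(fd, values) {
  log(fd$mass[fd_bin(fd, values)])
}

#' @export
print.feature_distribution <- function(x, ...) {
  cat(sprintf("<feature_distribution '%s'%s: %d bins, n = %d>\n",
              x$feature,
              if (!identical(x$stratum, "ALL")) paste0(" [", x$stratum, "]") else "",
              length(x$mass), x$n))
  invisible(x)
}

#' @export
tidy.feature_distribution <- function(x, ...) {
  tibble(
    feature = x$feature,
    stratum = as.character(x$stratum),
    bin = seq_along(x$mass),
    lower = x$breaks[-length(x$breaks)],
    upper = x$breaks[-1],
    mass = x$mass
  )
}

#' Total variation distance between two probability mass vectors
#'
#' @param p,q Probability masses on the same bins.
#' @return `sum(|p - q|) / 2`.
#' @export
total_variation <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}
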
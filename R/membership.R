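#' Parametric membership functions
#'
#' Three curve families describe every linguistic label in the system:
#' \describe{
#'   \item{`mf_z(a, m, b)`}{left shoulder: the quadratic-spline Z curve, 1 up
#'     to `a`, 0 from `b`, crossing 0.5 at `(a + b) / 2`.}
#'   \item{`mf_s(a, m, b)`}{right shoulder: the mirror S curve, 0 up to `a`,
#'     1 from `b`.}
#'   \item{`mf_gauss2(c1, sigma1, c2, sigma2)`}{two-sided Gaussian: the left
#'     flank is `exp(-(x - c1)^2 / (2 sigma1^2))`, the right flank
#'     `exp(-(x - c2)^2 / (2 sigma2^2))`, with a plateau of 1 on `[c1, c2]`.}
#' }
#'
#' For Z/S curves the stored crossover `m` is redundant with `(a + b) / 2`;
#' a value deviating by more than 5\% of the width `b - a` raises a warning
#' (not an error), since published parameter tables occasionally round it.
#' The curve itself is always anchored on `(a, b)`.
#'
#' @param a,b left and right knots (`a <= b`).
#' @param m nominal 0.5-crossover; defaults to `(a + b) / 2`.
#' @param c1,c2 left and right plateau edges (`c1 <= c2`).
#' @param sigma1,sigma2 positive flank widths.
#' @param warn emit the crossover-deviation warning? (internal loaders of
#'   fixed published tables disable it).
#' @return an object of class `frsys_mf`.
#' @seealso [eval_mf()], [linguistic_variable()]
#' @name membership-functions
NULL

#' @rdname membership-functions
#' @export
mf_z <- function(a, m = NULL, b, warn = TRUE) {
  new_shoulder_mf("z", a, m, b, warn)
}

#' @rdname membership-functions
#' @export
mf_s <- function(a, m = NULL, b, warn = TRUE) {
  new_shoulder_mf("s", a, m, b, warn)
}

new_shoulder_mf <- function(kind, a, m, b, warn) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (a > b) stop("membership knots must satisfy a <= b", call. = FALSE)
  if (is.null(m)) m <- (a + b) / 2
  if (warn && b > a && abs(m - (a + b) / 2) > 0.05 * (b - a))
    warning(sprintf(
      "stored crossover m = %g deviates from the spline midpoint %g",
      m, (a + b) / 2), call. = FALSE)
  structure(list(kind = kind, a = a, m = m, b = b), class = "frsys_mf")
}

#' @rdname membership-functions
#' @export
mf_gauss2 <- function(c1, sigma1, c2, sigma2) {
  stopifnot(is.numeric(c1), is.numeric(c2),
            length(c1) == 1L, length(c2) == 1L)
  if (c1 > c2) stop("gauss2 requires c1 <= c2", call. = FALSE)
  if (!is.numeric(sigma1) || sigma1 <= 0 || !is.numeric(sigma2) || sigma2 <= 0)
    stop("gauss2 widths must be positive", call. = FALSE)
  structure(list(kind = "gauss2", c1 = c1, sigma1 = sigma1,
                 c2 = c2, sigma2 = sigma2), class = "frsys_mf")
}

#' Evaluate a membership function
#'
#' @param mf an `frsys_mf` object from [mf_z()], [mf_s()] or [mf_gauss2()].
#' @param x numeric vector of crisp inputs.
#' @return numeric vector of membership degrees in `[0, 1]`.
#' @export
#' @examples
#' eval_mf(mf_z(0.5, 1.25, 2), c(0.5, 1.25, 2))  # 1, 0.5, 0
eval_mf <- function(mf, x) {
  stopifnot(inherits(mf, "frsys_mf"), is.numeric(x))
  switch(mf$kind,
    z = zmf(x, mf$a, mf$b),
    s = 1 - zmf(x, mf$a, mf$b),
    gauss2 = {
      out <- rep(1, length(x))
      lo <- x < mf$c1
      hi <- x > mf$c2
      out[lo] <- exp(-(x[lo] - mf$c1)^2 / (2 * mf$sigma1^2))
      out[hi] <- exp(-(x[hi] - mf$c2)^2 / (2 * mf$sigma2^2))
      out
    }
  )
}

# quadratic-spline Z curve anchored at (a, b); degenerate a == b is a step
zmf <- function(x, a, b) {
  if (a == b) return(as.numeric(x <= a))
  mid <- (a + b) / 2
  out <- numeric(length(x))
  out[x <= a] <- 1
  i <- x > a & x <= mid
  out[i] <- 1 - 2 * ((x[i] - a) / (b - a))^2
  i <- x > mid & x < b
  out[i] <- 2 * ((x[i] - b) / (b - a))^2
  out
}

#' Linguistic variable
#'
#' A named input (or output) quantity with a bounded universe and an ordered
#' family of exactly three labelled membership functions (`Lo`/`Me`/`Hi` for
#' features, `isLy`/`mayLy`/`notLy` for the pose output).
#'
#' @param name variable identifier.
#' @param universe numeric `c(lo, hi)` bounds, `lo < hi`.
#' @param labels named list of three `frsys_mf` objects, in label order.
#' @return an object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(name, universe, labels) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(universe), length(universe) == 2L)
  if (universe[1] >= universe[2])
    stop("universe must satisfy lo < hi", call. = FALSE)
  if (length(labels) != 3L || is.null(names(labels)) ||
      any(!nzchar(names(labels))))
    stop("a linguistic variable needs exactly 3 named labels", call. = FALSE)
  if (!all(vapply(labels, inherits, logical(1), "frsys_mf")))
    stop("every label must be an frsys_mf", call. = FALSE)
  structure(list(name = name, universe = universe, labels = labels),
            class = "linguistic_variable")
}

#' Fuzzify a crisp value
#'
#' Evaluates every label of a linguistic variable at `x`.  Inputs outside the
#' universe are clamped to its bounds first (sensor outliers otherwise land
#' on valid curve tails anyway).
#'
#' @param var a [linguistic_variable()].
#' @param x numeric scalar (or vector) of crisp values.
#' @return for scalar `x`, a named numeric vector of label degrees; for
#'   vector `x`, a matrix with one row per value and one column per label.
#' @export
fuzzify <- function(var, x) {
  stopifnot(inherits(var, "linguistic_variable"), is.numeric(x))
  xc <- pmin(pmax(x, var$universe[1]), var$universe[2])
  m <- vapply(var$labels, eval_mf, numeric(length(xc)), x = xc)
  if (length(xc) == 1L) {
    m <- as.numeric(m)
    names(m) <- names(var$labels)
    m
  } else {
    matrix(m, nrow = length(xc), dimnames = list(NULL, names(var$labels)))
  }
}

#' The shipped posture fuzzification configuration
#'
#' Returns the five linguistic variables of the lying-pose detector: the four
#' silhouette descriptors extracted from a segmented depth map -- `hw`
#' (bounding-box height/width ratio), `hmax` (current height over person
#' height), `sigma` (maximal point-cloud spread along the camera axes, mm)
#' and `p40` (fraction of points within 40 cm of the floor) -- plus the
#' `pose` output variable on `[0, 1]` with labels `isLy`, `mayLy`, `notLy`.
#' Each feature carries a `Lo` Z curve, a `Me` two-sided Gaussian and a `Hi`
#' S curve with expert-chosen knots.
#'
#' Universe bounds for the features are not part of the published parameter
#' set; they are chosen wide enough to contain every curve support with
#' realistic sensor margins, and the pose universe is `[0, 1]` (its label
#' knots span 0.22-0.77).
#'
#' @return named list of five [linguistic_variable()] objects
#'   (`hw`, `hmax`, `sigma`, `p40`, `pose`).
#' @export
#' @examples
#' vars <- posture_variables()
#' fuzzify(vars$pose, 0.36)  # isLy is still at full membership here
posture_variables <- function() {
  list(
    hw = linguistic_variable("hw", c(0, 5), list(
      Lo = mf_z(0.5, 1.25, 2),
      Me = mf_gauss2(2, 0.5, 2, 0.4),
      Hi = mf_s(2, 2.6, 3.2))),
    hmax = linguistic_variable("hmax", c(0, 1.1), list(
      # the published crossover 0.4 sits slightly off the spline midpoint
      # 0.425; accepted as printed
      Lo = mf_z(0.25, 0.4, 0.6, warn = FALSE),
      Me = mf_gauss2(0.6, 0.1, 0.6, 0.2),
      Hi = mf_s(0.6, 0.8, 1))),
    sigma = linguistic_variable("sigma", c(150, 500), list(
      Lo = mf_z(260, 285, 310),
      Me = mf_gauss2(310, 17, 310, 33),
      Hi = mf_s(310, 360, 410))),
    p40 = linguistic_variable("p40", c(0, 1), list(
      Lo = mf_z(0.18, 0.3, 0.42),
      Me = mf_gauss2(0.42, 0.08, 0.42, 0.09),
      Hi = mf_s(0.42, 0.55, 0.68))),
    pose = linguistic_variable("pose", c(0, 1), list(
      isLy  = mf_z(0.22, 0.36, 0.5),
      mayLy = mf_gauss2(0.5, 0.09, 0.5, 0.09),
      notLy = mf_s(0.5, 0.63, 0.77)))
  )
}

#' @export
print.frsys_mf <- function(x, ...) {
  if (x$kind == "gauss2")
    cat(sprintf("<mf gauss2: c1 = %g, sigma1 = %g, c2 = %g, sigma2 = %g>\n",
                x$c1, x$sigma1, x$c2, x$sigma2))
  else
    cat(sprintf("<mf %s: a = %g, m = %g, b = %g>\n", x$kind, x$a, x$m, x$b))
  invisible(x)
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat(sprintf("<linguistic variable '%s' on [%g, %g]: %s>\n",
              x$name, x$universe[1], x$universe[2],
              paste(names(x$labels), collapse = ", ")))
  invisible(x)
}
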
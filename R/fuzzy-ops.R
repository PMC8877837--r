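#' Fuzzy negation specification
#'
#' Constructs a fuzzy negation: a non-increasing map `N` on the unit interval
#' with `N(0) = 1` and `N(1) = 0`.  A negation is *strong* when it is an
#' involution, `N(N(p)) = p`.
#'
#' Available families:
#' \describe{
#'   \item{`standard`}{`N(p) = 1 - p`, the classical strong negation.}
#'   \item{`power`}{`N(p) = (1 - p^w)^(1/w)`, `w > 0`.}
#'   \item{`strict_sq`}{`N(p) = 1 - p^2`; strict but not strong.}
#'   \item{`sugeno`}{`N(p) = (1 - p) / (1 + lambda * p)`, `lambda > -1`; the
#'     Sugeno family of strong negations (`lambda = 0` recovers `standard`).}
#' }
#'
#' @param kind one of `"standard"`, `"power"`, `"strict_sq"`, `"sugeno"`.
#' @param w positive exponent for the power family.
#' @param lambda Sugeno parameter, a real greater than -1.
#' @return an object of class `fuzzy_negation`.
#' @seealso [fz_neg()]
#' @export
#' @examples
#' fz_neg(fuzzy_negation("sugeno", lambda = 1), 0.5)  # 1/3
fuzzy_negation <- function(kind = c("standard", "power", "strict_sq", "sugeno"),
                           w = NULL, lambda = NULL) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.null(w) || !is.numeric(w) || length(w) != 1L || w <= 0)
      stop("power negation requires a single w > 0", call. = FALSE)
  } else if (!is.null(w)) {
    stop("'w' is only meaningful for kind = \"power\"", call. = FALSE)
  }
  if (kind == "sugeno") {
    if (is.null(lambda) || !is.numeric(lambda) || length(lambda) != 1L ||
        lambda <= -1)
      stop("Sugeno negation requires a single lambda > -1", call. = FALSE)
  } else if (!is.null(lambda)) {
    stop("'lambda' is only meaningful for kind = \"sugeno\"", call. = FALSE)
  }
  structure(list(kind = kind, w = w, lambda = lambda),
            class = "fuzzy_negation")
}

#' Evaluate a fuzzy negation
#'
#' @param spec a [fuzzy_negation()] object.
#' @param p numeric vector of membership degrees in `[0, 1]`.
#' @return numeric vector of negated degrees, same length as `p`.
#' @export
fz_neg <- function(spec, p) {
  stopifnot(inherits(spec, "fuzzy_negation"))
  check_unit(p, "p")
  switch(spec$kind,
    standard  = 1 - p,
    power     = (1 - p^spec$w)^(1 / spec$w),
    strict_sq = 1 - p^2,
    sugeno    = (1 - p) / (1 + spec$lambda * p)
  )
}

#' Fuzzy implication specification
#'
#' Constructs a fuzzy implication: a binary map on the unit square, decreasing
#' in the first and increasing in the second argument, with the classical
#' boundary values `I(0,0) = I(0,1) = I(1,1) = 1` and `I(1,0) = 0`.
#'
#' Families: `lukasiewicz` (`min(1, 1 - p + q)`), `fodor` (1 when `p <= q`,
#' else `max(1 - p, q)`), `rescher` (1 when `p <= q`, else 0), `reichenbach`
#' (`1 - p + p*q`), and `kleene_dienes` (`max(1 - p, q)`).
#'
#' @param kind implication family name.
#' @return an object of class `fuzzy_implication`.
#' @export
fuzzy_implication <- function(kind = c("lukasiewicz", "fodor", "rescher",
                                       "reichenbach", "kleene_dienes")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "fuzzy_implication")
}

#' Evaluate a fuzzy implication
#'
#' @param spec a [fuzzy_implication()] object.
#' @param p,q numeric vectors in `[0, 1]` (recycled to a common length).
#' @return numeric vector of implication degrees.
#' @export
fz_impl <- function(spec, p, q) {
  stopifnot(inherits(spec, "fuzzy_implication"))
  check_unit(p, "p"); check_unit(q, "q")
  switch(spec$kind,
    lukasiewicz   = ifelse(p <= q, 1, 1 - p + q),
    fodor         = ifelse(p <= q, 1, pmax(1 - p, q)),
    rescher       = ifelse(p <= q, 1, 0),
    reichenbach   = 1 - p + p * q,
    kleene_dienes = pmax(1 - p, q)
  )
}

# binary kinds: t-norms/conorms extend n-ary by left fold (associativity);
# pre_f and lehmer are strictly binary (only ever used as the outer combiner).
.agg_binary_assoc <- c("tm", "sm", "tp", "sp", "tl", "sl")
.agg_binary_only  <- c("pre_f", "lehmer")
.agg_nary         <- c("amean", "gmean", "qmean", "owa")

#' Aggregation (and pre-aggregation) function specification
#'
#' Constructs an aggregation function: an increasing map `[0,1]^n -> [0,1]`
#' with `A(0,...,0) = 0` and `A(1,...,1) = 1`.  Two *pre-aggregation*
#' functions are also provided; these satisfy the boundary conditions but are
#' only directionally monotone, not coordinate-wise increasing.
#'
#' Kinds:
#' \describe{
#'   \item{`tm`/`sm`}{lattice t-norm `min` / t-conorm `max`.}
#'   \item{`tp`/`sp`}{algebraic product `p*q` / probabilistic sum `p+q-p*q`.}
#'   \item{`tl`/`sl`}{Lukasiewicz `max(0, p+q-1)` / `min(1, p+q)`.}
#'   \item{`amean`, `gmean`, `qmean`}{arithmetic, geometric and quadratic
#'     (square) means.}
#'   \item{`owa`}{ordered weighted averaging: inputs are sorted in descending
#'     order and combined with `weights` (non-negative, summing to 1).}
#'   \item{`pre_f`}{`F(p,q) = p - (max(0, p - q))^2`, a (0,1)-increasing
#'     pre-aggregation (not an aggregation function).}
#'   \item{`lehmer`}{the weighted Lehmer mean
#'     `(lambda*p^2 + (1-lambda)*q^2) / (lambda*p + (1-lambda)*q)` with the
#'     convention 0/0 = 0; (1-lambda, lambda)-increasing for
#'     `lambda` in `[0, 1]`.}
#' }
#'
#' The associative binary kinds (`tm`, `sm`, `tp`, `sp`, `tl`, `sl`) accept
#' any arity via a left fold; `pre_f` and `lehmer` are strictly binary and
#' refuse more than two arguments.
#'
#' @param kind aggregation family name.
#' @param weights OWA weight vector (non-negative, sums to 1 within 1e-12).
#' @param lambda Lehmer weight in `[0, 1]`.
#' @return an object of class `fz_aggregator`.
#' @seealso [fz_agg()]
#' @export
#' @examples
#' fz_agg(aggregator("owa", weights = c(1, 0)), c(0.2, 0.9))  # max
aggregator <- function(kind = c("tm", "sm", "tp", "sp", "tl", "sl",
                                "amean", "gmean", "qmean", "owa",
                                "pre_f", "lehmer"),
                       weights = NULL, lambda = NULL) {
  kind <- match.arg(kind)
  if (kind == "owa") {
    if (is.null(weights) || !is.numeric(weights) || length(weights) < 1L)
      stop("OWA requires a numeric weight vector", call. = FALSE)
    if (any(weights < 0) || any(weights > 1) ||
        abs(sum(weights) - 1) > 1e-12)
      stop("OWA weights must lie in [0,1] and sum to 1 (tolerance 1e-12)",
           call. = FALSE)
  } else if (!is.null(weights)) {
    stop("'weights' is only meaningful for kind = \"owa\"", call. = FALSE)
  }
  if (kind == "lehmer") {
    if (is.null(lambda) || !is.numeric(lambda) || length(lambda) != 1L ||
        lambda < 0 || lambda > 1)
      stop("Lehmer mean requires a single lambda in [0, 1]", call. = FALSE)
  } else if (!is.null(lambda)) {
    stop("'lambda' is only meaningful for kind = \"lehmer\"", call. = FALSE)
  }
  structure(list(kind = kind, weights = weights, lambda = lambda),
            class = "fz_aggregator")
}

# vectorised binary evaluation; used by fold and by grid property checks
fz_agg2 <- function(spec, p, q) {
  switch(spec$kind,
    tm = pmin(p, q),
    sm = pmax(p, q),
    tp = p * q,
    sp = p + q - p * q,
    tl = pmax(0, p + q - 1),
    sl = pmin(1, p + q),
    amean = (p + q) / 2,
    gmean = sqrt(p * q),
    qmean = sqrt((p^2 + q^2) / 2),
    pre_f = p - pmax(0, p - q)^2,
    lehmer = {
      lam <- spec$lambda
      num <- lam * p^2 + (1 - lam) * q^2
      den <- lam * p + (1 - lam) * q
      ifelse(den == 0, 0, num / den)
    },
    stop("no binary form for kind ", spec$kind, call. = FALSE)
  )
}

#' Apply an aggregation function
#'
#' @param spec an [aggregator()] object.
#' @param values non-empty numeric vector of degrees in `[0, 1]`.  For `owa`
#'   the weight vector length must match `length(values)`; `pre_f` and
#'   `lehmer` require exactly two values.
#' @return a single degree in `[0, 1]`.
#' @export
fz_agg <- function(spec, values) {
  stopifnot(inherits(spec, "fz_aggregator"))
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  check_unit(values, "values")
  kind <- spec$kind
  if (kind %in% .agg_binary_only) {
    if (length(values) > 2L)
      stop(sprintf("aggregator '%s' is strictly binary (got %d values)",
                   kind, length(values)), call. = FALSE)
    if (length(values) == 1L) return(values)
    return(fz_agg2(spec, values[1L], values[2L]))
  }
  switch(kind,
    amean = mean(values),
    gmean = if (any(values == 0)) 0 else exp(mean(log(values))),
    qmean = sqrt(mean(values^2)),
    owa = {
      if (length(spec$weights) != length(values))
        stop(sprintf(
          "OWA weight length (%d) does not match number of values (%d)",
          length(spec$weights), length(values)), call. = FALSE)
      sum(spec$weights * sort(values, decreasing = TRUE))
    },
    # associative binary kinds: left fold
    Reduce(function(p, q) fz_agg2(spec, p, q), values)
  )
}

# internal alias, usable where a function argument shadows the name
make_aggregator <- aggregator

check_unit <- function(x, name) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be numeric without NA", name), call. = FALSE)
  if (any(x < 0 | x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' @export
print.fuzzy_negation <- function(x, ...) {
  extra <- if (x$kind == "power") sprintf(" (w = %g)", x$w)
           else if (x$kind == "sugeno") sprintf(" (lambda = %g)", x$lambda)
           else ""
  cat(sprintf("<fuzzy negation: %s%s>\n", x$kind, extra))
  invisible(x)
}

#' @export
print.fz_aggregator <- function(x, ...) {
  extra <- if (x$kind == "owa")
    sprintf(" (weights = %s)", paste(signif(x$weights, 4), collapse = ", "))
  else if (x$kind == "lehmer") sprintf(" (lambda = %g)", x$lambda)
  else ""
  cat(sprintf("<aggregator: %s%s>\n", x$kind, extra))
  invisible(x)
}

#' @export
print.fuzzy_implication <- function(x, ...) {
  cat(sprintf("<fuzzy implication: %s>\n", x$kind))
  invisible(x)
}
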
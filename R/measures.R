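#' Precedence indicator specification
#'
#' A precedence indicator is a graded subsethood measure
#' `Prec : [0,1]^2 -> [0,1]` satisfying three axioms:
#' \describe{
#'   \item{P1}{`Prec(p, q) = 0` iff `p = 1` and `q = 0`;}
#'   \item{P2}{`Prec(p, q) = 1` iff `p <= q`;}
#'   \item{P3}{for `p <= q <= r`, `Prec(r, p) <= Prec(q, p)` and
#'     `Prec(r, p) <= Prec(r, q)`.}
#' }
#' The constructive form used here is `Prec(p, q) = 1` when `p <= q` and
#' `A(N(p), q)` otherwise, where `N` is a fuzzy negation and `A` an
#' aggregation function bounded above by `max`.  The bound `A <= max` is
#' verified empirically on a 101 x 101 grid at construction time.
#'
#' @param aggregator an [aggregator()] with `A(p,q) <= max(p,q)` pointwise
#'   (e.g. `tm`, `sm`, `amean`, `gmean`, `qmean`).
#' @param negation a [fuzzy_negation()].
#' @return an object of class `precedence_spec`.
#' @seealso [precedence()], [knowledge_spec()]
#' @export
#' @examples
#' sp <- precedence_spec(aggregator("amean"), fuzzy_negation("standard"))
#' precedence(sp, 0.8, 0.2)  # (1 - 0.8 + 0.2) / 2 = 0.2
precedence_spec <- function(aggregator, negation = fuzzy_negation("standard")) {
  if (missing(aggregator)) aggregator <- make_aggregator("sm")
  stopifnot(inherits(aggregator, "fz_aggregator"),
            inherits(negation, "fuzzy_negation"))
  if (aggregator$kind %in% .agg_binary_only)
    stop("precedence requires a genuine (monotone) aggregation function",
         call. = FALSE)
  g <- seq(0, 1, length.out = 101L)
  gr <- expand.grid(p = g, q = g)
  if (any(fz_agg2(aggregator, gr$p, gr$q) > pmax(gr$p, gr$q) + 1e-12))
    stop("aggregator violates A <= max; cannot build a precedence indicator",
         call. = FALSE)
  structure(list(aggregator = aggregator, negation = negation),
            class = "precedence_spec")
}

#' Evaluate a precedence indicator
#'
#' Returns 1 when `p <= q`, otherwise `A(N(p), q)` for the indicator's
#' aggregation `A` and negation `N`.  Vectorised over `p` and `q`.
#'
#' @param spec a [precedence_spec()].
#' @param p,q numeric vectors in `[0, 1]`.
#' @return numeric vector of precedence degrees in `[0, 1]`.
#' @export
precedence <- function(spec, p, q) {
  stopifnot(inherits(spec, "precedence_spec"))
  check_unit(p, "p"); check_unit(q, "q")
  ifelse(p <= q, 1, fz_agg2(spec$aggregator, fz_neg(spec$negation, p), q))
}

#' Knowledge measure specification
#'
#' A knowledge measure is the dual of fuzzy entropy: maximal exactly on crisp
#' membership vectors, minimal exactly on the all-0.5 vector, monotone under
#' sharpening, and invariant under complementation (axioms K1-K4).
#'
#' Kinds:
#' \describe{
#'   \item{`prec_based`}{built from a precedence indicator whose aggregation
#'     is symmetric and whose negation is strong with equilibrium 0.5:
#'     `K(R) = mean_i |Prec(1, x_i) - Prec(x_i, 0)| /
#'     (1 - min(Prec(1, x_i), Prec(x_i, 0)))`.  With the `max` aggregation
#'     and standard negation each term reduces to the closed form
#'     `|2x - 1| / (1 - min(x, 1 - x))`.}
#'   \item{`sls`}{`mean_i 2 * (x_i^2 + (1 - x_i)^2) - 1`.}
#'   \item{`ak`}{`log2( (2/n) * sum_i (x_i^2 + (1 - x_i)^2) )`.}
#' }
#' The construction requirements for `prec_based` (symmetry of the
#' aggregation, `N(0.5) = 0.5`) are checked empirically at build time.
#'
#' @param kind `"prec_based"`, `"sls"` or `"ak"`.
#' @param precedence a [precedence_spec()]; only for `prec_based`.  Defaults
#'   to the `max`-aggregation / standard-negation indicator.
#' @return an object of class `knowledge_spec`.
#' @seealso [knowledge()]
#' @export
knowledge_spec <- function(kind = c("prec_based", "sls", "ak"),
                           precedence = NULL) {
  kind <- match.arg(kind)
  if (kind != "prec_based") {
    if (!is.null(precedence))
      stop("'precedence' is only meaningful for kind = \"prec_based\"",
           call. = FALSE)
    return(structure(list(kind = kind, precedence = NULL),
                     class = "knowledge_spec"))
  }
  if (is.null(precedence))
    precedence <- precedence_spec(aggregator("sm"),
                                  fuzzy_negation("standard"))
  stopifnot(inherits(precedence, "precedence_spec"))
  g <- seq(0, 1, length.out = 101L)
  gr <- expand.grid(p = g, q = g)
  if (any(abs(fz_agg2(precedence$aggregator, gr$p, gr$q) -
              fz_agg2(precedence$aggregator, gr$q, gr$p)) > 1e-12))
    stop("knowledge measure requires a symmetric aggregation", call. = FALSE)
  N <- precedence$negation
  if (abs(fz_neg(N, 0.5) - 0.5) > 1e-12 ||
      max(abs(fz_neg(N, fz_neg(N, g)) - g)) > 1e-12)
    stop("knowledge measure requires a strong negation with equilibrium 0.5",
         call. = FALSE)
  structure(list(kind = kind, precedence = precedence),
            class = "knowledge_spec")
}

#' Amount of knowledge carried by a membership vector
#'
#' @param spec a [knowledge_spec()].
#' @param degrees non-empty numeric vector of membership degrees in `[0, 1]`.
#' @return a single value in `[0, 1]`: 1 for crisp vectors, 0 for the
#'   all-0.5 vector.
#' @export
#' @examples
#' k <- knowledge_spec("prec_based")
#' knowledge(k, c(1, 0))          # 1: crisp
#' knowledge(k, c(0.5, 0.5, 0.5)) # 0: maximally fuzzy
knowledge <- function(spec, degrees) {
  stopifnot(inherits(spec, "knowledge_spec"))
  if (length(degrees) == 0L)
    stop("'degrees' must be non-empty", call. = FALSE)
  check_unit(degrees, "degrees")
  x <- degrees
  switch(spec$kind,
    sls = mean(2 * (x^2 + (1 - x)^2) - 1),
    ak  = log2(2 * mean(x^2 + (1 - x)^2)),
    prec_based = {
      top <- precedence(spec$precedence, 1, x)   # Prec(1, x_i)
      bot <- precedence(spec$precedence, x, 0)   # Prec(x_i, 0)
      den <- 1 - pmin(top, bot)
      if (any(den <= 1e-12))
        stop("degenerate precedence values: denominator of the knowledge ",
             "term is not positive", call. = FALSE)
      mean(abs(top - bot) / den)
    }
  )
}

#' Knowledge-augmented premise aggregation (the OR operator)
#'
#' Combines the aggregated premise degrees of a rule with the amount of
#' knowledge those degrees carry: `OR = B(A(p_1, ..., p_n), K(p))`, where `A`
#' is the inner (premise) aggregation, `K` a knowledge measure over the same
#' degrees, and `B` a binary outer combiner (possibly a pre-aggregation such
#' as `pre_f`).  Certain premises (`all equal 1`) yield 1; maximally fuzzy
#' premises are suppressed towards the knowledge value 0.
#'
#' @param premises non-empty numeric vector of premise degrees in `[0, 1]`.
#' @param inner an [aggregator()] applied across the premises.
#' @param outer a binary [aggregator()] combining premise strength with
#'   knowledge.
#' @param kspec a [knowledge_spec()].
#' @return a single activation degree in `[0, 1]`.
#' @export
#' @examples
#' operator_or(c(0.9, 0.8, 1.0, 0.7), aggregator("qmean"),
#'             aggregator("pre_f"), knowledge_spec("prec_based"))
operator_or <- function(premises, inner, outer, kspec) {
  stopifnot(inherits(inner, "fz_aggregator"),
            inherits(outer, "fz_aggregator"))
  if (length(premises) == 0L)
    stop("'premises' must be non-empty", call. = FALSE)
  a <- fz_agg(inner, premises)
  k <- knowledge(kspec, premises)
  fz_agg(outer, c(a, k))
}

#' @export
print.precedence_spec <- function(x, ...) {
  cat(sprintf("<precedence indicator: A = %s, N = %s>\n",
              x$aggregator$kind, x$negation$kind))
  invisible(x)
}

#' @export
print.knowledge_spec <- function(x, ...) {
  if (x$kind == "prec_based")
    cat(sprintf("<knowledge measure: precedence-based (A = %s, N = %s)>\n",
                x$precedence$aggregator$kind, x$precedence$negation$kind))
  else
    cat(sprintf("<knowledge measure: %s>\n", x$kind))
  invisible(x)
}
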
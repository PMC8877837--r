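#' Serialise operator specs and fuzzification configs
#'
#' Operator specifications (negations, aggregators, implications, precedence
#' indicators, knowledge measures) round-trip through plain-list YAML
#' fragments such as `{kind: owa, weights: [0.5, 0.3, 0.2]}` or
#' `{kind: prec_based, precedence: {aggregator: {kind: max},
#' negation: {kind: standard}}}`.  The `kind` vocabularies of the families
#' are disjoint, so deserialisation dispatches on `kind` alone.
#'
#' @param x a spec object.
#' @return `spec_as_list()`: a plain list; `spec_to_yaml()`: a YAML string;
#'   `spec_from_yaml()` / `spec_from_list()`: the rebuilt spec object.
#' @name spec-io
NULL

#' @rdname spec-io
#' @export
spec_as_list <- function(x) {
  if (inherits(x, "precedence_spec"))
    return(list(aggregator = spec_as_list(x$aggregator),
                negation = spec_as_list(x$negation)))
  if (inherits(x, "knowledge_spec")) {
    out <- list(kind = x$kind)
    if (x$kind == "prec_based")
      out$precedence <- spec_as_list(x$precedence)
    return(out)
  }
  out <- unclass(x)
  out[!vapply(out, is.null, logical(1))]
}

# yaml maps "max"/"min" naturally; accept those aliases for sm/tm
.agg_alias <- c(max = "sm", min = "tm")

#' @rdname spec-io
#' @param lst a plain list as produced by [spec_as_list()].
#' @export
spec_from_list <- function(lst) {
  if (is.null(lst$kind)) {
    if (!is.null(lst$aggregator) && !is.null(lst$negation))
      return(precedence_spec(spec_from_list(lst$aggregator),
                             spec_from_list(lst$negation)))
    stop("cannot interpret spec fragment: no 'kind' field", call. = FALSE)
  }
  kind <- as.character(lst$kind)
  if (kind %in% names(.agg_alias)) kind <- .agg_alias[[kind]]
  if (kind %in% c("standard", "power", "strict_sq", "sugeno"))
    return(fuzzy_negation(kind, w = lst$w, lambda = lst$lambda))
  if (kind %in% c("lukasiewicz", "fodor", "rescher", "reichenbach",
                  "kleene_dienes"))
    return(fuzzy_implication(kind))
  if (kind %in% c("tm", "sm", "tp", "sp", "tl", "sl", "amean", "gmean",
                  "qmean", "owa", "pre_f", "lehmer"))
    return(aggregator(kind, weights = unlist(lst$weights),
                      lambda = lst$lambda))
  if (kind %in% c("prec_based", "sls", "ak")) {
    prec <- if (is.null(lst$precedence)) NULL
            else spec_from_list(lst$precedence)
    return(knowledge_spec(kind, precedence = prec))
  }
  stop("unknown spec kind: ", kind, call. = FALSE)
}

#' @rdname spec-io
#' @export
spec_to_yaml <- function(x) {
  yaml::as.yaml(spec_as_list(x))
}

#' @rdname spec-io
#' @param text a YAML string, or the path of a YAML file.
#' @export
spec_from_yaml <- function(text) {
  lst <- if (length(text) == 1L && file.exists(text)) yaml::read_yaml(text)
         else yaml::yaml.load(paste(text, collapse = "\n"))
  spec_from_list(lst)
}

#' Read and write fuzzification configurations
#'
#' A configuration is a named list of [linguistic_variable()] objects.  The
#' YAML schema is
#' `variables: {name: {universe: [lo, hi], labels: {Lo: {kind: z, a: ...,
#' m: ..., b: ...}, Me: {kind: gauss2, c1: ..., sigma1: ..., ...}, ...}}}`.
#'
#' @param vars named list of linguistic variables.
#' @param file path of the YAML file.
#' @return `read_variables_yaml()` returns the named list of variables;
#'   `write_variables_yaml()` returns `file` invisibly.
#' @export
write_variables_yaml <- function(vars, file) {
  body <- lapply(vars, function(v) {
    list(universe = as.numeric(v$universe),
         labels = lapply(v$labels, function(mf) unclass(mf)))
  })
  yaml::write_yaml(list(variables = body), file, precision = 15L)
  invisible(file)
}

#' @rdname write_variables_yaml
#' @export
read_variables_yaml <- function(file) {
  raw <- yaml::read_yaml(file)
  if (is.null(raw$variables))
    stop("configuration has no 'variables' block", call. = FALSE)
  out <- lapply(names(raw$variables), function(nm) {
    v <- raw$variables[[nm]]
    labels <- lapply(v$labels, function(p) {
      switch(p$kind,
        z = mf_z(p$a, p$m, p$b, warn = FALSE),
        s = mf_s(p$a, p$m, p$b, warn = FALSE),
        gauss2 = mf_gauss2(p$c1, p$sigma1, p$c2, p$sigma2),
        stop("unknown membership kind: ", p$kind, call. = FALSE))
    })
    linguistic_variable(nm, as.numeric(v$universe), labels)
  })
  names(out) <- names(raw$variables)
  out
}
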
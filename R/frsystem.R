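#' Assemble a fuzzy-rough posture classification system
#'
#' Bundles a rule base, an inference configuration and a fuzzification
#' configuration into a single classifier object.  The rule base can be the
#' enumerated expert knowledge base (`rules = "knowledge"`), induced from
#' labelled training data by LEM2 (`rules = "lem2"`, which discretises
#' `train` by argmax membership, resolves label conflicts by majority and
#' runs the induction), or any explicit `ruleset`.
#'
#' @param rules `"knowledge"`, `"lem2"`, or a `ruleset`.
#' @param config an [inference_config()]; default the `K2` knowledge preset.
#' @param variables linguistic variables (default [posture_variables()]).
#' @param train data.frame of features plus a `label` column; required for
#'   `rules = "lem2"`.
#' @return an object of class `frsystem` with `print`, `summary` and
#'   `predict` methods.
#' @export
#' @examples
#' fr <- frsystem("knowledge", inference_config("classic",
#'                                              aggregator("amean")))
#' predict(fr, data.frame(hw = 0.7, hmax = 0.3, sigma = 380,
#'                        p40 = 0.6))$pose_label  # "isLy"
frsystem <- function(rules = "knowledge", config = k_config("K2"),
                     variables = posture_variables(), train = NULL) {
  stopifnot(inherits(config, "inference_config"))
  if (is.character(rules)) {
    kind <- match.arg(rules, c("knowledge", "lem2"))
    rules <- if (kind == "knowledge") enumerate_knowledge_rules()
    else {
      if (is.null(train))
        stop("rules = \"lem2\" requires labelled training data", call. = FALSE)
      induce_rules(discretize(train, variables, resolve = "majority"))
    }
  }
  stopifnot(inherits(rules, "frsys_ruleset"))
  structure(list(rules = rules, config = config, variables = variables),
            class = "frsystem")
}

#' @export
print.frsystem <- function(x, ...) {
  cat("Fuzzy-rough posture classifier\n")
  kdesc <- if (x$config$mode != "knowledge") ""
  else {
    k <- x$config$kspec
    sprintf(", B = %s, K = %s", x$config$combiner$kind,
            if (k$kind == "prec_based")
              paste0("prec_", k$precedence$aggregator$kind)
            else k$kind)
  }
  cat(sprintf("  mode: %s (A = %s%s)\n", x$config$mode,
              x$config$premise_aggregator$kind, kdesc))
  tab <- table(vapply(x$rules, `[[`, character(1), "consequent"))
  cat(sprintf("  rules: %d (%s)\n", length(x$rules),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  decision: centroid < %g on the pose universe [%g, %g] ",
              x$config$decision_threshold, x$variables$pose$universe[1],
              x$variables$pose$universe[2]))
  cat("=> isLy\n")
  invisible(x)
}

#' @export
summary.frsystem <- function(object, ...) {
  print(object)
  prov <- table(vapply(object$rules, `[[`, character(1), "provenance"))
  cat(sprintf("  provenance: %s\n",
              paste(sprintf("%s %d", names(prov), prov), collapse = ", ")))
  lens <- table(vapply(object$rules, function(r) length(r$antecedent),
                       integer(1)))
  cat(sprintf("  antecedent lengths: %s\n",
              paste(sprintf("%s cond: %d rules", names(lens), lens),
                    collapse = ", ")))
  invisible(object)
}

#' Predict pose labels for new frames
#'
#' @param object an [frsystem()].
#' @param newdata data.frame of feature vectors (or a single named list).
#' @param ... unused.
#' @return the [classify_batch()] data.frame: input echo plus `cog`,
#'   `pose_label` and per-class activations.
#' @export
predict.frsystem <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(newdata)
  classify_batch(newdata, object$rules, object$config, object$variables)
}
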
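#' Fuzzy classification rules
#'
#' A rule is a conjunction of feature/label conditions with a pose-class
#' consequent, e.g. *if hw is Lo and p40 is Hi then isLy*.  `provenance`
#' records whether the rule came from the expert enumeration
#' (`"knowledge"`) or from rough-set induction (`"lem2"`).
#'
#' @param antecedent non-empty named list (or named character vector) mapping
#'   feature names to linguistic labels; at most one label per feature.
#' @param consequent pose class, one of `isLy`, `mayLy`, `notLy` (or any
#'   decision label for generic tables).
#' @param provenance `"knowledge"` or `"lem2"`.
#' @return an object of class `frsys_rule`.
#' @export
rule <- function(antecedent, consequent, provenance = "knowledge") {
  antecedent <- as.list(antecedent)
  if (length(antecedent) == 0L)
    stop("rule antecedent must be non-empty", call. = FALSE)
  if (is.null(names(antecedent)) || any(!nzchar(names(antecedent))) ||
      anyDuplicated(names(antecedent)))
    stop("antecedent needs unique feature names", call. = FALSE)
  stopifnot(is.character(consequent), length(consequent) == 1L)
  provenance <- match.arg(provenance, c("knowledge", "lem2"))
  structure(list(antecedent = lapply(antecedent, as.character),
                 consequent = consequent, provenance = provenance),
            class = "frsys_rule")
}

#' @rdname rule
#' @param rules list of `frsys_rule` objects.
#' @export
ruleset <- function(rules) {
  if (!all(vapply(rules, inherits, logical(1), "frsys_rule")))
    stop("all elements must be frsys_rule objects", call. = FALSE)
  structure(rules, class = "frsys_ruleset")
}

#' @export
print.frsys_rule <- function(x, ...) {
  conds <- paste(sprintf("%s is %s", names(x$antecedent),
                         unlist(x$antecedent)), collapse = " and ")
  cat(sprintf("if %s then %s  [%s]\n", conds, x$consequent, x$provenance))
  invisible(x)
}

#' @export
print.frsys_ruleset <- function(x, ...) {
  tab <- table(vapply(x, `[[`, character(1), "consequent"))
  cat(sprintf("<ruleset: %d rules (%s)>\n", length(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# label profiles of the most discriminative antecedents for each binary
# pose concept; disjunctions are expanded into one prototype per option
.pose_prototypes <- list(
  notLy = list(c(hw = "Hi", hmax = "Hi", sigma = "Lo", p40 = "Lo"),
               c(hw = "Me", hmax = "Hi", sigma = "Lo", p40 = "Lo"),
               c(hw = "Me", hmax = "Me", sigma = "Lo", p40 = "Lo")),
  isLy  = list(c(hw = "Lo", hmax = "Lo", sigma = "Lo", p40 = "Hi"),
               c(hw = "Lo", hmax = "Lo", sigma = "Me", p40 = "Hi"))
)

#' Default pose-class assignment for an antecedent
#'
#' Scores a full antecedent (one `Lo/Me/Hi` label per feature) against the
#' prototype label profiles of the two crisp pose concepts by Hamming
#' distance.  The strictly nearer concept wins when its distance is at most
#' 1; everything else (ties, or antecedents far from both concepts) is
#' `mayLy`.  This heuristic map is the shipped default for
#' [enumerate_knowledge_rules()] and is user-replaceable.
#'
#' @param antecedent named character vector with labels for `hw`, `hmax`,
#'   `sigma`, `p40`.
#' @return one of `"isLy"`, `"mayLy"`, `"notLy"`.
#' @export
default_class_map <- function(antecedent) {
  a <- unlist(antecedent)[c("hw", "hmax", "sigma", "p40")]
  d <- vapply(.pose_prototypes, function(protos)
    min(vapply(protos, function(p) sum(p != a), integer(1))), integer(1))
  if (d[["notLy"]] < d[["isLy"]] && d[["notLy"]] <= 1L) "notLy"
  else if (d[["isLy"]] < d[["notLy"]] && d[["isLy"]] <= 1L) "isLy"
  else "mayLy"
}

#' Enumerate the knowledge-approach rule base
#'
#' Builds the full combinatorial rule base: one rule per combination of the
#' three linguistic labels across the four silhouette features, i.e.
#' `3^4 = 81` rules, each assigned a pose-class consequent by `class_map`.
#'
#' @param class_map either a function mapping a named antecedent vector to a
#'   pose class (default [default_class_map()]), or a named character vector
#'   keyed by `"hw.hmax.sigma.p40"` label strings (e.g. `"Hi.Hi.Lo.Lo"`).
#'   A vector map must be total over all 81 antecedents.
#' @param features feature names (order fixes the antecedent key order).
#' @param labels linguistic labels per feature.
#' @return a `ruleset` of 81 rules with provenance `"knowledge"`.
#' @export
#' @examples
#' rs <- enumerate_knowledge_rules()
#' length(rs)  # 81
enumerate_knowledge_rules <- function(class_map = default_class_map,
                                      features = c("hw", "hmax", "sigma",
                                                   "p40"),
                                      labels = c("Lo", "Me", "Hi")) {
  grid <- expand.grid(rep(list(labels), length(features)),
                      stringsAsFactors = FALSE)
  names(grid) <- features
  keys <- apply(grid, 1L, paste, collapse = ".")
  if (!is.function(class_map)) {
    map <- class_map
    missing_keys <- setdiff(keys, names(map))
    if (length(missing_keys))
      stop("class map is missing antecedent(s): ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    lookup <- function(a) map[[paste(a, collapse = ".")]]
  } else {
    lookup <- function(a) class_map(a)
  }
  rules <- lapply(seq_len(nrow(grid)), function(i) {
    a <- stats::setNames(as.character(grid[i, ]), features)
    rule(as.list(a), lookup(a), provenance = "knowledge")
  })
  ruleset(rules)
}

#' Read and write rule sets as JSON
#'
#' Schema: a JSON array of objects
#' `{"if": {"hw": "Hi", ...}, "then": "notLy", "provenance": "lem2"}`.
#'
#' @param rules a `ruleset`.
#' @param file JSON file path.
#' @return `read_rules_json()` returns a `ruleset`; `write_rules_json()`
#'   returns `file` invisibly.
#' @export
write_rules_json <- function(rules, file) {
  stopifnot(inherits(rules, "frsys_ruleset"))
  body <- lapply(rules, function(r)
    list(`if` = r$antecedent, then = r$consequent,
         provenance = r$provenance))
  jsonlite::write_json(body, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname write_rules_json
#' @export
read_rules_json <- function(file) {
  body <- jsonlite::read_json(file)
  ruleset(lapply(body, function(r)
    rule(r$`if`, r$then, provenance = r$provenance %||% "knowledge")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rule effectiveness within the set and within its decision class
#'
#' Two ratios grade a rule after an evaluation run: the number of objects it
#' classified correctly over the whole set size, and the same count over the
#' size of its decision class.  Rule rankings sort by the first ratio and
#' break ties by the second, so the strongest rules set-wide are identified
#' first and refined within their class.
#'
#' @param correct number of correct classifications credited to the rule.
#' @param set_size number of objects in the evaluation set.
#' @param class_size number of objects in the rule's decision class.
#' @return named numeric vector `c(eff_set, eff_class)`.
#' @seealso [rank_rules()]
#' @export
rule_effectiveness <- function(correct, set_size, class_size) {
  stopifnot(correct >= 0, set_size >= class_size, class_size >= 0)
  if (class_size == 0 && correct > 0)
    stop("a rule cannot classify objects in an empty class", call. = FALSE)
  if (correct > class_size)
    stop("correct count exceeds the class size", call. = FALSE)
  if (set_size == 0) stop("'set_size' must be positive", call. = FALSE)
  c(eff_set = correct / set_size,
    eff_class = if (class_size == 0) 0 else correct / class_size)
}

#' Rank rules by effectiveness
#'
#' @param stats data.frame with columns `eff_set` and `eff_class` (one row
#'   per rule, e.g. from [run_experiment()]'s ranking output).
#' @return the data.frame reordered by decreasing `eff_set`, ties broken by
#'   decreasing `eff_class`.
#' @export
rank_rules <- function(stats) {
  stopifnot(all(c("eff_set", "eff_class") %in% names(stats)))
  stats[order(-stats$eff_set, -stats$eff_class), , drop = FALSE]
}
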
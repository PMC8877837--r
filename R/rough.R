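#' Decision tables
#'
#' A decision table is an information system `(U, AT, V, f)` in which the
#' attribute set splits into condition attributes `A` and a single decision
#' attribute `d`: a finite set of objects, a total assignment of discrete
#' labels to every object/attribute cell, and per-attribute finite value
#' domains.  The canonical attribute order is the column order of `data` and
#' the canonical value order within an attribute is its domain declaration
#' order; rule induction relies on this order for its deterministic
#' tie-break.
#'
#' @param data a data.frame of discrete labels (character or factor), one row
#'   per object, including the decision column.
#' @param decision name of the decision column.
#' @param domains optional named list of value domains (character vectors) in
#'   declaration order; defaults to order of first appearance in each column.
#' @param ids optional object identifiers (default row numbers).
#' @return an object of class `decision_table`.
#' @export
decision_table <- function(data, decision, domains = NULL, ids = NULL) {
  stopifnot(is.data.frame(data), is.character(decision),
            length(decision) == 1L)
  if (!decision %in% names(data))
    stop("decision column '", decision, "' not found", call. = FALSE)
  if (nrow(data) == 0L) stop("decision table has no objects", call. = FALSE)
  data[] <- lapply(data, as.character)
  if (anyNA(data)) stop("the information function must be total (no NA cells)",
                        call. = FALSE)
  attributes_ <- setdiff(names(data), decision)
  if (length(attributes_) == 0L)
    stop("decision table needs at least one condition attribute",
         call. = FALSE)
  if (is.null(domains)) {
    domains <- lapply(data, function(col) unique(col))
  } else {
    missing_dom <- setdiff(names(data), names(domains))
    for (nm in missing_dom) domains[[nm]] <- unique(data[[nm]])
    for (nm in names(data)) {
      bad <- setdiff(unique(data[[nm]]), domains[[nm]])
      if (length(bad))
        stop("values not in declared domain of '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(data)))
  stopifnot(length(ids) == nrow(data), !anyDuplicated(ids))
  structure(list(data = data, attributes = attributes_, decision = decision,
                 domains = domains[names(data)], ids = as.character(ids)),
            class = "decision_table")
}

#' Block of an attribute-value pair
#'
#' The block `[p]` of a pair `p = (a, v)` is the set of objects whose
#' attribute `a` carries value `v`.
#'
#' @param table a [decision_table()].
#' @param attribute condition-attribute name.
#' @param value a value from that attribute's domain.
#' @return integer vector of object indices (possibly empty).
#' @export
block <- function(table, attribute, value) {
  stopifnot(inherits(table, "decision_table"))
  if (!attribute %in% table$attributes)
    stop("unknown condition attribute: ", attribute, call. = FALSE)
  if (!value %in% table$domains[[attribute]])
    stop("value '", value, "' is not in the domain of '", attribute, "'",
         call. = FALSE)
  which(table$data[[attribute]] == value)
}

# canonical enumeration of all attribute-value pairs with their blocks
all_pairs <- function(table) {
  out <- list()
  for (a in table$attributes)
    for (v in table$domains[[a]])
      out[[length(out) + 1L]] <- list(attribute = a, value = v,
                                      block = which(table$data[[a]] == v))
  out
}

# [P]: intersection of the blocks of a set of pair indices (empty P -> U)
complex_block <- function(pairs, idx, n) {
  if (length(idx) == 0L) return(seq_len(n))
  Reduce(intersect, lapply(pairs[idx], `[[`, "block"))
}

#' LEM2 rule induction for one concept
#'
#' Computes a local covering of the concept `X` (all objects with the given
#' decision label) by greedily growing minimal complexes of attribute-value
#' pairs.  At each step the pair covering most of the remaining goal set `G`
#' is chosen; ties go to the pair with the smaller overall block, and a
#' further tie to the first pair in canonical order (attributes in table
#' order, values in domain order), which pins the output deterministically.
#' Each complex is then pruned to a minimal one and redundant complexes are
#' removed from the covering.
#'
#' An inconsistent table (two objects with identical condition values but
#' different decisions straddling the concept boundary) makes the concept
#' undefinable; this is detected up front and raised as an error naming the
#' clashing objects rather than looping forever.
#'
#' @param table a [decision_table()].
#' @param concept a decision label; its concept may be empty.
#' @return an object of class `local_covering`: a list with `complexes` (each
#'   a list of `(attribute, value)` pairs) and `concept`.
#' @export
lem2 <- function(table, concept) {
  stopifnot(inherits(table, "decision_table"))
  n <- nrow(table$data)
  X <- which(table$data[[table$decision]] == concept)
  if (length(X) == 0L)
    return(structure(list(complexes = list(), concept = concept),
                     class = "local_covering"))

  key <- do.call(paste, c(table$data[table$attributes], sep = "\r"))
  clash <- intersect(unique(key[X]), unique(key[setdiff(seq_len(n), X)]))
  if (length(clash)) {
    bad <- table$ids[key %in% clash]
    stop("concept '", concept, "' is not definable: objects {",
         paste(bad, collapse = ", "),
         "} share condition values across the concept boundary",
         call. = FALSE)
  }

  pairs <- all_pairs(table)
  blk_size <- vapply(pairs, function(p) length(p$block), integer(1))
  G <- X
  rho <- list()      # list of integer vectors of pair indices

  while (length(G) > 0L) {
    P <- integer(0)
    BP <- seq_len(n)
    repeat {
      if (length(P) > 0L && all(BP %in% X)) break
      inter <- vapply(pairs, function(p)
        length(intersect(p$block, G)), integer(1))
      inter[P] <- 0L
      cand <- which(inter > 0L)
      if (length(cand) == 0L)
        stop("LEM2 cannot extend the current complex; table is inconsistent",
             call. = FALSE)
      best <- cand[inter[cand] == max(inter[cand])]
      best <- best[blk_size[best] == min(blk_size[best])]
      p <- best[1L]
      P <- c(P, p)
      G <- intersect(pairs[[p]]$block, G)
      BP <- intersect(BP, pairs[[p]]$block)
    }
    # prune the complex to a minimal one (keep at least one pair)
    for (p in P) {
      if (length(P) > 1L) {
        rest <- setdiff(P, p)
        if (all(complex_block(pairs, rest, n) %in% X)) P <- rest
      }
    }
    rho[[length(rho) + 1L]] <- P
    covered <- unique(unlist(lapply(rho, complex_block, pairs = pairs, n = n)))
    G <- setdiff(X, covered)
  }

  # drop complexes whose removal still covers X exactly
  i <- 1L
  while (i <= length(rho)) {
    others <- rho[-i]
    if (length(others) > 0L) {
      cov <- sort(unique(unlist(lapply(others, complex_block,
                                       pairs = pairs, n = n))))
      if (identical(cov, sort(X))) {
        rho <- others
        next
      }
    }
    i <- i + 1L
  }

  complexes <- lapply(rho, function(idx)
    lapply(pairs[idx], function(p) p[c("attribute", "value")]))
  structure(list(complexes = complexes, concept = concept),
            class = "local_covering")
}

#' @export
print.local_covering <- function(x, ...) {
  cat(sprintf("<local covering of '%s': %d minimal complex(es)>\n",
              x$concept, length(x$complexes)))
  for (P in x$complexes)
    cat("  ", paste(vapply(P, function(p)
      paste0(p$attribute, "=", p$value), character(1)), collapse = " & "),
      "\n", sep = "")
  invisible(x)
}

#' Induce a rule set from a decision table
#'
#' Runs [lem2()] once per decision label (in domain order) and converts every
#' minimal complex into a conjunctive rule with provenance `"lem2"`.
#'
#' @param table a [decision_table()].
#' @return a `ruleset` (see [rule()]).
#' @export
induce_rules <- function(table) {
  stopifnot(inherits(table, "decision_table"))
  rules <- list()
  for (lab in table$domains[[table$decision]]) {
    cov <- lem2(table, lab)
    for (P in cov$complexes) {
      ante <- stats::setNames(
        vapply(P, `[[`, character(1), "value"),
        vapply(P, `[[`, character(1), "attribute"))
      rules[[length(rules) + 1L]] <- rule(as.list(ante), lab,
                                          provenance = "lem2")
    }
  }
  ruleset(rules)
}

#' Discretise continuous features into a decision table
#'
#' Each feature value is replaced by its argmax-membership label under the
#' corresponding linguistic variable; ties go to the lowest-ordered label
#' (`Lo` before `Me` before `Hi`).  When noisy data produce objects with
#' identical label patterns but different classes the table is inconsistent
#' for rule induction; `resolve = "majority"` replaces each conflicting
#' pattern's decisions by the majority class (ties to the earlier label in
#' order of appearance).
#'
#' @param features data.frame with one column per feature plus a class
#'   column.
#' @param variables named list of [linguistic_variable()]s covering every
#'   feature column (e.g. [posture_variables()]).
#' @param class_col name of the class column (default `"label"`).
#' @param resolve `"none"` (keep conflicts) or `"majority"`.
#' @return a [decision_table()] with label domains `Lo/Me/Hi` in that order.
#' @export
discretize <- function(features, variables, class_col = "label",
                       resolve = c("none", "majority")) {
  resolve <- match.arg(resolve)
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0L) stop("'features' is empty", call. = FALSE)
  if (!class_col %in% names(features))
    stop("class column '", class_col, "' not found", call. = FALSE)
  feat_cols <- setdiff(names(features), class_col)
  missing_v <- setdiff(feat_cols, names(variables))
  if (length(missing_v))
    stop("no linguistic variable for feature(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  disc <- lapply(feat_cols, function(fc) {
    v <- variables[[fc]]
    m <- fuzzify(v, features[[fc]])
    if (is.null(dim(m))) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(m)))
    labs <- names(v$labels)
    labs[apply(m, 1L, which.max)]   # which.max takes the first maximum
  })
  names(disc) <- feat_cols
  df <- as.data.frame(disc, stringsAsFactors = FALSE)
  df[[class_col]] <- as.character(features[[class_col]])
  if (resolve == "majority") {
    key <- do.call(paste, c(df[feat_cols], sep = "\r"))
    for (k in unique(key)) {
      i <- which(key == k)
      dec <- df[[class_col]][i]
      if (length(unique(dec)) > 1L) {
        tab <- table(factor(dec, levels = unique(dec)))
        df[[class_col]][i] <- names(tab)[which.max(tab)]
      }
    }
  }
  domains <- c(
    stats::setNames(rep(list(c("Lo", "Me", "Hi")), length(feat_cols)),
                    feat_cols),
    stats::setNames(list(unique(df[[class_col]])), class_col))
  decision_table(df, decision = class_col, domains = domains)
}
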
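#' Discrete fuzzy set
#'
#' Membership degrees sampled on a finite, strictly increasing grid.
#'
#' @param universe strictly increasing numeric grid.
#' @param degrees numeric vector of degrees in `[0, 1]`, same length.
#' @return an object of class `discrete_fuzzy_set`.
#' @export
discrete_fuzzy_set <- function(universe, degrees) {
  stopifnot(is.numeric(universe), is.numeric(degrees),
            length(universe) == length(degrees))
  if (length(universe) == 0L || any(diff(universe) <= 0))
    stop("universe must be a non-empty strictly increasing grid",
         call. = FALSE)
  check_unit(degrees, "degrees")
  structure(list(universe = universe, degrees = degrees),
            class = "discrete_fuzzy_set")
}

#' @export
print.discrete_fuzzy_set <- function(x, ...) {
  cat(sprintf("<discrete fuzzy set: %d points on [%g, %g], height %.3f>\n",
              length(x$universe), min(x$universe), max(x$universe),
              max(x$degrees)))
  invisible(x)
}

#' Inference engine configuration
#'
#' Bundles the tunable pieces of the Mamdani engine.  In `classic` mode a
#' rule's activation is simply the premise aggregation `A(p_1, ..., p_n)`;
#' in `knowledge` mode it is the knowledge-augmented
#' `OR = B(A(p_1, ..., p_n), K(p))` of [operator_or()].  Per pose class the
#' rule activations are combined by maximum, each consequent curve is
#' clipped at its class activation by `implication_clip` (a t-norm, `min` by
#' default), the class sets are merged by pointwise maximum, and the merged
#' set is defuzzified by centre of gravity on a `grid_points`-point grid
#' over the pose universe.  A centroid below `decision_threshold` is read as
#' the lying pose.
#'
#' @param mode `"classic"` or `"knowledge"`.
#' @param premise_aggregator inner [aggregator()] `A` across premises.
#' @param combiner binary [aggregator()] `B` (knowledge mode only).
#' @param kspec a [knowledge_spec()] (knowledge mode only).
#' @param implication_clip t-norm used to clip consequent curves.
#' @param grid_points pose-universe grid resolution (at least 101).
#' @param decision_threshold centroid cut between `isLy` and `notLy`,
#'   in `(0, 1)`.
#' @return an object of class `inference_config`.
#' @seealso [k_config()] for the named knowledge-mode presets.
#' @export
inference_config <- function(mode = c("classic", "knowledge"),
                             premise_aggregator = aggregator("tm"),
                             combiner = NULL, kspec = NULL,
                             implication_clip = aggregator("tm"),
                             grid_points = 1001L,
                             decision_threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(premise_aggregator, "fz_aggregator"),
            inherits(implication_clip, "fz_aggregator"))
  if (mode == "knowledge") {
    if (is.null(combiner) || is.null(kspec))
      stop("knowledge mode requires both 'combiner' and 'kspec'",
           call. = FALSE)
    stopifnot(inherits(combiner, "fz_aggregator"),
              inherits(kspec, "knowledge_spec"))
  }
  grid_points <- as.integer(grid_points)
  if (grid_points < 101L) stop("grid_points must be at least 101",
                               call. = FALSE)
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stop("decision_threshold must lie in (0, 1)", call. = FALSE)
  structure(list(mode = mode, premise_aggregator = premise_aggregator,
                 combiner = combiner, kspec = kspec,
                 implication_clip = implication_clip,
                 grid_points = grid_points,
                 decision_threshold = decision_threshold),
            class = "inference_config")
}

#' Named knowledge-mode configurations
#'
#' The five operator combinations compared in the system's evaluation, each
#' written `(A, B, P)`: inner premise aggregation `A`, outer combiner `B`,
#' and the aggregation `P` inside the precedence indicator of the
#' knowledge measure (standard negation throughout):
#' \describe{
#'   \item{K1}{`(qmean, pre_f, qmean)`}
#'   \item{K2}{`(qmean, pre_f, max)` -- the reference configuration, whose
#'     knowledge term has the closed form `|2x - 1| / (1 - min(x, 1 - x))`.}
#'   \item{K3}{`(min, pre_f, qmean)`}
#'   \item{K4}{`(amean, pre_f, amean)`}
#'   \item{K5}{`(amean, min, max)`}
#' }
#'
#' @param name one of `"K1"` ... `"K5"`.
#' @param ... further arguments passed to [inference_config()] (e.g.
#'   `grid_points`).
#' @return an [inference_config()] in knowledge mode.
#' @export
k_config <- function(name = c("K1", "K2", "K3", "K4", "K5"), ...) {
  name <- match.arg(name)
  parts <- switch(name,
    K1 = list(inner = "qmean", outer = "pre_f", prec = "qmean"),
    K2 = list(inner = "qmean", outer = "pre_f", prec = "sm"),
    K3 = list(inner = "tm",    outer = "pre_f", prec = "qmean"),
    K4 = list(inner = "amean", outer = "pre_f", prec = "amean"),
    K5 = list(inner = "amean", outer = "tm",    prec = "sm"))
  kspec <- knowledge_spec("prec_based",
                          precedence_spec(aggregator(parts$prec),
                                          fuzzy_negation("standard")))
  inference_config(mode = "knowledge",
                   premise_aggregator = aggregator(parts$inner),
                   combiner = aggregator(parts$outer), kspec = kspec, ...)
}

#' Activation of one rule for one frame
#'
#' @param rule an [rule()] object.
#' @param degrees named list: per feature, a named vector of label
#'   memberships (as returned by [fuzzify()]).
#' @param config an [inference_config()].
#' @return a single activation degree in `[0, 1]`.
#' @export
rule_activation <- function(rule, degrees, config) {
  stopifnot(inherits(rule, "frsys_rule"), inherits(config, "inference_config"))
  missing_f <- setdiff(names(rule$antecedent), names(degrees))
  if (length(missing_f))
    stop("no membership degrees for feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  premises <- vapply(names(rule$antecedent), function(f) {
    lab <- rule$antecedent[[f]]
    d <- degrees[[f]]
    if (!lab %in% names(d))
      stop("feature '", f, "' has no label '", lab, "'", call. = FALSE)
    d[[lab]]
  }, numeric(1))
  if (config$mode == "classic")
    fz_agg(config$premise_aggregator, premises)
  else
    operator_or(premises, config$premise_aggregator, config$combiner,
                config$kspec)
}

# aggregation of a premise matrix (rows = frames, cols = conditions),
# vectorised across frames
inner_apply <- function(spec, M) {
  k <- ncol(M)
  if (k == 1L) return(M[, 1L])
  kind <- spec$kind
  if (kind %in% .agg_binary_only) {
    if (k > 2L)
      stop(sprintf("aggregator '%s' is strictly binary (got %d values)",
                   kind, k), call. = FALSE)
    return(fz_agg2(spec, M[, 1L], M[, 2L]))
  }
  switch(kind,
    amean = rowMeans(M),
    gmean = ifelse(apply(M == 0, 1L, any), 0, exp(rowMeans(log(pmax(M, 1e-300))))),
    qmean = sqrt(rowMeans(M^2)),
    owa = {
      if (length(spec$weights) != k)
        stop("OWA weight length does not match the number of premises",
             call. = FALSE)
      S <- t(apply(M, 1L, sort, decreasing = TRUE))
      as.numeric(S %*% spec$weights)
    },
    Reduce(function(p, q) fz_agg2(spec, p, q),
           lapply(seq_len(k), function(j) M[, j]))
  )
}

# knowledge measure of each row of a degree matrix
knowledge_rows <- function(kspec, M) {
  x <- as.vector(M)
  switch(kspec$kind,
    sls = rowMeans(matrix(2 * (x^2 + (1 - x)^2) - 1, nrow = nrow(M))),
    ak  = log2(2 * rowMeans(matrix(x^2 + (1 - x)^2, nrow = nrow(M)))),
    prec_based = {
      top <- precedence(kspec$precedence, rep(1, length(x)), x)
      bot <- precedence(kspec$precedence, x, rep(0, length(x)))
      den <- 1 - pmin(top, bot)
      if (any(den <= 1e-12))
        stop("degenerate precedence values in knowledge term", call. = FALSE)
      rowMeans(matrix(abs(top - bot) / den, nrow = nrow(M)))
    })
}

# n x R activation matrix for all rules over fuzzified feature degrees
# (deg: named list of n x 3 membership matrices)
activation_matrix <- function(rules, deg, config) {
  n <- nrow(deg[[1L]])
  acts <- matrix(0, n, length(rules))
  for (j in seq_along(rules)) {
    r <- rules[[j]]
    M <- vapply(names(r$antecedent), function(f) {
      if (is.null(deg[[f]]))
        stop("no membership degrees for feature '", f, "'", call. = FALSE)
      deg[[f]][, r$antecedent[[f]]]
    }, numeric(n))
    if (n == 1L) M <- matrix(M, nrow = 1L)
    a <- inner_apply(config$premise_aggregator, M)
    if (config$mode == "knowledge")
      a <- fz_agg2(config$combiner, a, knowledge_rows(config$kspec, M))
    acts[, j] <- a
  }
  acts
}

#' Run the rule base on one frame and build the pose output set
#'
#' Per pose class the activation is the maximum over that class's rule
#' activations; the class's consequent curve is clipped at the activation by
#' the configured t-norm, and the three clipped sets are merged by pointwise
#' maximum.
#'
#' @param rules a `ruleset`.
#' @param fv named list or one-row data.frame with the feature values.
#' @param config an [inference_config()].
#' @param variables linguistic variables including the `pose` output (e.g.
#'   [posture_variables()]).
#' @return list with `activations` (named per pose class), `class_sets`
#'   (named list of [discrete_fuzzy_set()]), and `output` (the merged set).
#' @export
infer_output_set <- function(rules, fv, config, variables) {
  stopifnot(inherits(rules, "frsys_ruleset"),
            inherits(config, "inference_config"))
  if (length(rules) == 0L) stop("rule set is empty", call. = FALSE)
  pose <- variables$pose
  if (is.null(pose)) stop("'variables' must include the pose output",
                          call. = FALSE)
  classes <- names(pose$labels)
  cons <- vapply(rules, `[[`, character(1), "consequent")
  bad <- setdiff(unique(cons), classes)
  if (length(bad))
    stop("rule consequent(s) not among the pose labels: ",
         paste(bad, collapse = ", "), call. = FALSE)

  feats <- setdiff(names(variables), "pose")
  deg <- list()
  for (f in feats) {
    if (is.null(fv[[f]])) next
    d <- fuzzify(variables[[f]], as.numeric(fv[[f]]))
    deg[[f]] <- matrix(d, nrow = 1L, dimnames = list(NULL, names(d)))
  }
  acts <- activation_matrix(rules, deg, config)[1L, ]

  class_act <- vapply(classes, function(cl) {
    i <- which(cons == cl)
    if (length(i) == 0L) 0 else max(acts[i])
  }, numeric(1))

  grid <- seq(pose$universe[1], pose$universe[2],
              length.out = config$grid_points)
  class_sets <- lapply(classes, function(cl) {
    curve <- eval_mf(pose$labels[[cl]], grid)
    discrete_fuzzy_set(grid, fz_agg2(config$implication_clip,
                                     rep(class_act[[cl]], length(grid)),
                                     curve))
  })
  names(class_sets) <- classes
  merged <- Reduce(pmax, lapply(class_sets, `[[`, "degrees"))
  list(activations = class_act, class_sets = class_sets,
       output = discrete_fuzzy_set(grid, merged))
}

#' Centre-of-gravity defuzzification
#'
#' `sum(x_i * mu_i) / sum(mu_i)` over the grid of a discrete fuzzy set.
#'
#' @param fs a [discrete_fuzzy_set()] with at least one positive degree.
#' @return the centroid, a value inside the grid range.
#' @export
cog_defuzzify <- function(fs) {
  stopifnot(inherits(fs, "discrete_fuzzy_set"))
  s <- sum(fs$degrees)
  if (s <= 0)
    stop(structure(class = c("frsys_zero_set", "error", "condition"),
                   list(message = "centroid of an all-zero set is undefined",
                        call = sys.call(-1))))
  sum(fs$universe * fs$degrees) / s
}

#' Classify one frame
#'
#' Full single-frame pipeline: fuzzify the features, run the rule base,
#' defuzzify by centre of gravity and threshold the centroid.  A centroid
#' below the decision threshold means a lying pose (`isLy`), otherwise
#' `notLy`.  An all-zero output set (no rule fired) is mapped to `notLy`
#' with a warning: no evidence of lying must not raise an alarm.
#'
#' @inheritParams infer_output_set
#' @return list with `pose_label` (`"isLy"`/`"notLy"`), `cog_score`, and
#'   `class_activations`.
#' @seealso [classify_batch()] for feature tables.
#' @export
#' @examples
#' vars <- posture_variables()
#' rs <- enumerate_knowledge_rules()
#' cfg <- inference_config("classic", aggregator("amean"))
#' classify(list(hw = 0.7, hmax = 0.3, sigma = 380, p40 = 0.6),
#'          rs, cfg, vars)$pose_label  # "isLy"
classify <- function(fv, rules, config, variables) {
  res <- infer_output_set(rules, fv, config, variables)
  if (sum(res$output$degrees) <= 0) {
    warning("all-zero output set; defaulting to notLy", call. = FALSE)
    return(list(pose_label = "notLy", cog_score = NA_real_,
                class_activations = res$activations))
  }
  cog <- cog_defuzzify(res$output)
  list(pose_label = if (cog < config$decision_threshold) "isLy" else "notLy",
       cog_score = cog, class_activations = res$activations)
}

#' Classify a table of frames
#'
#' Vectorised batch variant of [classify()]: one row per frame, echoing the
#' input features and appending the centroid, the binary pose label and the
#' per-class activations.
#'
#' @param features data.frame with columns `hw`, `hmax`, `sigma`, `p40` (any
#'   extra columns are carried through).
#' @inheritParams infer_output_set
#' @return the input data.frame plus columns `cog`, `pose_label` and
#'   `act_<class>`.
#' @export
classify_batch <- function(features, rules, config, variables) {
  stopifnot(is.data.frame(features), inherits(rules, "frsys_ruleset"),
            inherits(config, "inference_config"))
  if (length(rules) == 0L) stop("rule set is empty", call. = FALSE)
  n <- nrow(features)
  if (n == 0L) stop("'features' is empty", call. = FALSE)
  pose <- variables$pose
  feats <- intersect(setdiff(names(variables), "pose"), names(features))
  deg <- lapply(feats, function(f) {
    m <- fuzzify(variables[[f]], as.numeric(features[[f]]))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                     dimnames = list(NULL, names(m)))
    m
  })
  names(deg) <- feats

  acts <- activation_matrix(rules, deg, config)
  cons <- vapply(rules, `[[`, character(1), "consequent")
  classes <- names(pose$labels)
  class_act <- vapply(classes, function(cl) {
    i <- which(cons == cl)
    if (length(i) == 0L) rep(0, n)
    else do.call(pmax, lapply(i, function(j) acts[, j]))
  }, numeric(n))
  if (n == 1L) class_act <- matrix(class_act, nrow = 1L,
                                   dimnames = list(NULL, classes))

  grid <- seq(pose$universe[1], pose$universe[2],
              length.out = config$grid_points)
  merged <- matrix(0, n, length(grid))
  for (cl in classes) {
    curve <- eval_mf(pose$labels[[cl]], grid)
    clipped <- outer(class_act[, cl], curve,
                     function(a, m) fz_agg2(config$implication_clip, a, m))
    merged <- pmax(merged, clipped)
  }
  mass <- rowSums(merged)
  cog <- ifelse(mass > 0, as.numeric(merged %*% grid) / mass, NA_real_)
  if (any(mass <= 0))
    warning(sum(mass <= 0),
            " frame(s) produced an all-zero output set; defaulting to notLy",
            call. = FALSE)
  out <- features
  out$cog <- cog
  out$pose_label <- ifelse(!is.na(cog) & cog < config$decision_threshold,
                           "isLy", "notLy")
  colnames(class_act) <- paste0("act_", classes)
  cbind(out, as.data.frame(class_act))
}

#' Generalised modus ponens composition
#'
#' Composes a fact set `D'` on universe `P` with a fuzzy relation `R` on
#' `P x Q`: `E'(q) = A_{p in P} B(D'(p), R(p, q))`, the aggregation-based
#' generalisation of sup-min composition (`A = max`, `B = min`).
#'
#' @param input_degrees numeric vector: the fact set `D'` over `P`.
#' @param relation numeric matrix `|P| x |Q|` of relation degrees.
#' @param outer n-ary [aggregator()] `A` taken over `P`.
#' @param inner binary [aggregator()] `B`.
#' @return numeric vector: the conclusion set `E'` over `Q`.
#' @seealso [relation_from_implication()], [relation_from_aggregation()]
#' @export
gmp_compose <- function(input_degrees, relation, outer, inner) {
  stopifnot(is.matrix(relation), is.numeric(input_degrees))
  if (length(input_degrees) != nrow(relation))
    stop("length of the fact set must match nrow(relation)", call. = FALSE)
  check_unit(input_degrees, "input_degrees")
  check_unit(as.vector(relation), "relation")
  vapply(seq_len(ncol(relation)), function(q)
    fz_agg(outer, fz_agg2(inner, input_degrees, relation[, q])),
    numeric(1))
}

#' Build a fuzzy relation for the generalised modus ponens
#'
#' `relation_from_implication()` sets `R(p, q) = I(D(p), E(q))` for a fuzzy
#' implication `I`; `relation_from_aggregation()` sets
#' `R(p, q) = A(1 - D(p), E(q))`, which is an implication whenever
#' `A(1, 0) = A(0, 1) = 1` (checked; e.g. `max`, `sl`).
#'
#' @param impl a [fuzzy_implication()].
#' @param agg an [aggregator()] with `A(1, 0) = A(0, 1) = 1`.
#' @param antecedent_degrees numeric vector: the rule antecedent set `D`.
#' @param consequent_degrees numeric vector: the rule consequent set `E`.
#' @return numeric matrix `length(D) x length(E)`.
#' @export
relation_from_implication <- function(impl, antecedent_degrees,
                                      consequent_degrees) {
  outer(antecedent_degrees, consequent_degrees,
        function(p, q) fz_impl(impl, p, q))
}

#' @rdname relation_from_implication
#' @export
relation_from_aggregation <- function(agg, antecedent_degrees,
                                      consequent_degrees) {
  stopifnot(inherits(agg, "fz_aggregator"))
  if (abs(fz_agg2(agg, 1, 0) - 1) > 1e-12 ||
      abs(fz_agg2(agg, 0, 1) - 1) > 1e-12)
    stop("aggregation must satisfy A(1,0) = A(0,1) = 1 to induce an ",
         "implication", call. = FALSE)
  outer(antecedent_degrees, consequent_degrees,
        function(p, q) fz_agg2(agg, 1 - p, q))
}
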
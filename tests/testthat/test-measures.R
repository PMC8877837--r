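# every precedence indicator the system ships: five symmetric aggregations
# below max, crossed with the standard and a Sugeno strong negation
shipped_precedence_specs <- function() {
  aggs <- c("amean", "gmean", "qmean", "tm", "sm")
  negs <- list(standard = fuzzy_negation("standard"),
               sugeno1 = fuzzy_negation("sugeno", lambda = 1))
  out <- list()
  for (a in aggs)
    for (nn in names(negs))
      out[[paste(a, nn, sep = ".")]] <-
        precedence_spec(aggregator(a), negs[[nn]])
  out
}

test_that("worked precedence values match the closed forms", {
  amean_std <- precedence_spec(aggregator("amean"),
                               fuzzy_negation("standard"))
  expect_equal(precedence(amean_std, 0.8, 0.2), 0.2)       # (1-p+q)/2
  amean_sug <- precedence_spec(aggregator("amean"),
                               fuzzy_negation("sugeno", lambda = 1))
  expect_equal(precedence(amean_sug, 0.5, 0.1),
               ((1 - 0.5) / (1 + 0.5) + 0.1) / 2, tolerance = 1e-12)
  expect_equal(round(precedence(amean_sug, 0.5, 0.1), 5), 0.21667)
  for (sp in shipped_precedence_specs()) {
    expect_equal(precedence(sp, 0.3, 0.7), 1)              # p <= q
    expect_equal(precedence(sp, 1, 0), 0)
  }
})

test_that("axioms P1-P3 hold on a 201x201 grid for every shipped indicator", {
  g <- unit_grid(201)
  gr <- expand.grid(p = g, q = g)
  # aggregations with A(p, q) = 0 only at (0, 0) give the full P1 "iff";
  # min and gmean vanish on the axes and P1 degenerates (checked below)
  strict_p1 <- c("amean", "qmean", "sm")
  for (nm in names(shipped_precedence_specs())) {
    sp <- shipped_precedence_specs()[[nm]]
    v <- precedence(sp, gr$p, gr$q)
    expect_true(all(v >= 0 & v <= 1), info = nm)
    expect_equal(precedence(sp, 1, 0), 0, info = nm)       # P1, "if"
    if (sp$aggregator$kind %in% strict_p1)
      expect_identical(which(v <= 1e-12),
                       which(gr$p == 1 & gr$q == 0), info = nm)
    # P2: one exactly on p <= q
    expect_identical(which(v >= 1 - 1e-12), which(gr$p <= gr$q), info = nm)
    # P3: for p <= q <= r, Prec(r,p) <= Prec(q,p) and Prec(r,p) <= Prec(r,q)
    m <- matrix(v, length(g))  # m[i, j] = Prec(p_i, q_j)
    expect_true(all(apply(m, 2, function(col) all(diff(col) <= 1e-12))),
                info = nm)     # antitone in the first argument
    expect_true(all(apply(m, 1, function(row) all(diff(row) >= -1e-12))),
                info = nm)     # isotone in the second argument
  }
  # characterised P1 degeneracy of the min- and gmean-built indicators:
  # they vanish away from (1, 0), so the "only at (1,0)" direction fails
  for (a in c("tm", "gmean")) {
    sp <- precedence_spec(aggregator(a), fuzzy_negation("standard"))
    expect_equal(precedence(sp, 0.5, 0), 0, info = a)
  }
})

test_that("construction rejects aggregations above max and binary-only kinds", {
  expect_error(precedence_spec(aggregator("sp"), fuzzy_negation("standard")),
               "A <= max")
  expect_error(precedence_spec(aggregator("sl"), fuzzy_negation("standard")),
               "A <= max")
  expect_error(precedence_spec(aggregator("pre_f"),
                               fuzzy_negation("standard")), "monotone")
})

test_that("the two known implication-but-not-precedence operations violate the axioms", {
  # operation 1: 1 on p <= q, 0 at p = 1 (any q != 1), 1/2 elsewhere
  op1 <- function(p, q) ifelse(p <= q, 1, ifelse(p == 1 & q != 1, 0, 0.5))
  # it is a fuzzy implication (boundary values check out) ...
  expect_equal(op1(0, 0), 1); expect_equal(op1(1, 1), 1)
  expect_equal(op1(1, 0), 0)
  # ... but P1 fails: it vanishes away from (1, 0)
  expect_equal(op1(1, 0.5), 0)

  # operation 2: |p-q| on p < q, 1 on p = q, A(N(p), q) otherwise
  op2 <- function(p, q) ifelse(p < q, abs(p - q),
                        ifelse(p == q, 1 - abs(p - q), (1 - p + q) / 2))
  # P2 fails: p <= q does not give 1
  expect_lt(op2(0.2, 0.7), 1)
  g <- unit_grid(201)
  gr <- expand.grid(p = g, q = g)
  bad2 <- op2(gr$p, gr$q)
  expect_false(all(bad2[gr$p <= gr$q] >= 1 - 1e-12))
})

test_that("worked knowledge values match hand computation", {
  kmax <- knowledge_spec("prec_based")
  expect_equal(knowledge(kmax, c(1, 0)), 1)
  expect_equal(knowledge(kmax, c(0.5, 0.5, 0.5)), 0)
  expect_equal(knowledge(kmax, 0.75), 2 / 3, tolerance = 1e-12)
  expect_equal(knowledge(knowledge_spec("sls"), 0.75), 0.25)
  expect_equal(round(knowledge(knowledge_spec("ak"), 0.75), 5), 0.32193)
  expect_error(knowledge(kmax, numeric(0)), "non-empty")
})

test_that("the max-aggregation measure equals its closed form elementwise", {
  kmax <- knowledge_spec("prec_based")
  x <- unit_grid(501)
  closed <- abs(2 * x - 1) / (1 - pmin(x, 1 - x))
  direct <- vapply(x, function(t) knowledge(kmax, t), numeric(1))
  expect_equal(direct, closed, tolerance = 1e-12)
})

test_that("construction enforces the symmetric-aggregation and equilibrium requirements", {
  # Sugeno lambda = 1 has equilibrium sqrt(2) - 1, not 0.5
  expect_error(
    knowledge_spec("prec_based",
                   precedence_spec(aggregator("sm"),
                                   fuzzy_negation("sugeno", lambda = 1))),
    "equilibrium")
  # 1 - p^2 is not strong
  expect_error(
    knowledge_spec("prec_based",
                   precedence_spec(aggregator("sm"),
                                   fuzzy_negation("strict_sq"))),
    "strong")
})

prop2_measures <- function() {
  aggs <- c("amean", "gmean", "qmean", "tm", "sm")
  stats::setNames(lapply(aggs, function(a)
    knowledge_spec("prec_based",
                   precedence_spec(aggregator(a),
                                   fuzzy_negation("standard")))), aggs)
}

test_that("axioms K1-K4 hold for the precedence-based measures", {
  set.seed(1203)
  rand_vecs <- replicate(10000, stats::runif(sample(1:6, 1)),
                         simplify = FALSE)
  grid_vals <- unit_grid(201)
  # the amean/qmean/max constructions satisfy the full iff axioms; the
  # min/gmean ones inherit the P1 degeneracy (their K is the crisp
  # fraction), so only the one-directional parts are asserted for them
  strict <- c("amean", "qmean", "sm")
  for (nm in names(prop2_measures())) {
    k <- prop2_measures()[[nm]]
    # K1: maximal on crisp vectors
    expect_equal(knowledge(k, c(0, 1, 1, 0)), 1, info = nm)
    kg <- vapply(grid_vals, function(t) knowledge(k, t), numeric(1))
    expect_true(all(kg[grid_vals > 0 & grid_vals < 1] < 1), info = nm)
    # K2: minimal on the all-0.5 vector
    expect_equal(knowledge(k, rep(0.5, 4)), 0, info = nm)
    kr <- vapply(rand_vecs, function(v) knowledge(k, v), numeric(1))
    expect_true(all(kr >= 0 & kr <= 1), info = nm)
    if (nm %in% strict) {
      expect_true(all(kg[abs(grid_vals - 0.5) > 1e-9] > 0), info = nm)
      expect_true(all(kr[vapply(rand_vecs, function(v)
        any(v > 1e-9 & v < 1 - 1e-9), logical(1))] < 1), info = nm)
    }
  }
  # characterised degeneracy of the min-built measure: it counts the crisp
  # fraction, so a non-0.5 fuzzy singleton still carries zero knowledge
  kmin <- prop2_measures()[["tm"]]
  expect_equal(knowledge(kmin, 0.3), 0)
})

test_that("sharpening a vector towards {0,1} never decreases knowledge", {
  set.seed(77)
  ks <- c(prop2_measures(),
          list(sls = knowledge_spec("sls"), ak = knowledge_spec("ak")))
  for (i in 1:200) {
    v <- stats::runif(sample(1:5, 1))
    # sharpened version: push every degree towards its nearest extreme
    t <- stats::runif(1)
    v_sharp <- ifelse(v >= 0.5, v + t * (1 - v), v * (1 - t))
    for (nm in names(ks))
      expect_gte(knowledge(ks[[nm]], v_sharp) + 1e-12,
                 knowledge(ks[[nm]], v))
  }
})

test_that("knowledge is invariant under standard-negation complement", {
  set.seed(42)
  ks <- c(prop2_measures(),
          list(sls = knowledge_spec("sls"), ak = knowledge_spec("ak")))
  for (i in 1:200) {
    v <- stats::runif(sample(1:5, 1))
    for (nm in names(ks))
      expect_equal(knowledge(ks[[nm]], v), knowledge(ks[[nm]], 1 - v),
                   tolerance = 1e-12)
  }
})

test_that("the literature measures satisfy K1 and K2 on the same harness", {
  for (k in list(knowledge_spec("sls"), knowledge_spec("ak"))) {
    expect_equal(knowledge(k, c(1, 0, 1)), 1)
    expect_equal(knowledge(k, rep(0.5, 3)), 0)
    g <- unit_grid(201)
    kg <- vapply(g, function(t) knowledge(k, t), numeric(1))
    expect_true(all(kg[g > 0 & g < 1] < 1))
    expect_true(all(kg[abs(g - 0.5) > 1e-9] > 0))
  }
})

test_that("the OR operator combines premise strength with knowledge", {
  kmax <- knowledge_spec("prec_based")
  # hand oracle on the worked premise vector
  x <- c(0.9, 0.8, 1.0, 0.7)
  a <- sqrt(mean(x^2))
  kv <- mean(abs(2 * x - 1) / (1 - pmin(x, 1 - x)))
  expect_equal(operator_or(x, aggregator("qmean"), aggregator("pre_f"),
                           kmax),
               a - max(0, a - kv)^2, tolerance = 1e-12)
  expect_equal(round(operator_or(x, aggregator("qmean"),
                                 aggregator("pre_f"), kmax), 4), 0.8543)
  # certain premises
  expect_equal(operator_or(c(1, 1, 1), aggregator("amean"),
                           aggregator("tm"), kmax), 1)
  # maximally fuzzy premises suppressed by the knowledge term
  expect_equal(operator_or(c(0.5, 0.5), aggregator("amean"),
                           aggregator("tm"), kmax), 0)
  expect_error(operator_or(numeric(0), aggregator("amean"),
                           aggregator("tm"), kmax), "non-empty")
})
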
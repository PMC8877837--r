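fv_lying <- list(hw = 0.7, hmax = 0.3, sigma = 380, p40 = 0.6)
fv_upright <- list(hw = 3.0, hmax = 0.95, sigma = 270, p40 = 0.2)

test_that("rule activations follow the configured aggregation mode", {
  deg <- list(hw = c(Lo = 0.9, Me = 0.1, Hi = 0),
              p40 = c(Lo = 0, Me = 0.2, Hi = 0.4))
  r <- rule(list(hw = "Lo", p40 = "Hi"), "isLy")
  classic_min <- inference_config("classic", aggregator("tm"))
  expect_equal(rule_activation(r, deg, classic_min), 0.4)
  # knowledge mode on the worked premise vector
  r4 <- rule(list(hw = "Lo", hmax = "Lo", sigma = "Me", p40 = "Hi"), "isLy")
  deg4 <- list(hw = c(Lo = 0.9, Me = 0, Hi = 0),
               hmax = c(Lo = 0.8, Me = 0, Hi = 0),
               sigma = c(Lo = 0, Me = 1.0, Hi = 0),
               p40 = c(Lo = 0, Me = 0, Hi = 0.7))
  expect_equal(round(rule_activation(r4, deg4, k_config("K2")), 4), 0.8543)
  # certain premises stay certain in knowledge mode
  deg1 <- list(hw = c(Lo = 1, Me = 0, Hi = 0),
               p40 = c(Lo = 0, Me = 0, Hi = 1))
  expect_equal(rule_activation(r, deg1, k_config("K2")), 1)
  expect_error(rule_activation(r, deg["hw"], classic_min), "p40")
})

test_that("classic activation is monotone in the premises; knowledge mode is not", {
  classic <- inference_config("classic", aggregator("qmean"))
  k2 <- k_config("K2")
  r <- rule(list(hw = "Lo", p40 = "Hi"), "isLy")
  act <- function(cfg, p, q)
    rule_activation(r, list(hw = c(Lo = p, Me = 0, Hi = 0),
                            p40 = c(Lo = 0, Me = 0, Hi = q)), cfg)
  g <- unit_grid(21)
  for (q in g) {
    classic_vals <- vapply(g, act, numeric(1), cfg = classic, q = q)
    expect_true(all(diff(classic_vals) >= -1e-12))
  }
  # characterised counterexample: raising a premise lowers the OR output
  expect_lt(act(k2, 0.5, 1), act(k2, 0.45, 1))
})

test_that("output sets are clipped consequents merged by maximum", {
  vars <- posture_variables()
  cfg <- inference_config("classic", aggregator("tm"), grid_points = 201)
  # single rule firing at 1: output equals the consequent curve exactly
  rs1 <- ruleset(list(rule(list(hw = "Lo"), "isLy")))
  res <- infer_output_set(rs1, list(hw = 0.1), cfg, vars)
  expect_equal(res$activations[["isLy"]], 1)
  grid <- res$output$universe
  expect_equal(res$class_sets$isLy$degrees,
               eval_mf(vars$pose$labels$isLy, grid))
  # two rules of the same class: the class activation is their maximum
  rs2 <- ruleset(list(rule(list(hw = "Lo"), "isLy"),
                      rule(list(p40 = "Hi"), "isLy")))
  deg_hw <- fuzzify(vars$hw, 1.4)[["Lo"]]
  deg_p40 <- fuzzify(vars$p40, 0.6)[["Hi"]]
  res2 <- infer_output_set(rs2, list(hw = 1.4, p40 = 0.6), cfg, vars)
  expect_equal(res2$activations[["isLy"]], max(deg_hw, deg_p40))
  # no rule fires: flat-zero output set
  res0 <- infer_output_set(rs1, list(hw = 4.9), cfg, vars)
  expect_true(all(res0$output$degrees == 0))
  # unknown consequent class
  bad <- ruleset(list(rule(list(hw = "Lo"), "standing")))
  expect_error(infer_output_set(bad, list(hw = 1), cfg, vars),
               "pose labels")
})

test_that("centre of gravity matches symmetry, spikes and fine quadrature", {
  # symmetric triangle about 0.5
  g <- seq(0, 1, length.out = 1001)
  tri <- pmax(0, 1 - abs(g - 0.5) / 0.3)
  expect_equal(cog_defuzzify(discrete_fuzzy_set(g, tri)), 0.5,
               tolerance = 1e-9)
  # singleton spike
  spike <- as.numeric(abs(g - 0.36) < 1e-9)
  expect_equal(cog_defuzzify(discrete_fuzzy_set(g, spike)), 0.36)
  # clipped Z-curve against a 1e5-point quadrature oracle
  z <- mf_z(0.22, b = 0.5)
  clip <- 0.6
  gg <- seq(0, 1, length.out = 1001)
  mu <- pmin(eval_mf(z, gg), clip)
  fine <- seq(0, 1, length.out = 100001)
  mu_fine <- pmin(eval_mf(z, fine), clip)
  oracle <- sum(fine * mu_fine) / sum(mu_fine)
  # agreement within the engine's grid-discretisation stability bound
  expect_lt(abs(cog_defuzzify(discrete_fuzzy_set(gg, mu)) - oracle), 1e-3)
  expect_error(cog_defuzzify(discrete_fuzzy_set(g, rep(0, length(g)))),
               "all-zero")
})

test_that("doubling the grid moves the centroid by less than 1e-3", {
  vars <- posture_variables()
  rs <- enumerate_knowledge_rules()
  for (pts in list(c(1001L, 2001L))) {
    c1 <- classify(fv_lying, rs,
                   inference_config("classic", aggregator("amean"),
                                    grid_points = pts[1]), vars)
    c2 <- classify(fv_lying, rs,
                   inference_config("classic", aggregator("amean"),
                                    grid_points = pts[2]), vars)
    expect_lt(abs(c1$cog_score - c2$cog_score), 1e-3)
  }
})

test_that("end-to-end classification recovers the concept profiles", {
  vars <- posture_variables()
  rs <- enumerate_knowledge_rules()
  for (cfg in list(inference_config("classic", aggregator("amean")),
                   k_config("K2"))) {
    lying <- classify(fv_lying, rs, cfg, vars)
    expect_equal(lying$pose_label, "isLy")
    expect_lt(lying$cog_score, 0.5)
    upright <- classify(fv_upright, rs, cfg, vars)
    expect_equal(upright$pose_label, "notLy")
    expect_gt(upright$cog_score, 0.5)
  }
  expect_error(classify(fv_lying, ruleset(list()),
                        inference_config("classic"), vars), "empty")
})

test_that("batch classification is deterministic and matches single frames", {
  vars <- posture_variables()
  rs <- enumerate_knowledge_rules()
  cfg <- k_config("K2")
  df <- data.frame(hw = c(0.7, 3.0, 1.8), hmax = c(0.3, 0.95, 0.6),
                   sigma = c(380, 270, 310), p40 = c(0.6, 0.2, 0.42))
  b1 <- classify_batch(df, rs, cfg, vars)
  b2 <- classify_batch(df, rs, cfg, vars)
  expect_identical(b1, b2)
  for (i in seq_len(nrow(df))) {
    single <- classify(as.list(df[i, ]), rs, cfg, vars)
    expect_equal(b1$cog[i], single$cog_score, tolerance = 1e-12)
    expect_equal(b1$pose_label[i], single$pose_label)
    expect_equal(unname(unlist(b1[i, c("act_isLy", "act_mayLy",
                                       "act_notLy")])),
                 unname(single$class_activations), tolerance = 1e-12)
  }
})

test_that("the GMP composition generalises sup-min and matches brute force", {
  D <- c(0, 1, 0)                        # singleton fact at p2
  R <- matrix(c(0.2, 0.7, 0.1,
                0.9, 0.4, 0.6,
                0.3, 0.8, 0.5), nrow = 3, byrow = TRUE)
  sup <- aggregator("sm"); inf <- aggregator("tm")
  expect_equal(gmp_compose(D, R, sup, inf), R[2, ])
  # annihilator: an all-zero fact set stays zero under any t-norm
  expect_equal(gmp_compose(c(0, 0, 0), R, sup, aggregator("tp")),
               c(0, 0, 0))
  # 3x3 exhaustive double-loop oracle with mean/product operators
  Dp <- c(0.3, 0.8, 0.5)
  outer_a <- aggregator("amean"); inner_a <- aggregator("tp")
  got <- gmp_compose(Dp, R, outer_a, inner_a)
  want <- vapply(1:3, function(q) {
    acc <- numeric(3)
    for (p in 1:3) acc[p] <- Dp[p] * R[p, q]
    mean(acc)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(gmp_compose(c(0.1, 0.2), R, sup, inf), "match")
})

test_that("relation builders produce implication-valued relations", {
  D <- c(1, 0.6, 0.1); E <- c(0.2, 0.9)
  R_imp <- relation_from_implication(fuzzy_implication("lukasiewicz"), D, E)
  expect_equal(dim(R_imp), c(3L, 2L))
  expect_equal(R_imp[1, 1], fz_impl(fuzzy_implication("lukasiewicz"), 1, 0.2))
  # aggregation-induced implication: A(1 - p, q) with A = max is
  # Kleene-Dienes
  R_agg <- relation_from_aggregation(aggregator("sm"), D, E)
  R_kd <- relation_from_implication(fuzzy_implication("kleene_dienes"), D, E)
  expect_equal(R_agg, R_kd, tolerance = 1e-12)
  # means do not satisfy A(1, 0) = 1 and are rejected
  expect_error(relation_from_aggregation(aggregator("amean"), D, E),
               "A\\(1,0\\)")
})

test_that("configuration validation catches incomplete knowledge setups", {
  expect_error(inference_config("knowledge",
                                premise_aggregator = aggregator("qmean")),
               "combiner")
  expect_error(inference_config("classic", grid_points = 50), "101")
  expect_error(inference_config("classic", decision_threshold = 1.2),
               "\\(0, 1\\)")
})
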
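# Independent reference curves, brute-force rough-set oracles and random
# generators used across the suite.

# internal vectorised binary evaluator, convenient for grid properties
fz_agg2 <- frsys:::fz_agg2

# scalar-loop reference implementations of the Z / S / two-sided Gaussian
# curves, written from the standard textbook definitions
ref_zmf <- function(x, a, b) {
  vapply(x, function(t) {
    if (t <= a) return(1)
    if (t >= b) return(0)
    mid <- (a + b) / 2
    if (t <= mid) 1 - 2 * ((t - a) / (b - a))^2
    else 2 * ((t - b) / (b - a))^2
  }, numeric(1))
}

ref_smf <- function(x, a, b) 1 - ref_zmf(x, a, b)

ref_gauss2 <- function(x, c1, s1, c2, s2) {
  vapply(x, function(t) {
    if (t < c1) exp(-(t - c1)^2 / (2 * s1^2))
    else if (t > c2) exp(-(t - c2)^2 / (2 * s2^2))
    else 1
  }, numeric(1))
}

# random consistent decision table: the decision is a deterministic function
# of the condition pattern, so no two identical rows ever disagree
random_decision_table <- function(n_obj, n_attr, n_vals, n_dec = 2L) {
  vals <- LETTERS[seq_len(n_vals)]
  decs <- paste0("d", seq_len(n_dec))
  df <- as.data.frame(
    lapply(seq_len(n_attr), function(i)
      sample(vals, n_obj, replace = TRUE)),
    col.names = paste0("a", seq_len(n_attr)))
  key <- do.call(paste, c(df, sep = "\r"))
  map <- stats::setNames(sample(decs, length(unique(key)), replace = TRUE),
                         unique(key))
  df$dec <- unname(map[key])
  decision_table(df, "dec",
                 domains = c(stats::setNames(rep(list(vals), n_attr),
                                             paste0("a", seq_len(n_attr))),
                             list(dec = decs)))
}

# brute-force block of a pair: plain column scan
bf_block <- function(tab, attribute, value) {
  which(tab$data[[attribute]] == value)
}

# brute-force block of a complex (list of attribute/value pairs)
bf_complex_block <- function(tab, complex) {
  Reduce(intersect, lapply(complex, function(p)
    bf_block(tab, p$attribute, p$value)))
}

# exhaustive enumeration of every minimal complex of a concept: all subsets
# of attribute-value pairs (one value per attribute) whose block is a
# non-empty subset of X and loses that property when any pair is dropped
bf_minimal_complexes <- function(tab, concept) {
  X <- which(tab$data[[tab$decision]] == concept)
  pairs <- list()
  for (a in tab$attributes)
    for (v in tab$domains[[a]])
      pairs[[length(pairs) + 1L]] <- list(attribute = a, value = v)
  n <- length(pairs)
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    cpx <- pairs[idx]
    attrs <- vapply(cpx, `[[`, character(1), "attribute")
    if (anyDuplicated(attrs)) next
    blk <- bf_complex_block(tab, cpx)
    if (length(blk) == 0L || !all(blk %in% X)) next
    # minimal iff no non-empty proper subset still depends on X
    minimal <- length(cpx) == 1L ||
      all(vapply(seq_along(cpx), function(i) {
        sub <- bf_complex_block(tab, cpx[-i])
        !(length(sub) > 0L && all(sub %in% X))
      }, logical(1)))
    if (minimal) out[[length(out) + 1L]] <- cpx
  }
  out
}

complex_key <- function(cpx) {
  paste(sort(vapply(cpx, function(p)
    paste0(p$attribute, "=", p$value), character(1))), collapse = "&")
}

# verify that a local covering has all defining properties, by brute force
expect_local_covering <- function(tab, cov) {
  X <- sort(which(tab$data[[tab$decision]] == cov$concept))
  blocks <- lapply(cov$complexes, bf_complex_block, tab = tab)
  # every complex block is a non-empty subset of the concept
  for (b in blocks) {
    expect_gt(length(b), 0)
    expect_true(all(b %in% X))
  }
  # union of the blocks covers the concept exactly
  expect_identical(sort(unique(unlist(blocks))), X)
  # minimality of each complex: dropping any pair breaks [P] subset-of X
  for (cpx in cov$complexes) {
    if (length(cpx) > 1L) {
      for (i in seq_along(cpx)) {
        sub <- bf_complex_block(tab, cpx[-i])
        expect_false(length(sub) > 0L && all(sub %in% X))
      }
    }
  }
  # irredundancy: no complex can be dropped while still covering X
  if (length(blocks) > 1L) {
    for (i in seq_along(blocks)) {
      rest <- sort(unique(unlist(blocks[-i])))
      expect_false(identical(rest, X))
    }
  }
  invisible(TRUE)
}

unit_grid <- function(n = 101L) seq(0, 1, length.out = n)
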
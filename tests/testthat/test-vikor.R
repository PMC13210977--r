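test_that("ideal solutions follow the benefit/cost orientation", {
  reg <- default_registry()
  x <- trait_matrix(matrix(c(1, 2, 3, 1, 2, 3, 5, 5, 5), 3, 3,
                           dimnames = list(paste0("V", 1:3),
                                           c("PH", "PLR", "FH"))),
                    registry = reg)
  ids <- ideal_solutions(x, reg)
  expect_equal(ids$f_plus[ids$code == "PH"], 3)    # benefit: max is ideal
  expect_equal(ids$f_minus[ids$code == "PH"], 1)
  expect_equal(ids$f_plus[ids$code == "PLR"], 1)   # cost: min is ideal
  expect_equal(ids$f_minus[ids$code == "PLR"], 3)
  expect_true(ids$degenerate[ids$code == "FH"])
})

test_that("vikor reproduces the frozen hand-computed 3x2 instance", {
  # Two benefit indicators, weights (0.6, 0.4), columns (3,2,1) and (1,3,2).
  # Worked by hand: distances d = w (f+ - x)/(f+ - f-) give
  #   V1: S = 0.4, R = 0.4;  V2: S = 0.3, R = 0.3;  V3: S = 0.8, R = 0.6
  # so Q = (0.266667, 0, 1) at v = 0.5 and ranks (2, 1, 3).
  reg <- default_registry()
  x <- trait_matrix(cbind(PH = c(3, 2, 1), FH = c(1, 3, 2)),
                    variety_ids = c("V1", "V2", "V3"), registry = reg)
  res <- vikor_scores(x, c(PH = 0.6, FH = 0.4), reg, v = 0.5)
  expect_equal(res$s, c(0.4, 0.3, 0.8), tolerance = 1e-12)
  expect_equal(res$r, c(0.4, 0.3, 0.6), tolerance = 1e-12)
  expect_equal(res$q, c(0.5 * 0.1 / 0.5 + 0.5 * 0.1 / 0.3, 0, 1),
               tolerance = 1e-12)
  expect_equal(res$rank, c(2L, 1L, 3L))
})

test_that("ideal and anti-ideal varieties hit the score bounds", {
  reg <- default_registry()
  set.seed(501)
  for (trial in 1:30) {
    x <- random_instance(7, 4)
    dirs <- indicator_dirs_for_test(colnames(x))
    best <- ifelse(dirs == "benefit", apply(x, 2, max), apply(x, 2, min))
    worst <- ifelse(dirs == "benefit", apply(x, 2, min), apply(x, 2, max))
    m <- unclass(x)
    m["V1", ] <- best   # V1 attains f+ everywhere (extremes unchanged)
    m["V2", ] <- worst  # V2 attains f- everywhere
    xm <- trait_matrix(m, registry = reg)
    w <- rep(1 / 4, 4); names(w) <- colnames(xm)
    res <- vikor_scores(xm, w, reg)
    i1 <- which(res$variety == "V1"); i2 <- which(res$variety == "V2")
    expect_equal(res$s[i1], 0, tolerance = 1e-12)
    expect_equal(res$r[i1], 0, tolerance = 1e-12)
    expect_equal(res$q[i1], 0, tolerance = 1e-12)
    expect_equal(res$rank[i1], 1L)
    expect_equal(res$s[i2], 1, tolerance = 1e-12)
    expect_equal(res$r[i2], max(w), tolerance = 1e-12)
    expect_equal(res$q[i2], 1, tolerance = 1e-12)
    expect_true(all(res$q >= 0 & res$q <= 1))
  }
})

test_that("v = 1 and v = 0 reproduce the S and R orderings", {
  reg <- default_registry()
  set.seed(502)
  for (trial in 1:30) {
    x <- random_instance(9, 5)
    w <- critic_weights(x, reg)
    r1 <- vikor_scores(x, w, reg, v = 1)
    expect_equal(rank(r1$q, ties.method = "min"),
                 rank(r1$s, ties.method = "min"))
    r0 <- vikor_scores(x, w, reg, v = 0)
    expect_equal(rank(r0$q, ties.method = "min"),
                 rank(r0$r, ties.method = "min"))
  }
})

test_that("improving a benefit indicator never worsens S or R (fixed weights)", {
  reg <- default_registry()
  set.seed(503)
  for (trial in 1:40) {
    x <- random_instance(8, 4)
    dirs <- indicator_dirs_for_test(colnames(x))
    benefit_cols <- which(dirs == "benefit")
    if (length(benefit_cols) == 0L) next
    j <- benefit_cols[sample.int(length(benefit_cols), 1)]
    # pick a variety strictly inside the column range so extremes are fixed
    col <- x[, j]
    inside <- which(col > min(col) & col < max(col))
    if (length(inside) == 0L) next
    i <- inside[1]
    w <- rep(1 / 4, 4); names(w) <- colnames(x)
    before <- vikor_scores(x, w, reg)
    m <- unclass(x)
    m[i, j] <- m[i, j] + 0.5 * (max(col) - m[i, j])  # improve, stay below max
    after <- vikor_scores(trait_matrix(m, registry = reg), w, reg)
    expect_lte(after$s[i], before$s[i] + 1e-12)
    expect_lte(after$r[i], before$r[i] + 1e-12)
  }
})

test_that("vikor matches the naive reference on random instances", {
  reg <- default_registry()
  set.seed(504)
  for (trial in 1:25) {
    x <- random_instance(8, 5)
    dirs <- indicator_dirs_for_test(colnames(x))
    w <- runif(5); w <- w / sum(w); names(w) <- colnames(x)
    v <- runif(1)
    res <- vikor_scores(x, w, reg, v = v)
    o <- naive_vikor(unclass(x), unname(w), dirs, v = v)
    expect_equal(res$s, o$s, tolerance = 1e-9)
    expect_equal(res$r, o$r, tolerance = 1e-9)
    expect_equal(res$q, o$q, tolerance = 1e-9)
  }
})

test_that("scoring the raw matrix equals scoring the normalized matrix", {
  # with min/max ideal solutions, direction handling via f+/f- on raw data
  # is algebraically the same as benefit-scoring the min-max normalized data
  reg <- default_registry()
  set.seed(505)
  x <- random_instance(10, 6)
  w <- critic_weights(x, reg)
  res_raw <- vikor_scores(x, w, reg)
  nm <- normalize_matrix(x, reg)
  # normalized columns are all "larger is better" regardless of direction;
  # reuse them under benefit codes of the registry
  ben <- default_registry()$code[default_registry()$direction == "benefit"][1:6]
  xn <- trait_matrix(matrix(nm, nrow(nm), dimnames = list(rownames(x), ben)),
                     registry = reg)
  wn <- setNames(w$weight, ben)
  res_norm <- vikor_scores(xn, wn, reg)
  expect_equal(res_raw$s, res_norm$s, tolerance = 1e-9)
  expect_equal(res_raw$r, res_norm$r, tolerance = 1e-9)
})

test_that("ties in Q break deterministically by S, then R, then variety ID", {
  reg <- default_registry()
  # two identical varieties: same S, R, Q; ID decides
  x <- trait_matrix(cbind(PH = c(5, 5, 1), FH = c(2, 2, 9)),
                    variety_ids = c("Vb", "Va", "Vc"), registry = reg)
  w <- c(PH = 0.5, FH = 0.5)
  res <- vikor_scores(x, w, reg)
  expect_equal(res$rank[res$variety == "Va"] < res$rank[res$variety == "Vb"],
               TRUE)
  expect_equal(sort(res$rank), 1:3)
})

test_that("topk_trait_extreme reduces over the k best-ranked varieties", {
  reg <- default_registry()
  set.seed(506)
  x <- random_instance(10, 4)
  w <- critic_weights(x, reg)
  res <- vikor_scores(x, w, reg)
  code <- colnames(x)[1]
  expect_equal(topk_trait_extreme(x, res, code, k = nrow(x)), max(x[, code]))
  top1 <- res$variety[res$rank == 1]
  expect_equal(topk_trait_extreme(x, res, code, k = 1), unname(x[top1, code]))
  expect_equal(topk_trait_extreme(x, res, code, k = 3, which = "min"),
               min(x[res$variety[order(res$rank)][1:3], code]))
  expect_error(topk_trait_extreme(x, res, code, k = 11), "exceeds")
  expect_error(topk_trait_extreme(x, res, "ZZZ", k = 2), "not in matrix")
})
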
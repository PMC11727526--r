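test_that("scale adjustment solves the 2x2 averaging system", {
  K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
  V22 <- matrix(c(2, 1, 1, 2), 2, dimnames = dimnames(K))
  adj <- adjust_scale(K, V22)
  expect_equal(adj$alpha, 1)
  expect_equal(adj$beta, 1)
  expect_equal(adj$Kstar, V22, ignore_attr = TRUE)

  self <- adjust_scale(V22, V22)
  expect_equal(self$alpha, 1)
  expect_equal(self$beta, 0)
})

test_that("singular averaging system falls back to diagonal scale with warning", {
  K <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  V22 <- matrix(0.2, 3, 3, dimnames = dimnames(K)) + diag(0.8, 3)
  expect_warning(adj <- adjust_scale(K, V22), "singular")
  expect_equal(adj$beta, 0)
  expect_equal(mean(diag(adj$Kstar)), mean(diag(V22)))
})

test_that("K_w is the exact convex combination", {
  Ks <- diag(2); V <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(blend_Kw(Ks, V, 0), Ks, ignore_attr = TRUE)
  expect_equal(blend_Kw(Ks, V, 1), V, ignore_attr = TRUE)
  expect_equal(blend_Kw(Ks, V, 0.5), matrix(c(1.5, 0.5, 0.5, 1.5), 2),
               ignore_attr = TRUE)
  expect_error(blend_Kw(Ks, V, 1.2), "\\[0, 1\\]")
  expect_error(blend_Kw(Ks, V, -0.1), "\\[0, 1\\]")
})

test_that("H collapses to V at w = 1 and to K_w with empty subset 1", {
  set.seed(21)
  V <- grm(random_psd(8), "A")
  K <- grm(random_psd(5, ids = paste0("id", 4:8)), "E")
  H1 <- make_H(K, V, w = 1)
  expect_equal(unclass(H1), unclass(V), tolerance = 1e-10, ignore_attr = TRUE)

  K2 <- grm(random_psd(8), "G")                 # same universe as V
  H0 <- make_H(K2, V, w = 0)
  adj <- adjust_scale(unclass(K2), unclass(V))  # subset 1 empty: H = K*
  expect_equal(unclass(H0), adj$Kstar, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("H agrees with the brute-force block-formula oracle", {
  # 3 individuals: 1 in subset 1, 2 in subset 2; V = A of the full-sib toy
  A <- make_A(ped_toy(), subset = c("1", "3", "4"))
  E <- grm(matrix(c(1, -1, -1, 1), 2, dimnames = list(c("3", "4"), c("3", "4"))) +
             diag(0.2, 2), "E")
  H <- make_H(E, A, w = 0.05)
  expect_equal(unclass(H), oracle_H(E, A, 0.05), tolerance = 1e-12,
               ignore_attr = TRUE)
  # H22 block equals K_w exactly
  adj <- adjust_scale(unclass(E), unclass(A)[c("3", "4"), c("3", "4")])
  Kw <- blend_Kw(adj$Kstar, unclass(A)[c("3", "4"), c("3", "4")], 0.05)
  expect_equal(unclass(H)[c("3", "4"), c("3", "4")], Kw, ignore_attr = TRUE)
})

test_that("H is symmetric, ordered like V, and continuous in w", {
  set.seed(33)
  V <- grm(random_psd(12), "A")
  K <- grm(random_psd(7, ids = paste0("id", 6:12)), "G")
  prev <- NULL
  for (w in seq(0, 1, by = 0.25)) {
    H <- make_H(K, V, w)
    expect_identical(rownames(H), rownames(V))
    expect_equal(max(abs(H - t(H))), 0, tolerance = 1e-12)
    if (!is.null(prev)) expect_lt(max(abs(H - prev)), 1)  # no jumps on the path
    prev <- H
  }
  expect_equal(unclass(make_H(K, V, 1)), unclass(V), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("singular V22 is gated with a remedy message; ridge unlocks it", {
  V <- matrix(0.5, 6, 6) + diag(1e-14, 6)
  dimnames(V) <- list(paste0("i", 1:6), paste0("i", 1:6))
  V <- grm(V)
  K <- grm(random_psd(3, ids = paste0("i", 4:6)), "G")
  expect_error(make_H(K, V, w = 0.05), "singular")
  expect_s3_class(make_H(K, V, w = 0.05, ridge = 0.01), "ssexp_grm")
})

test_that("nested H collapses to the base matrix at w = 1", {
  sim <- sim_small()
  H <- make_H_nested(sim$E, sim$A, K_inner = sim$G, w_inner = 1, w_outer = 1)
  expect_equal(unclass(H), unclass(sim$A), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("nested H equals the step-by-step oracle composition", {
  A <- make_A(ped_six())
  set.seed(5)
  G <- grm(random_psd(4, ids = c("3", "4", "5", "6")), "G")
  E <- grm(random_psd(2, ids = c("5", "6"), jitter = 1), "E")
  H <- make_H_nested(E, A, K_inner = G, w_inner = 0.5, w_outer = 0.5)
  expect_equal(unclass(H), oracle_H_nested(E, A, G, 0.5, 0.5),
               tolerance = 1e-12, ignore_attr = TRUE)
  # without an inner layer it reduces to plain make_H
  expect_equal(unclass(make_H_nested(E, A, w_inner = 0.3)),
               unclass(make_H(E, A, 0.3)), tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("subset nesting violations are reported with the offending IDs", {
  A <- make_A(ped_six())
  G <- grm(random_psd(2, ids = c("3", "4")), "G")
  E <- grm(random_psd(2, ids = c("5", "6")), "E")  # not within G's ids
  expect_error(make_H_nested(E, A, K_inner = G, w_inner = 0.1), "5")
})

test_that("double full-coverage nesting composes the two affine adjustments", {
  set.seed(77)
  ids <- paste0("i", 1:6)
  A <- grm(random_psd(6, ids), "A")
  G <- grm(random_psd(6, ids), "G")
  E <- grm(random_psd(6, ids), "E")
  H <- make_H_nested(E, A, K_inner = G, w_inner = 0, w_outer = 0)
  # w = 0 and full coverage at both levels: successive scale adjustments of E
  s1 <- adjust_scale(unclass(G), unclass(A))$Kstar
  s2 <- adjust_scale(unclass(E), s1)
  expect_equal(unclass(H), s2$Kstar, tolerance = 1e-10, ignore_attr = TRUE)
})
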
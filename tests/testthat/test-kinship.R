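test_that("QC filters apply sequentially: call rate, then MAF", {
  # 10 samples, one marker with a single missing call -> call rate 0.9
  calls <- matrix(1L, 10, 1); calls[1, 1] <- NA
  g <- toy_geno(cbind(calls, 1L - (seq_len(10) > 5)))
  out <- qc_filter(g, impute = "naive")
  expect_equal(out$report$n_fail_callrate, 1L)
  expect_equal(out$report$markers$verdict[1], "fail_callrate")

  # 100 samples, one heterozygote -> MAF 0.005 < 0.01
  calls <- matrix(0L, 100, 2)
  calls[1, 1] <- 1L
  calls[1:50, 2] <- 1L
  out2 <- qc_filter(toy_geno(calls))
  expect_equal(out2$report$n_fail_maf, 1L)
  expect_equal(out2$geno$map$marker, "m2")
})

test_that("QC report counts each marker once at its first failing stage", {
  # 4 markers: callrate 0.9 & MAF 0.3 | callrate 1 & MAF 0.005 | 2 x retained
  n <- 100
  m1 <- rep(c(0L, 1L), c(40, 60)); m1[1:10] <- NA          # callrate 0.9
  m2 <- c(1L, rep(0L, n - 1))                               # MAF 0.005
  m3 <- rep(c(0L, 1L), each = 50)                           # MAF 0.25
  out <- qc_filter(toy_geno(cbind(m1, m2, m3, m3)), impute = "naive")
  r <- out$report
  expect_equal(c(r$n_input, r$n_fail_callrate, r$n_fail_maf, r$n_retained),
               c(4L, 1L, 1L, 2L))
  expect_equal(r$n_input, r$n_fail_callrate + r$n_fail_maf + r$n_retained)
  expect_error(qc_filter(toy_geno(cbind(m2))), "all markers removed")
})

test_that("A matrix reproduces hand-computed tabular values", {
  A2 <- make_A(as_pedigree(c("1", "2"), c(NA, NA), c(NA, NA)))
  expect_equal(unclass(A2), diag(2), ignore_attr = TRUE)

  A <- make_A(ped_toy())
  expect_equal(A["1", "3"], 0.5)   # parent-offspring
  expect_equal(A["1", "4"], 0.5)
  expect_equal(A["3", "4"], 0.5)   # full sibs
  expect_equal(A["3", "3"], 1)
  expect_equal(A["5", "5"], 1.25)  # inbred: 1 + 0.5 * a(1,3)
  expect_error(make_A(ped_toy(), subset = "99"), "absent")
  # subset extraction is a pure submatrix
  expect_equal(unclass(make_A(ped_toy(), subset = c("4", "3"))),
               unclass(A)[c("4", "3"), c("4", "3")], ignore_attr = TRUE)
})

test_that("G reproduces the worked 3x2 example and centers rows", {
  g <- toy_geno(matrix(c(2L, 1L, 0L, 2L, 0L, 1L), 3, 2))
  G <- make_G(g)
  expect_equal(unclass(G),
               matrix(c(2, -1, -1, -1, 1, 0, -1, 0, 1), 3, 3),
               ignore_attr = TRUE)
  expect_equal(rowSums(G), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(make_G(toy_geno(matrix(2L, 4, 1))), "monomorphic")
})

test_that("D reproduces the worked 4-sample column and has trace n", {
  # genotypes AA, Aa, Aa, aa: p_AA = p_aa = 0.25, p_Aa = 0.5, c = 0.5
  g <- toy_geno(matrix(c(2L, 1L, 1L, 0L), 4, 1))
  D <- make_D(g)
  expect_equal(sum(diag(D)), 4, tolerance = 1e-8)
  # M_D column is (-0.5, 0.5, 0.5, -0.5); tr(MM') = 1; divide by 1/4
  expect_equal(unclass(D),
               outer(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, 0.5, 0.5, -0.5)) / 0.25,
               ignore_attr = TRUE)
})

test_that("D handles markers without heterozygotes via the direct formula", {
  # marker 1 usable; marker 2 has no heterozygote but c > 0
  calls <- cbind(c(2L, 1L, 1L, 0L), c(2L, 2L, 0L, 0L))
  D <- make_D(toy_geno(calls))
  # direct evaluation: per-marker codes, Gram, trace normalization
  codes <- sapply(1:2, function(j) {
    pAA <- mean(calls[, j] == 2); pAa <- mean(calls[, j] == 1); paa <- mean(calls[, j] == 0)
    cc <- pAA + paa - (pAA - paa)^2
    (c(-2 * pAA * pAa, 4 * pAA * paa, -2 * paa * pAa) / cc)[calls[, j] + 1]
  })
  MMt <- tcrossprod(codes)
  expect_equal(unclass(D), MMt / (sum(diag(MMt)) / 4), ignore_attr = TRUE)
  expect_equal(sum(diag(D)), 4, tolerance = 1e-8)
})

test_that("E reproduces the worked 2x2 example; rows sum to zero; PSD", {
  x <- matrix(c(1, 3, 3, 5), 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  E <- make_E(x)
  expect_equal(unclass(E), matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)

  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(paste0("i", 1:30), paste0("g", 1:8)))
  X[2, ] <- X[1, ]  # duplicate individuals
  E2 <- make_E(X)
  expect_equal(rowSums(E2), rep(0, 30), ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(E2[1, ], E2[2, ], ignore_attr = TRUE)
  expect_gte(min(eigen(unclass(E2), symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("zero-variance genes are dropped only under column scaling", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("i", 1:10), c("g1", "g2")))
  X[, 2] <- 7
  expect_silent(make_E(X))
  expect_message(E <- make_E(X, scale_columns = TRUE), "zero-variance")
  expect_equal(max(abs(diag(E) - 1)) < 10, TRUE)  # scaled Gram, finite
})

test_that("G and D are invariant to flipping the counted allele", {
  set.seed(9)
  calls <- matrix(rbinom(60 * 20, 2, 0.4), 60, 20)
  g <- toy_geno(calls)
  gf <- toy_geno(2L - calls)
  expect_equal(unclass(make_G(g)), unclass(make_G(gf)), tolerance = 1e-10)
  expect_equal(unclass(make_D(g)), unclass(make_D(gf)), tolerance = 1e-10)
})

test_that("permuting sample order permutes every matrix consistently", {
  set.seed(10)
  calls <- matrix(rbinom(40 * 15, 2, 0.5), 40, 15)
  ids <- paste0("i", 1:40)
  perm <- sample(40)
  G1 <- make_G(toy_geno(calls, ids = ids))
  G2 <- make_G(toy_geno(calls[perm, ], ids = ids[perm]))
  expect_equal(unclass(G2)[ids, ids], unclass(G1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("psd_repair clips negative eigenvalues and keeps symmetry", {
  M <- diag(c(2, 1, -0.5))
  dimnames(M) <- list(letters[1:3], letters[1:3])
  R <- psd_repair(grm(M))
  expect_gte(min(eigen(unclass(R), only.values = TRUE)$values), -1e-12)
  expect_equal(unclass(R)["a", "a"], 2)
})
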
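make_toy_design <- function(n = 40, m = 25, seed = 1, dominance = TRUE,
                            h2 = 0.5) {
  set.seed(seed)
  calls <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), n, m, byrow = TRUE)
  g <- toy_geno(calls)
  K <- make_G(g)
  KD <- if (dominance) make_D(g) else NULL
  a <- drop(crossprod(chol(unclass(K) + 1e-8 * diag(n)), rnorm(n)))
  a <- a / sd(a) * sqrt(h2)
  y <- 5 + a + rnorm(n, sd = sqrt(1 - h2))
  ph <- tibble::tibble(id = rownames(K), trait = "t", value = y,
                       sex = rep(c("M", "F"), length.out = n),
                       birth_year = "Y1")
  list(pheno = ph, K = K, KD = KD, geno = g)
}

test_that("design builder drops constant covariates and keeps K individuals", {
  d <- make_toy_design(n = 20)
  des <- build_design(d$pheno, "t", K_a = d$K, K_D = d$KD)
  # birth_year constant -> only intercept + one sex contrast
  expect_equal(ncol(des$X), 2L)
  expect_true(all(rowSums(des$Z) == 1))

  # a missing phenotype removes the record but not the individual
  ph2 <- d$pheno
  ph2$value[3] <- NA
  des2 <- build_design(ph2, "t", K_a = d$K, K_D = d$KD)
  expect_equal(length(des2$y), 19L)
  expect_equal(ncol(des2$Z), 20L)
  expect_equal(sum(des2$Z[, 3]), 0)
})

test_that("rank-deficient fixed effects and duplicates raise errors", {
  d <- make_toy_design(n = 20)
  ph <- d$pheno
  ph$dup <- ph$sex  # aliased covariate
  expect_error(build_design(ph, "t", K_a = d$K, fixed = c("sex", "dup")),
               "aliased")
  expect_error(build_design(rbind(d$pheno, d$pheno[1, ]), "t", K_a = d$K),
               "duplicate")
})

test_that("BLUP solutions match a direct dense-algebra evaluation", {
  d <- make_toy_design(n = 30, seed = 3)
  des <- build_design(d$pheno, "t", K_a = d$K, K_D = d$KD)
  vc <- list(sigma2_a = 0.4, sigma2_d = 0.1, sigma2_e = 0.5)
  fit <- blup_solve(des, vc)

  # oracle: textbook GLS + conditional expectation with explicit inverses
  V <- vc$sigma2_a * des$Z %*% unclass(d$K) %*% t(des$Z) +
    vc$sigma2_d * des$W %*% unclass(d$KD) %*% t(des$W) +
    vc$sigma2_e * diag(length(des$y))
  Vi <- solve(V)
  b <- solve(t(des$X) %*% Vi %*% des$X, t(des$X) %*% Vi %*% des$y)
  r <- des$y - des$X %*% b
  a <- vc$sigma2_a * unclass(d$K) %*% t(des$Z) %*% Vi %*% r
  expect_equal(unname(fit$b_hat), unname(drop(b)), tolerance = 1e-10)
  expect_equal(unname(fit$a_hat), unname(drop(a)), tolerance = 1e-10)
})

test_that("additive variance -> 0 gives OLS fixed effects and zero EBVs", {
  d <- make_toy_design(n = 25, seed = 5, dominance = FALSE)
  des <- build_design(d$pheno, "t", K_a = d$K)
  fit <- blup_solve(des, list(sigma2_a = 1e-12, sigma2_d = 0, sigma2_e = 1))
  ols <- unname(drop(solve(crossprod(des$X), crossprod(des$X, des$y))))
  expect_equal(unname(fit$b_hat), ols, tolerance = 1e-6)
  expect_lt(max(abs(fit$a_hat)), 1e-9)
})

test_that("record-less duplicates inherit predictions through K", {
  d <- make_toy_design(n = 20, seed = 7, dominance = FALSE)
  K <- unclass(d$K)
  # add a copy of individual 1 with identical relationships and no record
  Kx <- rbind(cbind(K, copy = K[, 1]), copy = c(K[1, ], K[1, 1]))
  rownames(Kx)[21] <- colnames(Kx)[21] <- "copy"
  des <- build_design(d$pheno, "t", K_a = grm(Kx, "G"))
  fit <- blup_solve(des, list(sigma2_a = 0.5, sigma2_d = 0, sigma2_e = 0.5))
  expect_equal(unname(fit$a_hat["copy"]), unname(fit$a_hat[rownames(K)[1]]),
               tolerance = 1e-10)
})

test_that("GBLUP predictions equal ridge marker-effect predictions", {
  n <- 50; m <- 30
  set.seed(13)
  calls <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)), n, m, byrow = TRUE)
  g <- toy_geno(calls)
  K <- make_G(g)
  p <- colMeans(calls) / 2
  M <- sweep(calls, 2, 2 * p)
  s <- sum(2 * p * (1 - p))
  y <- 3 + drop(M %*% rnorm(m, sd = 0.2)) + rnorm(n, sd = 0.5)
  ph <- tibble::tibble(id = rownames(K), trait = "t", value = y,
                       sex = "M", birth_year = "Y1")
  des <- build_design(ph, "t", K_a = K)
  vc <- list(sigma2_a = 0.4, sigma2_d = 0, sigma2_e = 0.6)
  fit <- blup_solve(des, vc)

  # SNP-BLUP oracle via Henderson's MME on marker effects, penalty sigma2_e*s/sigma2_a
  lambda <- vc$sigma2_e * s / vc$sigma2_a
  X <- des$X
  C <- rbind(cbind(crossprod(X), crossprod(X, M)),
             cbind(crossprod(M, X), crossprod(M) + lambda * diag(m)))
  sol <- solve(C, c(crossprod(X, y), crossprod(M, y)))
  u <- sol[-seq_len(ncol(X))]
  expect_equal(unname(fit$a_hat), drop(M %*% u), tolerance = 1e-8)
})

test_that("scaling the phenotype scales components by c^2 and predictions by c", {
  d <- make_toy_design(n = 60, m = 40, seed = 17)
  des1 <- build_design(d$pheno, "t", K_a = d$K, K_D = d$KD)
  f1 <- aireml_fit(des1)
  ph2 <- d$pheno; ph2$value <- 3 * ph2$value
  f2 <- aireml_fit(build_design(ph2, "t", K_a = d$K, K_D = d$KD))
  expect_equal(f2$vc$sigma2_a, 9 * f1$vc$sigma2_a, tolerance = 1e-3)
  expect_equal(f2$vc$sigma2_e, 9 * f1$vc$sigma2_e, tolerance = 1e-3)
  expect_equal(unname(f2$a_hat), unname(3 * f1$a_hat), tolerance = 1e-3)
})

test_that("REML log-likelihood never decreases across accepted iterations", {
  for (seed in 1:5) {
    d <- make_toy_design(n = 50, m = 30, seed = seed)
    f <- aireml_fit(build_design(d$pheno, "t", K_a = d$K, K_D = d$KD))
    expect_true(all(diff(f$ll_trace) >= -1e-9))
  }
})

test_that("noise-free fixed-effect-only data drives all components to the clamp", {
  d <- make_toy_design(n = 30, seed = 23)
  ph <- d$pheno
  ph$value <- 2 + 0.5 * (ph$sex == "M")  # y = Xb exactly
  f <- aireml_fit(build_design(ph, "t", K_a = d$K, K_D = d$KD))
  clamp <- 1e-8 * var(ph$value)
  expect_lt(f$vc$sigma2_a, 10 * clamp)
  expect_lt(f$vc$sigma2_d, 10 * clamp)
  expect_lt(f$vc$sigma2_e, 10 * clamp)
})

test_that("aliased kernels (K_a = K_D = I) raise a non-identifiability error", {
  n <- 30
  set.seed(29)
  I <- diag(n); dimnames(I) <- list(paste0("i", 1:n), paste0("i", 1:n))
  ph <- tibble::tibble(id = rownames(I), trait = "t", value = rnorm(n),
                       sex = "M", birth_year = "Y1")
  des <- build_design(ph, "t", K_a = grm(I, "custom"), K_D = grm(I, "custom"))
  expect_error(aireml_fit(des), "identifiab")
})

test_that("variance-component recovery is consistent as n grows", {
  rmse <- sapply(c(100, 400), function(n) {
    errs <- sapply(1:3, function(r) {
      d <- make_toy_design(n = n, m = 60, seed = 100 * n + r, dominance = FALSE,
                           h2 = 0.5)
      f <- aireml_fit(build_design(d$pheno, "t", K_a = d$K))
      f$vc$sigma2_a - 0.5
    })
    sqrt(mean(errs^2))
  })
  expect_lt(rmse[2], rmse[1] + 0.05)
})

test_that("tidy and glance expose fits in broom style", {
  d <- make_toy_design(n = 30, seed = 31)
  f <- aireml_fit(build_design(d$pheno, "t", K_a = d$K, K_D = d$KD))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(tidy(f, "additive")), 30L)
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$h2_narrow >= 0 && gl$h2_narrow <= 1)
})
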
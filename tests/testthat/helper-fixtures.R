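# fixtures and independent oracles shared across test files

# ---- toy pedigrees ---------------------------------------------------------

# founders 1,2; 3 and 4 full sibs from (1,2); 5 from parent-offspring mating (1,3)
ped_toy <- function() {
  as_pedigree(id = c("1", "2", "3", "4", "5"),
              sire = c(NA, NA, "1", "1", "1"),
              dam = c(NA, NA, "2", "2", "3"))
}

# six individuals, two generations, used for the gene-dropping comparison
ped_six <- function() {
  as_pedigree(id = c("1", "2", "3", "4", "5", "6"),
              sire = c(NA, NA, "1", "1", "1", "4"),
              dam = c(NA, NA, "2", "2", "3", "5"))
}

# ---- toy genotype / matrix builders ---------------------------------------

toy_geno <- function(calls, ids = NULL, markers = NULL) {
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(calls)))
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(calls)))
  dimnames(calls) <- list(ids, markers)
  geno_matrix(calls)
}

# random PSD matrix with ids, diagonal pushed up to keep it invertible
random_psd <- function(n, ids = paste0("id", seq_len(n)), jitter = 0.5) {
  M <- matrix(rnorm(n * n), n)
  K <- crossprod(M) / n + jitter * diag(n)
  dimnames(K) <- list(ids, ids)
  K
}

# ---- brute-force single-step oracle ---------------------------------------

# direct transcription of the block formula: permute to (subset1, subset2)
# contiguous blocks, use explicit solve() and explicit products, un-permute.
oracle_H <- function(K, V, w) {
  idsV <- rownames(V)
  ids2 <- rownames(K)
  ids1 <- setdiff(idsV, ids2)
  perm <- c(ids1, ids2)
  Vp <- unclass(V)[perm, perm]
  n1 <- length(ids1); n2 <- length(ids2)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  V22 <- Vp[i2, i2, drop = FALSE]
  dK <- mean(diag(unclass(K)[ids2, ids2]))
  oK <- (sum(unclass(K)[ids2, ids2]) - sum(diag(unclass(K)[ids2, ids2]))) / (n2^2 - n2)
  dV <- mean(diag(V22))
  oV <- (sum(V22) - sum(diag(V22))) / (n2^2 - n2)
  ab <- solve(matrix(c(dK, oK, 1, 1), 2), c(dV, oV))
  Kstar <- ab[1] * unclass(K)[ids2, ids2] + ab[2]
  Kw <- (1 - w) * Kstar + w * V22
  H <- matrix(0, n1 + n2, n1 + n2, dimnames = list(perm, perm))
  if (n1 > 0) {
    V22i <- solve(V22)
    V12 <- Vp[i1, i2, drop = FALSE]
    V21 <- Vp[i2, i1, drop = FALSE]
    H[i1, i1] <- Vp[i1, i1] + V12 %*% V22i %*% (Kw - V22) %*% V22i %*% V21
    H[i1, i2] <- V12 %*% V22i %*% Kw
    H[i2, i1] <- Kw %*% V22i %*% V21
  }
  H[i2, i2] <- Kw
  H[idsV, idsV]
}

oracle_H_nested <- function(K_outer, V_base, K_inner, w_inner, w_outer) {
  oracle_H(K_outer, oracle_H(K_inner, V_base, w_inner), w_outer)
}

# ---- gene-dropping IBD oracle ---------------------------------------------

# expected numerator relationships by simulating allele descent through the
# pedigree: a_ij = 4 * P(randomly drawn alleles of i and j are IBD) averaged
# over allele pairs; a_ii = 1 + P(the two alleles of i are IBD).
gene_drop_A <- function(ped, n_drops = 1e5) {
  ord <- attr(ped, "topo_order")
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  A1 <- matrix(0L, n_drops, n)
  A2 <- matrix(0L, n_drops, n)
  next_label <- 1L
  for (i in ord) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s)) {
      A1[, i] <- next_label; next_label <- next_label + 1L
    } else {
      si <- idx[s]
      pick <- runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick, A1[, si], A2[, si])
    }
    if (is.na(d)) {
      A2[, i] <- next_label; next_label <- next_label + 1L
    } else {
      di <- idx[d]
      pick <- runif(n_drops) < 0.5
      A2[, i] <- ifelse(pick, A1[, di], A2[, di])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
        (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])
      if (i == j) {
        A[i, i] <- 1 + mean(A1[, i] == A2[, i])
      } else {
        A[i, j] <- A[j, i] <- mean(ibd) / 2
      }
    }
  }
  A
}

# ---- cached simulated datasets --------------------------------------------

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .sim_cache)) assign(key, maker(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small but non-trivial dataset with all layers, used by lmm/evaluate tests
sim_small <- function() {
  cached("sim_small", function() {
    prepare_matrices(simulate_population(sim_config(
      n_f2 = 150, n_f1 = 24, m_markers = 300, r_genes = 80, n_qtl = 30,
      var_additive = 0.4, var_dominance = 0.1, var_residual = 0.5,
      prop_additive_mediated = 0.6, expression_noise_sd = 0.5,
      frac_expressed = 0.3, frac_phenotyped = 1, seed = 101)))
  })
}

# ---- tiny text fixtures ----------------------------------------------------

write_toy_vcf <- function(path, triallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t0/1")
  if (triallelic) {
    lines <- c(lines,
      "1\t300\tv3\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
      "1\t400\tv4\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
      "1\t500\tv5\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0")
  }
  writeLines(lines, path)
  path
}

write_toy_plink <- function(dir) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c("1\ts1\t0\t0\t1\t0\tA\tA",
               "1\ts2\t0\t0\t1\t0\tA\tG",
               "1\ts3\t0\t0\t2\t0\tG\tG"), ped)
  writeLines("1\tm1\t0\t100", map)
  ped
}
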
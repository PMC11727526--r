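#' Configuration for the F2-like population simulator
#'
#' Defaults emulate a two-breed F2 resource population: divergent founder
#' breeds (boar-like and sow-like founder pools with mirrored allele
#' frequencies), an F1 intermediate generation, and a recorded F2 in which
#' both additive and dominance variation segregate. All F2 individuals are
#' genotyped by default, roughly three quarters carry phenotype records, and
#' roughly one in nine has expression data — reproducing the coverage
#' asymmetry (expression << genotype <= pedigree) that the single-step
#' machinery exists for.
#'
#' @param n_founders_sire,n_founders_dam founder pool sizes (default 5, 20).
#' @param n_f1 F1 individuals (default 50).
#' @param n_f2 F2 individuals (default 393).
#' @param m_markers biallelic SNPs (default 2000).
#' @param r_genes expressed genes (default 500).
#' @param founder_freq_range range of counted-allele frequencies in the
#'   founder breeds (default `c(0.1, 0.9)`); breed 2 frequencies mirror
#'   breed 1 within this range.
#' @param var_additive,var_dominance,var_residual target realized variance
#'   components on the phenotype scale (defaults 0.3 / 0.1 / 0.6).
#' @param prop_additive_mediated share of additive variance flowing through
#'   the expression-generating markers (default 0.5).
#' @param expression_noise_sd independent noise s.d. added to each gene's
#'   genotype-driven signal, which is scaled to unit variance (default 1).
#' @param n_qtl markers with nonzero effects (default 100, capped at
#'   `m_markers/4`).
#' @param frac_genotyped,frac_expressed,frac_phenotyped F2 coverage
#'   fractions; `frac_expressed <= frac_genotyped` is required so simulated
#'   data obey the nesting the single-step module validates.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders_sire = 5, n_founders_dam = 20, n_f1 = 50,
                       n_f2 = 393, m_markers = 2000, r_genes = 500,
                       founder_freq_range = c(0.1, 0.9),
                       var_additive = 0.3, var_dominance = 0.1,
                       var_residual = 0.6,
                       prop_additive_mediated = 0.5,
                       expression_noise_sd = 1,
                       n_qtl = 100,
                       frac_genotyped = 1, frac_expressed = 42 / 393,
                       frac_phenotyped = 294 / 393,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_founders_sire >= 1, n_founders_dam >= 1, n_f1 >= 2, n_f2 >= 4,
            m_markers >= 2, r_genes >= 1,
            founder_freq_range[1] > 0, founder_freq_range[2] < 1,
            founder_freq_range[1] < founder_freq_range[2],
            var_additive >= 0, var_dominance >= 0, var_residual >= 0,
            prop_additive_mediated >= 0, prop_additive_mediated <= 1,
            expression_noise_sd >= 0,
            frac_genotyped > 0, frac_genotyped <= 1,
            frac_expressed > 0, frac_phenotyped > 0, frac_phenotyped <= 1)
  if (cfg$frac_expressed > cfg$frac_genotyped) {
    rlang::abort("frac_expressed must be <= frac_genotyped (expression subset nests in genotyped subset)")
  }
  if (var_additive + var_dominance + var_residual <= 0) {
    rlang::abort("degenerate config: all variance components zero")
  }
  cfg$n_qtl <- max(2L, min(as.integer(n_qtl), as.integer(m_markers / 4) + 1L))
  structure(cfg, class = "sim_config")
}

# one generation of Mendelian gene dropping, locus by locus (unlinked loci):
# each parent transmits its counted allele with probability dosage/2
drop_genotypes <- function(sire_geno, dam_geno) {
  stopifnot(all(dim(sire_geno) == dim(dam_geno)))
  n <- nrow(sire_geno); m <- ncol(sire_geno)
  from_sire <- matrix(stats::rbinom(n * m, 1L, as.vector(sire_geno) / 2), n, m)
  from_dam <- matrix(stats::rbinom(n * m, 1L, as.vector(dam_geno) / 2), n, m)
  from_sire + from_dam
}

#' Simulate an F2-like population with known ground truth
#'
#' Generative model: founder genotypes drawn per marker from breed-divergent
#' (mirrored) allele frequencies; Mendelian gene-dropping through F1 to F2;
#' additive effects on a QTL subset of markers, split into an
#' expression-mediated and a direct part; dominance effects on heterozygosity
#' codes at the same QTLs; each mediated gene's expression is a sparse linear
#' combination of mediated-QTL genotypes (signal scaled to unit variance)
#' plus independent noise; phenotype = mean + sex + birth-year + additive +
#' dominance + residual. Effects are rescaled post hoc so the *realized*
#' variance components match the configured targets exactly, giving
#' parameter-recovery tests exact truths. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `ssexp_sim` with `pedigree`, `geno`
#'   ([geno_matrix()] over the genotyped F2 subset), `expr` (matrix over the
#'   expression subset), `pheno` (long tibble over the phenotyped subset),
#'   membership vectors (`genotyped`, `expressed`, `phenotyped`), precomputed
#'   `A`/`G`/`E`/`K_D` matrices, and `truth` (true breeding values, dominance
#'   deviations, realized variance components, QTL indices and effects).
#' @export
simulate_population <- function(cfg = sim_config()) {
  withr::with_seed(derive_seed(cfg$seed), {
    lo <- cfg$founder_freq_range[1]; hi <- cfg$founder_freq_range[2]
    m <- cfg$m_markers
    p1 <- lo + (hi - lo) * stats::rbeta(m, 0.6, 0.6)  # breed 1 (sire line)
    p2 <- lo + hi - p1                                # mirrored breed 2

    sire_ids <- paste0("S", seq_len(cfg$n_founders_sire))
    dam_ids <- paste0("D", seq_len(cfg$n_founders_dam))
    f1_ids <- paste0("F1_", seq_len(cfg$n_f1))
    f2_ids <- paste0("F2_", seq_len(cfg$n_f2))

    g_sire <- matrix(stats::rbinom(cfg$n_founders_sire * m, 2L, rep(p1, each = cfg$n_founders_sire)),
                     cfg$n_founders_sire, m)
    g_dam <- matrix(stats::rbinom(cfg$n_founders_dam * m, 2L, rep(p2, each = cfg$n_founders_dam)),
                    cfg$n_founders_dam, m)

    f1_sire <- sample(sire_ids, cfg$n_f1, replace = TRUE)
    f1_dam <- sample(dam_ids, cfg$n_f1, replace = TRUE)
    g_f1 <- drop_genotypes(g_sire[match(f1_sire, sire_ids), , drop = FALSE],
                           g_dam[match(f1_dam, dam_ids), , drop = FALSE])

    # alternate F1 sexes so F2 matings are male x female
    f1_male <- f1_ids[seq(1, cfg$n_f1, by = 2)]
    f1_female <- f1_ids[seq(2, cfg$n_f1, by = 2)]
    f2_sire <- sample(f1_male, cfg$n_f2, replace = TRUE)
    f2_dam <- sample(f1_female, cfg$n_f2, replace = TRUE)
    g_f2 <- drop_genotypes(g_f1[match(f2_sire, f1_ids), , drop = FALSE],
                           g_f1[match(f2_dam, f1_ids), , drop = FALSE])
    rownames(g_f2) <- f2_ids

    ped <- as_pedigree(
      id = c(sire_ids, dam_ids, f1_ids, f2_ids),
      sire = c(rep(NA, length(sire_ids) + length(dam_ids)), f1_sire, f2_sire),
      dam = c(rep(NA, length(sire_ids) + length(dam_ids)), f1_dam, f2_dam))

    # --- genetic effects at a QTL subset ------------------------------------
    p_f2 <- colMeans(g_f2) / 2
    poly <- which(p_f2 > 0.02 & p_f2 < 0.98)
    n_qtl <- min(cfg$n_qtl, length(poly))
    qtl <- sort(sample(poly, n_qtl))
    n_med <- round(n_qtl * ifelse(cfg$prop_additive_mediated > 0, 0.5, 0))
    if (cfg$prop_additive_mediated >= 1) n_med <- n_qtl
    med_qtl <- qtl[seq_len(n_med)]
    dir_qtl <- setdiff(qtl, med_qtl)

    Zc <- scale(g_f2[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
    scale_to_var <- function(x, v) {
      if (v <= 0 || stats::var(x) == 0) return(x * 0)
      x * sqrt(v / stats::var(x))
    }
    u_med <- if (length(med_qtl)) {
      drop(Zc[, match(med_qtl, qtl), drop = FALSE] %*% stats::rnorm(length(med_qtl)))
    } else rep(0, cfg$n_f2)
    u_dir <- if (length(dir_qtl)) {
      drop(Zc[, match(dir_qtl, qtl), drop = FALSE] %*% stats::rnorm(length(dir_qtl)))
    } else rep(0, cfg$n_f2)
    u_med <- scale_to_var(u_med, cfg$prop_additive_mediated * cfg$var_additive)
    u_dir <- scale_to_var(u_dir, (1 - cfg$prop_additive_mediated) * cfg$var_additive)
    tbv <- scale_to_var(u_med + u_dir, cfg$var_additive)

    Hc <- scale((g_f2[, qtl, drop = FALSE] == 1) * 1, center = TRUE, scale = FALSE)
    dom <- scale_to_var(drop(Hc %*% stats::rnorm(n_qtl)), cfg$var_dominance)
    resid <- scale_to_var(stats::rnorm(cfg$n_f2), cfg$var_residual)

    sex <- sample(c("M", "F"), cfg$n_f2, replace = TRUE)
    birth_year <- sample(c("Y1", "Y2"), cfg$n_f2, replace = TRUE)
    mu <- 10
    y <- mu + 0.25 * (sex == "M") + 0.25 * (birth_year == "Y2") + tbv + dom + resid

    # --- expression: mediated genes tag the mediated QTLs -------------------
    r <- cfg$r_genes
    n_med_genes <- if (length(med_qtl)) round(0.7 * r) else 0
    expr <- matrix(stats::rnorm(cfg$n_f2 * r, sd = max(cfg$expression_noise_sd, 1e-8)),
                   cfg$n_f2, r)
    gene_src <- vector("list", r)
    if (n_med_genes > 0) {
      for (k in seq_len(n_med_genes)) {
        src <- sample(med_qtl, min(length(med_qtl), sample(1:3, 1)))
        sig <- drop(scale(g_f2[, src, drop = FALSE]) %*% stats::rnorm(length(src)))
        if (stats::sd(sig) > 0) sig <- sig / stats::sd(sig)
        expr[, k] <- expr[, k] + sig
        gene_src[[k]] <- src
      }
    }
    rownames(expr) <- f2_ids
    colnames(expr) <- paste0("gene", seq_len(r))

    # --- coverage subsets (expressed nests in genotyped) --------------------
    n_gt <- max(2L, round(cfg$frac_genotyped * cfg$n_f2))
    genotyped <- sort(sample(f2_ids, n_gt))
    n_ex <- max(2L, min(n_gt, round(cfg$frac_expressed * cfg$n_f2)))
    expressed <- sort(sample(genotyped, n_ex))
    n_ph <- max(4L, round(cfg$frac_phenotyped * cfg$n_f2))
    phenotyped <- sort(sample(f2_ids, n_ph))

    map <- tibble::tibble(marker = paste0("snp", seq_len(m)),
                          chrom = as.character(rep(seq_len(18), length.out = m)),
                          pos = as.integer(seq_len(m) * 1000L),
                          allele_a = rep("A", m), allele_b = rep("G", m))
    colnames(g_f2) <- map$marker
    geno <- geno_matrix(g_f2[genotyped, , drop = FALSE], map)

    pheno <- tibble::tibble(
      id = f2_ids, trait = "trait1", value = unname(y),
      sex = sex, birth_year = birth_year)[f2_ids %in% phenotyped, ]

    truth <- list(
      tbv = stats::setNames(tbv, f2_ids),
      dominance = stats::setNames(dom, f2_ids),
      residual = stats::setNames(resid, f2_ids),
      var_additive = stats::var(tbv),
      var_dominance = stats::var(dom),
      var_residual = stats::var(resid),
      qtl = map$marker[qtl], mediated_qtl = map$marker[med_qtl],
      gene_sources = gene_src,
      mu = mu, sex_effect = 0.25, year_effect = 0.25,
      # parental genotypes kept so Mendelian segregation is checkable
      f1_geno = structure(g_f1, dimnames = list(f1_ids, NULL)),
      f2_parents = tibble::tibble(id = f2_ids, sire = f2_sire, dam = f2_dam))

    sim <- list(config = cfg, pedigree = ped, geno = geno,
                expr = expr[expressed, , drop = FALSE], pheno = pheno,
                genotyped = genotyped, expressed = expressed,
                phenotyped = phenotyped, truth = truth)
    class(sim) <- "ssexp_sim"
    sim
  })
}

#' @export
print.ssexp_sim <- function(x, ...) {
  cat(sprintf(
    "<simulated F2 population: %d in pedigree, %d genotyped x %d markers, %d expressed x %d genes, %d phenotyped>\n",
    nrow(x$pedigree), length(x$genotyped), ncol(x$geno$calls),
    length(x$expressed), ncol(x$expr), length(x$phenotyped)))
  invisible(x)
}

#' Precompute the relationship matrices of a simulated (or real) dataset
#'
#' Convenience step before [fit_blup()] / [cross_validate()] / [sweep_w()]:
#' builds `A` (full pedigree), `G` and `K_D` (genotyped subset, after QC),
#' and `E` (expression subset).
#'
#' @param sim a `ssexp_sim` (or any list with the same fields).
#' @param qc run [qc_filter()] with naive imputation before G/D (default TRUE).
#' @param scale_expression pass `scale_columns` to [make_E()].
#' @return the input list augmented with `A`, `G`, `E`, `K_D` and (if `qc`)
#'   `qc_report`.
#' @export
prepare_matrices <- function(sim, qc = TRUE, scale_expression = FALSE) {
  g <- sim$geno
  if (qc) {
    out <- qc_filter(g, impute = "naive")
    g <- out$geno
    sim$qc_report <- out$report
  }
  sim$A <- make_A(sim$pedigree)
  sim$G <- make_G(g)
  sim$K_D <- make_D(g)
  sim$E <- make_E(sim$expr, scale_columns = scale_expression)
  sim
}

#' Write a simulated dataset as plain-text files
#'
#' Emits `genotypes.vcf` (VCF v4.2), `pedigree.tsv`, `expression.tsv`,
#' `phenotypes.tsv` and `truth.tsv` into `outdir`; the bundle loads back
#' through the package readers without warnings.
#'
#' @param sim a `ssexp_sim` from [simulate_population()].
#' @param outdir writable directory (created if absent).
#' @return invisible character vector of the file paths.
#' @export
write_fixture_bundle <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("cannot create output directory: %s", outdir))
  }
  if (file.access(outdir, mode = 2) != 0) {
    rlang::abort(sprintf("output directory not writable: %s", outdir))
  }
  paths <- file.path(outdir, c("genotypes.vcf", "pedigree.tsv", "expression.tsv",
                               "phenotypes.tsv", "truth.tsv"))

  calls <- sim$geno$calls; map <- sim$geno$map
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(t(calls))], nrow = ncol(calls))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=ssexp_simulator",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$marker, map$allele_b, map$allele_a,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths[1])

  ped <- sim$pedigree
  utils::write.table(
    data.frame(id = ped$id,
               sire = ifelse(is.na(ped$sire), "0", ped$sire),
               dam = ifelse(is.na(ped$dam), "0", ped$dam)),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(data.frame(id = rownames(sim$expr), sim$expr,
                                check.names = FALSE),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(sim$pheno), paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = names(sim$truth$tbv), tbv = sim$truth$tbv,
               dominance = sim$truth$dominance, residual = sim$truth$residual),
    paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
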
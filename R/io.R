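#' Read biallelic SNP genotypes from VCF or PLINK text files
#'
#' Calls count copies of "allele A": the first ALT allele for VCF, the
#' lexicographically smaller observed allele for PLINK text. The counted
#' allele is recorded per marker in the map, so downstream matrices are
#' reproducible regardless of file orientation (G and D are invariant to a
#' consistent flip). Multi-allelic VCF sites are dropped with a message.
#'
#' @param path VCF (`.vcf`, optionally gzipped) or PLINK `.ped` file path
#'   (a `.map` with the same stem must sit beside a `.ped`).
#' @param format `"auto"` (by extension), `"vcf"` or `"plink"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ped$", path, ignore.case = TRUE)) "plink" else "vcf"
  }
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  switch(format, vcf = read_genotypes_vcf(path), plink = read_genotypes_plink(path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(alt) == 1L & nchar(ref) == 1L
  n_drop <- sum(!biallelic)
  if (n_drop > 0) {
    rlang::inform(sprintf("dropped %d non-biallelic-SNP site(s)", n_drop))
  }
  if (!any(biallelic)) rlang::abort("no biallelic SNPs in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # count ALT copies; accept phased or unphased diploid calls
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", as.vector(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  counts[] <- unname(known[clean])
  marker <- fix[, "ID"]
  marker[is.na(marker) | marker == "."] <-
    paste0(fix[is.na(marker) | marker == ".", "CHROM"], "_",
           fix[is.na(marker) | marker == ".", "POS"])
  calls <- t(counts)
  rownames(calls) <- colnames(gt)
  colnames(calls) <- marker
  map <- tibble::tibble(marker = marker,
                        chrom = as.character(fix[, "CHROM"]),
                        pos = as.integer(fix[, "POS"]),
                        allele_a = as.character(alt[biallelic]),
                        allele_b = as.character(ref[biallelic]))
  geno_matrix(calls, map)
}

read_genotypes_plink <- function(path) {
  map_path <- sub("\\.ped$", ".map", path, ignore.case = TRUE)
  if (!file.exists(map_path)) {
    rlang::abort(sprintf("PLINK .map file not found next to .ped: %s", map_path))
  }
  map_raw <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map_raw) < 4) rlang::abort(sprintf("malformed .map (need 4 columns): %s", map_path))
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  m <- nrow(map_raw)
  if (ncol(ped) != 6 + 2 * m) {
    rlang::abort(sprintf("malformed .ped: %d columns but .map declares %d markers",
                         ncol(ped), m))
  }
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = m)
  allele_a <- allele_b <- character(m)
  keep <- logical(m)
  for (j in seq_len(m)) {
    obs <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(obs) > 2) next  # multi-allelic: drop
    keep[j] <- TRUE
    if (length(obs) == 0) obs <- c("?", "?")
    # counted allele = lexicographically smaller observed allele
    allele_a[j] <- obs[1]
    allele_b[j] <- if (length(obs) == 2) obs[2] else obs[1]
    calls[, j] <- (a1[, j] == allele_a[j]) + (a2[, j] == allele_a[j])
    calls[is.na(a1[, j]) | is.na(a2[, j]), j] <- NA_integer_
  }
  if (!any(keep)) rlang::abort("no biallelic markers in .ped")
  if (any(!keep)) rlang::inform(sprintf("dropped %d multi-allelic marker(s)", sum(!keep)))
  calls <- calls[, keep, drop = FALSE]
  rownames(calls) <- ids
  colnames(calls) <- map_raw[[2]][keep]
  map <- tibble::tibble(marker = map_raw[[2]][keep],
                        chrom = map_raw[[1]][keep],
                        pos = as.integer(map_raw[[4]][keep]),
                        allele_a = allele_a[keep], allele_b = allele_b[keep])
  geno_matrix(calls, map)
}

#' Read a pedigree table
#'
#' Expects 3+ delimited columns (id, sire, dam); `0`, `NA` or empty cells mean
#' unknown parent. Parents that never appear as individuals are appended as
#' founder records, and a topological order (parents before offspring) is
#' computed and stored.
#'
#' @param path delimited text file with a header row.
#' @return a `ssexp_pedigree` tibble with columns `id`, `sire`, `dam` and a
#'   `topo_order` attribute (integer permutation).
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "", colClasses = "character",
                           fill = TRUE)
  if (ncol(tab) < 3) rlang::abort("pedigree file needs at least 3 columns (id, sire, dam)")
  as_pedigree(tab[[1]], tab[[2]], tab[[3]])
}

#' Build a pedigree object from id/sire/dam vectors
#'
#' @param id,sire,dam character vectors; unknown parents as `NA`, `"0"` or `""`.
#' @return a `ssexp_pedigree` tibble (see [read_pedigree()]).
#' @export
as_pedigree <- function(id, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA
    x
  }
  id <- check_ids(as.character(id), "pedigree")
  sire <- norm(sire); dam <- norm(dam)
  if (any(id == sire, na.rm = TRUE) || any(id == dam, na.rm = TRUE)) {
    bad <- id[(id == sire & !is.na(sire)) | (id == dam & !is.na(dam))]
    rlang::abort(sprintf("individual recorded as its own parent: %s",
                         paste(bad, collapse = ", ")))
  }
  # implicit founders: parents never listed as individuals
  parents <- unique(stats::na.omit(c(sire, dam)))
  implicit <- setdiff(parents, id)
  if (length(implicit)) {
    id <- c(id, implicit)
    sire <- c(sire, rep(NA_character_, length(implicit)))
    dam <- c(dam, rep(NA_character_, length(implicit)))
  }
  ped <- tibble::tibble(id = id, sire = sire, dam = dam)
  ord <- pedigree_topo_order(ped)
  structure(ped, topo_order = ord, class = c("ssexp_pedigree", class(ped)))
}

# Kahn's algorithm; errors with the offending ids if a cycle exists
pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    cyc <- ped$id[setdiff(seq_len(n), ord)]
    rlang::abort(sprintf("pedigree contains a cycle involving: %s",
                         paste(utils::head(cyc, 10), collapse = ", ")))
  }
  ord
}

#' Read / write an ID-indexed relationship matrix as TSV
#'
#' The file is a square numeric table whose first column and header row carry
#' the same IDs in the same order. On read the matrix is symmetrized by
#' `(K + t(K))/2`, with a warning when the asymmetry exceeds `1e-8`.
#'
#' @param path TSV path.
#' @param K a matrix or [grm()].
#' @param kind kind label attached on read.
#' @return `read_grm`: a [grm()]; `write_grm`: `path`, invisibly.
#' @export
read_grm <- function(path, kind = "custom") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  M <- as.matrix(tab)
  if (nrow(M) != ncol(M)) rlang::abort("relationship matrix table is not square")
  if (!identical(rownames(M), colnames(M))) {
    rlang::abort("row IDs and column IDs of relationship matrix differ")
  }
  M <- symmetrize(M, warn_above = 1e-8, what = "relationship matrix")
  grm(M, kind = kind)
}

#' @rdname read_grm
#' @export
write_grm <- function(K, path) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  colnames(df) <- c("id", colnames(K))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples-by-genes expression table
#'
#' First column = sample ID, remaining columns = genes (numeric).
#'
#' @param path TSV path with a header row.
#' @param missing `"error"` (default) or `"impute_mean"` (per-gene mean).
#' @return numeric matrix, samples x genes, with ID rownames.
#' @export
read_expression <- function(path, missing = c("error", "impute_mean")) {
  missing <- match.arg(missing)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- check_ids(as.character(tab[[1]]))
  if (anyNA(X) || any(!is.finite(X))) {
    if (missing == "error") {
      rlang::abort("expression matrix has missing/non-finite values; use missing = 'impute_mean'")
    }
    for (j in seq_len(ncol(X))) {
      bad <- !is.finite(X[, j])
      if (any(bad)) X[bad, j] <- mean(X[!bad, j])
    }
  }
  X
}

#' Read a phenotype + covariate table
#'
#' Columns: `id`, `trait`, `value`, `sex`, `birth_year` (extra columns kept).
#' Alternatively a wide table (`id`, `sex`, `birth_year`, one column per trait)
#' is pivoted to this long layout.
#'
#' @param path CSV/TSV path with a header row.
#' @return tibble with columns `id`, `trait`, `value`, `sex`, `birth_year`.
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                             check.names = FALSE))
  if (!all(c("id", "trait", "value") %in% names(tab))) {
    fixed <- intersect(c("id", "sex", "birth_year"), names(tab))
    tab <- tidyr::pivot_longer(tab, cols = -dplyr::all_of(fixed),
                               names_to = "trait", values_to = "value")
  }
  tab <- dplyr::mutate(tab, id = as.character(.data$id),
                       value = as.numeric(.data$value))
  if (anyDuplicated(tab[, c("id", "trait")])) {
    rlang::abort("duplicate (id, trait) pairs in phenotype table")
  }
  tab
}

#' Align sample IDs across heterogeneous inputs
#'
#' Builds one ordered sample universe spanning pedigrees, genotype objects,
#' expression matrices, relationship matrices and phenotype tables, either as
#' the intersection (order of the first object) or the union (first-seen
#' order) of their IDs. Union mode also returns per-object membership masks,
#' which is how single-step subset-1/subset-2 partitions are derived.
#'
#' @param objects named list of ID-bearing objects.
#' @param policy `"intersect"` or `"union"`.
#' @return list with `index` (character IDs), `masks` (named list of logical
#'   vectors over `index`) and `membership` (long tibble: object, id).
#' @export
align_samples <- function(objects, policy = c("intersect", "union")) {
  policy <- match.arg(policy)
  if (!length(objects)) rlang::abort("need at least one object to align")
  if (is.null(names(objects)) || any(!nzchar(names(objects)))) {
    names(objects) <- paste0("object", seq_along(objects))
  }
  ids_list <- lapply(objects, sample_ids)
  index <- switch(policy,
    intersect = Reduce(intersect, ids_list[-1], ids_list[[1]]),
    union = Reduce(union, ids_list))
  if (policy == "intersect" && !length(index)) {
    rlang::abort("sample-ID intersection is empty")
  }
  masks <- lapply(ids_list, function(ids) index %in% ids)
  membership <- purrr::map2_dfr(names(objects), ids_list, function(nm, ids) {
    tibble::tibble(object = nm, id = intersect(index, ids))
  })
  list(index = index, masks = masks, membership = membership)
}
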
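#' Relationship matrix constructor
#'
#' Wraps a symmetric, ID-indexed numeric matrix as a relationship matrix.
#' The `kind` records how it was built: `"A"` (pedigree numerator),
#' `"G"` (genomic additive), `"D"` (genomic dominance), `"E"` (transcriptomic),
#' `"H"` (single-step combined) or `"custom"`.
#'
#' @param values square numeric matrix with identical row/column ID dimnames.
#' @param kind one of `"A"`, `"G"`, `"D"`, `"E"`, `"H"`, `"custom"`.
#' @param tol maximum tolerated asymmetry before an error is thrown.
#' @return a `ssexp_grm`: the matrix with a `kind` attribute.
#' @export
grm <- function(values, kind = "custom", tol = 1e-8) {
  kind <- match.arg(kind, c("A", "G", "D", "E", "H", "custom"))
  if (!is.matrix(values) || !is.numeric(values) || nrow(values) != ncol(values)) {
    rlang::abort("a relationship matrix must be a square numeric matrix")
  }
  ids <- check_ids(rownames(values))
  if (!identical(ids, as.character(colnames(values)))) {
    rlang::abort("row and column IDs of a relationship matrix must match")
  }
  if (max(abs(values - t(values))) > tol) {
    rlang::abort(sprintf("matrix is asymmetric beyond %g; use read_grm()/symmetrize first", tol))
  }
  values <- (values + t(values)) / 2
  structure(values, kind = kind, class = c("ssexp_grm", class(values)))
}

#' @export
print.ssexp_grm <- function(x, ...) {
  cat(sprintf("<relationship matrix: kind %s, %d individuals>\n",
              attr(x, "kind"), nrow(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 6L))
  invisible(x)
}

# subset a grm to ids (order given by ids), keeping class/kind
grm_subset <- function(K, ids) {
  miss <- setdiff(ids, rownames(K))
  if (length(miss)) {
    rlang::abort(sprintf("IDs absent from relationship matrix: %s",
                         paste(utils::head(miss, 5), collapse = ", ")))
  }
  grm(unclass(K)[ids, ids, drop = FALSE], kind = attr(K, "kind") %||% "custom")
}

#' Genotype matrix constructor
#'
#' @param calls integer matrix of 0/1/2 allele-A dosages (NA = missing) with
#'   sample IDs as rownames and marker IDs as colnames.
#' @param map tibble with columns `marker`, `chrom`, `pos`, `allele_a`
#'   (the counted allele), `allele_b`; row order matches `calls` columns.
#' @return a `ssexp_geno` object (list with `calls` and `map`).
#' @export
geno_matrix <- function(calls, map = NULL) {
  if (!is.matrix(calls)) rlang::abort("calls must be a matrix")
  check_ids(rownames(calls), "sample")
  check_ids(colnames(calls), "marker")
  bad <- !is.na(calls) & !(calls %in% c(0, 1, 2))
  if (any(bad)) rlang::abort("genotype calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  if (is.null(map)) {
    map <- tibble::tibble(marker = colnames(calls),
                          chrom = NA_character_, pos = NA_integer_,
                          allele_a = NA_character_, allele_b = NA_character_)
  }
  if (!identical(as.character(map$marker), colnames(calls))) {
    rlang::abort("map rows must match call columns (same markers, same order)")
  }
  structure(list(calls = calls, map = tibble::as_tibble(map)),
            class = "ssexp_geno")
}

#' @export
print.ssexp_geno <- function(x, ...) {
  cat(sprintf("<genotypes: %d samples x %d markers, %.2f%% missing>\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.ssexp_geno <- function(x) dim(x$calls)

# generic accessors used by align_samples()
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.ssexp_geno <- function(x) rownames(x$calls)
#' @export
sample_ids.matrix <- function(x) rownames(x)
#' @export
sample_ids.ssexp_grm <- function(x) rownames(x)
#' @export
sample_ids.ssexp_pedigree <- function(x) x$id
#' @export
sample_ids.data.frame <- function(x) unique(as.character(x$id))
#' @export
sample_ids.character <- function(x) x
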
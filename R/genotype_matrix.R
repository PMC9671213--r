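#' Genotype matrix container
#'
#' A `genotype_matrix` is a samples x SNPs integer matrix of genotype classes
#' with `NA` as the missing sentinel, plus per-sample identifiers and per-SNP
#' variant metadata. In diploid mode entries are the number of non-reference
#' alleles: 0 (hom ref), 1 (het), 2 (hom alt). In haploid (yeast-style) mode
#' entries are the two strain classes 1 and 2 (the vineyard strain recoded
#' from -1 to 2 so that all classes are non-negative).
#'
#' @param values integer matrix, samples in rows, SNPs in columns; `NA` marks
#'   a missing genotype.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to existing rownames or `S1..Sn`.
#' @param variant_meta data frame with one row per SNP and columns `chrom`,
#'   `pos`, `id`, `ref`, `alt`; synthesized if omitted. `pos` must be
#'   strictly increasing within a chromosome.
#' @param ploidy `"diploid"` (classes 0/1/2) or `"haploid"` (classes 1/2).
#'
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, variant_meta = NULL,
                            ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  }
  if (length(sample_ids) != n) {
    abort("`sample_ids` length must equal the number of rows of `values`.")
  }
  if (anyDuplicated(sample_ids)) abort("`sample_ids` must be unique.")
  if (is.null(variant_meta)) {
    variant_meta <- tibble(
      chrom = "1", pos = seq_len(p), id = sprintf("snp%d", seq_len(p)),
      ref = "A", alt = "G"
    )
  } else {
    variant_meta <- as_tibble(variant_meta)
  }
  if (nrow(variant_meta) != p) {
    abort("`variant_meta` must have one row per SNP column.")
  }
  allowed <- if (ploidy == "diploid") 0:2 else 1:2
  bad <- !is.na(values) & !(values %in% allowed)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Invalid genotype value %d at sample '%s', SNP '%s' for %s mode.",
      values[bad][1L], sample_ids[idx[1L]], variant_meta$id[idx[2L]], ploidy
    ))
  }
  rownames(values) <- sample_ids
  colnames(values) <- variant_meta$id
  structure(
    values,
    variant_meta = variant_meta,
    ploidy = ploidy,
    class = c("genotype_matrix", "matrix", "array")
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d SNPs (%s), %.1f%% missing\n",
    nrow(x), ncol(x), gt_ploidy(x), 100 * mean(is.na(x))
  ))
  k <- min(6L, nrow(x)); m <- min(8L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(m), drop = FALSE])
  invisible(x)
}

#' Variant metadata of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
variant_meta <- function(x) attr(x, "variant_meta")

#' Ploidy mode of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return `"diploid"` or `"haploid"`.
#' @export
gt_ploidy <- function(x) attr(x, "ploidy")

#' Sample identifiers of a genotype matrix
#' @param x a `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x)

# subset a genotype_matrix keeping metadata consistent
gt_subset <- function(x, samples = NULL, snps = NULL) {
  v <- unclass(x)
  meta <- variant_meta(x)
  if (is.null(samples)) samples <- seq_len(nrow(v))
  if (is.null(snps)) snps <- seq_len(ncol(v))
  genotype_matrix(
    v[samples, snps, drop = FALSE],
    sample_ids = rownames(v)[samples],
    variant_meta = meta[snps, , drop = FALSE],
    ploidy = gt_ploidy(x)
  )
}

# replace values, keep metadata
gt_replace <- function(x, values) {
  genotype_matrix(values,
    sample_ids = sample_ids(x),
    variant_meta = variant_meta(x), ploidy = gt_ploidy(x)
  )
}

#' @export
tidy.genotype_matrix <- function(x, ...) {
  meta <- variant_meta(x)
  v <- unclass(x)
  tibble(
    sample_id = rep(rownames(v), times = ncol(v)),
    variant_id = rep(meta$id, each = nrow(v)),
    genotype = as.integer(v)
  )
}

#' @export
glance.genotype_matrix <- function(x, ...) {
  tibble(
    n_samples = nrow(x), n_snps = ncol(x), ploidy = gt_ploidy(x),
    missing_fraction = mean(is.na(x))
  )
}
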
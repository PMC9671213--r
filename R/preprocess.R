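#' Per-SNP minor allele frequency
#'
#' Alternate-allele frequency is (het + 2 * hom-alt) / (2 * non-missing
#' samples); the MAF folds it as min(f, 1 - f). SNPs with no non-missing
#' calls get `NA`.
#'
#' @param matrix a diploid [genotype_matrix()].
#' @return Numeric vector of MAFs, one per SNP, named by variant id.
#' @export
compute_maf <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (gt_ploidy(matrix) != "diploid") {
    abort("`compute_maf` supports diploid matrices only.")
  }
  v <- unclass(matrix)
  n_ok <- colSums(!is.na(v))
  alt <- colSums(v, na.rm = TRUE)
  f <- alt / (2 * n_ok)
  f[n_ok == 0L] <- NA_real_
  maf <- pmin(f, 1 - f)
  names(maf) <- variant_meta(matrix)$id
  maf
}

#' Bin SNPs by minor allele frequency
#'
#' Labels each SNP with one of the four standard evaluation bins:
#' `MAF > 5%`, `1% < MAF < 5%`, `0.5% < MAF < 1%`, `0.1% < MAF < 0.5%`.
#' Boundary values are assigned to the lower bin (bins are left-open);
#' MAF at or below the lowest edge is labeled `below-range` (such SNPs are
#' normally removed upstream by [filter_snps()]).
#'
#' @param mafs numeric vector of MAFs in \[0, 0.5\].
#' @param edges increasing bin edges, default `c(0.001, 0.005, 0.01, 0.05)`.
#' @return Factor of bin labels, ordered rare to common, with level
#'   `below-range` first.
#' @export
bin_by_maf <- function(mafs, edges = c(0.001, 0.005, 0.01, 0.05)) {
  stopifnot(length(edges) == 4L, !is.unsorted(edges, strictly = TRUE))
  pct <- function(x) {
    s <- 100 * x
    ifelse(s == round(s), sprintf("%d%%", as.integer(round(s))), sprintf("%g%%", s))
  }
  labs <- c(
    "below-range",
    sprintf("%s < MAF < %s", pct(edges[1]), pct(edges[2])),
    sprintf("%s < MAF < %s", pct(edges[2]), pct(edges[3])),
    sprintf("%s < MAF < %s", pct(edges[3]), pct(edges[4])),
    sprintf("MAF > %s", pct(edges[4]))
  )
  cut(mafs, breaks = c(-Inf, edges, Inf), labels = labs, right = TRUE)
}

# one-degree-of-freedom chi-square HWE test on observed genotype counts
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (2 * n0 + n1) / (2 * n)
  q <- 1 - p
  e <- n * c(p^2, 2 * p * q, q^2)
  if (any(e == 0)) return(1)  # monomorphic: no testable departure, keep
  x2 <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Filter SNPs on missingness, HWE and MAF
#'
#' Drops SNPs whose missing fraction exceeds `max_missing_fraction`
#' (default 0: any missing call removes the SNP), whose one-degree-of-
#' freedom chi-square Hardy-Weinberg test p-value is below `hwe_p_min`, or
#' whose MAF is below `maf_min`. Filters are applied in that order for the
#' removal tally; a SNP failing several criteria is counted once, at the
#' first failing criterion.
#'
#' @param matrix a diploid [genotype_matrix()].
#' @param max_missing_fraction maximum tolerated per-SNP missing fraction.
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @param maf_min minimum MAF (default 0.001).
#' @return The filtered [genotype_matrix()]; attribute `removal_counts` is a
#'   named integer vector (`missingness`, `hwe`, `maf`).
#' @export
filter_snps <- function(matrix, max_missing_fraction = 0,
                        hwe_p_min = 1e-6, maf_min = 0.001) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (gt_ploidy(matrix) != "diploid") {
    abort("`filter_snps` supports diploid matrices only.")
  }
  v <- unclass(matrix)
  miss_frac <- colMeans(is.na(v))
  fail_miss <- miss_frac > max_missing_fraction
  n0 <- colSums(v == 0L, na.rm = TRUE)
  n1 <- colSums(v == 1L, na.rm = TRUE)
  n2 <- colSums(v == 2L, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(v)),
                  function(j) hwe_chisq_p(n0[j], n1[j], n2[j]), numeric(1))
  fail_hwe <- !fail_miss & !is.na(hwe_p) & hwe_p < hwe_p_min
  maf <- compute_maf(matrix)
  fail_maf <- !fail_miss & !fail_hwe & (is.na(maf) | maf < maf_min)
  keep <- !(fail_miss | fail_hwe | fail_maf)
  if (!any(keep)) warn("All SNPs removed by filtering; returning empty matrix.")
  out <- gt_subset(matrix, snps = which(keep))
  attr(out, "removal_counts") <- c(
    missingness = sum(fail_miss), hwe = sum(fail_hwe), maf = sum(fail_maf)
  )
  out
}

#' Truncate SNP count to a multiple of the model's downsampling factor
#'
#' Keeps the first `floor(n_snps / divisor) * divisor` SNPs in position
#' order, so the SNP dimension survives the encoder's pooling layers (the
#' default divisor 4 is pool size 2 raised to the 2 pooling layers).
#'
#' @param matrix a [genotype_matrix()].
#' @param divisor positive integer, default 4.
#' @return The truncated [genotype_matrix()].
#' @export
truncate_to_multiple <- function(matrix, divisor = 4L) {
  stopifnot(inherits(matrix, "genotype_matrix"), divisor >= 1L)
  keep <- (ncol(matrix) %/% divisor) * divisor
  if (keep == 0L) {
    abort(sprintf("Truncating %d SNPs to a multiple of %d leaves none.",
                  ncol(matrix), divisor))
  }
  if (keep == ncol(matrix)) return(matrix)
  gt_subset(matrix, snps = seq_len(keep))
}

#' Split samples into train / validation / test partitions
#'
#' Random sample permutation under `seed`, partitioned by cumulative
#' fractions. Validation and test sizes are floored; the remainder goes to
#' the training split, so 100 samples at the default 64/16/20 split give
#' exactly 64/16/20.
#'
#' @param matrix a [genotype_matrix()].
#' @param fractions length-3 numeric summing to 1: train, validation, test.
#' @param seed integer seed.
#' @return Named list of three [genotype_matrix()] objects (`train`,
#'   `validation`, `test`) plus the `assignment` factor in sample order.
#' @export
split_samples <- function(matrix, fractions = c(0.64, 0.16, 0.20), seed = 1L) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three numbers summing to 1.")
  }
  n <- nrow(matrix)
  if (n < 3L) abort("Need at least 3 samples to split.")
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    abort("Each split must contain at least one sample.")
  }
  set.seed(seed)
  perm <- sample.int(n)
  idx <- list(
    train = sort(perm[seq_len(n_train)]),
    validation = sort(perm[n_train + seq_len(n_val)]),
    test = sort(perm[n_train + n_val + seq_len(n_test)])
  )
  assignment <- factor(rep(NA_character_, n),
                       levels = c("train", "validation", "test"))
  for (nm in names(idx)) assignment[idx[[nm]]] <- nm
  out <- lapply(idx, function(i) gt_subset(matrix, samples = i))
  out$assignment <- assignment
  out
}

#' Randomly mask genotypes to create enforced missing values
#'
#' Selects `round(ratio * n_nonmissing)` currently non-missing entries
#' uniformly without replacement and sets them missing in the returned
#' copy, recording them in a mask plan. This is the enforced-missing
#' protocol used to benchmark imputation at 0%, 10% and 20% missing rates;
#' it is applied after sample splitting, independently per partition.
#'
#' @param matrix a [genotype_matrix()].
#' @param ratio masking fraction in \[0, 1).
#' @param seed integer seed.
#' @return List with `masked` (the masked [genotype_matrix()]) and `plan`
#'   (a `mask_plan`: `ratio`, logical `mask` matrix, `seed`).
#' @export
mask_random <- function(matrix, ratio, seed = 1L) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (ratio < 0 || ratio >= 1) abort("`ratio` must lie in [0, 1).")
  v <- unclass(matrix)
  eligible <- which(!is.na(v))
  n_mask <- round(ratio * length(eligible))
  mask <- matrix(FALSE, nrow(v), ncol(v),
                 dimnames = list(rownames(v), colnames(v)))
  if (n_mask > 0L) {
    set.seed(seed)
    mask[sample(eligible, n_mask)] <- TRUE
    v[mask] <- NA_integer_
  }
  plan <- structure(list(ratio = ratio, mask = mask, seed = as.integer(seed)),
                    class = "mask_plan")
  list(masked = gt_replace(matrix, v), plan = plan)
}

#' @export
print.mask_plan <- function(x, ...) {
  cat(sprintf("<mask_plan> ratio %.3f: %d of %d entries masked\n",
              x$ratio, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Serialize a mask plan to a replayable text table
#'
#' Three tab-separated columns: sample id, variant id, original genotype.
#'
#' @param plan a `mask_plan`.
#' @param truth the unmasked source [genotype_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_mask_plan <- function(plan, truth, path) {
  idx <- which(plan$mask, arr.ind = TRUE)
  df <- data.frame(
    sample_id = rownames(plan$mask)[idx[, 1]],
    variant_id = colnames(plan$mask)[idx[, 2]],
    original_genotype = unclass(truth)[plan$mask]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
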
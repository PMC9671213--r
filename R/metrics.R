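# Evaluation metrics for imputation quality. Aggregation conventions:
#   CR        : per sample across its in-scope SNPs, then mean over samples.
#   IQS       : per SNP across its in-scope samples, then mean over SNPs.
#   Hellinger : per (SNP, sample); per-SNP mean and per-SNP min across
#   / SEN       samples, then mean over SNPs (the min variant is a lower
#               bound on imputation quality).
# Scope: the masked entries when a mask plan is supplied, otherwise every
# entry with a non-missing truth genotype (the 0%-missing regime).

scope_matrix <- function(truth, mask = NULL) {
  t_ok <- !is.na(unclass(truth))
  if (is.null(mask)) return(t_ok)
  m <- if (inherits(mask, "mask_plan")) mask$mask else mask
  if (!identical(dim(m), dim(unclass(truth)))) {
    abort("Mask dimensions do not match the truth matrix.")
  }
  m & t_ok
}

genotype_classes <- function(truth) {
  if (gt_ploidy(truth) == "diploid") 0:2 else 1:2
}

#' Concordance rate
#'
#' Fraction of in-scope entries where the hard call equals the truth,
#' computed per sample across SNPs first and then averaged (unweighted)
#' over samples with at least one in-scope entry.
#'
#' @param truth ground-truth [genotype_matrix()].
#' @param calls imputed hard-call [genotype_matrix()].
#' @param mask optional `mask_plan` (or logical matrix) restricting the
#'   evaluation to artificially masked entries.
#' @return Scalar CR in \[0, 1\]; per-sample fractions in attribute
#'   `per_sample`.
#' @export
concordance_rate <- function(truth, calls, mask = NULL) {
  stopifnot(identical(dim(truth), dim(calls)))
  scope <- scope_matrix(truth, mask)
  if (!any(scope)) abort("No in-scope entries; concordance rate undefined.")
  match_m <- scope & (unclass(calls) == unclass(truth))
  match_m[is.na(match_m)] <- FALSE   # NA call counts as discordant
  n_scope <- rowSums(scope)
  per_sample <- ifelse(n_scope > 0, rowSums(match_m) / n_scope, NA_real_)
  out <- mean(per_sample, na.rm = TRUE)
  attr(out, "per_sample") <- per_sample
  out
}

# per-entry renormalized posterior probability of the true genotype class
true_class_prob <- function(truth, posterior) {
  d <- dim(posterior)
  n <- d[1]; L <- d[2]; C <- d[3]
  P <- matrix(as.numeric(posterior), n * L, C)
  geno <- P[, -1L, drop = FALSE]
  geno <- geno / pmax(rowSums(geno), .Machine$double.eps)
  shift <- if (gt_ploidy(truth) == "diploid") 1L else 0L
  cls <- as.integer(unclass(truth)) + shift    # genotype channel - 1
  q <- geno[cbind(seq_len(n * L), cls)]        # NA truth -> NA
  matrix(q, n, L)
}

aggregate_snp_scores <- function(score, scope) {
  score[!scope] <- NA_real_
  n_in <- colSums(scope)
  per_snp_mean <- ifelse(n_in > 0, colMeans(score, na.rm = TRUE), NA_real_)
  per_snp_min <- rep(NA_real_, ncol(score))
  has <- n_in > 0
  if (any(has)) {
    per_snp_min[has] <- suppressWarnings(
      apply(score[, has, drop = FALSE], 2, min, na.rm = TRUE)
    )
  }
  list(
    per_snp_mean = per_snp_mean, per_snp_min = per_snp_min,
    mean = mean(per_snp_mean, na.rm = TRUE),
    min_mean = mean(per_snp_min, na.rm = TRUE),
    n_excluded_snps = sum(!has)
  )
}

#' Hellinger score
#'
#' Per in-scope (SNP, sample): with P the point mass at the true genotype
#' and Q the posterior renormalized over the genotype channels, the
#' Hellinger distance is H = sqrt(1 - sum_g sqrt(P_g Q_g)) =
#' sqrt(1 - sqrt(Q_true)) and the score is 1 - H. Scores are averaged (and
#' separately minimized) across samples per SNP, then averaged over SNPs.
#'
#' @inheritParams concordance_rate
#' @param posterior `posterior_tensor` of model outputs.
#' @return List: `per_snp_mean`, `per_snp_min`, scalar `mean`, scalar
#'   `min_mean`, and `n_excluded_snps` (SNPs with empty scope).
#' @export
hellinger_score <- function(truth, posterior, mask = NULL) {
  scope <- scope_matrix(truth, mask)
  q <- true_class_prob(truth, posterior)
  score <- 1 - sqrt(pmax(1 - sqrt(pmin(pmax(q, 0), 1)), 0))
  aggregate_snp_scores(score, scope)
}

#' Scaled Euclidean norm (SEN) score
#'
#' Per in-scope (SNP, sample): 1 - |d_true - d_imp| / 2, the Euclidean
#' distance between true and imputed scalar dosages scaled by its maximum
#' of 2. Aggregation matches [hellinger_score()] including the min variant.
#'
#' @inheritParams concordance_rate
#' @param dosages samples x SNPs matrix of imputed dosages in \[0, 2\].
#' @return Same structure as [hellinger_score()].
#' @export
sen_score <- function(truth, dosages, mask = NULL) {
  if (gt_ploidy(truth) != "diploid") {
    abort("`sen_score` requires diploid dosages.")
  }
  stopifnot(identical(dim(unclass(truth)), dim(dosages)))
  scope <- scope_matrix(truth, mask)
  score <- 1 - abs(unclass(truth) - dosages) / 2
  aggregate_snp_scores(score, scope)
}

#' Imputation quality score (IQS)
#'
#' Cohen's-kappa-style chance-corrected agreement. Per SNP, over its n
#' in-scope samples, the truth-vs-call genotype contingency table gives the
#' observed agreement Po (diagonal mass) and the chance agreement
#' Pc = sum_g row_g * col_g / n^2; IQS = (Po - Pc) / (1 - Pc). When both
#' margins concentrate on one class (Pc = 1) kappa is undefined: the SNP
#' scores 1 if Po = 1 and 0 otherwise, and is flagged degenerate. This
#' correction is what keeps rare-variant quality honest where the raw CR is
#' inflated by majority-class guessing.
#'
#' @inheritParams concordance_rate
#' @return List: `per_snp`, scalar `mean`, `n_degenerate`.
#' @export
iqs <- function(truth, calls, mask = NULL) {
  stopifnot(identical(dim(truth), dim(calls)))
  scope <- scope_matrix(truth, mask)
  classes <- genotype_classes(truth)
  tv <- unclass(truth); cv <- unclass(calls)
  L <- ncol(tv)
  per_snp <- rep(NA_real_, L)
  degenerate <- logical(L)
  for (j in seq_len(L)) {
    ok <- scope[, j] & !is.na(cv[, j])
    n <- sum(ok)
    if (n == 0L) next
    tt <- factor(tv[ok, j], levels = classes)
    cc <- factor(cv[ok, j], levels = classes)
    tab <- table(tt, cc)
    po <- sum(diag(tab)) / n
    pc <- sum(rowSums(tab) * colSums(tab)) / n^2
    if (pc >= 1 - .Machine$double.eps^0.5) {
      per_snp[j] <- if (po >= 1) 1 else 0
      degenerate[j] <- TRUE
    } else {
      per_snp[j] <- (po - pc) / (1 - pc)
    }
  }
  names(per_snp) <- variant_meta(truth)$id
  list(per_snp = per_snp, mean = mean(per_snp, na.rm = TRUE),
       n_degenerate = sum(degenerate))
}

#' Pearson correlation between true genotypes and imputed dosages
#'
#' Per SNP, the correlation across in-scope samples between the true
#' genotype (0/1/2) and the imputed dosage. SNPs with fewer than two
#' in-scope samples or zero variance in either vector are excluded and
#' counted.
#'
#' @inheritParams sen_score
#' @return List: `per_snp`, scalar `mean`, `n_excluded_snps`.
#' @export
pcc_dosage <- function(truth, dosages, mask = NULL) {
  if (gt_ploidy(truth) != "diploid") {
    abort("`pcc_dosage` requires diploid dosages.")
  }
  scope <- scope_matrix(truth, mask)
  tv <- unclass(truth)
  per_snp <- rep(NA_real_, ncol(tv))
  for (j in seq_len(ncol(tv))) {
    ok <- scope[, j] & !is.na(dosages[, j])
    if (sum(ok) < 2L) next
    a <- tv[ok, j]; b <- dosages[ok, j]
    if (sd(a) == 0 || sd(b) == 0) next
    per_snp[j] <- cor(a, b)
  }
  names(per_snp) <- variant_meta(truth)$id
  list(per_snp = per_snp,
       mean = if (all(is.na(per_snp))) NA_real_ else mean(per_snp, na.rm = TRUE),
       n_excluded_snps = sum(is.na(per_snp)))
}

#' Full metric report
#'
#' Computes CR, Hellinger (mean and min), SEN (mean and min, diploid),
#' IQS and dosage PCC (diploid) under one evaluation scope; with
#' `maf_bins`, each metric is additionally computed restricted to the SNPs
#' of each bin.
#'
#' @inheritParams concordance_rate
#' @param posterior `posterior_tensor` of model outputs.
#' @param dosages optional dosage matrix (required for SEN/PCC, diploid).
#' @param maf_bins optional per-SNP factor from [bin_by_maf()].
#' @return A `metric_report` tibble with one row per scope/bin; per-SNP and
#'   per-sample intermediates in attributes `per_snp` and `per_sample`.
#' @export
full_report <- function(truth, posterior, calls, dosages = NULL, mask = NULL,
                        maf_bins = NULL) {
  diploid <- gt_ploidy(truth) == "diploid"
  if (diploid && is.null(dosages)) dosages <- dosage(posterior)
  one_scope <- function(tr, po, ca, do, mk, bin_label) {
    cr <- concordance_rate(tr, ca, mk)
    he <- hellinger_score(tr, po, mk)
    iq <- iqs(tr, ca, mk)
    se <- if (diploid) sen_score(tr, do, mk) else NULL
    pc <- if (diploid) pcc_dosage(tr, do, mk) else NULL
    row <- tibble(
      bin = bin_label,
      scope = if (is.null(mk)) "all-entries" else "masked-only",
      n_snps = ncol(tr),
      cr = as.numeric(cr),
      hellinger_mean = he$mean, hellinger_min = he$min_mean,
      sen_mean = if (diploid) se$mean else NA_real_,
      sen_min = if (diploid) se$min_mean else NA_real_,
      iqs = iq$mean,
      pcc = if (diploid) pc$mean else NA_real_,
      iqs_degenerate_snps = iq$n_degenerate
    )
    per_snp <- tibble(
      variant_id = variant_meta(tr)$id,
      bin = bin_label,
      hellinger_mean = he$per_snp_mean, hellinger_min = he$per_snp_min,
      sen_mean = if (diploid) se$per_snp_mean else NA_real_,
      sen_min = if (diploid) se$per_snp_min else NA_real_,
      iqs = iq$per_snp,
      pcc = if (diploid) pc$per_snp else NA_real_
    )
    per_sample <- tibble(
      sample_id = sample_ids(tr), bin = bin_label,
      cr = attr(cr, "per_sample")
    )
    list(row = row, per_snp = per_snp, per_sample = per_sample)
  }
  sub_mask <- function(mk, snps) {
    if (is.null(mk)) return(NULL)
    m <- if (inherits(mk, "mask_plan")) mk$mask else mk
    m[, snps, drop = FALSE]
  }
  parts <- list(one_scope(truth, posterior, calls, dosages, mask, "all"))
  if (!is.null(maf_bins)) {
    stopifnot(length(maf_bins) == ncol(truth))
    for (b in levels(droplevels(maf_bins[!is.na(maf_bins)]))) {
      snps <- which(!is.na(maf_bins) & maf_bins == b)
      if (length(snps) == 0L) next
      parts[[length(parts) + 1L]] <- one_scope(
        gt_subset(truth, snps = snps),
        new_posterior_tensor(
          unclass(posterior)[, snps, , drop = FALSE], gt_ploidy(truth)),
        gt_subset(calls, snps = snps),
        if (diploid) dosages[, snps, drop = FALSE] else NULL,
        sub_mask(mask, snps), b
      )
    }
  }
  out <- dplyr::bind_rows(lapply(parts, `[[`, "row"))
  attr(out, "per_snp") <- dplyr::bind_rows(lapply(parts, `[[`, "per_snp"))
  attr(out, "per_sample") <- dplyr::bind_rows(lapply(parts, `[[`, "per_sample"))
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
tidy.metric_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
    cols = c("cr", "hellinger_mean", "hellinger_min", "sen_mean",
             "sen_min", "iqs", "pcc"),
    names_to = "metric", values_to = "value"
  )
}
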
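#' Simulation configuration for LD-structured genotype panels
#'
#' Parameters for the haplotype-mosaic simulator. Offspring haplotypes are
#' built by copying founder haplotypes with occasional uniform switches
#' (a first-order Markov mosaic), so low `switch_rate` produces long shared
#' segments and strong local linkage disequilibrium -- the correlation
#' structure among nearby markers that a convolutional imputer exploits.
#'
#' @param n_founders number of founder haplotypes.
#' @param n_samples number of diploid samples (2 haplotypes each).
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric, target founder alternate-allele
#'   frequency range; lower bound > 0, upper bound <= 0.5.
#' @param switch_rate per-SNP probability of switching the copied founder,
#'   strictly inside (0, 1).
#' @param seed integer seed controlling all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 20L, n_samples = 200L, n_snps = 64L,
                       maf_range = c(0.1, 0.5), switch_rate = 0.02,
                       seed = 1L) {
  for (fld in c("n_founders", "n_samples", "n_snps")) {
    v <- get(fld)
    if (length(v) != 1L || !is.finite(v) || v < 1) {
      abort(sprintf("`%s` must be a positive count.", fld))
    }
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must satisfy 0 < lower <= upper <= 0.5.")
  }
  if (length(switch_rate) != 1L || switch_rate <= 0 || switch_rate >= 1) {
    abort("`switch_rate` must lie strictly inside (0, 1).")
  }
  structure(
    list(
      n_founders = as.integer(n_founders), n_samples = as.integer(n_samples),
      n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
      switch_rate = as.numeric(switch_rate), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

new_haplotype_panel <- function(alleles, positions = seq_len(ncol(alleles))) {
  stopifnot(is.matrix(alleles), all(alleles %in% c(0L, 1L)))
  if (length(positions) != ncol(alleles)) {
    abort("`positions` length must equal the number of SNPs.")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing.")
  }
  storage.mode(alleles) <- "integer"
  structure(list(alleles = alleles, positions = as.integer(positions)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d SNPs\n",
              nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}

#' Simulate founder haplotypes
#'
#' Draws a per-SNP target alternate-allele frequency uniformly inside
#' `config$maf_range`, then places `round(f * n_founders)` alternate alleles
#' (clamped to at least 1 and at most `n_founders - 1`) at random founders,
#' so every column's realized founder frequency falls inside the target range
#' up to the 1/(2 n_founders) rounding grid and no column is monomorphic.
#'
#' @param config a [sim_config()].
#' @return A `haplotype_panel` with `n_founders` haplotypes.
#' @export
simulate_founders <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  nf <- config$n_founders
  if (nf < 2L) abort("`n_founders` must be at least 2 to avoid monomorphic SNPs.")
  f <- runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  k <- pmin(pmax(round(f * nf), 1L), nf - 1L)
  alleles <- matrix(0L, nf, config$n_snps)
  for (j in seq_len(config$n_snps)) {
    alleles[sample.int(nf, k[j]), j] <- 1L
  }
  new_haplotype_panel(alleles)
}

#' Simulate mosaic haplotypes from founders
#'
#' First-order Markov copying process: each output haplotype starts from a
#' uniformly chosen founder; at every subsequent SNP it switches to a new
#' uniformly chosen founder with probability `switch_rate`, otherwise keeps
#' copying the same founder. Long copied segments (low `switch_rate`)
#' produce high adjacent-SNP r-squared that decays with distance.
#'
#' @param founders a `haplotype_panel` of founder haplotypes.
#' @param n_haplotypes number of mosaic haplotypes to generate.
#' @param switch_rate per-SNP switch probability in (0, 1).
#' @param seed integer seed.
#' @return A `haplotype_panel` of `n_haplotypes` mosaics.
#' @export
simulate_mosaic <- function(founders, n_haplotypes, switch_rate, seed = 1L) {
  if (!inherits(founders, "haplotype_panel") || nrow(founders$alleles) == 0L) {
    abort("`founders` must be a non-empty haplotype_panel.")
  }
  if (switch_rate <= 0 || switch_rate >= 1) {
    abort("`switch_rate` must lie strictly inside (0, 1).")
  }
  set.seed(seed)
  nf <- nrow(founders$alleles)
  L <- ncol(founders$alleles)
  H <- as.integer(n_haplotypes)
  src <- matrix(0L, H, L)
  src[, 1L] <- sample.int(nf, H, replace = TRUE)
  if (L > 1L) {
    switch <- matrix(runif(H * (L - 1L)) < switch_rate, H, L - 1L)
    fresh <- matrix(sample.int(nf, H * (L - 1L), replace = TRUE), H, L - 1L)
    for (j in 2L:L) {
      src[, j] <- ifelse(switch[, j - 1L], fresh[, j - 1L], src[, j - 1L])
    }
  }
  alleles <- matrix(0L, H, L)
  for (j in seq_len(L)) alleles[, j] <- founders$alleles[src[, j], j]
  new_haplotype_panel(alleles, founders$positions)
}

#' Pair haplotypes into diploid genotypes
#'
#' Consecutive haplotype pairs (1,2), (3,4), ... are summed per SNP into
#' genotype classes 0/1/2, the number of non-reference alleles.
#'
#' @param panel a `haplotype_panel` with an even number of haplotypes.
#' @return A diploid [genotype_matrix()] with no missing entries.
#' @export
haplotypes_to_genotypes <- function(panel) {
  H <- nrow(panel$alleles)
  if (H %% 2L != 0L) abort("Haplotype count must be even to form diploid samples.")
  a <- panel$alleles[seq(1L, H, by = 2L), , drop = FALSE]
  b <- panel$alleles[seq(2L, H, by = 2L), , drop = FALSE]
  genotype_matrix(
    a + b,
    variant_meta = tibble(
      chrom = "1", pos = panel$positions,
      id = sprintf("snp%d", seq_along(panel$positions)), ref = "A", alt = "G"
    ),
    ploidy = "diploid"
  )
}

#' Simulate an LD-structured diploid genotype panel
#'
#' Convenience wrapper: founders -> mosaic haplotypes -> paired genotypes.
#'
#' @param config a [sim_config()].
#' @return A diploid [genotype_matrix()].
#' @export
simulate_panel <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  founders <- simulate_founders(config)
  mosaics <- simulate_mosaic(founders, 2L * config$n_samples,
                             config$switch_rate, seed = config$seed + 1L)
  haplotypes_to_genotypes(mosaics)
}

#' Simulate a yeast-style haploid two-strain panel
#'
#' Emulates a two-strain yeast cross panel in the recoded convention where
#' the laboratory strain is class 1 and the vineyard strain is class 2 (the
#' original -1 labels replaced with 2 so all classes are non-negative).
#' Each sample is a sequence of contiguous strain blocks whose lengths are
#' geometric with mean `block_length`, alternating between the two classes.
#'
#' @param n_samples number of haploid samples.
#' @param n_snps number of SNPs.
#' @param block_length expected block length in SNPs (>= 1).
#' @param seed integer seed.
#' @return A haploid [genotype_matrix()] with values in \{1, 2\}.
#' @export
simulate_yeast_panel <- function(n_samples, n_snps, block_length, seed = 1L) {
  if (block_length < 1) abort("`block_length` must be >= 1.")
  set.seed(seed)
  p <- 1 / block_length
  start <- sample(c(1L, 2L), n_samples, replace = TRUE)
  values <- matrix(0L, n_samples, n_snps)
  values[, 1L] <- start
  if (n_snps > 1L) {
    flips <- matrix(runif(n_samples * (n_snps - 1L)) < p, n_samples, n_snps - 1L)
    for (j in 2L:n_snps) {
      cur <- values[, j - 1L]
      values[, j] <- ifelse(flips[, j - 1L], 3L - cur, cur)
    }
  }
  genotype_matrix(values, ploidy = "haploid")
}

#' Pairwise LD (r-squared) at a fixed SNP distance
#'
#' Mean squared Pearson correlation between allele columns `d` SNPs apart,
#' computed on a haplotype panel. Monomorphic columns are skipped.
#'
#' @param panel a `haplotype_panel`.
#' @param distance inter-SNP distance in index units.
#' @return Mean r-squared across usable SNP pairs.
#' @export
ld_r2_at_distance <- function(panel, distance) {
  a <- panel$alleles
  L <- ncol(a)
  if (distance >= L) abort("`distance` must be smaller than the SNP count.")
  j1 <- seq_len(L - distance)
  j2 <- j1 + distance
  keep <- apply(a[, j1, drop = FALSE], 2, sd) > 0 &
    apply(a[, j2, drop = FALSE], 2, sd) > 0
  r <- vapply(which(keep), function(i) cor(a[, j1[i]], a[, j2[i]]), numeric(1))
  mean(r^2)
}
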
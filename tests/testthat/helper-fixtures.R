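# Shared fixtures and naive oracles. All fixtures are generated in code;
# the oracles are deliberately slow per-entry loops kept independent of the
# vectorized implementations they check.

# genotype values stripped to dim/dimnames for identity comparisons
gt_values <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

tiny_panel <- function(n_samples = 64L, n_snps = 64L, seed = 7L,
                       n_founders = 12L, switch_rate = 0.03) {
  simulate_panel(sim_config(
    n_founders = n_founders, n_samples = n_samples, n_snps = n_snps,
    switch_rate = switch_rate, seed = seed
  ))
}

# random truth / calls / posterior instance for metric oracle checks
random_metric_instance <- function(n = 20L, L = 30L, seed = 1L,
                                   with_mask = TRUE) {
  set.seed(seed)
  truth <- genotype_matrix(matrix(sample(0:2, n * L, replace = TRUE), n, L))
  probs <- array(runif(n * L * 4), c(n, L, 4))
  for (i in seq_len(n)) for (j in seq_len(L)) {
    probs[i, j, ] <- probs[i, j, ] / sum(probs[i, j, ])
  }
  posterior <- dcimpute:::new_posterior_tensor(probs, "diploid")
  calls <- decode_calls(posterior, variant_meta = variant_meta(truth),
                        sample_ids = sample_ids(truth))
  mask <- if (with_mask) matrix(runif(n * L) < 0.4, n, L) else NULL
  list(truth = truth, posterior = posterior, calls = calls,
       dosages = dosage(posterior), mask = mask)
}

scope_of <- function(truth, mask) {
  if (is.null(mask)) !is.na(unclass(truth)) else mask & !is.na(unclass(truth))
}

# ---- naive per-entry loop oracles ----

oracle_cr <- function(truth, calls, mask = NULL) {
  tv <- unclass(truth); cv <- unclass(calls)
  scope <- scope_of(truth, mask)
  per_sample <- c()
  for (i in seq_len(nrow(tv))) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(tv))) {
      if (scope[i, j]) {
        den <- den + 1
        if (!is.na(cv[i, j]) && cv[i, j] == tv[i, j]) num <- num + 1
      }
    }
    if (den > 0) per_sample <- c(per_sample, num / den)
  }
  mean(per_sample)
}

# generic two-distribution Hellinger distance, used as the independent
# reference for the point-mass shortcut in hellinger_score
hellinger_dist <- function(p, q) sqrt(1 - sum(sqrt(p * q)))

oracle_hellinger <- function(truth, posterior, mask = NULL) {
  tv <- unclass(truth)
  pr <- unclass(posterior)
  scope <- scope_of(truth, mask)
  per_snp_mean <- per_snp_min <- rep(NA_real_, ncol(tv))
  for (j in seq_len(ncol(tv))) {
    vals <- c()
    for (i in seq_len(nrow(tv))) {
      if (!scope[i, j]) next
      q <- pr[i, j, 2:4]
      q <- q / sum(q)
      p <- c(0, 0, 0); p[tv[i, j] + 1L] <- 1
      vals <- c(vals, 1 - hellinger_dist(p, q))
    }
    if (length(vals)) {
      per_snp_mean[j] <- mean(vals)
      per_snp_min[j] <- min(vals)
    }
  }
  list(mean = mean(per_snp_mean, na.rm = TRUE),
       min_mean = mean(per_snp_min, na.rm = TRUE),
       per_snp_mean = per_snp_mean, per_snp_min = per_snp_min)
}

oracle_sen <- function(truth, dosages, mask = NULL) {
  tv <- unclass(truth)
  scope <- scope_of(truth, mask)
  per_snp_mean <- per_snp_min <- rep(NA_real_, ncol(tv))
  for (j in seq_len(ncol(tv))) {
    vals <- c()
    for (i in seq_len(nrow(tv))) {
      if (scope[i, j]) vals <- c(vals, 1 - abs(tv[i, j] - dosages[i, j]) / 2)
    }
    if (length(vals)) {
      per_snp_mean[j] <- mean(vals)
      per_snp_min[j] <- min(vals)
    }
  }
  list(mean = mean(per_snp_mean, na.rm = TRUE),
       min_mean = mean(per_snp_min, na.rm = TRUE))
}

oracle_iqs <- function(truth, calls, mask = NULL) {
  tv <- unclass(truth); cv <- unclass(calls)
  scope <- scope_of(truth, mask)
  per_snp <- rep(NA_real_, ncol(tv))
  for (j in seq_len(ncol(tv))) {
    t_in <- c(); c_in <- c()
    for (i in seq_len(nrow(tv))) {
      if (scope[i, j] && !is.na(cv[i, j])) {
        t_in <- c(t_in, tv[i, j]); c_in <- c(c_in, cv[i, j])
      }
    }
    n <- length(t_in)
    if (n == 0) next
    po <- mean(t_in == c_in)
    pc <- 0
    for (g in 0:2) pc <- pc + sum(t_in == g) * sum(c_in == g)
    pc <- pc / n^2
    per_snp[j] <- if (pc >= 1 - 1e-12) (if (po >= 1) 1 else 0)
                  else (po - pc) / (1 - pc)
  }
  list(per_snp = per_snp, mean = mean(per_snp, na.rm = TRUE))
}

oracle_pcc <- function(truth, dosages, mask = NULL) {
  tv <- unclass(truth)
  scope <- scope_of(truth, mask)
  per_snp <- rep(NA_real_, ncol(tv))
  for (j in seq_len(ncol(tv))) {
    a <- c(); b <- c()
    for (i in seq_len(nrow(tv))) {
      if (scope[i, j] && !is.na(dosages[i, j])) {
        a <- c(a, tv[i, j]); b <- c(b, dosages[i, j])
      }
    }
    if (length(a) >= 2 && sd(a) > 0 && sd(b) > 0) per_snp[j] <- cor(a, b)
  }
  list(per_snp = per_snp, mean = mean(per_snp, na.rm = TRUE))
}

# posterior tensor that is a point mass on given calls (diploid)
point_mass_posterior <- function(calls) {
  v <- unclass(calls)
  probs <- array(0, c(nrow(v), ncol(v), 4L))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    ch <- if (is.na(v[i, j])) 1L else v[i, j] + 2L
    probs[i, j, ch] <- 1
  }
  dcimpute:::new_posterior_tensor(probs, "diploid")
}

# per-SNP majority-genotype imputer: fills masked entries with the most
# frequent observed genotype of that SNP (ties to the lower class)
majority_baseline <- function(masked, plan) {
  v <- unclass(masked)
  for (j in seq_len(ncol(v))) {
    obs <- v[!is.na(v[, j]), j]
    maj <- if (length(obs)) {
      tab <- table(obs)
      as.integer(names(tab)[which.max(tab)])
    } else 0L
    v[plan$mask[, j], j] <- maj
  }
  genotype_matrix(v, sample_ids = sample_ids(masked),
                  variant_meta = variant_meta(masked),
                  ploidy = dcimpute::gt_ploidy(masked))
}
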
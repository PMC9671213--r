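#' Experiment plan
#'
#' Defines the repeated-run benchmark: enforced missing ratios (default
#' 0%, 10%, 20%), number of repeats (default 3), the training modes to
#' contrast (default the per-batch custom loop vs gradient accumulation
#' over two batches), and the base seed every repeat derives from.
#'
#' @param missing_ratios numeric vector of masking ratios in \[0, 1).
#' @param n_repeats repeats per cell (>= 2 so paired t-tests are defined).
#' @param base_seed integer base seed.
#' @param modes character vector of training modes (see [training_config()]).
#' @param k accumulation count for the `averaged_k` mode.
#' @param maf_binning stratify reports by MAF bin.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(missing_ratios = c(0, 0.10, 0.20),
                            n_repeats = 3L, base_seed = 1L,
                            modes = c("per_batch", "averaged_k"), k = 2L,
                            maf_binning = FALSE) {
  if (any(missing_ratios < 0 | missing_ratios >= 1)) {
    abort("`missing_ratios` must lie in [0, 1).")
  }
  if (n_repeats < 2L) abort("`n_repeats` must be >= 2 for paired t-tests.")
  if (!all(modes %in% c("per_batch", "averaged_k"))) {
    abort("`modes` must be drawn from 'per_batch' and 'averaged_k'.")
  }
  structure(
    list(missing_ratios = missing_ratios, n_repeats = as.integer(n_repeats),
         base_seed = as.integer(base_seed), modes = modes, k = as.integer(k),
         maf_binning = isTRUE(maf_binning)),
    class = "experiment_plan"
  )
}

#' Paired t-test
#'
#' Two-sided paired t-test on per-repeat metric values paired by shared
#' seed: d = a - b, t = mean(d) / (sd(d) / sqrt(n)) with the (n-1)-
#' denominator sample SD, p from the Student-t distribution with n - 1
#' degrees of freedom. Zero-variance differences give t = 0, p = 1 when
#' the mean difference is zero, and p = 0 with a degeneracy flag otherwise.
#'
#' @param a,b equal-length numeric vectors of paired values.
#' @return One-row tibble: `statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal lengths.")
  n <- length(a)
  if (n < 2L) abort("Need at least 2 pairs.")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(tibble(statistic = 0, p_value = 1, df = n - 1L,
                    degenerate = FALSE))
    }
    return(tibble(statistic = sign(mean(d)) * Inf, p_value = 0,
                  df = n - 1L, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  tibble(statistic = t, p_value = 2 * pt(-abs(t), df = n - 1L),
         df = n - 1L, degenerate = FALSE)
}

metric_columns <- c("cr", "hellinger_mean", "hellinger_min",
                    "sen_mean", "sen_min", "iqs", "pcc")

# one training + imputation + evaluation cell of the experiment grid
run_cell <- function(splits, ratio, mode, seed, spec, config, maf_bins) {
  masked <- lapply(seq_along(splits[c("train", "validation", "test")]),
                   function(i) {
    mask_random(splits[[i]], ratio, seed = seed + 17L * i)
  })
  names(masked) <- c("train", "validation", "test")
  enc_in <- lapply(masked, function(m) encode_onehot(m$masked))
  enc_tg <- lapply(splits[c("train", "validation", "test")], encode_onehot)
  model <- build_model(spec, seed = seed)
  cfg <- training_config(
    epochs = config$epochs, batch_size = config$batch_size,
    learning_rate = config$learning_rate, alpha = config$alpha,
    loss_mode = mode, k = config$k, seed = seed
  )
  fit <- train(model, enc_in$train, enc_tg$train,
               enc_in$validation, enc_tg$validation, cfg)
  imp <- impute(fit, masked$test$masked, preserve_observed = FALSE)
  mask_arg <- if (ratio > 0) masked$test$plan else NULL
  report <- full_report(splits$test, imp$posterior, imp$calls,
                        dosages = imp$dosage, mask = mask_arg,
                        maf_bins = maf_bins)
  list(report = report, history = fit$history)
}

run_experiment_impl <- function(dataset, plan, spec, config, maf_bins) {
  cells <- list()
  histories <- list()
  for (r in seq_len(plan$n_repeats)) {
    seed_r <- plan$base_seed + 101L * r
    splits <- split_samples(dataset, c(0.64, 0.16, 0.20), seed = seed_r)
    for (ri in seq_along(plan$missing_ratios)) {
      ratio <- plan$missing_ratios[ri]
      for (mode in plan$modes) {
        cell_id <- sprintf("r%d_m%g_%s", r, ratio, mode)
        res <- tryCatch(
          run_cell(splits, ratio, mode, seed = seed_r + 1000L * ri,
                   spec = spec, config = config, maf_bins = maf_bins),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          warn(sprintf("Cell %s failed: %s", cell_id, conditionMessage(res)))
          cells[[cell_id]] <- tibble(
            repeat_id = r, ratio = ratio, mode = mode, bin = "all",
            failed = TRUE
          )
          next
        }
        rep_tbl <- as_tibble(res$report)
        cells[[cell_id]] <- dplyr::bind_cols(
          tibble(repeat_id = r, ratio = ratio, mode = mode)[
            rep(1L, nrow(rep_tbl)), ],
          rep_tbl, tibble(failed = rep(FALSE, nrow(rep_tbl)))
        )
        histories[[cell_id]] <- dplyr::mutate(
          res$history, repeat_id = r, ratio = ratio, mode = mode
        )
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  present <- intersect(metric_columns, names(cells))
  long <- tidyr::pivot_longer(
    dplyr::filter(cells, !.data$failed),
    cols = dplyr::all_of(present), names_to = "metric", values_to = "value"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$ratio, .data$bin, .data$mode),
    mean = mean(.data$value), sd = sd(.data$value),
    n = dplyr::n(), .groups = "drop"
  )
  tests <- NULL
  if (length(plan$modes) >= 2L) {
    wide <- tidyr::pivot_wider(
      dplyr::select(long, "repeat_id", "ratio", "bin", "metric",
                    "mode", "value"),
      names_from = "mode", values_from = "value"
    )
    m1 <- plan$modes[1]; m2 <- plan$modes[2]
    tests <- dplyr::reframe(
      dplyr::group_by(wide, .data$metric, .data$ratio, .data$bin),
      {
        a <- .data[[m1]]; b <- .data[[m2]]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) >= 2L) paired_t_test(a[ok], b[ok])
        else tibble(statistic = NA_real_, p_value = NA_real_,
                    df = NA_integer_, degenerate = NA)
      }
    )
  }
  structure(
    list(cells = cells, summary = summary, tests = tests,
         histories = dplyr::bind_rows(histories), plan = plan),
    class = "comparison_result"
  )
}

#' Run the repeated-run imputation experiment
#'
#' For every repeat: derive a seed, split samples 64/16/20, and for every
#' missing ratio mask all three partitions; for every training mode (with
#' identical split, masks and initialization within the repeat, so the
#' modes are paired) train on masked-train against unmasked-train with
#' validation monitoring, impute the test partition, and score it with
#' [full_report()]. Cell means/SDs and paired t-tests between the first
#' two modes are assembled per (metric, ratio).
#'
#' @param dataset a preprocessed [genotype_matrix()].
#' @param plan an [experiment_plan()].
#' @param spec a [model_spec()] matching the dataset's SNP count; defaults
#'   to the standard architecture.
#' @param config a [training_config()] providing epochs/batch size/learning
#'   rate (its `loss_mode`/`seed` are overridden per cell).
#' @return A `comparison_result`: `cells` (per-repeat metric grid),
#'   `summary` (mean/SD), `tests` (paired t-tests), `histories`.
#' @export
run_experiment <- function(dataset, plan = experiment_plan(),
                           spec = NULL, config = training_config()) {
  stopifnot(inherits(dataset, "genotype_matrix"))
  if (is.null(spec)) {
    spec <- model_spec(ncol(dataset),
                       n_channels = if (gt_ploidy(dataset) == "diploid") 4L else 3L)
  }
  run_experiment_impl(dataset, plan, spec, config, maf_bins = NULL)
}

#' MAF-stratified imputation experiment
#'
#' [run_experiment()] with every metric additionally restricted to the
#' SNPs of each MAF bin (bins computed on the unmasked full dataset),
#' reproducing the rare-variant evaluation regime. Defaults to a single
#' 20% missing ratio.
#'
#' @inheritParams run_experiment
#' @param edges MAF bin edges passed to [bin_by_maf()].
#' @return A `comparison_result` whose rows carry a `bin` column.
#' @export
maf_stratified_experiment <- function(dataset,
                                      plan = experiment_plan(missing_ratios = 0.20),
                                      spec = NULL,
                                      config = training_config(),
                                      edges = c(0.001, 0.005, 0.01, 0.05)) {
  stopifnot(inherits(dataset, "genotype_matrix"))
  if (gt_ploidy(dataset) != "diploid") {
    abort("MAF stratification requires a diploid dataset.")
  }
  if (is.null(spec)) spec <- model_spec(ncol(dataset), n_channels = 4L)
  bins <- bin_by_maf(compute_maf(dataset), edges = edges)
  empty <- setdiff(levels(bins), c("below-range", levels(droplevels(bins))))
  if (length(empty)) {
    warn(sprintf("Empty MAF bins skipped: %s", paste(empty, collapse = ", ")))
  }
  run_experiment_impl(dataset, plan, spec, config, maf_bins = bins)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d repeats x %d ratios x %d modes\n",
              x$plan$n_repeats, length(x$plan$missing_ratios),
              length(x$plan$modes)))
  print(x$summary, n = 20)
  invisible(x)
}

#' @export
tidy.comparison_result <- function(x, ...) x$summary

#' @export
glance.comparison_result <- function(x, ...) {
  tibble(
    n_repeats = x$plan$n_repeats,
    n_ratios = length(x$plan$missing_ratios),
    n_modes = length(x$plan$modes),
    n_failed_cells = sum(x$cells$failed)
  )
}
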
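#' One-hot encode a genotype matrix
#'
#' Diploid genotypes are first shifted by +1 so that 0 can stand for a
#' missing value, then one-hot encoded over 4 channels: shifted class 0
#' (missing) -> (1,0,0,0), 1 -> (0,1,0,0), 2 -> (0,0,1,0), 3 -> (0,0,0,1).
#' Haploid (yeast-style) panels use 3 channels with class 0 (missing) ->
#' (1,0,0), 1 -> (0,1,0), 2 -> (0,0,1); their classes are already positive
#' so no shift is applied. Channel 1 is therefore the reserved missing
#' channel in both modes.
#'
#' @param matrix a [genotype_matrix()].
#' @return An `encoded_tensor`: samples x SNPs x channels 0/1 array with
#'   attributes `ploidy` and `channels`.
#' @export
encode_onehot <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  v <- unclass(matrix)
  ploidy <- gt_ploidy(matrix)
  C <- if (ploidy == "diploid") 4L else 3L
  shift <- if (ploidy == "diploid") 1L else 0L
  cls <- v + shift
  cls[is.na(cls)] <- 0L
  n <- nrow(v); L <- ncol(v)
  probs <- array(0, c(n, L, C))
  # linear index into the 3D array: channel = class + 1
  idx <- seq_len(n * L) + as.integer(cls) * (n * L)
  probs[idx] <- 1
  new_encoded_tensor(probs, ploidy)
}

new_encoded_tensor <- function(probs, ploidy) {
  structure(probs, ploidy = ploidy, channels = dim(probs)[3],
            class = c("encoded_tensor", "array"))
}

new_posterior_tensor <- function(probs, ploidy) {
  structure(probs, ploidy = ploidy, channels = dim(probs)[3],
            class = c("posterior_tensor", "array"))
}

#' @export
print.encoded_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<encoded_tensor> %d samples x %d SNPs x %d channels (%s)\n",
              d[1], d[2], d[3], attr(x, "ploidy")))
  invisible(x)
}

#' @export
print.posterior_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<posterior_tensor> %d samples x %d SNPs x %d channels (%s)\n",
              d[1], d[2], d[3], attr(x, "ploidy")))
  invisible(x)
}

#' Decode hard genotype calls from a posterior tensor
#'
#' Per (sample, SNP), the call is the argmax over the genotype channels.
#' By default the reserved missing channel (channel 1) is excluded so the
#' decoder always emits a genotype; with `exclude_missing_channel = FALSE`
#' an argmax landing on the missing channel yields `NA`. Ties break toward
#' the lower genotype class, deterministically. Diploid channels map back
#' to classes by subtracting the +1 shift; haploid channels are the classes.
#'
#' @param posterior a `posterior_tensor` (or `encoded_tensor`).
#' @param exclude_missing_channel drop channel 1 from the argmax (default).
#' @param variant_meta,sample_ids optional metadata for the result.
#' @return A [genotype_matrix()] of hard calls.
#' @export
decode_calls <- function(posterior, exclude_missing_channel = TRUE,
                         variant_meta = NULL, sample_ids = NULL) {
  d <- dim(posterior)
  n <- d[1]; L <- d[2]; C <- d[3]
  ploidy <- attr(posterior, "ploidy") %||% if (C == 4L) "diploid" else "haploid"
  P <- matrix(as.numeric(posterior), n * L, C)
  cols <- if (exclude_missing_channel) 2:C else 1:C
  sub <- P[, cols, drop = FALSE]
  best <- max.col(sub, ties.method = "first")  # first = lower class on ties
  ch <- cols[best]                             # winning channel, 1-based
  shift <- if (ploidy == "diploid") 1L else 0L
  g <- ch - 1L - shift
  g[ch == 1L] <- NA_integer_                   # missing channel won
  values <- matrix(as.integer(g), n, L)
  genotype_matrix(values, sample_ids = sample_ids,
                  variant_meta = variant_meta, ploidy = ploidy)
}

#' Expected allele dosage from a diploid posterior
#'
#' Per (sample, SNP) the genotype channels (2..4) are renormalized to sum to
#' one and the dosage is the expectation 0*p(0) + 1*p(1) + 2*p(2), bounded
#' in \[0, 2\]. Entries whose genotype-channel mass is entirely zero get
#' `NA` and are counted in attribute `n_degenerate`.
#'
#' @param posterior a diploid `posterior_tensor`.
#' @return samples x SNPs numeric matrix of dosages.
#' @export
dosage <- function(posterior) {
  d <- dim(posterior)
  ploidy <- attr(posterior, "ploidy") %||% if (d[3] == 4L) "diploid" else "haploid"
  if (ploidy != "diploid" || d[3] != 4L) {
    abort("`dosage` requires a diploid 4-channel posterior.")
  }
  n <- d[1]; L <- d[2]
  P <- matrix(as.numeric(posterior), n * L, 4L)
  mass <- P[, 2L] + P[, 3L] + P[, 4L]
  dose <- (P[, 3L] + 2 * P[, 4L]) / mass
  bad <- mass <= 0
  dose[bad] <- NA_real_
  out <- matrix(dose, n, L)
  attr(out, "n_degenerate") <- sum(bad)
  out
}
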
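#' Read a biallelic genotype matrix from VCF
#'
#' Parses a VCF 4.x file (plain or bgzipped) and maps GT fields to genotype
#' classes: `0|0`/`0/0` -> 0, `0|1`/`1|0`/`0/1`/`1/0` -> 1, `1|1`/`1/1` -> 2.
#' Phase is discarded. Any allele of `.` (including half-calls such as
#' `0/.`) yields a missing entry. Multiallelic records (two or more ALT
#' alleles) are skipped and counted, matching the usual upstream removal of
#' multi-allelic SNPs.
#'
#' @param path VCF file path.
#' @param mode `"diploid"` or `"haploid"`; in haploid mode the GT classes are
#'   expected to already be the two strain classes (1/2 written as diploid
#'   0/1 coding is not supported -- haploid panels round-trip through
#'   [write_vcf()] using classes 1 and 2 directly).
#' @return A [genotype_matrix()]; the number of skipped multiallelic records
#'   is attached as attribute `n_multiallelic_skipped`.
#' @export
read_vcf <- function(path, mode = c("diploid", "haploid")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(sprintf("VCF file '%s' does not exist.", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("Failed to parse VCF '%s': %s",
                                      path, conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) abort("VCF contains no variant records.")
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi)
  keep <- !multi
  if (!any(keep)) abort("VCF contains no biallelic records.")
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (mode == "diploid") {
    # strip phase, map allele pairs to non-reference allele counts
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    norm <- gsub("|", "/", gt_raw, fixed = TRUE)
    values <- matrix(map[norm], nrow = nrow(norm), ncol = ncol(norm))
    # anything unmapped (".", "./.", half-calls) is missing
  } else {
    values <- suppressWarnings(matrix(as.integer(gt_raw),
                                      nrow = nrow(gt_raw), ncol = ncol(gt_raw)))
    values[!(values %in% c(1L, 2L))] <- NA_integer_
  }
  meta <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT
  )
  out <- genotype_matrix(t(values), sample_ids = colnames(gt_raw),
                         variant_meta = meta, ploidy = mode)
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Write a genotype matrix to VCF 4.2
#'
#' Emits a plain-text VCF with one sample column per sample id. Diploid
#' genotypes are written unphased (`0/0`, `0/1`, `1/1`) and missing entries
#' as `./.`. Haploid panels write the class value itself (`1`, `2`, missing
#' `.`) so that haploid round-trips are exact.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  meta <- variant_meta(matrix)
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(sprintf("Cannot write '%s'.", path)))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dcimpute",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(matrix)), collapse = "\t")
  ), con)
  if (ncol(matrix) == 0L) return(invisible(path))
  v <- unclass(matrix)
  if (gt_ploidy(matrix) == "diploid") {
    codes <- c("0/0", "0/1", "1/1")
    gt <- matrix(ifelse(is.na(v), "./.", codes[v + 1L]),
                 nrow = nrow(v), ncol = ncol(v))
  } else {
    gt <- matrix(ifelse(is.na(v), ".", as.character(v)),
                 nrow = nrow(v), ncol = ncol(v))
  }
  lines <- vapply(seq_len(ncol(v)), function(j) {
    paste(c(meta$chrom[j], meta$pos[j], meta$id[j], meta$ref[j], meta$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
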
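#' Genotype dosage matrices
#'
#' A thin container for per-sample, per-variant effect-allele dosages in
#' \[0, 2\].  Missing dosages are `NA`, never silently zero.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#' @param sample_ids,variant_keys Row and column labels; default to the
#'   matrix dimnames.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            variant_keys = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids) || is.null(variant_keys))
    stop("sample and variant labels are required", call. = FALSE)
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  dimnames(dosage) <- list(sample_ids, variant_keys)
  structure(list(dosage = dosage), class = "genotype_matrix")
}

#' Read a genotype dosage TSV
#'
#' First column is the sample id; remaining columns are one per variant
#' key.  Missing dosages are encoded `NA`.
#'
#' @param path Path to the TSV file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("genotype file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  genotype_matrix(m, sample_ids = as.character(df[[1]]),
                  variant_keys = colnames(m))
}

#' Score a PRS from genotype dosages
#'
#' Computes the raw PRS for each sample as the weighted sum of
#' effect-allele dosages, \eqn{\sum_j w_j d_{ij}}.  Dosage columns are
#' assumed to count the alt allele of the variant key; when a weight's
#' effect allele is the ref allele the dosage is flipped to
#' `2 - dosage` (logged).
#'
#' @param genotypes A [genotype_matrix()].
#' @param weights A [parse_weights()] result.
#' @param missing_policy `"fail"` (default) errors on any missing
#'   variant or dosage; `"mean_impute"` substitutes the per-variant mean
#'   observed dosage.
#' @return Named numeric vector of raw PRS values, one per sample.
#' @export
score_prs <- function(genotypes, weights,
                      missing_policy = c("fail", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(weights, "prs_weights"))
  v <- weights$variants
  have <- v$variant %in% colnames(genotypes$dosage)
  if (any(!have)) {
    if (missing_policy == "fail")
      stop(sprintf("variants missing from genotype matrix: %s",
                   paste(v$variant[!have], collapse = ", ")), call. = FALSE)
    v <- v[have, , drop = FALSE]
  }
  d <- genotypes$dosage[, v$variant, drop = FALSE]
  pk <- parse_variant_key(v$variant)
  flip <- v$effect_allele == toupper(pk$ref)
  if (any(flip)) {
    message(sprintf("flipping dosage (effect allele = ref) for: %s",
                    paste(v$variant[flip], collapse = ", ")))
    d[, flip] <- 2 - d[, flip]
  }
  if (anyNA(d)) {
    if (missing_policy == "fail") {
      bad <- colnames(d)[colSums(is.na(d)) > 0]
      stop(sprintf("missing dosages for: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    for (j in which(colSums(is.na(d)) > 0)) {
      mj <- mean(d[, j], na.rm = TRUE)
      if (is.nan(mj)) mj <- 0
      d[is.na(d[, j]), j] <- mj
    }
  }
  s <- drop(d %*% v$weight)
  names(s) <- rownames(d)
  s
}

#' Standardize raw PRS values against a reference distribution
#'
#' @param raw Numeric vector of raw PRS values.
#' @param ref_mean,ref_sd Reference mean and standard deviation
#'   (conventionally from the control group); `ref_sd` must be positive.
#' @return Z-scores `(raw - ref_mean) / ref_sd`.
#' @export
standardize <- function(raw, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0)
    stop("`ref_sd` must be positive", call. = FALSE)
  (raw - ref_mean) / ref_sd
}
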
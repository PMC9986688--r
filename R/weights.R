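#' Variants tagging CHEK2*1100delC
#'
#' Two chromosome-22 PRS variants are strongly correlated with the
#' protein-truncating variant CHEK2*1100delC.  When a PRS is used
#' alongside gene-panel testing they must be dropped, because the risk
#' model assumes the PRS and major-gene genotypes are independent.
#'
#' @return Character vector of the two variant keys
#'   (`chrom_pos_ref_alt`, GRCh37).
#' @export
chek2_linked_variants <- function() {
  c("22_29203724_C_T", "22_29551872_A_G")
}

parse_variant_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)
  ok <- lengths(parts) == 4L
  list(ok = ok,
       ref = vapply(parts, function(p) if (length(p) == 4L) p[3L] else NA_character_, ""),
       alt = vapply(parts, function(p) if (length(p) == 4L) p[4L] else NA_character_, ""))
}

#' Parse a PRS weight file
#'
#' Weight files are TSV or CSV with a header naming columns `variant`
#' (key `chrom_pos_ref_alt` on GRCh37 coordinates), `effect_allele` and
#' `weight` (per-effect-allele log odds ratio).  Leading lines beginning
#' `#` may carry `name=` and `alpha=` metadata in the CanRisk PRS-file
#' dialect.
#'
#' @param path Path to the weight file.
#' @param name Optional label overriding any `name=` header value.
#' @return An object of class `prs_weights`: a list with elements
#'   `name`, `alpha` (or `NA`) and `variants`, a data frame with columns
#'   `variant`, `effect_allele`, `weight`.
#' @export
parse_weights <- function(path, name = NULL) {
  if (!file.exists(path))
    stop(sprintf("weight file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- regmatches(m, gregexpr("[A-Za-z_]+=[^,\t ]+", m))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[tolower(p[1])]] <- p[2]
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L)
    stop(sprintf("weight file %s has no data rows", path), call. = FALSE)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  names(df) <- tolower(names(df))
  need <- c("variant", "effect_allele", "weight")
  if (!all(need %in% names(df)))
    stop(sprintf("weight file must have columns %s (got: %s)",
                 paste(need, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  df <- df[need]
  df$variant <- as.character(df$variant)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  problems <- character()
  w <- suppressWarnings(as.numeric(df$weight))
  bad_w <- which(!is.finite(w))
  if (length(bad_w))
    problems <- c(problems, sprintf("line %d: unparseable weight '%s'",
                                    bad_w, df$weight[bad_w]))
  df$weight <- w
  dup <- df$variant[duplicated(df$variant)]
  if (length(dup))
    problems <- c(problems, sprintf("duplicated variant key '%s'", unique(dup)))
  pk <- parse_variant_key(df$variant)
  bad_key <- which(!pk$ok)
  if (length(bad_key))
    problems <- c(problems, sprintf("line %d: malformed variant key '%s'",
                                    bad_key, df$variant[bad_key]))
  bad_allele <- which(pk$ok & df$effect_allele != toupper(pk$ref) &
                        df$effect_allele != toupper(pk$alt))
  if (length(bad_allele))
    problems <- c(problems, sprintf(
      "line %d: effect allele '%s' is neither allele of '%s'",
      bad_allele, df$effect_allele[bad_allele], df$variant[bad_allele]))
  if (length(problems))
    stop(sprintf("invalid weight file %s:\n  %s", path,
                 paste(problems, collapse = "\n  ")), call. = FALSE)
  out <- structure(
    list(name = name %||% meta$name %||% basename(path),
         alpha = suppressWarnings(as.numeric(meta$alpha %||% NA)),
         variants = df),
    class = "prs_weights")
  message(sprintf("parsed PRS '%s': %d variants", out$name, nrow(df)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prs_weights <- function(x, ...) {
  cat(sprintf("PRS weight set '%s': %d variants\n", x$name, nrow(x$variants)))
  invisible(x)
}

#' Drop variants from a PRS weight set
#'
#' By default removes the two CHEK2*1100delC-correlated chromosome-22
#' variants (see [chek2_linked_variants()]).  Keys absent from the set
#' are ignored with a notice, so the operation is idempotent.
#'
#' @param weights A [parse_weights()] result.
#' @param exclusion Character vector of variant keys to remove.
#' @return A `prs_weights` object without the excluded variants.
#' @export
exclude_variants <- function(weights, exclusion = chek2_linked_variants()) {
  stopifnot(inherits(weights, "prs_weights"))
  present <- exclusion %in% weights$variants$variant
  if (any(!present) && length(exclusion))
    message(sprintf("exclusion keys not present (ignored): %s",
                    paste(exclusion[!present], collapse = ", ")))
  weights$variants <-
    weights$variants[!(weights$variants$variant %in% exclusion), , drop = FALSE]
  rownames(weights$variants) <- NULL
  weights
}
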
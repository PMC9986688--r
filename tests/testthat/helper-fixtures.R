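# Fixtures are generated in code at test time.

# Synthetic weight file with `n` variants (GRCh37-style keys).  When
# `with_chek2` the two CHEK2*1100delC-linked chromosome-22 keys are
# included among them.
make_weight_file <- function(n = 313, with_chek2 = TRUE, sep = "\t",
                             name = "TESTPRS", seed = 99) {
  set.seed(seed)
  n_random <- n - if (with_chek2) 2L else 0L
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_random, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  keys <- sprintf("%d_%d_%s_%s", sample(1:21, n_random, replace = TRUE),
                  sample(1e6:5e7, n_random), ref, alt)
  keys <- make.unique(keys, sep = "0")   # astronomically unlikely anyway
  df <- data.frame(variant = keys, effect_allele = alt,
                   weight = round(rnorm(n_random, 0, 0.05), 4))
  if (with_chek2) {
    df <- rbind(df, data.frame(
      variant = c("22_29203724_C_T", "22_29551872_A_G"),
      effect_allele = c("T", "G"),
      weight = c(0.05, -0.03)))
  }
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(sprintf("#name=%s", name),
               paste(c("variant", "effect_allele", "weight"), collapse = sep),
               apply(df, 1, paste, collapse = sep)), path)
  list(path = path, variants = df)
}

make_genotype_file <- function(weights_df, n_samples = 4, seed = 7) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_samples * nrow(weights_df), replace = TRUE),
              nrow = n_samples,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              weights_df$variant))
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(data.frame(sample_id = rownames(d), d,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  list(path = path, dosage = d)
}

default_params <- function() variance_params()

default_baseline <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- constrain_baseline(ew_breast_incidence(), variance_params())
    cache
  }
})

# Small simulated cohort under the default study conditions.
make_cohort <- function(n_cases, n_controls, alpha, seed,
                        country_shifts = NULL) {
  simulate_cohort(sim_config(n_cases, n_controls, alpha, seed = seed,
                             country_shifts = country_shifts))
}

# Run the packaged CLI in a subprocess against the installed package.
run_cli <- function(args) {
  script <- system.file("cli", "prscalib.R", package = "prscalib")
  out <- suppressWarnings(system2(
    "Rscript", c(script, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
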
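#' Population incidence tables
#'
#' An incidence table holds age-specific population incidence as a rate
#' per person-year on a contiguous yearly age grid.  Tables supplied in
#' age bands (e.g. 5-year registry bands) are expanded to yearly rates by
#' constant interpolation within each band.
#'
#' @param ages Integer ages, contiguous after sorting.
#' @param rate Incidence per person-year (not per 100,000) at each age;
#'   all values must be non-negative.
#' @return An object of class `incidence_table`: a data frame with
#'   columns `age` and `rate`.
#' @seealso [read_incidence()], [ew_breast_incidence()]
#' @export
incidence_table <- function(ages, rate) {
  ages <- as.integer(ages)
  ord <- order(ages)
  ages <- ages[ord]
  rate <- as.numeric(rate)[ord]
  if (length(ages) == 0L)
    stop("empty incidence table", call. = FALSE)
  if (anyDuplicated(ages))
    stop("duplicated ages in incidence table", call. = FALSE)
  if (!all(diff(ages) == 1L))
    stop("incidence table ages must be contiguous (one row per year)",
         call. = FALSE)
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("incidence rates must be finite and non-negative", call. = FALSE)
  structure(data.frame(age = ages, rate = rate),
            class = c("incidence_table", "data.frame"))
}

#' Read an incidence table from CSV
#'
#' The expected columns are `age_low`, `age_high`, `rate_per_100000`,
#' one row per half-open integer age band `[age_low, age_high)`.
#' Yearly rows (`age_high == age_low + 1`) are allowed.  Rates are
#' converted to per person-year and bands expanded to yearly resolution.
#'
#' @param path Path to the CSV file.
#' @param age_min,age_max Optional clip range; rows are expanded first,
#'   then restricted to `[age_min, age_max]`.
#' @return An [incidence_table()].
#' @export
read_incidence <- function(path, age_min = NULL, age_max = NULL) {
  if (!file.exists(path))
    stop(sprintf("incidence file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("age_low", "age_high", "rate_per_100000")
  if (!all(need %in% names(df)))
    stop(sprintf("incidence CSV must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (any(df$age_high <= df$age_low))
    stop("each band must satisfy age_high > age_low", call. = FALSE)
  ages <- unlist(Map(seq.int, df$age_low, df$age_high - 1L))
  rate <- rep(df$rate_per_100000, df$age_high - df$age_low) / 1e5
  keep <- rep(TRUE, length(ages))
  if (!is.null(age_min)) keep <- keep & ages >= age_min
  if (!is.null(age_max)) keep <- keep & ages <= age_max
  incidence_table(ages[keep], rate[keep])
}

#' Packaged breast-cancer incidence fixture
#'
#' A yearly-resolution female breast-cancer incidence table emulating the
#' magnitude of recent England & Wales registry rates (expanded from
#' 5-year bands).  It is a synthetic fixture for tests and simulations,
#' not the registry table itself.
#'
#' @param age_min,age_max Age range to return (defaults \[20, 79\]).
#' @return An [incidence_table()].
#' @export
ew_breast_incidence <- function(age_min = 20L, age_max = 79L) {
  path <- system.file("extdata", "incidence_ew_breast_synthetic.csv",
                      package = "prscalib", mustWork = TRUE)
  read_incidence(path, age_min = age_min, age_max = age_max)
}

check_incidence_covers <- function(incidence, params) {
  if (!inherits(incidence, "incidence_table"))
    stop("`incidence` must be an incidence_table", call. = FALSE)
  need <- seq.int(params$age_min, params$age_max)
  if (!all(need %in% incidence$age))
    stop(sprintf("incidence table must cover ages [%d, %d]",
                 params$age_min, params$age_max), call. = FALSE)
  incidence[match(need, incidence$age), , drop = FALSE]
}
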
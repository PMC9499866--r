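#' Write / read a cohort as a flat TSV
#'
#' One row per individual; per-disease event ages are disease-indexed
#' columns prefixed `event_`, with absent events written as empty fields.
#' The round trip is lossless up to numeric printing precision (15
#' significant digits).
#'
#' @param cohort A `"cohort"`.
#' @param path Output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  ev <- as.data.frame(cohort$event_age)
  names(ev) <- paste0("event_", colnames(cohort$event_age))
  df <- cbind(cohort$individuals, ev)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @param exposure_ids,covariate_ids Column names identifying exposures
#'   and covariates in the file (defaults: columns not otherwise claimed
#'   are treated as exposures; `cov*` columns as covariates).
#' @return `read_cohort_tsv()` returns a `"cohort"`.
#' @export
read_cohort_tsv <- function(path, exposure_ids = NULL, covariate_ids = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = "")
  ev_cols <- grep("^event_", names(df), value = TRUE)
  base_cols <- c("id", "sex", "entry_age", "exit_age", "death_age")
  if (!all(base_cols %in% names(df)))
    stop("cohort TSV missing columns: ",
         paste(setdiff(base_cols, names(df)), collapse = ", "), call. = FALSE)
  rest <- setdiff(names(df), c(base_cols, ev_cols))
  if (is.null(covariate_ids)) covariate_ids <- grep("^cov", rest, value = TRUE)
  if (is.null(exposure_ids)) exposure_ids <- setdiff(rest, covariate_ids)
  ev <- as.matrix(df[, ev_cols, drop = FALSE])
  colnames(ev) <- sub("^event_", "", ev_cols)
  structure(list(individuals = df[, c(base_cols, covariate_ids, exposure_ids),
                                  drop = FALSE],
                 event_age = ev, exposure_ids = exposure_ids,
                 covariate_ids = covariate_ids),
            class = "cohort")
}

#' Write / read an estimate table as TSV
#'
#' Columns `exposure_id`, `disease_id`, `log_hr`, `se` plus any of
#' `cohort_id`, `sex_stratum`, `n_events`, `status`, `null_prob`,
#' `retained` present.
#'
#' @param estimates Data frame of per-pair estimates.
#' @param path File path.
#' @export
write_estimates_tsv <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_tsv
#' @export
read_estimates_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("exposure_id", "disease_id", "log_hr", "se")
  if (!all(need %in% names(df)))
    stop("estimate TSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df
}

#' Read a DALY rate table in the GBD GHDx CSV dialect
#'
#' Expects at least the columns `cause`, `sex`, `measure`, `val` of a
#' GHDx export (yearly DALYs per 100,000 population); only rows whose
#' `measure` contains "DALYs" are consumed. Cause names are mapped to
#' internal disease ids through a user-supplied mapping (the manual
#' cause-to-endpoint mapping is an explicit input, not inferred);
#' unmapped causes and duplicate (cause, sex) rows are rejected with an
#' explicit listing.
#'
#' @param path CSV path.
#' @param mapping Optional data frame with columns `cause`, `disease_id`;
#'   when `NULL`, cause names are used as disease ids directly.
#' @return Data frame with columns `disease_id`, `sex` (lowercase
#'   male/female/both) and `dalys_per_100k`.
#' @export
read_daly_table <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cause", "sex", "measure", "val")
  if (!all(need %in% names(df)))
    stop("DALY CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df <- df[grepl("DALYs", df$measure), , drop = FALSE]
  if (nrow(df) == 0L) stop("no DALYs rows in file", call. = FALSE)
  df$sex <- tolower(df$sex)
  if (!all(df$sex %in% c("male", "female", "both")))
    stop("unrecognised sex values: ",
         paste(unique(setdiff(df$sex, c("male", "female", "both"))),
               collapse = ", "), call. = FALSE)
  dup <- duplicated(df[, c("cause", "sex")])
  if (any(dup))
    stop("duplicate (cause, sex) rows: ",
         paste(unique(df$cause[dup]), collapse = ", "), call. = FALSE)
  if (!is.null(mapping)) {
    stopifnot(all(c("cause", "disease_id") %in% names(mapping)))
    miss <- setdiff(unique(df$cause), mapping$cause)
    if (length(miss) > 0L)
      stop("unmapped causes: ", paste(miss, collapse = ", "), call. = FALSE)
    df$disease_id <- mapping$disease_id[match(df$cause, mapping$cause)]
  } else {
    df$disease_id <- df$cause
  }
  if (any(df$val < 0)) stop("negative DALY rates", call. = FALSE)
  data.frame(disease_id = df$disease_id, sex = df$sex,
             dalys_per_100k = df$val, stringsAsFactors = FALSE)
}

#' Write a DALY table in the GBD GHDx CSV dialect
#'
#' @param daly_table Data frame with `disease_id`, `sex`,
#'   `dalys_per_100k` (e.g. from [generate_daly_table()]).
#' @param path Output CSV path.
#' @export
write_daly_csv <- function(daly_table, path) {
  stopifnot(all(c("disease_id", "sex", "dalys_per_100k") %in%
                  names(daly_table)))
  sex_out <- paste0(toupper(substring(daly_table$sex, 1, 1)),
                    substring(daly_table$sex, 2))
  out <- data.frame(cause = daly_table$disease_id,
                    sex = sex_out,
                    measure = "DALYs (Disability-Adjusted Life Years)",
                    val = daly_table$dalys_per_100k)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
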
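# Validated CSV dialects shared by the pipeline stages. NA cells are the
# literal token "NA" on write; empty fields are also accepted on read.

#' @keywords internal
read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s file '%s' is missing columns: %s", what, path,
                 paste(miss, collapse = ", ")))
  df
}

#' Read well-level qPCR records
#'
#' Expects columns `sample_id,mir_id,replicate,ct,tm,is_positive_control`;
#' empty fields mean no amplification / no visible melt curve.
#'
#' @param path CSV path.
#' @return Data frame of well records.
#' @export
read_wells <- function(path) {
  df <- read_csv_checked(path, c("sample_id", "mir_id", "replicate", "ct", "tm"),
                         "wells")
  df$ct <- as.numeric(df$ct)
  df$tm <- as.numeric(df$tm)
  ok_ct <- is.na(df$ct) | df$ct > 0
  ok_tm <- is.na(df$tm) | (df$tm > 50 & df$tm < 100)
  if (!all(ok_ct)) stop("wells file has non-positive Ct values")
  if (!all(ok_tm)) stop("wells file has Tm values outside (50, 100) C")
  df
}

#' Read the positive-control reference Tm table
#'
#' @param path CSV with columns `mir_id,reference_tm`.
#' @return Data frame.
#' @export
read_reference_tm <- function(path) {
  df <- read_csv_checked(path, c("mir_id", "reference_tm"), "reference-Tm")
  df$reference_tm <- as.numeric(df$reference_tm)
  df
}

#' Write / read a binary call matrix
#'
#' Samples as rows (first column `sample_id`), panel microRNAs as columns,
#' cells in `{1, 0, NA}`. The write/read pair round-trips bit-identically,
#' including missing cells.
#'
#' @param m calls matrix as from [build_call_matrix()].
#' @param path CSV path.
#' @return `write_call_matrix()` returns `path` invisibly;
#'   `read_call_matrix()` returns the integer matrix.
#' @export
write_call_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_call_matrix
#' @export
read_call_matrix <- function(path) {
  df <- read_csv_checked(path, "sample_id", "call-matrix")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (!all(m %in% c(0L, 1L, NA))) stop("call matrix cells must be 1, 0 or NA")
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  m
}

#' Read / write long-format tissue profiles
#'
#' Columns `individual_id,tissue,mir_id,call` with call in `{1, 0, NA}`.
#'
#' @param path CSV path.
#' @return `read_profiles()` returns a [tissue_profile_set()].
#' @export
read_profiles <- function(path) {
  df <- read_csv_checked(path, c("individual_id", "tissue", "mir_id", "call"),
                         "profiles")
  df$call <- as.integer(df$call)
  tissue_profile_set(df)
}

#' @rdname read_profiles
#' @param set a [tissue_profile_set()].
#' @export
write_profiles <- function(set, path) {
  stopifnot(inherits(set, "tissue_profile_set"))
  grid <- expand.grid(individual_id = set$individuals, tissue = set$tissues,
                      mir_id = set$mirs, stringsAsFactors = FALSE)
  grid$call <- set$profiles[cbind(match(grid$individual_id, set$individuals),
                                  match(grid$tissue, set$tissues),
                                  match(grid$mir_id, set$mirs))]
  utils::write.csv(grid, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a case-control cohort sheet
#'
#' Expects `subject_id,status,age,gender,smoking_status,pack_years,
#' quit_years,uld_group,stage,histology` plus one column per panel microRNA
#' with cells in `{1, 0, NA}`. MicroRNA column headers may use the dot or
#' dash spelling; they are normalised to the canonical dash form.
#'
#' @param path CSV path.
#' @param panel microRNA panel expected in the sheet. Default
#'   [ebc_mir_panel()]; absent panel columns are an error.
#' @return Cohort data frame with validated codings.
#' @export
read_cohort <- function(path, panel = ebc_mir_panel()) {
  df <- read_csv_checked(path, c("subject_id", "status", clinical_covariates()),
                         "cohort")
  nm <- names(df)
  is_mir <- normalize_mir_id(nm) %in% normalize_mir_id(panel)
  names(df)[is_mir] <- normalize_mir_id(nm[is_mir])
  missing_panel <- setdiff(normalize_mir_id(panel), names(df))
  if (length(missing_panel))
    stop("cohort file is missing panel microRNA columns: ",
         paste(missing_panel, collapse = ", "))
  for (m in normalize_mir_id(panel)) {
    v <- df[[m]]
    if (!all(v %in% c(0L, 1L, NA))) stop(sprintf("column '%s' must be 1/0/NA", m))
    df[[m]] <- as.integer(v)
  }
  prepare_cohort(df)  # validates codings
  df
}

#' @rdname read_cohort
#' @param cohort cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}
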
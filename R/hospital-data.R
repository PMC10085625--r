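#' Patient-level hospital compare dataset
#'
#' Bundles the clustered sample (Y_hj, X_hj, T_hj, V_h): one row per patient
#' with a binary outcome, patient covariates X, optional zero-inflation
#' covariates T and a single hospital-level attribute V, constant within
#' hospital.  Hospitals are indexed by first appearance; ids are kept as
#' opaque strings.
#'
#' @param hospital Vector of hospital identifiers, one per patient row.
#' @param y Binary outcome vector (1 = event/death).
#' @param X Patient covariate matrix (no intercept column).
#' @param T_mat Optional zero-inflation covariate matrix; by convention its
#'   first column is a constant 1 (the at-risk model has its own intercept).
#' @param V Hospital attribute: either one value per patient row (constant
#'   within hospital) or one value per hospital in first-appearance order.
#' @return A `hospital_data` object with fields `hospital` (integer index
#'   1..H per row), `hospital_ids`, `y`, `X`, `T_mat`, `V` (length H), `H`,
#'   `n_h`, `N`.
#' @export
hospital_data <- function(hospital, y, X, T_mat = NULL, V) {
  if (anyNA(hospital)) stop("'hospital' must not contain NA")
  ids <- unique(as.character(hospital))
  idx <- match(as.character(hospital), ids)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y) || length(idx) != length(y)) {
    stop("'hospital', 'y' and 'X' must have the same number of rows")
  }
  if (anyNA(X)) stop("'X' must not contain missing values")
  if (!is.null(T_mat)) {
    T_mat <- as.matrix(T_mat)
    storage.mode(T_mat) <- "double"
    if (nrow(T_mat) != length(y)) stop("'T_mat' must match the number of rows")
    if (anyNA(T_mat)) stop("'T_mat' must not contain missing values")
  }
  H <- length(ids)
  n_h <- as.integer(tabulate(idx, nbins = H))
  if (any(n_h < 1L)) stop("every hospital must have at least one patient row")
  V <- as.numeric(V)
  if (length(V) == length(y)) {
    spread <- tapply(V, idx, function(z) diff(range(z)))
    if (any(spread > 0)) {
      stop("'V' must be constant within hospital: ",
           paste(ids[which(spread > 0)], collapse = ", "))
    }
    V <- V[match(seq_len(H), idx)]
  } else if (length(V) != H) {
    stop("'V' must have one value per row or one per hospital")
  }
  if (anyNA(V)) stop("'V' must not contain NA")
  structure(
    list(hospital = idx, hospital_ids = ids, y = y, X = X, T_mat = T_mat,
         V = V, H = H, n_h = n_h, N = length(y)),
    class = "hospital_data"
  )
}

#' @export
print.hospital_data <- function(x, ...) {
  cat(sprintf(
    "Hospital compare dataset: %d patients in %d hospitals (n_h %d-%d)\n",
    x$N, x$H, min(x$n_h), max(x$n_h)))
  cat(sprintf("  outcome rate %.4f; %d patient covariates%s\n",
              mean(x$y), ncol(x$X),
              if (is.null(x$T_mat)) "" else
                sprintf("; %d zero-inflation covariates", ncol(x$T_mat))))
  invisible(x)
}

#' Load a patient CSV into a hospital dataset
#'
#' Reads a comma-separated file (header required, UTF-8, "." decimal) and
#' assembles a [hospital_data()] object from named column roles.  Rows with
#' missing values in any used column can be dropped (as is standard
#' preprocessing for ICU registry extracts), as can hospitals with no
#' observed events, whose observed rate carries no ranking information.
#'
#' @param path CSV file path.
#' @param hospital_col,outcome_col,v_col Single column names.
#' @param x_cols Character vector of patient covariate columns.
#' @param t_cols Optional character vector of zero-inflation covariate
#'   columns (a constant-1 column named `"(Intercept)"` is prepended unless
#'   the first listed column is already constant).
#' @param drop_missing Drop rows with missing values in used columns
#'   (default TRUE).
#' @param drop_no_event_hospitals Drop hospitals whose outcome never equals 1
#'   (default FALSE).
#' @return A `hospital_data` object; attribute `"preprocessing"` is a list
#'   with `rows_dropped_missing` and `hospitals_dropped_no_event`.
#' @export
load_dataset <- function(path, hospital_col, outcome_col, x_cols, v_col,
                         t_cols = NULL, drop_missing = TRUE,
                         drop_no_event_hospitals = FALSE) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  used <- c(hospital_col, outcome_col, x_cols, v_col, t_cols)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) {
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  n0 <- nrow(df)
  rows_dropped <- 0L
  if (drop_missing) {
    keep <- stats::complete.cases(df[used])
    rows_dropped <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  if (!nrow(df)) stop("no complete rows left in ", path)
  if (anyNA(df[used])) stop("missing values present; set drop_missing = TRUE")
  hosp_dropped <- 0L
  if (drop_no_event_hospitals) {
    ev <- tapply(df[[outcome_col]], df[[hospital_col]], function(z) any(z == 1))
    bad <- names(ev)[!ev]
    hosp_dropped <- length(bad)
    df <- df[!(as.character(df[[hospital_col]]) %in% bad), , drop = FALSE]
    if (!nrow(df)) stop("all hospitals dropped: no events anywhere")
  }
  T_mat <- NULL
  if (!is.null(t_cols)) {
    T_mat <- as.matrix(df[t_cols])
    if (stats::var(T_mat[, 1L]) > 0) {
      T_mat <- cbind("(Intercept)" = 1, T_mat)
    }
  }
  out <- hospital_data(df[[hospital_col]], df[[outcome_col]],
                       as.matrix(df[x_cols]), T_mat, df[[v_col]])
  attr(out, "preprocessing") <- list(
    rows_read = n0,
    rows_dropped_missing = rows_dropped,
    hospitals_dropped_no_event = hosp_dropped
  )
  out
}

#' Write a hospital dataset back to CSV
#'
#' Inverse of [load_dataset()] for round-tripping: columns `hospital`, `y`,
#' the X columns, optional T columns (prefixed `t_`) and `v`.
#'
#' @param data A `hospital_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "hospital_data"))
  X <- data$X
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(hospital = data$hospital_ids[data$hospital], y = data$y,
                   X, v = data$V[data$hospital], check.names = FALSE)
  if (!is.null(data$T_mat)) {
    Tm <- data$T_mat
    colnames(Tm) <- paste0("t_", seq_len(ncol(Tm)))
    df <- cbind(df, Tm)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
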
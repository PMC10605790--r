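#' Right-censored survival data container
#'
#' Bundles observed times, event indicators and a numeric covariate matrix
#' into a validated object used by every fitting, updating and evaluation
#' function in the package. Times share one unit (days, months, ...)
#' throughout; an event indicator of 1 means the event was observed, 0 means
#' the subject was right-censored at that time.
#'
#' @param times Numeric vector of strictly positive observation times.
#' @param events Vector of 0/1 (or logical) event indicators, one per subject.
#' @param covariates Numeric matrix or data frame, subjects in rows. May have
#'   zero columns for intercept-only models.
#' @param feature_kinds Character vector tagging each column as
#'   `"continuous"`, `"binary"`, or `"onehot"`. Guessed from the data when
#'   omitted (columns containing only 0/1 are tagged binary).
#'
#' @return An object of class `survival_data` with elements `times`,
#'   `events`, `covariates` (numeric matrix with column names),
#'   `feature_names` and `feature_kinds`.
#' @examples
#' d <- survival_data(times = c(2, 5, 1), events = c(1, 0, 1),
#'                    covariates = cbind(age = c(0.3, -1, 0.7)))
#' d$feature_kinds
#' @export
survival_data <- function(times, events, covariates = NULL,
                          feature_kinds = NULL) {
  times <- as.numeric(times)
  if (is.logical(events)) events <- as.integer(events)
  events <- as.numeric(events)
  n <- length(times)
  if (n == 0L) stop("survival_data needs at least one subject")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, nrow = n)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n || length(events) != n) {
    stop("times, events and covariates must describe the same subjects ",
         "(got ", n, ", ", length(events), ", ", nrow(covariates), " rows)")
  }
  if (anyNA(times) || anyNA(events) || anyNA(covariates)) {
    stop("missing values are not allowed; drop incomplete cases first ",
         "(see load_survival_csv)")
  }
  if (any(times <= 0)) stop("all times must be strictly positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  if (is.null(colnames(covariates)) && ncol(covariates) > 0) {
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }
  if (is.null(feature_kinds)) {
    feature_kinds <- vapply(seq_len(ncol(covariates)), function(j) {
      v <- covariates[, j]
      if (all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  feature_kinds <- as.character(feature_kinds)
  if (length(feature_kinds) != ncol(covariates)) {
    stop("feature_kinds must have one entry per covariate column")
  }
  ok <- feature_kinds %in% c("continuous", "binary", "onehot")
  if (!all(ok)) stop("unknown feature kind: ", feature_kinds[!ok][1])
  structure(list(times = times, events = events, covariates = covariates,
                 feature_names = colnames(covariates),
                 feature_kinds = feature_kinds),
            class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat("<survival_data> ", length(x$times), " subjects, ",
      sum(x$events), " events (",
      round(100 * (1 - mean(x$events)), 1), "% censored), ",
      ncol(x$covariates), " features\n", sep = "")
  invisible(x)
}

#' Number of subjects in a survival_data object
#' @param data A `survival_data` object.
#' @return Integer subject count.
#' @export
n_subjects <- function(data) length(data$times)

# Row subset preserving metadata; internal but used across modules.
subset_survival_data <- function(data, idx) {
  survival_data(data$times[idx], data$events[idx],
                data$covariates[idx, , drop = FALSE],
                feature_kinds = data$feature_kinds)
}

# Row-bind two survival_data objects with identical features.
bind_survival_data <- function(a, b) {
  stopifnot(identical(a$feature_names, b$feature_names))
  survival_data(c(a$times, b$times), c(a$events, b$events),
                rbind(a$covariates, b$covariates),
                feature_kinds = a$feature_kinds)
}

#' Load right-censored survival data from CSV
#'
#' Reads one row per subject, drops incomplete cases (no imputation),
#' coerces binary columns to 0/1, one-hot encodes categorical columns
#' (all levels kept), and rejects rows with non-positive times.
#'
#' @param path CSV file path.
#' @param time_col,event_col Column names holding time and 0/1 event status.
#' @param schema Optional list describing covariate columns by kind:
#'   `list(continuous = c(...), binary = c(...), categorical = c(...))`.
#'   When omitted, every non-time, non-event column is used and kinds are
#'   guessed: character/factor or few-valued integer columns become
#'   categorical, 0/1 columns binary, the rest continuous.
#' @param quiet Suppress the dropped-row log messages.
#'
#' @return A [survival_data] object. Attributes `n_dropped_incomplete` and
#'   `n_dropped_nonpositive` record how many rows were removed.
#' @export
load_survival_csv <- function(path, time_col = "time", event_col = "event",
                              schema = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(df)) stop("required column missing: ", col)
  }
  n0 <- nrow(df)
  keep_cols <- setdiff(names(df), c(time_col, event_col))
  if (!is.null(schema)) {
    keep_cols <- c(schema$continuous, schema$binary, schema$categorical)
    missing <- setdiff(keep_cols, names(df))
    if (length(missing)) stop("schema columns missing: ",
                              paste(missing, collapse = ", "))
  }
  df <- df[, c(time_col, event_col, keep_cols), drop = FALSE]
  complete <- stats::complete.cases(df)
  n_incomplete <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  pos <- df[[time_col]] > 0
  n_nonpos <- sum(!pos)
  df <- df[pos, , drop = FALSE]
  if (!quiet && n_incomplete > 0) {
    message("dropped ", n_incomplete, " incomplete row(s) of ", n0)
  }
  if (!quiet && n_nonpos > 0) {
    message("dropped ", n_nonpos, " row(s) with non-positive time")
  }
  if (nrow(df) == 0L) stop("no usable rows in ", path)

  kind_of <- function(col) {
    if (!is.null(schema)) {
      if (col %in% schema$continuous) return("continuous")
      if (col %in% schema$binary) return("binary")
      if (col %in% schema$categorical) return("categorical")
    }
    v <- df[[col]]
    if (is.character(v) || is.factor(v)) return("categorical")
    u <- unique(v)
    if (all(u %in% c(0, 1))) return("binary")
    if (is.numeric(v) && length(u) <= 5 && all(u == round(u))) {
      return("categorical")
    }
    "continuous"
  }

  mats <- list(); kinds <- character(0)
  for (col in keep_cols) {
    k <- kind_of(col)
    v <- df[[col]]
    if (k == "categorical") {
      lev <- sort(unique(as.character(v)))
      m <- sapply(lev, function(l) as.numeric(as.character(v) == l))
      m <- matrix(m, nrow = nrow(df),
                  dimnames = list(NULL, paste0(col, "_", lev)))
      mats[[col]] <- m
      kinds <- c(kinds, rep("onehot", length(lev)))
    } else if (k == "binary") {
      u <- sort(unique(v))
      if (!all(u %in% c(0, 1))) v <- as.numeric(v == max(u))
      mats[[col]] <- matrix(as.numeric(v), ncol = 1,
                            dimnames = list(NULL, col))
      kinds <- c(kinds, "binary")
    } else {
      mats[[col]] <- matrix(as.numeric(v), ncol = 1,
                            dimnames = list(NULL, col))
      kinds <- c(kinds, "continuous")
    }
  }
  X <- if (length(mats)) do.call(cbind, mats) else
    matrix(numeric(0), nrow = nrow(df), ncol = 0)
  out <- survival_data(df[[time_col]], as.numeric(df[[event_col]]), X,
                       feature_kinds = kinds)
  attr(out, "n_dropped_incomplete") <- n_incomplete
  attr(out, "n_dropped_nonpositive") <- n_nonpos
  attr(out, "source_columns") <- keep_cols
  out
}

#' Read a dataset schema file
#'
#' A schema is a small JSON document naming the time and event columns and
#' listing covariate columns by kind (`binary`, `categorical`,
#' `continuous`). Schemas for five classic public survival datasets ship
#' under `system.file("extdata", "schemas", package = "bpsurv")`; pass the
#' result to [load_survival_csv()].
#'
#' @param path Path to the schema JSON file.
#' @return A list with `time_col`, `event_col` and the three kind vectors.
#' @examples
#' sch <- read_dataset_schema(system.file("extdata", "schemas",
#'                                        "veteran.json",
#'                                        package = "bpsurv"))
#' sch$categorical
#' @export
read_dataset_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("time_col", "event_col")) {
    if (is.null(doc[[k]])) stop("schema lacks field: ", k)
  }
  doc$binary <- as.character(doc$binary %||% character(0))
  doc$categorical <- as.character(doc$categorical %||% character(0))
  doc$continuous <- as.character(doc$continuous %||% character(0))
  doc
}
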
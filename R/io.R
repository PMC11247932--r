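#' Column schema for a categorical table
#'
#' Declares, per column, its role and measurement type. The type decides the
#' IRT family (`binary` -> 2-PL, `ordinal` -> GRM, `nominal` -> NRM,
#' `continuous` -> quantile-discretized then GRM), so it is always explicit:
#' silent type inference would silently change the model.
#'
#' @param name Column name as it appears in the CSV header.
#' @param type `"binary"`, `"ordinal"`, `"nominal"`, or `"continuous"`.
#' @param role `"feature"` (default), `"target"`, `"outcome"`,
#'   `"conditional"`, or `"ignore"`. Outcome columns are excluded from
#'   fitting; at most one target column per impute run.
#' @param levels For categorical types, the category labels in code order
#'   (first label becomes code 0). If omitted, the sorted unique observed
#'   values are used.
#' @return An object of class `irtci_column`.
#' @export
schema_column <- function(name, type, role = "feature", levels = NULL) {
  type <- match.arg(type, c("binary", "ordinal", "nominal", "continuous"))
  role <- match.arg(role, c("feature", "target", "outcome", "conditional",
                            "ignore"))
  if (type == "binary" && !is.null(levels) && length(levels) != 2L)
    stop("a binary column must have exactly 2 levels", call. = FALSE)
  structure(list(name = as.character(name), type = type, role = role,
                 levels = if (is.null(levels)) NULL else as.character(levels)),
            class = "irtci_column")
}

#' Read a table schema from JSON
#'
#' The JSON is an array of objects with fields `name`, `type`, and optionally
#' `role` and `levels`.
#'
#' @param path Path to the JSON file.
#' @return List of [schema_column()] objects.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(col) {
    schema_column(name = col$name, type = col$type,
                  role = if (is.null(col$role)) "feature" else col$role,
                  levels = if (is.null(col$levels)) NULL
                           else unlist(col$levels))
  })
}

.family_for_type <- function(type) {
  switch(type, binary = "binary_2pl", ordinal = "ordinal_grm",
         nominal = "nominal_nrm", continuous = "ordinal_grm")
}

#' Read a CSV table into a response matrix
#'
#' Categorical columns are integer-coded in schema label order (the label/code
#' map is retained for decoding); continuous columns are quantile-discretized
#' into `n_bins` ordinal levels for fitting, with the raw values kept in a
#' side table. Cells equal to the missing sentinel (default `"-1"`) or empty
#' become missing. Columns with role `"ignore"` are dropped; role
#' `"outcome"` columns are coded but flagged for exclusion from fitting.
#'
#' @param path CSV file with a header row.
#' @param schema List of [schema_column()] objects covering the columns to
#'   use (see [read_schema()]).
#' @param sentinel Character string marking missing cells. Default `"-1"`.
#' @param n_bins Bins for continuous columns. Default 4 (quartiles).
#' @return An object of class `irtci_table`: `responses` (an
#'   [response_matrix()] over the modelled columns), `label_maps`,
#'   `disc_maps`, `continuous` (raw values of continuous columns),
#'   `outcome_cols`, `target_col`, `conditional_cols`, `schema`.
#' @export
read_table <- function(path, schema, sentinel = "-1", n_bins = 4L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate column names in input", call. = FALSE)
  used <- Filter(function(col) col$role != "ignore", schema)
  missing_cols <- setdiff(vapply(used, `[[`, "", "name"), names(df))
  if (length(missing_cols))
    stop(sprintf("schema columns absent from file: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  targets <- Filter(function(col) col$role == "target", used)
  if (length(targets) > 1L)
    stop("at most one target column per run", call. = FALSE)

  n <- nrow(df)
  values <- matrix(NA_integer_, n, length(used))
  specs <- vector("list", length(used))
  label_maps <- disc_maps <- vector("list", length(used))
  continuous <- list()
  for (j in seq_along(used)) {
    col <- used[[j]]
    x <- df[[col$name]]
    x[trimws(x) == "" | trimws(x) == sentinel | is.na(x)] <- NA
    if (col$type == "continuous") {
      xv <- suppressWarnings(as.numeric(x))
      if (any(is.na(xv) & !is.na(x)))
        stop(sprintf("column '%s': non-numeric values in a continuous column",
                     col$name), call. = FALSE)
      d <- discretize_continuous(xv, n_bins = n_bins)
      values[, j] <- d$codes
      disc_maps[[j]] <- d$map
      continuous[[col$name]] <- xv
      m <- d$map$n_bins
    } else {
      lv <- if (is.null(col$levels)) sort(unique(x[!is.na(x)])) else col$levels
      codes <- match(x, lv) - 1L
      bad <- which(!is.na(x) & is.na(codes))
      if (length(bad))
        stop(sprintf("column '%s': unknown labels at rows %s",
                     col$name, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
      values[, j] <- as.integer(codes)
      label_maps[[j]] <- lv
      m <- length(lv)
    }
    specs[[j]] <- item_spec(col$name, .family_for_type(col$type), m, j - 1L)
  }
  names(label_maps) <- names(disc_maps) <- vapply(used, `[[`, "", "name")

  structure(list(
    responses = response_matrix(values, specs, validate = FALSE),
    label_maps = label_maps, disc_maps = disc_maps,
    continuous = continuous,
    outcome_cols = which(vapply(used, `[[`, "", "role") == "outcome"),
    target_col = if (length(targets)) match(targets[[1L]]$name,
                                            vapply(used, `[[`, "", "name"))
                 else NULL,
    conditional_cols = which(vapply(used, `[[`, "", "role") == "conditional"),
    schema = used), class = "irtci_table")
}

#' Decode a completed code matrix back to labels
#'
#' Inverts the integer coding of [read_table()]: categorical codes become
#' their original labels (no invented labels), and continuous columns get
#' their raw values back where they were observed. Imputed cells of a
#' continuous column stay as bin codes: back-mapping bins to values is out of
#' scope.
#'
#' @param completed Integer matrix (e.g. `irtci_impute(...)$completed`).
#' @param table An `irtci_table` from [read_table()].
#' @return A data.frame of character/numeric columns in schema order.
#' @export
decode_table <- function(completed, table) {
  stopifnot(inherits(table, "irtci_table"))
  out <- vector("list", length(table$schema))
  for (j in seq_along(table$schema)) {
    col <- table$schema[[j]]
    codes <- completed[, j]
    if (col$type == "continuous") {
      raw <- table$continuous[[col$name]]
      filled <- ifelse(is.na(raw), as.numeric(codes), raw)
      out[[j]] <- filled
    } else {
      out[[j]] <- table$label_maps[[col$name]][codes + 1L]
    }
  }
  names(out) <- vapply(table$schema, `[[`, "", "name")
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a decoded table to CSV
#'
#' @param df Data.frame (e.g. from [decode_table()]).
#' @param path Output CSV path.
#' @param sentinel Value written for any remaining missing cell. Default
#'   `"-1"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, sentinel = "-1") {
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- sentinel
    x
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
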
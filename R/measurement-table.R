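#' Measurement table: long-format paired soil/leaf records
#'
#' The pipeline's universal input: one row per (site, tree, compartment,
#' analyte) with a non-negative value and its units. Missing values are
#' explicit `NA`s, never sentinel numbers.
#'
#' @param records data.frame with columns `site_id`, `tree_id`,
#'   `compartment` (`"leaf"` or `"soil"`), `analyte`, `value`, `units`.
#' @return a validated `measurement_table` (a data.frame subclass).
#' @export
measurement_table <- function(records) {
  req <- c("site_id", "tree_id", "compartment", "analyte", "value", "units")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[req]
  records$site_id <- as.character(records$site_id)
  records$tree_id <- as.character(records$tree_id)
  records$compartment <- as.character(records$compartment)
  records$analyte <- as.character(records$analyte)
  records$units <- as.character(records$units)
  bad_comp <- setdiff(unique(records$compartment), c("leaf", "soil"))
  if (length(bad_comp))
    stop("compartment must be 'leaf' or 'soil'; found: ",
         paste(bad_comp, collapse = ", "))
  if (!is.numeric(records$value))
    stop("value column must be numeric")
  if (any(is.infinite(records$value)))
    stop("non-finite values present; use NA for missing")
  if (any(records$value < 0, na.rm = TRUE))
    stop("negative values present in rows: ",
         paste(which(records$value < 0), collapse = ", "))
  key <- paste(records$site_id, records$tree_id, records$compartment,
               records$analyte, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (site, tree, compartment, analyte) keys: ",
         paste(unique(gsub("\r", "/", key[dup])), collapse = "; "))
  # units must be consistent within analyte x compartment
  uk <- paste(records$analyte, records$compartment, sep = "\r")
  n_units <- tapply(records$units, uk, function(u) length(unique(u)))
  if (any(n_units > 1))
    stop("inconsistent units for: ",
         paste(gsub("\r", "/", names(n_units)[n_units > 1]), collapse = ", "))
  rownames(records) <- NULL
  class(records) <- c("measurement_table", "data.frame")
  records
}

#' Read measurements from CSV
#'
#' Long layout has columns `site_id,tree_id,compartment,analyte,value,units`.
#' Wide layout has `site_id,tree_id` followed by one column per analyte and is
#' melted to long form; `compartment` and `units` are then supplied via
#' arguments (`units` may be a single string or a named map analyte->units).
#'
#' @param path CSV file path (UTF-8, comma separator, dot decimal).
#' @param layout `"long"` or `"wide"`.
#' @param compartment compartment for wide input (default `"leaf"`).
#' @param units units for wide input; single string or named character vector.
#' @return a [measurement_table()].
#' @export
load_measurements <- function(path, layout = c("long", "wide"),
                              compartment = "leaf", units = "mg/kg") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  if (layout == "long") {
    if (!is.numeric(df$value)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$value))) &
                     !is.na(df$value) & df$value != "")
      if (length(bad))
        stop("non-numeric value cells at rows ", paste(bad, collapse = ", "))
      df$value <- as.numeric(df$value)
    }
    return(measurement_table(df))
  }
  id <- c("site_id", "tree_id")
  if (!all(id %in% names(df)))
    stop("wide layout requires site_id and tree_id columns")
  analytes <- setdiff(names(df), id)
  if (!length(analytes)) stop("wide layout has no analyte columns")
  for (a in analytes) {
    v <- suppressWarnings(as.numeric(df[[a]]))
    bad <- which(is.na(v) & !is.na(df[[a]]) & df[[a]] != "")
    if (length(bad))
      stop("non-numeric cell(s) in column '", a, "' at rows ",
           paste(bad, collapse = ", "))
    df[[a]] <- v
  }
  long <- do.call(rbind, lapply(analytes, function(a) {
    data.frame(site_id = df$site_id, tree_id = df$tree_id,
               compartment = compartment, analyte = a, value = df[[a]],
               units = if (length(units) == 1 && is.null(names(units)))
                 units else unname(units[a]),
               stringsAsFactors = FALSE)
  }))
  measurement_table(long)
}

#' Write a measurement table to CSV
#'
#' Values are written with 17 significant digits so a write/read round-trip
#' reproduces the table bit-exactly.
#'
#' @param table a [measurement_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  out <- as.data.frame(table)
  out$value <- vapply(out$value, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d records | %d sites | analytes: %s\n",
              nrow(x), length(unique(x$site_id)),
              paste(unique(x$analyte), collapse = ", ")))
  NextMethod()
}
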
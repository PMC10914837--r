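## Sample tables -------------------------------------------------------------

#' Construct a validated water-sample table
#'
#' A `water_samples` object is a plain data frame with one row per sampling
#' event: `sample_id`, optional `village`, optional planar coordinates
#' `x`/`y`, and one numeric column per measured parameter (mg/L; pH
#' unitless). An optional `HCO3` column (mg/L) is honoured by the
#' milliequivalent conversion; otherwise bicarbonate is derived from total
#' alkalinity.
#'
#' @param df Data frame with at least a `sample_id` column.
#' @param provenance Free-text provenance tag (e.g. `"measured"` or
#'   `"synthetic seed=1"`).
#' @return `df` with class `water_samples` and a `provenance` attribute.
#' @export
water_samples <- function(df, provenance = "measured") {
  if (!is.data.frame(df)) stop("df must be a data frame", call. = FALSE)
  if (is.null(df$sample_id)) stop("sample_id column is required", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("sample_id values must be unique", call. = FALSE)
  conc <- intersect(setdiff(.wqi_parameters, "pH"), names(df))
  for (p in c(conc, intersect("HCO3", names(df)))) {
    v <- df[[p]]
    if (!is.numeric(v))
      stop("column ", p, " is not numeric", call. = FALSE)
    if (any(is.finite(v) & v < 0))
      stop("negative concentration in column ", p, call. = FALSE)
  }
  if (!is.null(df$pH)) {
    if (!is.numeric(df$pH)) stop("column pH is not numeric", call. = FALSE)
    if (any(df$pH <= 0 | df$pH >= 14))
      stop("pH must lie strictly between 0 and 14", call. = FALSE)
  }
  structure(df, provenance = provenance,
            class = c("water_samples", "data.frame"))
}

#' Read a per-sample major-ion table from CSV
#'
#' Reads a CSV with one row per sample and validates it for the requested
#' analysis stages. Column names can be remapped through `schema`, so files
#' with headers like `"TDS (mg/L)"` need no editing.
#'
#' @param path CSV file path.
#' @param schema Optional named character vector mapping canonical names to
#'   file column names, e.g. `c(TDS = "TDS (mg/L)")`.
#' @param require Character vector of parameters that must be present
#'   (default: all 12 index parameters). Use `character(0)` to accept any
#'   subset.
#' @return A [water_samples] object; row order of the file is preserved.
#' @export
read_sample_table <- function(path, schema = NULL,
                              require = .wqi_parameters) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        stop("schema maps ", canon, " to missing column '", src, "'",
             call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (is.null(raw$sample_id))
    stop("required column missing: sample_id", call. = FALSE)
  miss <- setdiff(require, names(raw))
  if (length(miss))
    stop("required column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num_cols <- intersect(c(.wqi_parameters, "HCO3", "x", "y"), names(raw))
  for (p in num_cols) {
    v <- raw[[p]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value in column ", p, " at row ", bad[1],
             call. = FALSE)
      raw[[p]] <- vn
    }
  }
  water_samples(raw, provenance = paste("file:", path))
}

#' @export
print.water_samples <- function(x, ...) {
  cat("water_samples: ", nrow(x), " samples",
      if (!is.null(x$village)) paste0(", ", length(unique(x$village)),
                                      " villages"),
      " (", attr(x, "provenance"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE, ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Summary statistics of a sample set
#'
#' Per-parameter minimum, maximum, mean and standard deviation — the
#' standard descriptive table for a hydrochemical survey.
#'
#' @param object A [water_samples] object.
#' @param ... Unused.
#' @return Data frame with columns `parameter`, `min`, `max`, `mean`, `sd`.
#' @export
summary.water_samples <- function(object, ...) {
  pars <- intersect(.wqi_parameters, names(object))
  out <- do.call(rbind, lapply(pars, function(p) {
    v <- object[[p]]
    data.frame(parameter = p, min = min(v), max = max(v),
               mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
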
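#' @keywords internal
"_PACKAGE"

## Parameter catalog ---------------------------------------------------------
##
## The assessment works on 12 physicochemical parameters: nine major ions
## (plus bicarbonate, derived from total alkalinity when not measured
## directly), two aggregate measures carried as CaCO3-equivalents (TA, TH),
## TDS, and unitless pH.

# canonical order of the 12 index parameters
.wqi_parameters <- c("F", "TA", "TDS", "Cl", "Na", "K",
                     "SO4", "NO3", "Mg", "Ca", "TH", "pH")

# equivalent weights (g/eq = formula weight / |charge|); ionic species only
.eq_weights <- c(Ca = 20.04, Mg = 12.15, Na = 22.99, K = 39.10,
                 Cl = 35.45, SO4 = 48.03, HCO3 = 61.02, NO3 = 62.00,
                 F = 19.00)

.ion_charge <- c(Ca = 2L, Mg = 2L, Na = 1L, K = 1L,
                 Cl = -1L, SO4 = -2L, HCO3 = -1L, NO3 = -1L, F = -1L)

# fixed catalog order used to break ties in dominance sequences
.cation_order <- c("Ca", "Mg", "Na", "K")
.anion_order  <- c("HCO3", "Cl", "SO4", "NO3", "F")

# mg/L of HCO3- per mg/L of total alkalinity expressed as CaCO3
# (equivalent weight of HCO3 over equivalent weight of CaCO3)
.hco3_per_ta <- 61.02 / 50.04

#' Equivalent weight of a major ion
#'
#' Returns the equivalent weight (formula weight divided by absolute ionic
#' charge, in g/eq) used to convert mg/L concentrations to meq/L. Only ionic
#' parameters have an equivalent weight; aggregate parameters (`TDS`, `TH`,
#' `TA`) and `pH` never enter milliequivalent arithmetic.
#'
#' @param parameter Character vector of ion names; one or more of
#'   `"Ca"`, `"Mg"`, `"Na"`, `"K"`, `"Cl"`, `"SO4"`, `"HCO3"`, `"NO3"`, `"F"`.
#' @return Named numeric vector of equivalent weights in g/eq.
#' @examples
#' equivalent_weight("Na")          # 22.99
#' equivalent_weight(c("Ca", "SO4"))
#' @export
equivalent_weight <- function(parameter) {
  bad <- setdiff(parameter, names(.eq_weights))
  if (length(bad))
    stop("not an ionic parameter (no equivalent weight): ",
         paste(bad, collapse = ", "), call. = FALSE)
  .eq_weights[parameter]
}

#' Built-in drinking-water guideline standards
#'
#' Standards tables for the weighted-arithmetic water quality index: the
#' permissible value `Xs` and ideal value `Xi` of each of the 12 parameters.
#' `"WHO"` holds the WHO permissible limits; `"BIS-upper"` resolves each BIS
#' (IS 10500) range to its upper bound. BIS publishes no limit for Na and K,
#' so `"BIS-upper"` falls back to the WHO value for those two parameters and
#' flags them in the `fallback` column rather than merging silently.
#'
#' `Xi` is 0 for every parameter except pH, whose ideal (neutral) value is 7.
#'
#' @param guideline `"WHO"` or `"BIS-upper"`.
#' @return A `standards_table`: data frame with columns `parameter`, `Xs`,
#'   `Xi`, `unit`, `fallback`, and a `guideline` attribute.
#' @examples
#' builtin_standards("WHO")
#' @export
builtin_standards <- function(guideline = c("WHO", "BIS-upper")) {
  guideline <- tryCatch(match.arg(guideline), error = function(e)
    stop("unknown guideline name: ", paste(guideline, collapse = ", "),
         call. = FALSE))
  who <- c(F = 1.5, TA = 500, TDS = 1000, Cl = 250, Na = 200, K = 12,
           SO4 = 250, NO3 = 50, Mg = 50, Ca = 200, TH = 500, pH = 8.5)
  bis_upper <- c(F = 1.5, TA = 600, TDS = 2000, Cl = 1000, Na = NA, K = NA,
                 SO4 = 400, NO3 = 45, Mg = 100, Ca = 200, TH = 600, pH = 8.5)
  xs <- who[.wqi_parameters]
  fallback <- rep(FALSE, length(xs))
  if (guideline == "BIS-upper") {
    xs <- bis_upper[.wqi_parameters]
    fallback <- is.na(xs)
    xs[fallback] <- who[.wqi_parameters][fallback]
  }
  xi <- ifelse(.wqi_parameters == "pH", 7, 0)
  out <- data.frame(parameter = .wqi_parameters,
                    Xs = unname(xs),
                    Xi = xi,
                    unit = ifelse(.wqi_parameters == "pH", "unitless", "mg/L"),
                    fallback = fallback,
                    stringsAsFactors = FALSE)
  structure(out, guideline = guideline,
            class = c("standards_table", "data.frame"))
}

#' Read a standards table from CSV or YAML
#'
#' Lets users supply their own guideline without code changes. A CSV needs
#' columns `parameter`, `Xs`, `Xi` (optionally `unit`); a YAML file needs a
#' top-level mapping with the same fields per parameter, or `parameter:`/
#' `Xs:`/`Xi:` sequences.
#'
#' @param path Path to a `.csv`, `.yml` or `.yaml` file.
#' @param guideline Label recorded on the returned table.
#' @return A `standards_table` (see [builtin_standards()]).
#' @export
read_standards <- function(path, guideline = basename(path)) {
  if (!file.exists(path)) stop("standards file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    df <- if (!is.null(y$parameter)) {
      data.frame(parameter = as.character(y$parameter),
                 Xs = as.numeric(y$Xs), Xi = as.numeric(y$Xi),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(parameter = names(y),
                 Xs = vapply(y, function(p) as.numeric(p$Xs), numeric(1)),
                 Xi = vapply(y, function(p) as.numeric(p$Xi), numeric(1)),
                 stringsAsFactors = FALSE)
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("parameter", "Xs", "Xi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("standards file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$unit))
    df$unit <- ifelse(df$parameter == "pH", "unitless", "mg/L")
  df$fallback <- FALSE
  validate_standards(structure(df[c("parameter", "Xs", "Xi", "unit", "fallback")],
                               guideline = guideline,
                               class = c("standards_table", "data.frame")))
}

#' @keywords internal
validate_standards <- function(standards) {
  if (any(!is.finite(standards$Xs)) || any(standards$Xs <= 0))
    stop("every permissible value Xs must be finite and > 0", call. = FALSE)
  if (any(standards$Xi >= standards$Xs))
    stop("ideal value Xi must be below permissible value Xs for every parameter",
         call. = FALSE)
  if (anyDuplicated(standards$parameter))
    stop("duplicated parameter in standards table", call. = FALSE)
  standards
}

#' @export
print.standards_table <- function(x, ...) {
  cat("Drinking-water guideline standards (", attr(x, "guideline"), ")\n",
      sep = "")
  df <- as.data.frame(x)
  df$fallback <- ifelse(df$fallback, "WHO fallback", "")
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
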
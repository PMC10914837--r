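## Milliequivalent conversion and charge-balance QC --------------------------

#' Convert a sample table to ionic profiles in meq/L
#'
#' Re-expresses each sample's ionic concentrations in milliequivalents per
#' litre (mg/L divided by equivalent weight) and computes the cation sum
#' (Ca + Mg + Na + K), anion sum (HCO3 + Cl + SO4 + NO3 + F) and the signed
#' charge-balance error
#' \deqn{CBE = 100 (\Sigma cat - \Sigma an) / (\Sigma cat + \Sigma an).}
#'
#' Bicarbonate comes from an explicit `HCO3` column when present; otherwise
#' it is derived from total alkalinity as `TA * 61.02/50.04` (CaCO3 to HCO3
#' equivalent conversion). pH and the aggregate parameters never enter meq
#' arithmetic.
#'
#' @param samples A [water_samples] object containing `Ca`, `Mg`, `Na`, `K`,
#'   `Cl`, `SO4`, `NO3`, `F` and either `HCO3` or `TA`.
#' @return An `ionic_profiles` data frame: `sample_id`, one meq/L column per
#'   ion, `cation_sum`, `anion_sum`, `cbe_percent`; attribute `hco3_source`
#'   records whether bicarbonate was measured or alkalinity-derived.
#' @examples
#' s <- water_samples(data.frame(sample_id = "a", Na = 22.99, Ca = 40.08,
#'   Mg = 0, K = 0, Cl = 35.45, SO4 = 0, NO3 = 0, F = 0, TA = 0, pH = 7))
#' to_meq(s)
#' @export
to_meq <- function(samples) {
  ions_needed <- c("Ca", "Mg", "Na", "K", "Cl", "SO4", "NO3", "F")
  miss <- setdiff(ions_needed, names(samples))
  if (length(miss))
    stop("missing ionic column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(samples$HCO3)) {
    hco3_mg <- samples$HCO3
    hco3_source <- "measured HCO3"
  } else if (!is.null(samples$TA)) {
    hco3_mg <- samples$TA * .hco3_per_ta
    hco3_source <- "derived from TA (x 61.02/50.04)"
  } else {
    stop("missing ionic column(s): HCO3 (or TA to derive it)", call. = FALSE)
  }
  meq <- data.frame(sample_id = samples$sample_id, stringsAsFactors = FALSE)
  for (ion in c(.cation_order, .anion_order)) {
    mg <- if (ion == "HCO3") hco3_mg else samples[[ion]]
    meq[[ion]] <- mg / .eq_weights[[ion]]
  }
  meq$cation_sum <- rowSums(meq[.cation_order])
  meq$anion_sum <- rowSums(meq[.anion_order])
  tot <- meq$cation_sum + meq$anion_sum
  meq$cbe_percent <- ifelse(tot > 0,
                            100 * (meq$cation_sum - meq$anion_sum) / tot,
                            NA_real_)
  structure(meq, hco3_source = hco3_source,
            class = c("ionic_profiles", "data.frame"))
}

#' Cation-anion charge-balance quality gate
#'
#' Laboratory QC: an analysis is acceptable when the absolute charge-balance
#' error is within the tolerance (conventionally +-5%). Samples failing the
#' gate are flagged, not dropped.
#'
#' @param profiles An `ionic_profiles` object from [to_meq()].
#' @param tolerance Acceptable absolute CBE in percent (default 5).
#' @return Data frame `sample_id`, `cation_sum`, `anion_sum`, `cbe_percent`,
#'   `pass`.
#' @export
charge_balance <- function(profiles, tolerance = 5) {
  stopifnot(inherits(profiles, "ionic_profiles"), tolerance > 0)
  if (any(profiles$cation_sum + profiles$anion_sum <= 0))
    stop("undefined charge balance: all-zero ion vector for sample(s) ",
         paste(profiles$sample_id[profiles$cation_sum + profiles$anion_sum <= 0],
               collapse = ", "), call. = FALSE)
  out <- profiles[c("sample_id", "cation_sum", "anion_sum", "cbe_percent")]
  out <- as.data.frame(out)
  out$pass <- abs(out$cbe_percent) <= tolerance
  out
}

#' Ion dominance sequences
#'
#' Orders cations and anions of each sample by descending meq/L, the usual
#' way a survey reports e.g. Na > Ca > Mg > K. Exact ties are broken by the
#' fixed catalog order (Ca, Mg, Na, K; HCO3, Cl, SO4, NO3, F) and flagged.
#'
#' @param profiles An `ionic_profiles` object.
#' @return A list, one element per sample, each with `cations`, `anions`
#'   (ordered character vectors), and logical `cation_tie`, `anion_tie`.
#' @export
dominance_sequence <- function(profiles) {
  stopifnot(inherits(profiles, "ionic_profiles"))
  order_ions <- function(vals, catalog) {
    v <- unlist(vals[catalog])
    # stable sort: catalog order wins on exact ties
    idx <- order(-v)
    list(ions = catalog[idx], tie = anyDuplicated(v) > 0)
  }
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    cat_o <- order_ions(profiles[i, ], .cation_order)
    an_o <- order_ions(profiles[i, ], .anion_order)
    list(cations = cat_o$ions, anions = an_o$ions,
         cation_tie = cat_o$tie, anion_tie = an_o$tie)
  })
  names(out) <- profiles$sample_id
  out
}

#' @export
print.ionic_profiles <- function(x, ...) {
  cat("ionic_profiles: ", nrow(x), " samples; HCO3 ",
      attr(x, "hco3_source"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE,
                   digits = 4, ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}
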
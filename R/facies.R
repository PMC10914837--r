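## Piper trilinear coordinates, facies, Schoeller profiles -------------------

#' Piper trilinear and diamond coordinates
#'
#' Expresses each sample as percentages of the classical Piper ion groups:
#' the cation triangle over Ca, Mg and Na+K, the anion triangle over
#' HCO3+CO3, SO4 and Cl, and the central diamond with
#' `d1 = %(Na+K)` of the cation triangle and `d2 = %(SO4+Cl)` of the anion
#' triangle (the standard upward projection).
#'
#' The Piper sums deliberately use only the major ions — NO3 and F are
#' excluded here although they do count in the charge-balance QC. CO3 is
#' folded into the bicarbonate apex and defaults to 0 (alkaline waters
#' around pH 8-9 hold little free carbonate, and many surveys do not titrate
#' it separately).
#'
#' @param profiles An `ionic_profiles` object from [to_meq()].
#' @param co3 Optional carbonate vector in meq/L (recycled; default 0).
#' @return A `piper_coordinates` data frame: `sample_id`, `Ca`, `Mg`, `NaK`
#'   (cation %), `HCO3CO3`, `SO4`, `Cl` (anion %), `d1`, `d2`.
#' @export
piper_coordinates <- function(profiles, co3 = 0) {
  stopifnot(inherits(profiles, "ionic_profiles"))
  cat_sum <- profiles$Ca + profiles$Mg + profiles$Na + profiles$K
  an_sum <- profiles$HCO3 + co3 + profiles$SO4 + profiles$Cl
  if (any(cat_sum <= 0) || any(an_sum <= 0))
    stop("zero Piper-ion sum for sample(s) ",
         paste(profiles$sample_id[cat_sum <= 0 | an_sum <= 0], collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    sample_id = profiles$sample_id,
    Ca = 100 * profiles$Ca / cat_sum,
    Mg = 100 * profiles$Mg / cat_sum,
    NaK = 100 * (profiles$Na + profiles$K) / cat_sum,
    HCO3CO3 = 100 * (profiles$HCO3 + co3) / an_sum,
    SO4 = 100 * profiles$SO4 / an_sum,
    Cl = 100 * profiles$Cl / an_sum,
    stringsAsFactors = FALSE)
  out$d1 <- out$NaK
  out$d2 <- out$SO4 + out$Cl
  structure(out, class = c("piper_coordinates", "data.frame"))
}

#' Hydrochemical facies from Piper coordinates
#'
#' Names each water by its dominant cation and anion: an ion group is
#' dominant when it exceeds 50% of its triangle (Na+K reported as Na,
#' HCO3+CO3 as HCO3); with no ion above 50% the side is "mixed". Typical
#' results are facies strings like `Na-HCO3`, `Ca-HCO3` or `Ca-Cl`.
#'
#' @param coords A `piper_coordinates` object.
#' @return Data frame `sample_id`, `cation_dominant`, `anion_dominant`,
#'   `facies`.
#' @export
classify_facies <- function(coords) {
  stopifnot(inherits(coords, "piper_coordinates"))
  pick <- function(pct, labels) {
    i <- max.col(pct, ties.method = "first")
    top <- pct[cbind(seq_len(nrow(pct)), i)]
    ifelse(top > 50, labels[i], "mixed")
  }
  cat_d <- pick(as.matrix(coords[c("Ca", "Mg", "NaK")]),
                c("Ca", "Mg", "Na"))
  an_d <- pick(as.matrix(coords[c("HCO3CO3", "SO4", "Cl")]),
               c("HCO3", "SO4", "Cl"))
  data.frame(sample_id = coords$sample_id,
             cation_dominant = cat_d,
             anion_dominant = an_d,
             facies = paste(cat_d, an_d, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Schoeller semi-logarithmic profiles
#'
#' Builds the per-sample log10(meq/L) values along the parallel ion axes of
#' a Schoeller diagram. The default uses seven axes (Ca, Mg, Na, K, Cl, SO4,
#' HCO3); `axes = "six"` combines Na and K into one axis. Non-positive
#' concentrations cannot be drawn on a log axis; they are returned as `NA`
#' and flagged as censored.
#'
#' @param profiles An `ionic_profiles` object.
#' @param axes `"seven"` (default) or `"six"` (Na+K combined).
#' @return A `schoeller_profile`: list with `ions`, matrix `log10_meq`
#'   (samples x ions) and logical matrix `censored`.
#' @export
schoeller_profile <- function(profiles, axes = c("seven", "six")) {
  stopifnot(inherits(profiles, "ionic_profiles"))
  axes <- match.arg(axes)
  m <- as.matrix(profiles[c("Ca", "Mg", "Na", "K", "Cl", "SO4", "HCO3")])
  if (axes == "six") {
    m <- cbind(m[, c("Ca", "Mg"), drop = FALSE],
               NaK = m[, "Na"] + m[, "K"],
               m[, c("Cl", "SO4", "HCO3"), drop = FALSE])
  }
  rownames(m) <- profiles$sample_id
  censored <- m <= 0
  lg <- suppressWarnings(log10(m))
  lg[censored] <- NA_real_
  structure(list(ions = colnames(m), log10_meq = lg, censored = censored),
            class = "schoeller_profile")
}

#' @export
print.schoeller_profile <- function(x, ...) {
  cat("Schoeller profile:", nrow(x$log10_meq), "samples on axes",
      paste(x$ions, collapse = ", "), "\n")
  if (any(x$censored)) cat(sum(x$censored), "censored (non-positive) points\n")
  invisible(x)
}

#' @describeIn schoeller_profile Draw the profiles (one polyline per
#'   sample) on a semi-logarithmic axis.
#' @param x A `schoeller_profile`.
#' @param col Line colours, recycled over samples.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.schoeller_profile <- function(x, col = "steelblue", ...) {
  graphics::matplot(seq_along(x$ions), t(x$log10_meq), type = "l", lty = 1,
                    col = col, xaxt = "n", xlab = "",
                    ylab = expression(log[10] ~ "meq/L"), ...)
  graphics::axis(1, at = seq_along(x$ions), labels = x$ions)
  invisible(x)
}

#' Plot Piper coordinates
#'
#' A data-level rendering of the Piper diagram: cation triangle (lower
#' left), anion triangle (lower right) and central diamond, with one point
#' per sample in each field.
#'
#' @param x A `piper_coordinates` object.
#' @param col Point colour(s).
#' @param pch Point symbol.
#' @param ... Unused.
#' @export
plot.piper_coordinates <- function(x, col = "steelblue", pch = 16, ...) {
  coords <- x
  tern_xy <- function(a_left, a_right, a_top, ox) {
    # left apex = 100% of a_left, right = a_right, top = a_top
    x <- ox + (a_right + a_top / 2) / 100
    y <- sqrt(3) / 2 * a_top / 100
    cbind(x, y)
  }
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 2.2), ylim = c(0, 1.95), asp = 1)
  tri <- function(ox) graphics::polygon(ox + c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  tri(0); tri(1.2)
  graphics::polygon(1.1 + c(-0.5, 0, 0.5, 0), sqrt(3) / 2 + c(0.6, 0.1, 0.6, 1.1))
  ct <- tern_xy(coords$Ca, coords$NaK, coords$Mg, 0)
  an <- tern_xy(coords$HCO3CO3, coords$Cl, coords$SO4, 1.2)
  graphics::points(ct, col = col, pch = pch)
  graphics::points(an, col = col, pch = pch)
  dx <- 1.1 + (coords$d1 - coords$d2) / 200
  dy <- sqrt(3) / 2 + 0.1 + (coords$d1 + coords$d2) / 200
  graphics::points(dx, dy, col = col, pch = pch)
  graphics::text(c(0.5, 1.7, 1.1), c(-0.08, -0.08, sqrt(3) / 2 + 1.2),
                 c("cations", "anions", "diamond"))
  invisible(coords)
}
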
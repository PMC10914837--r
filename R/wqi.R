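## Weighted-arithmetic water quality index -----------------------------------

#' Unit weights for the weighted-arithmetic WQI
#'
#' Each parameter receives a unit weight inversely proportional to its
#' permissible standard:
#' \deqn{W_n = K / X_s, \qquad K = 1 / \sum X_s,}
#' so the most tightly regulated constituents weigh most.
#'
#' @param standards A `standards_table` (see [builtin_standards()]).
#' @param include Parameters entering the index (default: all in the table).
#' @return A `weight_vector`: list with `K` and named numeric `Wn`.
#' @examples
#' unit_weights(builtin_standards("WHO"))
#' @export
unit_weights <- function(standards, include = standards$parameter) {
  stopifnot(inherits(standards, "standards_table"))
  if (!length(include)) stop("include must be non-empty", call. = FALSE)
  miss <- setdiff(include, standards$parameter)
  if (length(miss))
    stop("parameter(s) not in standards table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  xs <- standards$Xs[match(include, standards$parameter)]
  if (any(xs <= 0)) stop("Xs must be > 0", call. = FALSE)
  K <- 1 / sum(xs)
  Wn <- K / xs
  names(Wn) <- include
  structure(list(K = K, Wn = Wn), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("WQI unit weights: K =", format(x$K, digits = 6), "\n")
  print(round(x$Wn, 8), ...)
  invisible(x)
}

#' Per-parameter quality ratings
#'
#' The quality rating of parameter n scales its excursion from the ideal
#' value to 100 at the permissible standard:
#' \deqn{Q_n = 100 (X_n - X_i) / (X_s - X_i).}
#' Ratings exceed 100 when a concentration exceeds its standard.
#'
#' For pH (ideal 7) the default uses the absolute deviation
#' `100 * |pH - 7| / (Xs - 7)`, treating acid and alkaline excursions
#' symmetrically and keeping ratings non-negative; `ph_rating = "signed"`
#' applies the raw formula instead.
#'
#' @param samples A [water_samples] object.
#' @param standards A `standards_table`.
#' @param include Parameters to rate (default: all in the table).
#' @param ph_rating `"absolute"` (default) or `"signed"`.
#' @return Numeric matrix, samples x parameters, of ratings.
#' @export
quality_rating <- function(samples, standards,
                           include = standards$parameter,
                           ph_rating = c("absolute", "signed")) {
  ph_rating <- match.arg(ph_rating)
  miss <- setdiff(include, names(samples))
  if (length(miss))
    stop("sample table lacks parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- match(include, standards$parameter)
  if (anyNA(idx))
    stop("parameter(s) not in standards table: ",
         paste(include[is.na(idx)], collapse = ", "), call. = FALSE)
  xs <- standards$Xs[idx]
  xi <- standards$Xi[idx]
  Q <- matrix(NA_real_, nrow(samples), length(include),
              dimnames = list(samples$sample_id, include))
  for (j in seq_along(include)) {
    xn <- samples[[include[j]]]
    dev <- xn - xi[j]
    if (include[j] == "pH" && ph_rating == "absolute") dev <- abs(dev)
    Q[, j] <- 100 * dev / (xs[j] - xi[j])
  }
  Q
}

#' Aggregate quality ratings into the WQI
#'
#' The index is the weighted mean of the ratings,
#' \deqn{WQI = \sum Q_n W_n / \sum W_n,}
#' invariant to rescaling all weights by a positive constant.
#'
#' @param Qn Matrix from [quality_rating()] (or a named vector for one
#'   sample).
#' @param weights A `weight_vector` from [unit_weights()] over the same
#'   parameter set.
#' @return Numeric vector of index values, one per sample.
#' @export
compute_wqi <- function(Qn, weights) {
  stopifnot(inherits(weights, "weight_vector"))
  if (is.null(dim(Qn))) Qn <- matrix(Qn, 1, dimnames = list(NULL, names(Qn)))
  if (!setequal(colnames(Qn), names(weights$Wn)))
    stop("rating and weight parameter sets differ", call. = FALSE)
  W <- weights$Wn[colnames(Qn)]
  drop(Qn %*% W) / sum(W)
}

#' Classify WQI values into quality bands
#'
#' The conventional five-band scale: 0-25 potable, 26-50 palatable, 51-75
#' moderately poor, 76-100 poor, above 100 unfit for drinking. Bands are
#' closed on their upper edge, so exactly 100 is still "poor" and anything
#' beyond is "unfit".
#'
#' @param wqi Numeric vector of non-negative index values.
#' @return Factor with levels `potable`, `palatable`, `moderately poor`,
#'   `poor`, `unfit`.
#' @examples
#' categorize_wqi(c(12, 99.3, 185.9))
#' @export
categorize_wqi <- function(wqi) {
  if (any(wqi < 0)) stop("WQI must be non-negative", call. = FALSE)
  cut(wqi, breaks = c(-Inf, 25, 50, 75, 100, Inf),
      labels = c("potable", "palatable", "moderately poor", "poor", "unfit"),
      right = TRUE)
}

#' Water quality index of a sample set
#'
#' One call from concentrations to classified index values: unit weights
#' from the guideline, per-parameter ratings, weighted aggregation, and
#' band classification.
#'
#' @inheritParams quality_rating
#' @return A `wqi` data frame: `sample_id`, `village` (if present), `wqi`,
#'   `category`; the rating matrix is attached as attribute `Qn`, the
#'   weights as `weights`.
#' @examples
#' std <- builtin_standards("WHO")
#' s <- water_samples(data.frame(sample_id = "s1", F = 2.1, TA = 350,
#'   TDS = 1400, Cl = 470, Na = 340, K = 29, SO4 = 60, NO3 = 7, Mg = 13,
#'   Ca = 82, TH = 240, pH = 8.5))
#' wqi(s, std)
#' @export
wqi <- function(samples, standards = builtin_standards("WHO"),
                include = standards$parameter,
                ph_rating = c("absolute", "signed")) {
  ph_rating <- match.arg(ph_rating)
  w <- unit_weights(standards, include)
  Q <- quality_rating(samples, standards, include, ph_rating)
  idx <- compute_wqi(Q, w)
  out <- data.frame(sample_id = samples$sample_id, stringsAsFactors = FALSE)
  if (!is.null(samples$village)) out$village <- samples$village
  out$wqi <- unname(idx)
  neg <- out$wqi < 0
  if (any(neg))
    warning("negative WQI under signed pH rating for ",
            sum(neg), " sample(s); category set to NA")
  out$category <- factor(NA, levels = levels(categorize_wqi(0)))
  out$category[!neg] <- categorize_wqi(out$wqi[!neg])
  structure(out, Qn = Q, weights = w, guideline = attr(standards, "guideline"),
            ph_rating = ph_rating, class = c("wqi", "data.frame"))
}

#' @export
print.wqi <- function(x, ...) {
  cat("Water quality index (", attr(x, "guideline"), " standards, pH rating ",
      attr(x, "ph_rating"), ")\n", sep = "")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 5, ...)
  invisible(x)
}

#' @export
summary.wqi <- function(object, ...) {
  cat("WQI over", nrow(object), "samples: range",
      format(min(object$wqi), digits = 5), "-",
      format(max(object$wqi), digits = 5),
      "mean", format(mean(object$wqi), digits = 5), "\n")
  print(table(object$category))
  invisible(table(object$category))
}

#' Per-village WQI summary
#'
#' Aggregates sample-level indices to one value and quality band per
#' village. `"mean-of-wqi"` (default) averages per-sample indices;
#' `"wqi-of-mean"` first averages concentrations within the village and
#' rates the mean water.
#'
#' @inheritParams wqi
#' @param method `"mean-of-wqi"` or `"wqi-of-mean"`.
#' @return Data frame `village`, `n_samples`, `wqi`, `category`, with the
#'   aggregation method as attribute `method`.
#' @export
village_summary <- function(samples, standards = builtin_standards("WHO"),
                            method = c("mean-of-wqi", "wqi-of-mean"),
                            include = standards$parameter,
                            ph_rating = c("absolute", "signed")) {
  method <- match.arg(method)
  ph_rating <- match.arg(ph_rating)
  if (is.null(samples$village))
    stop("samples carry no village column", call. = FALSE)
  keep <- !is.na(samples$village)
  if (!all(keep)) {
    warning("skipping ", sum(!keep), " sample(s) without a village label")
    samples <- samples[keep, ]
  }
  villages <- unique(samples$village)
  if (method == "mean-of-wqi") {
    per <- wqi(samples, standards, include, ph_rating)
    agg <- tapply(per$wqi, samples$village, mean)
    agg <- agg[villages]
  } else {
    means <- do.call(rbind, lapply(villages, function(v) {
      sub <- samples[samples$village == v, include, drop = FALSE]
      as.data.frame(lapply(sub, mean))
    }))
    means$sample_id <- villages
    agg <- wqi(water_samples(means, "village means"), standards, include,
               ph_rating)$wqi
    names(agg) <- villages
  }
  out <- data.frame(village = villages,
                    n_samples = as.integer(table(samples$village)[villages]),
                    wqi = unname(agg),
                    category = categorize_wqi(unname(agg)),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}
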
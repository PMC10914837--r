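## End-to-end assessment pipeline --------------------------------------------

#' Run the full groundwater-quality assessment pipeline
#'
#' Chains the stages — charge-balance QC, per-sample and per-village WQI,
#' hydrochemical facies, Spearman correlation, PCA with varimax rotation,
#' and IDW interpolation of village WQI — over a measured sample table or a
#' synthetic set, and writes one CSV per tabular artifact plus a JSON run
#' manifest recording every choice in effect. Reruns with an identical
#' configuration produce byte-identical outputs.
#'
#' @param input Path to a sample CSV (see [read_sample_table()]), a
#'   [water_samples] object, or `NULL` to simulate.
#' @param simulate List of arguments for [generate_samples()] when `input`
#'   is `NULL` (the `seed` argument below is injected).
#' @param out_dir Output directory, created if missing.
#' @param guideline `"WHO"` (default) or `"BIS-upper"`; or a
#'   `standards_table`.
#' @param include Parameters entering the index.
#' @param aggregation Village aggregation method (see [village_summary()]).
#' @param ph_rating pH rating convention (see [quality_rating()]).
#' @param cbe_tolerance Charge-balance gate in percent (default 5).
#' @param drop_qc_failures Drop samples failing the gate instead of only
#'   flagging them (default `FALSE`).
#' @param pca_normalize Kaiser row normalization in the varimax step.
#' @param idw_power,idw_grid IDW exponent and grid resolution.
#' @param seed Integer seed for simulation and coordinate placement.
#' @return Invisibly, a list with every stage result and the paths written.
#' @export
run_pipeline <- function(input = NULL, simulate = list(),
                         out_dir = tempfile("gwqi-run-"),
                         guideline = "WHO",
                         include = NULL,
                         aggregation = "mean-of-wqi",
                         ph_rating = "absolute",
                         cbe_tolerance = 5,
                         drop_qc_failures = FALSE,
                         pca_normalize = FALSE,
                         idw_power = 2, idw_grid = 50,
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  standards <- if (inherits(guideline, "standards_table")) guideline
               else builtin_standards(guideline)
  if (is.null(include)) include <- standards$parameter

  samples <- if (is.null(input)) {
    message("stage simulate: drawing synthetic samples (seed ", seed, ")")
    do.call(generate_samples, utils::modifyList(simulate, list(seed = seed)))
  } else if (inherits(input, "water_samples")) {
    input
  } else {
    message("stage read: ", input)
    read_sample_table(input, require = include)
  }
  message("stage read: ", nrow(samples), " samples")

  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  paths <- character(0)

  ## QC
  profiles <- to_meq(samples)
  qc <- charge_balance(profiles, tolerance = cbe_tolerance)
  message("stage qc: ", sum(!qc$pass), " of ", nrow(qc),
          " samples outside +-", cbe_tolerance, "% charge balance")
  paths["qc"] <- emit(qc, "qc_report.csv")
  if (drop_qc_failures && any(!qc$pass)) {
    samples <- samples[qc$pass, ]
    profiles <- profiles[qc$pass, ]
  }

  ## summary statistics
  stats_tab <- summary(samples)
  paths["summary"] <- emit(stats_tab, "summary_statistics.csv")

  ## WQI
  per_sample <- wqi(samples, standards, include, ph_rating)
  Qn <- attr(per_sample, "Qn")
  paths["wqi_samples"] <- emit(
    cbind(as.data.frame(per_sample)[c("sample_id",
                                      intersect("village",
                                                names(per_sample)))],
          round(Qn, 6),
          wqi = round(per_sample$wqi, 6),
          category = as.character(per_sample$category)),
    "wqi_samples.csv")
  villages <- NULL
  if (!is.null(samples$village)) {
    villages <- village_summary(samples, standards, aggregation, include,
                                ph_rating)
    message("stage wqi: ", nrow(villages), " villages aggregated (",
            aggregation, ")")
    paths["wqi_villages"] <- emit(villages, "wqi_villages.csv")
  }

  ## facies
  coords <- piper_coordinates(profiles)
  fac <- classify_facies(coords)
  paths["facies"] <- emit(cbind(round(coords[-1], 6),
                                fac[c("cation_dominant", "anion_dominant",
                                      "facies")],
                                sample_id = coords$sample_id),
                          "facies.csv")
  message("stage facies: ", length(unique(fac$facies)), " facies present")

  ## correlation + PCA
  vars <- intersect(include, names(samples))
  rho <- spearman_matrix(samples, vars)
  paths["correlation"] <- emit(
    data.frame(parameter = rownames(rho), round(unclass(rho), 4),
               check.names = FALSE),
    "spearman_correlation.csv")
  pca <- pca_correlation(samples, vars, rotate = TRUE,
                         normalize = pca_normalize)
  paths["eigenvalues"] <- emit(
    data.frame(component = seq_along(pca$eigenvalues),
               eigenvalue = round(pca$eigenvalues, 6),
               pct_variance = round(pca$pct_variance, 4)),
    "pca_eigenvalues.csv")
  if (!is.null(pca$rotated_loadings)) {
    lm <- round(unclass(pca$rotated_loadings), 4)
    comp_tab <- data.frame(parameter = rownames(lm), lm, check.names = FALSE)
    for (j in colnames(lm))
      comp_tab[[paste0(j, "_strength")]] <- pca$strength_labels[, j]
    paths["components"] <- emit(comp_tab, "pca_components.csv")
  }
  message("stage pca: ", pca$n_retained, " components retained (Kaiser)")

  ## spatial
  surface <- NULL
  if (!is.null(villages)) {
    if (all(c("x", "y") %in% names(samples))) {
      vc <- stats::aggregate(samples[c("x", "y")],
                             by = list(village = samples$village), mean)
    } else {
      vc <- generate_coordinates(nrow(villages), seed = seed)
      vc <- vc[match(villages$village, vc$village), ]
      vc$village <- villages$village
    }
    sites <- data.frame(site = villages$village,
                        x = vc$x, y = vc$y, value = villages$wqi)
    surface <- idw_interpolate(sites, grid = idw_grid, power = idw_power)
    bands <- classify_surface(surface)
    grid_long <- expand.grid(x = surface$x, y = surface$y)
    grid_long$value <- round(as.vector(surface$values), 6)
    grid_long$band <- as.vector(bands$bands)
    paths["idw_grid"] <- emit(grid_long, "idw_grid.csv")
    message("stage map: ", length(surface$x), "x", length(surface$y),
            " grid interpolated (p = ", idw_power, ")")
  }

  ## manifest
  manifest <- list(
    package = "gwqi",
    version = as.character(utils::packageVersion("gwqi")),
    seed = seed,
    input = if (is.character(input)) input else
      if (is.null(input)) "simulated" else "in-memory water_samples",
    provenance = attr(samples, "provenance"),
    guideline = attr(standards, "guideline"),
    included_parameters = include,
    ph_rating = ph_rating,
    aggregation = aggregation,
    cbe_tolerance = cbe_tolerance,
    drop_qc_failures = drop_qc_failures,
    hco3_source = attr(profiles, "hco3_source"),
    pca = list(retention = "kaiser strict > 1 on unrotated eigenvalues",
               rotation = "varimax",
               row_normalized = pca_normalize),
    idw = list(power = idw_power, grid = idw_grid, neighborhood = "all"),
    n_samples = nrow(samples),
    artifacts = as.list(basename(paths)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths["manifest"] <- manifest_path

  invisible(list(samples = samples, qc = qc, summary = stats_tab,
                 wqi = per_sample, villages = villages, facies = fac,
                 piper = coords, correlation = rho, pca = pca,
                 surface = surface, paths = paths, out_dir = out_dir))
}
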
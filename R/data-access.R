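#' Published per-village WQI values for the Achhnera block
#'
#' The ten per-village weighted-arithmetic WQI values reported for the
#' Achhnera block survey (Agra district, northern India), shipped as a
#' plain-text fixture. Useful as real-world input for band classification
#' and interpolation examples; the underlying 50 raw samples are not
#' public.
#'
#' @return Data frame `village`, `wqi`.
#' @examples
#' v <- achhnera_village_wqi()
#' categorize_wqi(v$wqi)
#' @export
achhnera_village_wqi <- function() {
  utils::read.csv(system.file("extdata", "achhnera_village_wqi.csv",
                              package = "gwqi"),
                  stringsAsFactors = FALSE)
}
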
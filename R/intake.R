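#' Neutral detergent fiber intake capacity
#'
#' The maximum daily NDF load a lactating (sub-)tropical cow can process,
#' proportional to body weight: \eqn{0.0135 \cdot BW} kg NDF/day.
#'
#' @param bw Body weight (kg); vectorized.
#' @return NDF intake capacity (kg/day).
#' @examples
#' ndf_intake_capacity(415)
#' @export
ndf_intake_capacity <- function(bw) {
  if (any(bw <= 0)) stop_domain("body weight must be positive")
  0.0135 * bw
}

#' Voluntary dry-matter intake and metabolizable-energy intake
#'
#' Semi-mechanistic intake prediction for stall-fed cattle blending a
#' physically regulated term (NDF intake capacity divided by the diet NDF
#' concentration) and a physiologically regulated term (total potential ME
#' requirement divided by the diet ME concentration):
#' \deqn{DMI = \frac{1}{2}\left(\frac{NDF\,capacity}{diet\,NDF}
#'   + \frac{total\,ME\,requirement}{diet\,ME}\right).}
#' Because the physiological term is driven by *potential* requirements,
#' the blended estimate is down-scaled once by the body-weight condition
#' index and finally capped by the feed offer.  ME intake is
#' \eqn{MEI = DMI \cdot diet\,ME}.
#'
#' @param bw Body weight (kg).
#' @param total_me_req Total potential ME requirement (MJ/day), from
#'   [total_requirements()].
#' @param feed A [ration()].
#' @param index Body-weight condition index in \[0, 1\], from
#'   [condition_index()].
#' @return One-row tibble with columns `ndf_capacity` (kg NDF/d),
#'   `physical_dmi`, `physiological_dmi`, `raw_dmi`, `scaled_dmi` (kg
#'   DM/d) and `mei` (MJ/d).
#' @examples
#' r <- ration(dm = 890, me = 9.4, ndf = 0.55, cp = 93.1)
#' voluntary_dmi(415, total_me_req = 100, feed = r, index = 1)
#' @export
voluntary_dmi <- function(bw, total_me_req, feed, index = 1) {
  if (feed$ndf <= 0 || feed$me <= 0) {
    stop_domain("diet NDF and ME concentrations must be positive")
  }
  if (index < 0 || index > 1) stop_domain("condition index must be in [0, 1]")
  if (total_me_req < 0) stop_domain("total ME requirement must be non-negative")
  cap <- ndf_intake_capacity(bw)
  physical <- cap / feed$ndf
  physiological <- total_me_req / feed$me
  raw <- (physical + physiological) / 2
  scaled <- min(raw * index, feed$offered_dm)
  tibble(
    ndf_capacity = cap,
    physical_dmi = physical,
    physiological_dmi = physiological,
    raw_dmi = raw,
    scaled_dmi = scaled,
    mei = scaled * feed$me
  )
}
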
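#' Stereotaxic NMDA infusion sites for hippocampal lesions
#'
#' The twelve published unilateral infusion coordinates (AP/ML from bregma in
#' mm, DV from the dural surface) used to produce excitotoxic lesions of the
#' dorsal and dorsal-intermediate hippocampal formation in the Long-Evans
#' rat. The printed table lists ML magnitudes; lesions were bilateral, so
#' mirroring each row across the midline enumerates the 24 sites actually
#' drilled and injected. The synthetic lesion generator anchors its cavity
#' geometry to exactly these sites.
#'
#' @param bilateral If `TRUE` (default) mirror each row across the midline
#'   (left = negative ML), yielding 24 sites; if `FALSE` return the 12
#'   printed right-hemisphere rows.
#' @return A data frame with columns `site`, `side` (`left`/`right`),
#'   `ap_mm`, `ml_mm` (signed), `dv_mm`.
#' @export
infusion_sites <- function(bilateral = TRUE) {
  ap <- c(-2.8, -3.3, -4.1, -4.1, -4.8, -4.8, -5.5, -5.5, -5.5, -5.5, -6.2, -6.2)
  ml <- c( 1.4,  2.4,  1.8,  3.4,  2.0,  4.2,  2.6,  3.6,  5.0,  5.0,  4.0,  5.4)
  dv <- c(-3.0, -3.0, -2.8, -2.8, -2.8, -3.1, -3.0, -2.9, -3.5, -5.5, -3.4, -4.4)
  right <- data.frame(site = seq_along(ap), side = "right",
                      ap_mm = ap, ml_mm = ml, dv_mm = dv)
  if (!bilateral) return(right)
  left <- right
  left$side <- "left"
  left$ml_mm <- -left$ml_mm
  out <- rbind(right, left)
  rownames(out) <- NULL
  out
}

#' Lesion extent along the model layer implied by a set of infusion sites
#'
#' The synthetic hippocampal layer is parameterized by a septo-temporal
#' fraction t in \[0, 1\] (0 = anterior/septal tip of the model layer). The
#' infusion table is mapped onto t by an affine calibration of bregma AP
#' that places the table's AP span onto the dorsal plus dorsal-intermediate
#' segment of the model layer: AP -2.8 mm maps to t = 0.25 and AP -6.2 mm to
#' t = 0.65, leaving the ventral-most portion of the layer untargeted (as in
#' the surgical design). The returned interval is the fractional AP window
#' that the lesion generator carves.
#'
#' @param sites Data frame from [infusion_sites()].
#' @return Named list: `extent` (length-2 fractional interval) and
#'   `site_frac` (per-site fractional position).
#' @export
lesion_extent_from_sites <- function(sites = infusion_sites()) {
  stopifnot(is.data.frame(sites), all(c("ap_mm") %in% names(sites)))
  frac <- 0.25 + (-sites$ap_mm - 2.8) * (0.65 - 0.25) / (6.2 - 2.8)
  list(extent = range(frac), site_frac = frac)
}
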
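#' Describe a stretched DNA substrate
#'
#' The one-dimensional arena on which particles move: a flow-stretched DNA
#' molecule anchored to a coverslip by one or both ends, optionally carrying
#' nucleosomes that act as point barriers to sliding. Positions along the
#' molecule are expressed in micrometres of stretched contour; the
#' base-pair-to-micrometre conversion is `nm_per_bp` (B-form contour
#' 0.34 nm/bp times a stretching extension factor, 0.8 by default for
#' flow-stretched molecules).
#'
#' @param length_bp DNA length in base pairs. Default 48502, the lambda-phage
#'   genome used as the standard single-molecule substrate.
#' @param barriers_bp Integer vector of nucleosome dyad positions in bp.
#'   Must be unique and within `[0, length_bp]`; stored sorted.
#' @param anchoring `"double_tethered"` (both ends fixed, no flow drift) or
#'   `"single_tethered"` (one end fixed, the far end free; drift applies
#'   when flow is on, and particles reaching the free tip stick there).
#' @param nm_per_bp Stretched extension in nm per bp, in `(0, 0.34]`.
#'
#' @return An object of class `dna_substrate`: a list with the validated
#'   fields plus `length_um`, the stretched length in micrometres, and
#'   `barriers_um`, barrier positions in micrometres.
#' @examples
#' lambda <- dna_substrate()
#' lambda$length_um
#' nuc <- dna_substrate(barriers_bp = c(12000, 30000))
#' @export
dna_substrate <- function(length_bp = 48502,
                          barriers_bp = integer(),
                          anchoring = c("double_tethered", "single_tethered"),
                          nm_per_bp = 0.34 * 0.8) {
  anchoring <- match.arg(anchoring)
  check_number(length_bp, "length_bp", lower = 1)
  check_number(nm_per_bp, "nm_per_bp", lower = 1e-12, upper = 0.34)
  barriers_bp <- as.numeric(barriers_bp)
  if (anyNA(barriers_bp)) abort("`barriers_bp` must not contain NA")
  if (any(barriers_bp < 0 | barriers_bp > length_bp)) {
    abort("`barriers_bp` must lie within [0, length_bp]")
  }
  barriers_bp <- sort(barriers_bp)
  if (anyDuplicated(barriers_bp) || any(diff(barriers_bp) < 1)) {
    abort("`barriers_bp` must be unique and spaced by at least 1 bp")
  }
  structure(
    list(
      length_bp = length_bp,
      barriers_bp = barriers_bp,
      anchoring = anchoring,
      nm_per_bp = nm_per_bp,
      length_um = length_bp * nm_per_bp / 1000,
      barriers_um = barriers_bp * nm_per_bp / 1000
    ),
    class = "dna_substrate"
  )
}

#' @export
print.dna_substrate <- function(x, ...) {
  cat(sprintf("<dna_substrate> %d bp (%.2f um at %.3f nm/bp), %s\n",
              round(x$length_bp), x$length_um, x$nm_per_bp, x$anchoring))
  if (length(x$barriers_bp)) {
    cat(sprintf("  %d barrier(s) at bp: %s\n", length(x$barriers_bp),
                paste(round(x$barriers_bp), collapse = ", ")))
  } else {
    cat("  no barriers (bare DNA)\n")
  }
  invisible(x)
}

#' Convert between base pairs and micrometres on a substrate
#'
#' @param x Positions (bp for `bp_to_um()`, micrometres for `um_to_bp()`).
#' @param substrate A [dna_substrate()].
#' @return Numeric vector of converted positions.
#' @export
bp_to_um <- function(x, substrate) x * substrate$nm_per_bp / 1000

#' @rdname bp_to_um
#' @export
um_to_bp <- function(x, substrate) x * 1000 / substrate$nm_per_bp

# Segment boundaries (um) induced by barriers and the DNA ends.
segment_edges <- function(substrate) {
  unique(c(0, substrate$barriers_um, substrate$length_um))
}

# Index of the inter-barrier segment containing each position.
segment_of <- function(x, substrate) {
  edges <- segment_edges(substrate)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}
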
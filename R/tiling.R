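#' Tile a protein sequence into overlapping windows
#'
#' Produces the tiling design of an activation-domain screen: windows of
#' `window` residues advanced by `step`, in 1-based inclusive coordinates.
#' When the last regular window does not reach the C-terminus, an additional
#' terminal tile anchored at the C-terminus is appended so every residue is
#' covered. A sequence shorter than `window` yields a single full-length
#' tile with a warning.
#'
#' @param sequence Protein sequence (single string) or its length (integer).
#' @param window Tile width in residues (default 40).
#' @param step Offset between tile starts (default 10).
#' @return data.frame with columns `tile_id`, `start`, `end`.
#' @examples
#' tile_sequence(50)  # tiles 1-40 and 11-50
#' @export
tile_sequence <- function(sequence, window = 40, step = 10) {
  len <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  if (len < 1) stop("empty sequence")
  if (len < window) {
    warning("sequence shorter than the window; returning one full-length tile")
    return(data.frame(tile_id = "tile_001", start = 1L, end = len))
  }
  starts <- seq.int(1L, len - window + 1L, by = step)
  if (starts[length(starts)] + window - 1L < len)
    starts <- c(starts, len - window + 1L)   # terminal-coverage tile
  data.frame(tile_id = sprintf("tile_%03d", seq_along(starts)),
             start = starts, end = starts + window - 1L)
}

#' Construct a tiling-screen object
#'
#' Couples a tiling design to the sorting-bin count matrix of a fluorescence-
#' activated screen and the activity calibration of the bins (median
#' reporter-to-expression ratio per bin).
#'
#' @param tiles data.frame from [tile_sequence()] (columns `tile_id`,
#'   `start`, `end`).
#' @param counts Numeric matrix, tiles x bins, of sequencing read counts per
#'   sorting bin; rows ordered as `tiles`.
#' @param bin_medians Numeric vector (length = ncol(counts)) of the median
#'   GFP:mCherry ratio of each bin.
#' @return Object of class `tile_screen`.
#' @export
tile_screen <- function(tiles, counts, bin_medians) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(tiles))
    stop("'counts' must have one row per tile")
  if (length(bin_medians) != ncol(counts))
    stop("'bin_medians' must have one value per bin")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(tiles = tiles, counts = counts, bin_medians = bin_medians),
            class = "tile_screen")
}

#' Per-tile activation-domain scores
#'
#' For each tile, read counts are normalized to fractions across the sorting
#' bins (removing sequencing-depth differences), the fraction vector is
#' dotted with the per-bin median activity ratios, and the resulting raw
#' scores are z-score normalized across all tiles of the screen. Tiles with
#' zero total counts are masked (`NA`).
#'
#' @param screen A [tile_screen()].
#' @return data.frame: `tile_id`, `start`, `end`, `raw_score`, `ad_score`
#'   (z-scored; `NA` for masked tiles).
#' @export
ad_score <- function(screen) {
  stopifnot(inherits(screen, "tile_screen"))
  tot <- rowSums(screen$counts)
  raw <- rep(NA_real_, length(tot))
  ok <- tot > 0
  raw[ok] <- (screen$counts[ok, , drop = FALSE] / tot[ok]) %*% screen$bin_medians
  mu <- mean(raw[ok]); s <- stats::sd(raw[ok])
  z <- rep(NA_real_, length(raw))
  z[ok] <- if (is.na(s) || s == 0) 0 else (raw[ok] - mu) / s
  data.frame(screen$tiles, raw_score = raw, ad_score = z)
}

#' Aggregate tile scores to per-residue scores
#'
#' Each residue's score is the mean of the scores of all tiles covering it.
#' Residues covered by no (unmasked) tile are absent from the output rather
#' than reported as zero.
#'
#' @param scores data.frame from [ad_score()] (or any with `start`, `end`
#'   and `ad_score` columns).
#' @return data.frame: `residue`, `score`, `n_tiles` (number of covering
#'   tiles).
#' @export
residue_scores <- function(scores) {
  scores <- scores[is.finite(scores$ad_score), , drop = FALSE]
  if (!nrow(scores)) return(data.frame(residue = integer(),
                                       score = numeric(), n_tiles = integer()))
  res <- seq.int(min(scores$start), max(scores$end))
  cover <- lapply(res, function(r)
    scores$ad_score[scores$start <= r & scores$end >= r])
  n <- lengths(cover)
  keep <- n > 0
  data.frame(residue = res[keep],
             score = vapply(cover[keep], mean, numeric(1)),
             n_tiles = n[keep])
}

#' Call activation-domain regions from tile scores
#'
#' Returns the maximal runs of residues for which every covering tile scores
#' above `threshold` (the conservative all-tiles rule: a residue belongs to
#' an AD only if no covering tile is inactive).
#'
#' @param scores data.frame from [ad_score()].
#' @param threshold Numeric score threshold.
#' @return data.frame with columns `start`, `end` (1-based inclusive), one
#'   row per called region; zero rows when nothing passes.
#' @export
call_ad_regions <- function(scores, threshold) {
  scores <- scores[is.finite(scores$ad_score), , drop = FALSE]
  if (!nrow(scores)) return(data.frame(start = integer(), end = integer()))
  res <- seq.int(min(scores$start), max(scores$end))
  pass <- vapply(res, function(r) {
    covering <- scores$start <= r & scores$end >= r
    any(covering) && all(scores$ad_score[covering] > threshold)
  }, logical(1))
  if (!any(pass)) return(data.frame(start = integer(), end = integer()))
  runs <- rle(pass)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- runs$values
  data.frame(start = res[starts[hit]], end = res[ends[hit]])
}
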
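#' Acquisition protocol: an ordered list of saturation points
#'
#' Each point is one presaturation block: amplitude `b1_uT` (uT), frequency
#' `offset_ppm` (ppm relative to the free guest), duration `t_sat_s` (s) and
#' the recovery delay `t_rec_s` (s) that precedes it.
#'
#' @param points A data.frame with columns `b1_uT`, `offset_ppm`, `t_sat_s`,
#'   `t_rec_s`.
#' @param reference_offset_ppm Offset (ppm) of the far off-resonance point
#'   used as the normalization reference.
#'
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(points, reference_offset_ppm = 200) {
  stopifnot(is.data.frame(points))
  need <- c("b1_uT", "offset_ppm", "t_sat_s", "t_rec_s")
  missing <- setdiff(need, names(points))
  if (length(missing))
    stop("points is missing columns: ", paste(missing, collapse = ", "))
  points <- points[, need]
  points[] <- lapply(points, as.numeric)
  reference_offset_ppm <- as.numeric(reference_offset_ppm)
  if (nrow(points) == 0) stop("protocol must contain at least one point")
  if (any(points$b1_uT < 0)) stop("b1 must be non-negative")
  if (any(points$t_sat_s <= 0)) stop("saturation durations must be positive")
  if (any(points$t_rec_s < 0)) stop("recovery delays must be non-negative")
  rownames(points) <- NULL
  structure(
    list(points = points, reference_offset_ppm = reference_offset_ppm),
    class = "acquisition_protocol"
  )
}

#' Build the default three-block 40-point fingerprinting protocol
#'
#' Block 1 (points 1-15): the off-resonance reference followed by the 14
#' characteristic library offsets, saturated at a mild 1.75 uT.  Block 2
#' (points 16-30): the same 15 offsets at a stronger 2.87 uT.  Block 3
#' (points 31-40): 10 offsets evenly spanning 1-11 ppm, where many effects
#' overlap, at 2.87 uT with a shorter saturation time.  Every point is
#' preceded by the same recovery delay (9.57 s by default).
#'
#' Within blocks 1-2 the 14 library offsets are ordered by descending
#' absolute offset; this ordering is a fixed convention of the package
#' (any fixed order yields an equivalent fingerprint space).
#'
#' @param library_offsets Exactly 14 distinct characteristic offsets (ppm),
#'   one per lanthanide of the library.
#' @param cfg A [spectrometer_config()] (carried for provenance only).
#' @param b1_mild,b1_strong Saturation amplitudes (uT) for block 1 and for
#'   blocks 2-3.
#' @param t_sat_long,t_sat_short Saturation durations (s) for blocks 1-2 and
#'   for block 3; `t_sat_short` must be shorter.
#' @param t_rec Recovery delay before every point (s).
#' @param reference_offset Off-resonance reference offset (ppm), far outside
#'   the ca. 45 ppm span of the library.
#'
#' @return An [acquisition_protocol()] with exactly 40 points.
#' @export
#' @examples
#' lib <- default_library()
#' prot <- build_default_protocol(vapply(lib, `[[`, numeric(1), "delta_omega_ppm"))
#' nrow(prot$points)  # 40
build_default_protocol <- function(library_offsets,
                                   cfg = spectrometer_config(),
                                   b1_mild = 1.75, b1_strong = 2.87,
                                   t_sat_long = 4.0, t_sat_short = 2.0,
                                   t_rec = 9.57,
                                   reference_offset = 200) {
  library_offsets <- as.numeric(library_offsets)
  if (length(library_offsets) != 14L)
    stop("exactly 14 library offsets are required")
  if (anyDuplicated(library_offsets)) stop("library offsets must be distinct")
  if (t_sat_short >= t_sat_long)
    stop("block-3 saturation time must be shorter than blocks 1-2")
  ordered <- library_offsets[order(-abs(library_offsets), library_offsets)]
  block12_offsets <- c(reference_offset, ordered)
  block3_offsets <- seq(1, 11, length.out = 10)
  points <- data.frame(
    b1_uT = c(rep(b1_mild, 15), rep(b1_strong, 15), rep(b1_strong, 10)),
    offset_ppm = c(block12_offsets, block12_offsets, block3_offsets),
    t_sat_s = c(rep(t_sat_long, 30), rep(t_sat_short, 10)),
    t_rec_s = rep(t_rec, 40)
  )
  acquisition_protocol(points, reference_offset_ppm = reference_offset)
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(
    "<acquisition_protocol> %d points, B1 in {%s} uT, reference at %+g ppm\n",
    nrow(x$points),
    paste(sort(unique(x$points$b1_uT)), collapse = ", "),
    x$reference_offset_ppm))
  invisible(x)
}

#' Serialize a protocol to and from JSON
#'
#' The file holds `{points: [{b1_uT, offset_ppm, t_sat_s, t_rec_s}, ...],
#' reference_offset_ppm}`.  Numbers are written at full precision so the
#' round trip is bit-exact.
#'
#' @param protocol An [acquisition_protocol()].
#' @param path File path.
#' @return `read_protocol()` returns an [acquisition_protocol()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  jsonlite::write_json(
    list(points = protocol$points,
         reference_offset_ppm = protocol$reference_offset_ppm),
    path, digits = I(17), auto_unbox = TRUE, dataframe = "rows"
  )
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_protocol(as.data.frame(obj$points),
                       reference_offset_ppm = obj$reference_offset_ppm)
}

protocol_id <- function(protocol) {
  json_id(list(points = protocol$points,
               ref = protocol$reference_offset_ppm))
}

# index of the normalization reference point (first point at the reference
# offset; the default protocol has one in block 1 and one in block 2)
reference_point_index <- function(protocol) {
  idx <- which(protocol$points$offset_ppm == protocol$reference_offset_ppm)
  if (length(idx) == 0)
    stop("protocol has no point at the reference offset")
  idx[1]
}
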
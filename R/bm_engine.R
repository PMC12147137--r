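#' Thermal-equilibrium magnetization state
#'
#' The state vector holds (Mx, My, Mz) per pool — free pool first, then the
#' bound pools in sample order — followed by an augmentation constant 1 that
#' carries the inhomogeneous relaxation terms.  At equilibrium the free pool
#' has Mz = 1 and bound pool i has Mz = f_i * c_i.
#'
#' @param sample An [ln_sample()].
#' @return Numeric vector of length `3 * (n_pools + 1) + 1`.
#' @export
equilibrium_state <- function(sample) {
  stopifnot(inherits(sample, "ln_sample"))
  n <- length(sample$pools)
  m0 <- c(1, vapply(seq_len(n), function(i)
    sample$pools[[i]]$f * sample$concentrations[i], numeric(1)))
  state <- numeric(3 * (n + 1) + 1)
  state[3 * seq_len(n + 1)] <- m0
  state[length(state)] <- 1
  state
}

# Offset-independent parts of the BM generator: relaxation, exchange and the
# augmentation column.  The RF (omega_1) and frequency-offset (Delta) entries
# are patched in per saturation point.
bm_base_matrix <- function(sample) {
  n <- length(sample$pools)
  dim <- 3 * (n + 1) + 1
  A <- matrix(0, dim, dim)
  aug <- dim
  t1 <- c(sample$t1_free,
          vapply(sample$pools, `[[`, numeric(1), "t1_bound"))
  t2 <- c(sample$t2_free,
          vapply(sample$pools, `[[`, numeric(1), "t2_bound"))
  m0 <- c(1, vapply(seq_len(n), function(i)
    sample$pools[[i]]$f * sample$concentrations[i], numeric(1)))
  for (p in seq_len(n + 1)) {
    ix <- 3 * (p - 1) + 1; iy <- ix + 1; iz <- ix + 2
    A[ix, ix] <- A[ix, ix] - 1 / t2[p]
    A[iy, iy] <- A[iy, iy] - 1 / t2[p]
    A[iz, iz] <- A[iz, iz] - 1 / t1[p]
    A[iz, aug] <- A[iz, aug] + m0[p] / t1[p]
  }
  # star-topology exchange: each bound pool exchanges only with the free pool
  for (i in seq_len(n)) {
    kex <- sample$pools[[i]]$k_ex
    kf <- sample$pools[[i]]$f * sample$concentrations[i] * kex
    for (comp in 0:2) {
      fr <- 1 + comp          # free-pool component row
      bo <- 3 * i + 1 + comp  # bound-pool i component row
      A[fr, fr] <- A[fr, fr] - kf
      A[fr, bo] <- A[fr, bo] + kex
      A[bo, fr] <- A[bo, fr] + kf
      A[bo, bo] <- A[bo, bo] - kex
    }
  }
  delta_rad <- c(0, vapply(sample$pools, function(p)
    ppm_to_rad_per_s(p$delta_omega_ppm, sample$spectrometer), numeric(1)))
  list(A = A, delta_rad = delta_rad, n = n)
}

# Patch RF amplitude and per-pool frequency offsets into a base matrix.
bm_patch_matrix <- function(base, offset_rad, w1) {
  A <- base$A
  for (p in seq_len(base$n + 1)) {
    ix <- 3 * (p - 1) + 1; iy <- ix + 1; iz <- ix + 2
    d <- base$delta_rad[p] - offset_rad
    A[ix, iy] <- A[ix, iy] + d
    A[iy, ix] <- A[iy, ix] - d
    A[iy, iz] <- A[iy, iz] + w1
    A[iz, iy] <- A[iz, iy] - w1
  }
  A
}

#' Assemble the augmented Bloch-McConnell propagation matrix
#'
#' Builds the generator A of dM/dt = A M for a sample under one saturation
#' point: per-pool relaxation and off-resonance precession at
#' `Delta_p = delta_p - offset` (rad/s), RF nutation at
#' `omega_1 = gamma B1`, and two-site exchange of every bound pool with the
#' free pool at forward rate `f_i c_i k_ex_i` and reverse rate `k_ex_i`
#' applied to all three magnetization components.  Constant relaxation terms
#' are folded into the augmentation column, so `exp(A t)` propagates the
#' augmented state exactly.
#'
#' @param sample An [ln_sample()].
#' @param point A one-row data.frame (or list) with `b1_uT` and `offset_ppm`
#'   (a row of `protocol$points`).
#' @return A square matrix of dimension `3 * (n_pools + 1) + 1`.
#' @export
assemble_bm_matrix <- function(sample, point) {
  stopifnot(inherits(sample, "ln_sample"))
  base <- bm_base_matrix(sample)
  bm_patch_matrix(base,
                  ppm_to_rad_per_s(point$offset_ppm, sample$spectrometer),
                  b1_to_rad_per_s(point$b1_uT, sample$spectrometer))
}

#' Propagate a magnetization state through time
#'
#' Applies `exp(A t)` to the augmented state vector (matrix exponential by
#' scaling-and-squaring).
#'
#' @param state Augmented state vector (see [equilibrium_state()]).
#' @param A Propagation matrix from [assemble_bm_matrix()].
#' @param t Duration in seconds (>= 0).
#' @return The propagated state vector.
#' @export
propagate <- function(state, A, t) {
  stopifnot(is.numeric(state), is.matrix(A),
            nrow(A) == ncol(A), length(state) == nrow(A))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single non-negative number")
  as.numeric(.propagate_cpp(state, A, t))
}

#' Simulate a z-spectrum
#'
#' For each offset the sample starts at thermal equilibrium, evolves through
#' the recovery delay (RF off) and the saturation block, and the free-pool
#' Mz is read out.  Values are normalized by the identical pipeline run at
#' the far off-resonance reference offset.
#'
#' @param sample An [ln_sample()].
#' @param offsets_ppm Saturation offsets (ppm), non-empty.
#' @param b1_uT Saturation amplitude (uT).
#' @param t_sat Saturation duration (s).
#' @param t_rec Recovery delay before saturation (s).
#' @param reference_offset_ppm Normalization reference offset (ppm).
#' @return An object of class `zspectrum` with fields `offsets_ppm`,
#'   `z` (normalized, in `[0, 1]`), `b1_uT`, `t_sat_s`.
#' @export
#' @examples
#' dy <- default_library()[["Dy"]]
#' s <- ln_sample(list(dy))
#' zs <- simulate_zspectrum(s, seq(-35, 5, by = 2.5), b1_uT = 2.87, t_sat = 4)
simulate_zspectrum <- function(sample, offsets_ppm, b1_uT, t_sat,
                               t_rec = 9.57, reference_offset_ppm = 200) {
  stopifnot(inherits(sample, "ln_sample"))
  if (length(offsets_ppm) == 0) stop("offset list must be non-empty")
  base <- bm_base_matrix(sample)
  w1 <- b1_to_rad_per_s(b1_uT, sample$spectrometer)
  eq <- equilibrium_state(sample)
  read_idx <- 3L  # Mz of the free pool
  one <- function(off_ppm) {
    state <- eq
    if (t_rec > 0) {
      Arec <- bm_patch_matrix(base, 0, 0)
      state <- as.numeric(.propagate_cpp(state, Arec, t_rec))
    }
    Asat <- bm_patch_matrix(
      base, ppm_to_rad_per_s(off_ppm, sample$spectrometer), w1)
    as.numeric(.propagate_cpp(state, Asat, t_sat))[read_idx]
  }
  ref <- one(reference_offset_ppm)
  z <- vapply(offsets_ppm, one, numeric(1)) / ref
  structure(
    list(offsets_ppm = as.numeric(offsets_ppm), z = z,
         b1_uT = b1_uT, t_sat_s = t_sat),
    class = "zspectrum"
  )
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf(
    "<zspectrum> %d offsets in [%g, %g] ppm at B1 = %g uT, t_sat = %g s; min z = %.3f\n",
    length(x$offsets_ppm), min(x$offsets_ppm), max(x$offsets_ppm),
    x$b1_uT, x$t_sat_s, min(x$z)))
  invisible(x)
}

#' Simulate a fingerprint: the signal trajectory over a protocol
#'
#' Runs the acquisition protocol sequentially, carrying the magnetization
#' through each recovery delay and saturation block in order (no reset
#' between points), and records the free-pool Mz after each saturation.
#' The trajectory is normalized by the readout at the protocol's
#' off-resonance reference point.
#'
#' @param sample An [ln_sample()].
#' @param protocol An [acquisition_protocol()].
#' @return An object of class `fingerprint`: `values` (normalized
#'   intensities, one per point) and `protocol_id`.
#' @export
#' @examples
#' lib <- default_library()
#' prot <- build_default_protocol(vapply(lib, `[[`, numeric(1), "delta_omega_ppm"))
#' fp <- simulate_fingerprint(ln_sample(list(lib[["Dy"]])), prot)
simulate_fingerprint <- function(sample, protocol) {
  stopifnot(inherits(sample, "ln_sample"),
            inherits(protocol, "acquisition_protocol"))
  if (is.null(sample$spectrometer))
    stop("sample carries no spectrometer configuration")
  pts <- protocol$points
  base <- bm_base_matrix(sample)
  dim <- nrow(base$A)
  Asat <- array(0, c(dim, dim, nrow(pts)))
  for (i in seq_len(nrow(pts))) {
    Asat[, , i] <- bm_patch_matrix(
      base, ppm_to_rad_per_s(pts$offset_ppm[i], sample$spectrometer),
      b1_to_rad_per_s(pts$b1_uT[i], sample$spectrometer))
  }
  Arec <- bm_patch_matrix(base, 0, 0)
  raw <- as.numeric(.trajectory_cpp(
    Asat, pts$t_sat_s, Arec, pts$t_rec_s,
    equilibrium_state(sample), 2L))  # 0-based index of free-pool Mz
  values <- raw / raw[reference_point_index(protocol)]
  new_fingerprint(values, protocol_id(protocol))
}

new_fingerprint <- function(values, protocol_id = NA_character_) {
  structure(list(values = as.numeric(values), protocol_id = protocol_id),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d points, range [%.4f, %.4f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Read and write fingerprints as CSV with a JSON envelope
#'
#' The CSV holds `point_index, signal`; a sidecar `<path>.json` envelope
#' records the protocol id and any simulation settings supplied.
#'
#' @param fp A `fingerprint`.
#' @param path CSV file path.
#' @param settings Optional named list stored in the envelope.
#' @return `read_fingerprint()` returns a `fingerprint`.
#' @export
write_fingerprint <- function(fp, path, settings = list()) {
  stopifnot(inherits(fp, "fingerprint"))
  lines <- c("point_index,signal",
             sprintf("%d,%.17g", seq_along(fp$values), fp$values))
  writeLines(lines, path)
  jsonlite::write_json(
    list(protocol_id = fp$protocol_id, settings = settings),
    paste0(path, ".json"), digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("point_index", "signal") %in% names(df)))
  pid <- NA_character_
  envelope <- paste0(path, ".json")
  if (file.exists(envelope)) {
    env <- jsonlite::read_json(envelope, simplifyVector = TRUE)
    if (!is.null(env$protocol_id)) pid <- env$protocol_id
  }
  new_fingerprint(df$signal[order(df$point_index)], pid)
}
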
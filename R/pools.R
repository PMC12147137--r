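#' Exchange and relaxation parameters for one lanthanide-host bound pool
#'
#' Describes one host-guest pair: the chemical-shift offset of the bound
#' guest (dispersed by the lanthanide's pseudocontact shift), the bound-pool
#' fraction at the reference host concentration, the guest exchange rate out
#' of the bound state, and the relaxation times observed for the pair.
#'
#' @param name Lanthanide identifier (e.g. `"Dy"`).
#' @param delta_omega_ppm Bound-guest offset in ppm relative to the free guest
#'   at 0 ppm (positive = downfield); `|delta_omega| <= 50`.
#' @param f Bound-pool fraction relative to the free pool, in `[0, 1)`.
#' @param k_ex Exchange rate of the guest leaving the bound pool, s^-1 (> 0).
#' @param t1_free,t2_free Free-pool relaxation times observed for this pair, s.
#' @param t1_bound,t2_bound Bound-pool relaxation times, s.  These are not
#'   directly observable for a minor pool; defaults are `t1_free` and 0.02 s.
#'
#' @return An object of class `lanthanide_pool`.
#' @export
#' @examples
#' lanthanide_pool("Dy", delta_omega_ppm = -28.6, f = 0.005, k_ex = 1800,
#'                 t1_free = 1.5, t2_free = 0.3)
lanthanide_pool <- function(name, delta_omega_ppm, f, k_ex,
                            t1_free, t2_free,
                            t1_bound = t1_free, t2_bound = 0.02) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num <- c(delta_omega_ppm = delta_omega_ppm, f = f, k_ex = k_ex,
           t1_free = t1_free, t2_free = t2_free,
           t1_bound = t1_bound, t2_bound = t2_bound)
  if (!all(is.finite(num))) stop("all pool parameters must be finite")
  if (f < 0 || f >= 1) stop("f must lie in [0, 1)")
  if (k_ex <= 0) stop("k_ex must be positive")
  if (abs(delta_omega_ppm) > 50) stop("|delta_omega| must be <= 50 ppm")
  if (t2_free <= 0 || t1_free < t2_free)
    stop("free-pool relaxation must satisfy t1 >= t2 > 0")
  if (t2_bound <= 0 || t1_bound < t2_bound)
    stop("bound-pool relaxation must satisfy t1 >= t2 > 0")
  structure(
    c(list(name = name), as.list(num)),
    class = "lanthanide_pool"
  )
}

#' @export
print.lanthanide_pool <- function(x, ...) {
  cat(sprintf(
    "<lanthanide_pool> %s: dw = %+.2f ppm, f = %.4g, k_ex = %.0f /s, T1/T2(free) = %.2f/%.2f s\n",
    x$name, x$delta_omega_ppm, x$f, x$k_ex, x$t1_free, x$t2_free))
  invisible(x)
}

pool_library_columns <- c(
  "name", "delta_omega_ppm", "f", "k_ex_s", "t1_free_s", "t2_free_s",
  "t1_bound_s", "t2_bound_s"
)

#' Read or write a pool-parameter library as CSV
#'
#' The library file is a plain CSV with columns `name, delta_omega_ppm, f,
#' k_ex_s, t1_free_s, t2_free_s, t1_bound_s, t2_bound_s`, one row per
#' lanthanide-host pair.  Numeric values are written with 17 significant
#' digits so a write/read cycle is bit-exact.
#'
#' @param path File path.
#' @return `read_pool_library()` returns a named list of
#'   [lanthanide_pool()] objects.
#' @export
read_pool_library <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(pool_library_columns, names(df))
  if (length(missing))
    stop("library CSV is missing columns: ", paste(missing, collapse = ", "))
  pools <- lapply(seq_len(nrow(df)), function(i) {
    lanthanide_pool(
      name = df$name[i],
      delta_omega_ppm = df$delta_omega_ppm[i],
      f = df$f[i],
      k_ex = df$k_ex_s[i],
      t1_free = df$t1_free_s[i],
      t2_free = df$t2_free_s[i],
      t1_bound = df$t1_bound_s[i],
      t2_bound = df$t2_bound_s[i]
    )
  })
  names(pools) <- df$name
  if (anyDuplicated(names(pools))) stop("duplicate pool names in library")
  pools
}

#' @param pools A named list of [lanthanide_pool()] objects.
#' @rdname read_pool_library
#' @export
write_pool_library <- function(pools, path) {
  stopifnot(is.list(pools), length(pools) > 0)
  rows <- vapply(pools, function(p) {
    c(p$name,
      vapply(c(p$delta_omega_ppm, p$f, p$k_ex, p$t1_free, p$t2_free,
               p$t1_bound, p$t2_bound),
             function(v) sprintf("%.17g", v), character(1)))
  }, character(8))
  lines <- c(paste(pool_library_columns, collapse = ","),
             apply(rows, 2, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' A sample: free guest pool plus any number of lanthanide-host bound pools
#'
#' The free pool is implicit (equilibrium magnetization 1); each bound pool
#' carries its reference bound fraction `f`, scaled by a per-pool
#' concentration factor.  Sample-level free-pool relaxation defaults to the
#' first pool's pair values for a single-pool sample; mixtures should be
#' built with [generate_sample()], which combines paramagnetic relaxation
#' enhancements additively.
#'
#' @param pools List of [lanthanide_pool()] objects (may be empty for a
#'   free-pool-only sample).
#' @param concentrations Per-pool concentration scaling factors (> 0),
#'   multipliers of the reference `f`; recycled if length 1.
#' @param spectrometer A [spectrometer_config()].
#' @param t1_free,t2_free Sample-level free-pool relaxation times, s.
#'   Required when `pools` is empty or has more than one member.
#'
#' @return An object of class `ln_sample`.
#' @export
ln_sample <- function(pools, concentrations = 1,
                      spectrometer = spectrometer_config(),
                      t1_free = NULL, t2_free = NULL) {
  stopifnot(is.list(pools), inherits(spectrometer, "spectrometer_config"))
  for (p in pools)
    if (!inherits(p, "lanthanide_pool")) stop("pools must be lanthanide_pool objects")
  n <- length(pools)
  if (n > 0) {
    nm <- vapply(pools, `[[`, character(1), "name")
    if (anyDuplicated(nm)) stop("pool names must be unique")
    names(pools) <- nm
  }
  if (length(concentrations) == 1L) concentrations <- rep(concentrations, n)
  if (length(concentrations) != n)
    stop("concentrations must match the number of pools")
  if (n > 0 && any(concentrations <= 0)) stop("concentration scalings must be > 0")
  eff <- if (n > 0)
    sum(vapply(pools, `[[`, numeric(1), "f") * concentrations) else 0
  if (eff >= 1) stop("total effective bound fraction sum(f_i * c_i) must be < 1")
  if (is.null(t1_free) || is.null(t2_free)) {
    if (n == 1L) {
      t1_free <- pools[[1]]$t1_free
      t2_free <- pools[[1]]$t2_free
    } else {
      stop("t1_free and t2_free must be given explicitly unless the sample has exactly one pool")
    }
  }
  if (t2_free <= 0 || t1_free < t2_free)
    stop("free-pool relaxation must satisfy t1 >= t2 > 0")
  structure(
    list(pools = pools, concentrations = as.numeric(concentrations),
         spectrometer = spectrometer,
         t1_free = t1_free, t2_free = t2_free),
    class = "ln_sample"
  )
}

#' @export
print.ln_sample <- function(x, ...) {
  if (length(x$pools) == 0) {
    cat("<ln_sample> free pool only\n")
  } else {
    cat(sprintf(
      "<ln_sample> %d bound pool(s): %s; free-pool T1/T2 = %.2f/%.2f s\n",
      length(x$pools),
      paste(sprintf("%s(c=%g)", names(x$pools), x$concentrations), collapse = ", "),
      x$t1_free, x$t2_free))
  }
  invisible(x)
}

sample_id <- function(sample) {
  json_id(list(
    pools = lapply(sample$pools, function(p) p[pool_fields()]),
    conc = sample$concentrations,
    t1_free = sample$t1_free, t2_free = sample$t2_free,
    larmor = sample$spectrometer$larmor_freq_19F
  ))
}

pool_fields <- function() {
  c("name", "delta_omega_ppm", "f", "k_ex", "t1_free", "t2_free",
    "t1_bound", "t2_bound")
}
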
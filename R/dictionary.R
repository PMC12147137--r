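#' Enumerate lanthanide-mixture subsets
#'
#' All unordered subsets of the requested sizes drawn from the library
#' names, in deterministic lexicographic order (names sorted alphabetically,
#' sizes ascending).  For the 14-member library and sizes `{1, 2, 3, 5}`
#' this yields 2471 subsets.
#'
#' @param library_names Character vector of lanthanide names (unique).
#' @param sizes Integer subset sizes, each in `1..length(library_names)`.
#' @return A list of character vectors (sorted within each subset).
#' @export
#' @examples
#' length(enumerate_subsets(names(default_library()), c(1, 2, 3, 5)))  # 2471
enumerate_subsets <- function(library_names, sizes) {
  if (length(library_names) == 0) stop("library must be non-empty")
  if (anyDuplicated(library_names)) stop("library names must be unique")
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0 || any(sizes < 1L) || any(sizes > length(library_names)))
    stop("sizes must lie in 1..length(library_names)")
  nm <- sort(library_names)
  out <- list()
  for (k in sizes) {
    subs <- combn(nm, k, simplify = FALSE)
    out <- c(out, subs)
  }
  out
}

hypothesis_key <- function(subset, conc) {
  paste0(paste(subset, collapse = "+"), "|",
         paste(sprintf("%.17g", conc), collapse = ","))
}

#' Build a simulated-fingerprint dictionary
#'
#' One entry per (subset, concentration assignment): every subset of the
#' requested sizes is crossed with the full Cartesian product of the
#' concentration grid over its members, each hypothesis is turned into a
#' sample with [generate_sample()] and simulated with
#' [simulate_fingerprint()].  The entry count is
#' `sum_k choose(n, k) * g^k` for grid size `g`.
#'
#' @param library Named list of [lanthanide_pool()] objects (the 14-member
#'   fixture library by default).
#' @param sizes Subset sizes to enumerate.
#' @param grid Concentration scaling factors (> 0), applied per member.
#' @param protocol An [acquisition_protocol()].
#' @param spectrometer A [spectrometer_config()].
#' @param diamagnetic_reference The diamagnetic baseline pair used by the
#'   mixture relaxation rule (see [generate_sample()]): a library name or a
#'   [lanthanide_pool()].
#' @param progress Print a line every `progress` entries (0 = silent).
#' @return An object of class `fingerprint_dictionary` with fields
#'   `vectors` (entries x points matrix), `hypotheses` (data.frame with
#'   `key`, `subset`, `conc`), and `meta` (provenance: protocol and library
#'   hashes, grid, sizes, creation time).
#' @export
build_dictionary <- function(library, sizes, grid, protocol,
                             spectrometer = spectrometer_config(),
                             diamagnetic_reference = "La",
                             progress = 0) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  grid <- as.numeric(grid)
  if (length(grid) == 0 || any(grid <= 0))
    stop("grid must be a non-empty set of positive scaling factors")
  subsets <- enumerate_subsets(names(library), sizes)
  n_points <- nrow(protocol$points)
  n_entries <- sum(vapply(subsets, function(s) length(grid)^length(s), numeric(1)))
  vectors <- matrix(NA_real_, n_entries, n_points)
  keys <- character(n_entries)
  subset_str <- character(n_entries)
  conc_str <- character(n_entries)
  row <- 0L
  for (s in subsets) {
    conc_grid <- as.matrix(expand.grid(rep(list(grid), length(s))))
    for (j in seq_len(nrow(conc_grid))) {
      conc <- as.numeric(conc_grid[j, ])
      smp <- generate_sample(s, conc, library, spectrometer,
                             diamagnetic_reference = diamagnetic_reference)
      fp <- simulate_fingerprint(smp, protocol)
      row <- row + 1L
      vectors[row, ] <- fp$values
      keys[row] <- hypothesis_key(s, conc)
      subset_str[row] <- paste(s, collapse = "+")
      conc_str[row] <- paste(sprintf("%.17g", conc), collapse = ",")
      if (progress > 0 && row %% progress == 0)
        message(sprintf("dictionary: %d / %d entries", row, n_entries))
    }
  }
  # deterministic entry order independent of library permutation
  ord <- order(keys)
  structure(
    list(
      vectors = vectors[ord, , drop = FALSE],
      hypotheses = data.frame(key = keys[ord], subset = subset_str[ord],
                              conc = conc_str[ord], stringsAsFactors = FALSE),
      meta = list(
        protocol_id = protocol_id(protocol),
        library_id = json_id(lapply(library, function(p) p[pool_fields()])),
        sizes = sort(unique(as.integer(sizes))),
        grid = grid,
        n_entries = n_entries,
        n_points = n_points,
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "fingerprint_dictionary"
  )
}

#' @export
print.fingerprint_dictionary <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_dictionary> %d entries x %d points; sizes {%s}, grid {%s}\n",
    nrow(x$vectors), ncol(x$vectors),
    paste(x$meta$sizes, collapse = ","),
    paste(x$meta$grid, collapse = ",")))
  invisible(x)
}

#' Write and read a dictionary (columnar parquet container)
#'
#' Entries are stored as one parquet table — hypothesis columns `key`,
#' `subset`, `conc` plus one float column per protocol point — with the
#' provenance metadata embedded as a JSON attribute, so a write/read cycle
#' restores vectors and metadata identically.
#'
#' @param dict A `fingerprint_dictionary`.
#' @param path File path (`.parquet`).
#' @return `read_dictionary()` returns a `fingerprint_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "fingerprint_dictionary"))
  vec_df <- as.data.frame(dict$vectors)
  names(vec_df) <- sprintf("v%02d", seq_len(ncol(dict$vectors)))
  df <- cbind(dict$hypotheses, vec_df)
  attr(df, "paragest_meta") <-
    as.character(jsonlite::toJSON(dict$meta, digits = I(17), auto_unbox = TRUE))
  arrow::write_parquet(df, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  df <- as.data.frame(arrow::read_parquet(path))
  meta <- jsonlite::fromJSON(attr(df, "paragest_meta"))
  vec_cols <- grep("^v[0-9]+$", names(df), value = TRUE)
  structure(
    list(
      vectors = unname(as.matrix(df[, vec_cols, drop = FALSE])),
      hypotheses = df[, c("key", "subset", "conc")],
      meta = meta
    ),
    class = "fingerprint_dictionary"
  )
}
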
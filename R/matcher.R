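#' L2-normalize a fingerprint vector
#'
#' @param v Numeric vector with positive norm.
#' @return `v / ||v||_2`.
#' @export
normalize_fingerprint <- function(v) {
  if (inherits(v, "fingerprint")) v <- v$values
  stopifnot(is.numeric(v), length(v) > 0, all(is.finite(v)))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot normalize a zero vector")
  v / nrm
}

#' Match a fingerprint against a simulated dictionary
#'
#' Standard fingerprinting pattern recognition: the measured trajectory and
#' every dictionary entry are L2-normalized and compared by inner product
#' (cosine similarity).  Entries are scored in chunks so memory stays
#' bounded for large dictionaries; the result is invariant to chunk size
#' and to entry order (ties are broken by lexicographic hypothesis key).
#'
#' @param fp A `fingerprint` or numeric vector, same length as the
#'   dictionary entries.
#' @param dict A `fingerprint_dictionary`.
#' @param top_k Number of ranked hypotheses to return.
#' @param chunk_size Entries scored per chunk.
#' @return An object of class `match_result`: `table` (a data.frame of the
#'   `top_k` hypotheses with `key`, `subset`, `conc`, `score`, descending),
#'   `best` (the rank-1 row), `best_vector` (its simulated trajectory) and
#'   `fidelity_r2` (coefficient of determination of the best simulated
#'   trajectory against the input).
#' @export
#' @examples
#' lib <- default_library()
#' prot <- build_default_protocol(vapply(lib, `[[`, numeric(1), "delta_omega_ppm"))
#' dict <- build_dictionary(lib["Dy"], sizes = 1, grid = 1, protocol = prot)
#' fp <- simulate_fingerprint(generate_sample("Dy", 1, lib), prot)
#' match_fingerprint(fp, dict)$best$subset  # "Dy"
match_fingerprint <- function(fp, dict, top_k = 10, chunk_size = 65536L) {
  stopifnot(inherits(dict, "fingerprint_dictionary"))
  v <- if (inherits(fp, "fingerprint")) fp$values else as.numeric(fp)
  n <- nrow(dict$vectors)
  if (n == 0) stop("dictionary is empty")
  if (length(v) != ncol(dict$vectors))
    stop(sprintf("fingerprint length %d does not match dictionary entries (%d points)",
                 length(v), ncol(dict$vectors)))
  u <- normalize_fingerprint(v)
  scores <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    end <- min(start + chunk_size - 1L, n)
    block <- dict$vectors[start:end, , drop = FALSE]
    norms <- sqrt(rowSums(block^2))
    if (any(norms == 0)) stop("dictionary contains a zero entry")
    # rowSums keeps the per-row summation order fixed, so scores are
    # bit-identical for any chunking (BLAS gemm/gemv reductions are not)
    scores[start:end] <-
      rowSums(block * rep(u, each = nrow(block))) / norms
  }
  ord <- order(-scores, dict$hypotheses$key)
  take <- ord[seq_len(min(top_k, n))]
  table <- cbind(dict$hypotheses[take, , drop = FALSE],
                 score = scores[take])
  rownames(table) <- NULL
  best_vector <- dict$vectors[take[1], ]
  structure(
    list(table = table, best = table[1, ], best_vector = best_vector,
         fidelity_r2 = fidelity_r2(v, best_vector)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> best: %s (score %.6f, R2 = %.4f)\n",
              x$best$key, x$best$score, x$fidelity_r2))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Coefficient of determination between measured and simulated trajectories
#'
#' `R2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' mean of the experimental (measured) vector.  Used as the fidelity of a
#' matched simulated fingerprint to the data it was matched to.
#'
#' @param experimental Measured trajectory (numeric vector, non-constant).
#' @param simulated Simulated trajectory of equal length.
#' @return The coefficient of determination (1 for identical vectors; can be
#'   negative when the model fits worse than the mean).
#' @export
fidelity_r2 <- function(experimental, simulated) {
  if (inherits(experimental, "fingerprint")) experimental <- experimental$values
  if (inherits(simulated, "fingerprint")) simulated <- simulated$values
  stopifnot(is.numeric(experimental), is.numeric(simulated),
            length(experimental) == length(simulated),
            length(experimental) > 1)
  ss_tot <- sum((experimental - mean(experimental))^2)
  if (ss_tot == 0) stop("experimental vector is constant; R2 undefined")
  1 - sum((experimental - simulated)^2) / ss_tot
}
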
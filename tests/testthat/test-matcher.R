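test_that("normalization returns unit vectors and is scale invariant", {
  e1 <- c(1, rep(0, 39))
  expect_identical(normalize_fingerprint(e1), e1)
  set.seed(5)
  for (trial in 1:20) {
    v <- rnorm(40)
    u <- normalize_fingerprint(v)
    expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
    expect_equal(normalize_fingerprint(3.7 * v), u)
  }
  expect_error(normalize_fingerprint(rep(0, 40)), "zero vector")
})

singles_dict <- build_dictionary(test_lib, sizes = 1, grid = 1,
                                 protocol = test_protocol)

test_that("every noiseless fingerprint self-matches with score 1 and R2 = 1", {
  for (nm in names(test_lib)) {
    fp <- simulate_fingerprint(generate_sample(nm, 1, test_lib),
                               test_protocol)
    m <- match_fingerprint(fp, singles_dict)
    expect_identical(m$best$subset, nm)
    expect_gte(m$best$score, 1 - 1e-9)
    expect_equal(m$fidelity_r2, 1, tolerance = 1e-9)
  }
})

test_that("a fingerprint orthogonal to an entry scores zero against it", {
  d <- singles_dict
  v <- d$vectors[1, ]
  orth <- c(-v[2], v[1], rep(0, length(v) - 2))  # orthogonal by construction
  m <- match_fingerprint(orth, d, top_k = nrow(d$vectors))
  row1 <- which(m$table$key == d$hypotheses$key[1])
  expect_equal(m$table$score[row1], 0, tolerance = 1e-12)
})

test_that("matching is invariant to chunk size and rejects bad input", {
  fp <- simulate_fingerprint(generate_sample("Tb", 1, test_lib),
                             test_protocol)
  m1 <- match_fingerprint(fp, singles_dict, top_k = 5, chunk_size = 3L)
  m2 <- match_fingerprint(fp, singles_dict, top_k = 5, chunk_size = 1000L)
  expect_identical(m1$table, m2$table)
  expect_error(match_fingerprint(fp$values[1:10], singles_dict), "length")
})

test_that("noisy fingerprints recover their generating hypothesis", {
  # 200 seeded trials against a pairs+singles dictionary (861 entries)
  dict <- build_dictionary(test_lib, sizes = c(1, 2), grid = c(0.5, 1, 2),
                           protocol = test_protocol)
  expect_equal(nrow(dict$vectors), 14 * 3 + 91 * 9)
  set.seed(77)
  hits <- 0L
  for (trial in 1:200) {
    i <- sample(nrow(dict$vectors), 1)
    noisy <- dict$vectors[i, ] + rnorm(40, 0, 0.005)
    m <- match_fingerprint(noisy, dict, top_k = 1)
    if (identical(m$best$subset, dict$hypotheses$subset[i])) hits <- hits + 1L
  }
  expect_gte(hits, 190L)  # >= 95%
})

test_that("recovery accuracy does not improve as noise grows", {
  set.seed(99)
  acc <- vapply(c(0.001, 0.005, 0.02, 0.05), function(sigma) {
    hits <- 0L
    for (trial in 1:60) {
      i <- sample(nrow(singles_dict$vectors), 1)
      noisy <- singles_dict$vectors[i, ] + rnorm(40, 0, sigma)
      m <- match_fingerprint(noisy, singles_dict, top_k = 1)
      if (identical(m$best$key, singles_dict$hypotheses$key[i]))
        hits <- hits + 1L
    }
    hits / 60
  }, numeric(1))
  expect_true(all(diff(acc) <= 0.05))  # non-increasing up to MC jitter
})

test_that("a near-flat shallow member slips into matched mixtures undetected", {
  # when the Gd pair loses its distinguishing relaxation enhancement its
  # fingerprint is nearly featureless (tiny offset, heavily broadened dip);
  # adding such a member to any hypothesis perturbs the simulated
  # trajectory less than adding any other member, so it is the lanthanide
  # that matching confuses first -- singles still self-match exactly, but a
  # mixture wrongly including it is nearly indistinguishable from the truth
  flat_lib <- test_lib
  la <- test_lib[["La"]]
  flat_lib[["Gd"]] <- lanthanide_pool(
    "Gd", delta_omega_ppm = 0.3, f = 0.001, k_ex = 1500,
    t1_free = la$t1_free, t2_free = la$t2_free,
    t1_bound = la$t1_free, t2_bound = 0.002)
  nm <- names(flat_lib)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  fps <- lapply(nm, function(x)
    simulate_fingerprint(generate_sample(x, 1, flat_lib), test_protocol)$values)
  names(fps) <- nm
  # detectability of adding member y at half concentration to a singleton x
  add_dist <- vapply(nm, function(y) {
    1 - max(vapply(setdiff(nm, y), function(x) {
      both <- simulate_fingerprint(
        generate_sample(c(x, y), c(1, 0.5), flat_lib), test_protocol)$values
      cosine(fps[[x]], both)
    }, numeric(1)))
  }, numeric(1))
  expect_identical(names(which.min(add_dist)), "Gd")
  expect_lt(add_dist[["Gd"]], 0.1 * min(add_dist[nm != "Gd"]))
})

test_that("the coefficient of determination follows its definition", {
  x <- c(0.9, 0.5, 0.7, 0.95, 0.2)
  expect_equal(fidelity_r2(x, x), 1)
  expect_equal(fidelity_r2(x, rep(mean(x), 5)), 0)
  set.seed(8)
  for (trial in 1:20) {
    e <- runif(40)
    s <- e + rnorm(40, 0, 0.1)
    byhand <- 1 - sum((e - s)^2) / sum((e - mean(e))^2)
    expect_equal(fidelity_r2(e, s), byhand, tolerance = 1e-12)
  }
  expect_error(fidelity_r2(rep(1, 5), runif(5)), "constant")
})
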
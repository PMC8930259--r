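test_that("gray values encode to MSB-first 8-bit blocks and decode back exactly", {
  expect_identical(encode_gray(0), rep(0L, 8))
  expect_identical(encode_gray(255), rep(1L, 8))
  expect_identical(encode_gray(128), c(1L, rep(0L, 7)))
  for (v in c(0:10, 127, 128, 200, 255)) {
    expect_identical(decode_gray(encode_gray(v)), as.integer(v))
  }
  # multi-block round trip
  centers <- c(30L, 90L, 150L, 220L)
  expect_identical(decode_gray(encode_gray(centers)), centers)
  expect_error(encode_gray(256), "\\[0, 255\\]")
})

test_that("hamming distance and its affinity follow the 1/(1+m) form", {
  expect_equal(hamming(rep(0L, 8), rep(1L, 8)), 8)
  b <- rand_bits(16, seed = 2)
  expect_equal(hamming(b, b), 0)
  expect_equal(hamming(c(1L, rep(0L, 7)), c(rep(0L, 7), 1L)), 2)
  expect_equal(ab_affinity_hamming(rep(0L, 8), rep(1L, 8)), 1 / 9)
  for (seed in 1:5) {
    a <- rand_bits(24, seed); b <- rand_bits(24, seed + 100)
    expect_equal(ab_affinity_hamming(a, b), ab_affinity_hamming(b, a))
  }
  expect_error(hamming(rep(0L, 8), rep(0L, 16)), "equal lengths")
})

test_that("concentration matches a brute-force pairwise count and stays in [1/N, 1]", {
  # all-identical population: every pair affinity is 1 > lambda
  pop <- matrix(rep(c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 5), 5, byrow = TRUE)
  for (i in 1:5) expect_equal(concentration(pop, i, 0.95), 1)

  # isolated antibody: only self counts
  pop2 <- rbind(rep(0L, 8), rep(1L, 8), c(rep(1L, 4), rep(0L, 4)))
  expect_equal(concentration(pop2, 1, 0.95), 1 / 3)

  # random population vs explicit double loop
  set.seed(9)
  pop3 <- matrix(sample(c(0L, 1L), 10 * 8, TRUE), 10)
  for (i in 1:10) {
    brute <- sum(vapply(1:10, function(j) {
      ab_affinity_hamming(pop3[i, ], pop3[j, ]) > 0.95
    }, logical(1))) / 10
    d <- concentration(pop3, i, 0.95)
    expect_equal(d, brute)
    expect_gte(d, 1 / 10)
    expect_lte(d, 1)
  }
})

test_that("adjusted fitness applies exp(k * D) and preserves within-concentration ranking", {
  expect_equal(adjusted_fitness(0.7, 0, -0.8), 0.7)
  expect_equal(adjusted_fitness(0.5, 1, -0.8), 0.5 * exp(-0.8))
  expect_equal(adjusted_fitness(0, 0.4, -0.8), 0)
  aff <- c(0.9, 0.5, 0.7, 0.1)
  fit <- adjusted_fitness(aff, rep(0.3, 4), -0.8)
  expect_identical(order(fit), order(aff))
  # strictly decreasing in concentration
  expect_true(adjusted_fitness(0.5, 0.2, -0.8) > adjusted_fitness(0.5, 0.9, -0.8))
})

test_that("clonal selection follows the rank-proportional rule with stable ties", {
  pop <- rbind(rep(0L, 8), rep(1L, 8), c(1L, rep(0L, 7)))
  clones <- clone_select(pop, c(0.9, 0.5, 0.1), mc = 3)
  src <- attr(clones, "source")
  # m = 2 selected; rank 1 -> max(1, round(3/1)) = 3, rank 2 -> round(3/2) = 2
  expect_equal(sum(src == 1L), 3L)
  expect_equal(sum(src == 2L), 2L)
  expect_false(any(src == 3L))
  # highest-fitness antibody heads the clone group
  expect_identical(clones[1, ], pop[1, ])

  # two-antibody population: only rank 1 is selected, with mc clones
  clones2 <- clone_select(pop[1:2, ], c(0.9, 0.5), mc = 2)
  expect_equal(sum(attr(clones2, "source") == 1L), 2L)
  expect_false(any(attr(clones2, "source") == 2L))

  # ties keep original population order
  tied <- clone_select(pop, c(0.5, 0.5, 0.5), mc = 3)
  expect_equal(sort(unique(attr(tied, "source"))), c(1L, 2L))
  expect_error(clone_select(pop, c(1, 1, 1), mc = 4), "exceed")
})

test_that("crossover is suffix exchange with the stated boundary behavior", {
  set.seed(4)
  clones <- matrix(sample(c(0L, 1L), 6 * 8, TRUE), 6)
  expect_identical(crossover(clones, qc = 0), clones)
  # qc = 1 with the clone as its own partner leaves it unchanged
  expect_identical(crossover(clones, qc = 1, partners = clones), clones)
  # all-zero clones, all-one partners: each row must be a 0-prefix then 1-suffix
  zero <- matrix(0L, 10, 8)
  ones <- matrix(1L, 10, 8)
  crossed <- crossover(zero, qc = 1, partners = ones)
  for (i in 1:10) {
    expect_true(all(diff(crossed[i, ]) >= 0))
    expect_equal(crossed[i, 8], 1L)
  }
  # determinism under a fixed seed
  set.seed(11); a <- crossover(clones, qc = 1)
  set.seed(11); b <- crossover(clones, qc = 1)
  expect_identical(a, b)
})

test_that("mutation flips at most one uniformly chosen bit per antibody", {
  set.seed(5)
  grp <- matrix(sample(c(0L, 1L), 20 * 16, TRUE), 20)
  expect_identical(mutate_antibodies(grp, qm = 0), grp)
  set.seed(6)
  mut <- mutate_antibodies(grp, qm = 1)
  for (i in 1:20) expect_equal(hamming(grp[i, ], mut[i, ]), 1)
  for (qm in c(0.06, 0.5)) {
    set.seed(7)
    m <- mutate_antibodies(grp, qm)
    for (i in 1:20) expect_lte(hamming(grp[i, ], m[i, ]), 1)
  }
})

test_that("the engine finds a needle objective and honors the stall rule", {
  # single rewarded code out of 256 with zero gradient elsewhere: the stall
  # rule allows only ~stall_gens generations of blind search, so finding the
  # needle in a majority of seeded runs shows the variation operators keep
  # generating genuinely new codes on a flat fitness plateau
  needle <- function(bits) as.numeric(decode_gray(bits) == 200L)
  hits <- 0L
  for (seed in 1:40) {
    fit <- run_immune(needle, L = 8L,
                      params = immune_params(seed = seed))
    if (decode_gray(fit$bits) == 200L) hits <- hits + 1L
  }
  expect_gte(hits, 20L)

  # constant objective: stall rule fires well before maxgen
  flat <- run_immune(function(bits) 1, L = 8L,
                     params = immune_params(seed = 1))
  expect_lt(flat$generations, 200L)
  expect_lte(flat$generations, 1L + 20L)
})

test_that("engine runs are bit-exact reproducible and traces are monotone", {
  obj <- function(bits) sum(bits)  # favors all-ones
  f1 <- run_immune(obj, L = 16L, params = quick_params(seed = 42))
  f2 <- run_immune(obj, L = 16L, params = quick_params(seed = 42))
  expect_identical(f1$bits, f2$bits)
  expect_equal(as.data.frame(f1$trace), as.data.frame(f2$trace))

  f3 <- run_immune(obj, L = 16L, params = quick_params(seed = 43))
  expect_true(all(diff(f3$trace$best_affinity) >= 0))
  expect_true(all(diff(f3$trace$generation) > 0))
  expect_true(all(f3$trace$mean_concentration >= 1 / 10 &
                    f3$trace$mean_concentration <= 1))
})

test_that("a non-finite objective is reported with the offending antibody", {
  bad <- function(bits) if (decode_gray(bits) > 100) NaN else 1
  expect_error(run_immune(bad, L = 8L, params = quick_params(seed = 1)),
               "non-finite affinity")
})
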
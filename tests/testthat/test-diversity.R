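test_that("Shannon index: closed forms, relabeling, maximality", {
  expect_equal(shannon_diversity(rep(5, 4)), log(4))
  expect_identical(shannon_diversity(c(10, 0, 0)), 0)
  expect_equal(shannon_diversity(c(50, 30, 20)), 1.0297, tolerance = 1e-4)
  expect_error(shannon_diversity(c(0, 0)), "zero")
  set.seed(9)
  x <- rpois(40, 8) + 1
  expect_equal(shannon_diversity(x), shannon_diversity(sample(x)))
  expect_lt(shannon_diversity(x), log(40)) # uniform maximizes H
})

test_that("evenness reproduces the printed species-level cells", {
  expect_equal(round(evenness(3.0, 288), 2), 0.53)
  expect_equal(round(evenness(3.6, 338), 2), 0.62)
  expect_equal(evenness(log(50), 50), 1)
  expect_error(evenness(1, 1), "S_obs")
})

test_that("Chao1: bias-corrected form and printed-table fixtures", {
  expect_identical(chao1(100, 0, 10), 100)
  # F2 = 38 is the derived fixture reproducing the printed 647.7
  expect_equal(chao1(288, 168, 38), 647.7, tolerance = 0.05)
  expect_equal(chao1(42, 14, 6), 55.0, tolerance = 0.05)
  expect_error(chao1(-1, 0, 0), ">= 0")
  expect_error(chao1(10, 8, 4), "exceed")
  expect_error(chao1(50, 10, 0, bias_corrected = FALSE), "F2 = 0")
  expect_equal(chao1(50, 10, 5, bias_corrected = FALSE), 50 + 100 / 10)
})

test_that("Chao1 and ACE agree with the vegan implementations", {
  skip_if_not_installed("vegan")
  for (seed in 1:8) {
    x <- random_counts(seed)
    x <- x[x > 0]
    est <- vegan::estimateR(x)
    expect_equal(chao1(length(x), sum(x == 1), sum(x == 2)),
                 unname(est["S.chao1"]), tolerance = 1e-9)
    expect_equal(ace(x), unname(est["S.ACE"]), tolerance = 1e-9)
  }
})

test_that("ACE edge classes", {
  expect_identical(ace(c(20, 30, 40)), 3)       # no rare class
  x <- c(rep(2, 6), rep(3, 4), 50, 60)          # rare class, F1 = 0
  expect_equal(ace(x), 12)                      # coverage 1, gamma 0
  expect_error(ace(c(1, 1, 1)), "singleton")
  expect_gte(ace(c(1, 1, 2, 3, 50)), 5)
})

test_that("coverage variants reproduce the printed cells", {
  expect_equal(round(goods_coverage(168, S_obs = 288), 2), 41.67)
  expect_equal(round(goods_coverage(206, S_obs = 338), 2), 39.05)
  expect_equal(round(goods_coverage(169, S_obs = 289), 2), 41.52)
  expect_equal(round(goods_coverage(13, S_obs = 41), 2), 68.29)
  expect_identical(goods_coverage(0, N = 500, variant = "good"), 100)
  expect_equal(goods_coverage(168, N = 2977, variant = "good"),
               100 * (1 - 168 / 2977))
  expect_error(goods_coverage(10, S_obs = 5), "exceed")
})

test_that("rarefaction: endpoints, vegan oracle, shape", {
  x <- random_counts(3, S = 60, N = 800)
  x <- x[x > 0]
  N <- sum(x)
  expect_equal(rarefy_richness(x, N), length(x))
  expect_equal(rarefy_richness(x, 1), 1)
  expect_error(rarefy_richness(x, N + 1), "depth")

  skip_if_not_installed("vegan")
  depths <- c(10, 50, 200, 500, N)
  expect_equal(rarefy_richness(x, depths),
               as.vector(vegan::rarefy(x, depths)), tolerance = 1e-8)
  # nondecreasing and concave in depth
  d <- seq(1, N, by = 20)
  e <- rarefy_richness(x, d)
  expect_true(all(diff(e) >= -1e-10))
  expect_true(all(diff(diff(e)) <= 1e-8))
})

test_that("Monte-Carlo rarefaction agrees with the closed form", {
  x <- random_counts(11, S = 40, N = 400)
  x <- x[x > 0]
  depths <- c(20, 100, 250)
  analytic <- rarefy_richness(x, depths)
  # independent resampling oracle with its own SE
  reads <- rep.int(seq_along(x), x)
  set.seed(99)
  n_rep <- 1000
  for (j in seq_along(depths)) {
    reps <- replicate(n_rep,
                      length(unique(sample(reads, depths[j]))))
    se <- sd(reps) / sqrt(n_rep)
    expect_lt(abs(mean(reps) - analytic[j]), 3 * max(se, 1e-8))
  }
  mc <- rarefy_richness(x, depths, method = "montecarlo", n_rep = 1000,
                        seed = 5)
  expect_lt(max(abs(mc - analytic)), 0.5)
})

test_that("venn regions partition the union", {
  m <- rbind(A = c(1, 1, 0, 2, 0), B = c(1, 0, 3, 2, 0),
             C = c(1, 0, 0, 2, 4))
  colnames(m) <- paste0("Otu", 1:5)
  v <- venn_counts(otu_table(m))
  expect_identical(v[["A&B&C"]], 2L) # Otu1, Otu4
  expect_identical(unname(v[c("A", "B", "C")]), rep(1L, 3))
  expect_identical(v[["A&B"]], 0L)
  expect_identical(sum(v), 5L)

  same <- otu_table(rbind(A = c(2, 1), B = c(5, 9)))
  vs <- venn_counts(same)
  expect_identical(unname(vs[c("A", "B")]), c(0L, 0L))
  expect_identical(vs[["A&B"]], 2L)

  disj <- otu_table(rbind(A = c(3, 0), B = c(0, 7)))
  vd <- venn_counts(disj)
  expect_identical(vd[["A&B"]], 0L)

  expect_error(venn_counts(same, samples = c("A", "A")), "duplicate")
  expect_error(venn_counts(same, samples = c("A", "Z")), "unknown")
})

test_that("three-sample planted overlap structure is recovered", {
  # plant: 4 core, 3 exclusive to each sample, 2 in each pairwise region
  otus <- 4 + 3 * 3 + 2 * 3
  m <- matrix(0L, 3, otus,
              dimnames = list(c("r1", "r2", "r3"), NULL))
  idx <- 1
  put <- function(rows, n) {
    for (k in seq_len(n)) { m[rows, idx] <<- 1L; idx <<- idx + 1 }
  }
  put(1:3, 4); put(1, 3); put(2, 3); put(3, 3)
  put(c(1, 2), 2); put(c(1, 3), 2); put(c(2, 3), 2)
  v <- venn_counts(otu_table(m))
  expect_identical(unname(v[c("r1", "r2", "r3")]), rep(3L, 3))
  expect_identical(unname(v[c("r1&r2", "r1&r3", "r2&r3")]), rep(2L, 3))
  expect_identical(v[["r1&r2&r3"]], 4L)
})

test_that("alpha summary is internally consistent on random tables", {
  for (seed in 1:20) {
    x <- random_counts(seed + 40)
    x <- x[x > 0]
    s <- alpha_summary(x)
    expect_gte(s$chao1, s$n_otus)
    expect_gte(s$ace, s$n_otus)
    expect_lte(s$n_singletons + s$n_doubletons, s$n_otus)
    expect_true(s$evenness >= 0 && s$evenness <= 1)
    expect_equal(s$chao1, chao1(s$n_otus, s$n_singletons, s$n_doubletons))
  }
})
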
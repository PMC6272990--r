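make_amova_fixture <- function() {
  v <- rbind(a1 = c(1, 1, 0), a2 = c(1, 1, 0),
             b1 = c(0, 0, 1), b2 = c(0, 0, 1))
  colnames(v) <- c("x", "y", "z")
  tiny_bm(v)
}

test_that("hand-computed two-group AMOVA", {
  bm <- make_amova_fixture()
  grp <- setNames(c("A", "A", "B", "B"), rownames(bm$values))
  res <- amova_oneway(squared_euclidean(bm), grp, n_perm = 0)
  tab <- res$table
  # cross-group pairs differ at all 3 bands: SS_total = 4 pairs * 3 / 4
  expect_equal(tab$SS, c(3, 0, 3))
  expect_equal(tab$df, c(1, 2, 3))
  expect_equal(res$n0, 2)
  expect_equal(tab$sigma2[2], 0)
  expect_equal(res$phi, 1)
  expect_equal(tab$percent[1], 100)
})

test_that("no variation means zero components everywhere", {
  v <- matrix(rep(c(1, 0, 1), each = 4), 4,
              dimnames = list(paste0("s", 1:4), paste0("b", 1:3)))
  bm <- tiny_bm(v)
  grp <- setNames(c("A", "A", "B", "B"), rownames(v))
  res <- amova_oneway(squared_euclidean(bm), grp, n_perm = 19, seed = 1)
  expect_equal(res$table$SS, c(0, 0, 0))
  expect_equal(res$table$sigma2, c(0, 0, 0))
  expect_equal(res$table$percent, c(0, 0, 100))
})

test_that("distance formulation matches the Euclidean ANOVA identity", {
  set.seed(71)
  for (r in 1:8) {
    sizes <- sample(2:6, 3, replace = TRUE)
    bm <- random_bm(sum(sizes), 12)
    grp <- setNames(rep(paste0("g", 1:3), sizes), rownames(bm$values))
    res <- amova_oneway(squared_euclidean(bm), grp, n_perm = 0)
    oracle <- amova_ss_oracle(bm, grp)
    expect_equal(res$table$SS[3], unname(oracle["total"]), tolerance = 1e-9)
    expect_equal(res$table$SS[2], unname(oracle["within"]), tolerance = 1e-9)
    expect_equal(res$table$SS[1], unname(oracle["among"]), tolerance = 1e-9)
    # SS additivity
    expect_equal(res$table$SS[1] + res$table$SS[2], res$table$SS[3],
                 tolerance = 1e-9)
  }
})

test_that("n0 equals n for balanced designs, relabeling is irrelevant", {
  set.seed(72)
  bm <- random_bm(12, 10)
  grp <- setNames(rep(c("a", "b", "c"), each = 4), rownames(bm$values))
  res <- amova_oneway(squared_euclidean(bm), grp, n_perm = 0)
  expect_equal(res$n0, 4)
  # permute sample order (keeping labels attached): identical result
  perm <- sample(12)
  bmp <- bm[perm, ]
  resp <- amova_oneway(squared_euclidean(bmp), grp[rownames(bmp$values)],
                       n_perm = 0)
  expect_equal(resp$table, res$table)
})

test_that("permutation p-value is +1-corrected and seeded", {
  sim <- simulate_band_matrix(sim_config(n_pops = 2, samples_per_pop = 8,
                                         primers = c(SSR = 5),
                                         divergence = 0.3, seed = 73,
                                         study_labels = FALSE))
  grp <- setNames(sim$metadata$population, sim$metadata$sample_id)
  d2 <- squared_euclidean(sim$matrix)
  r1 <- amova_oneway(d2, grp, n_perm = 99, seed = 5)
  r2 <- amova_oneway(d2, grp, n_perm = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_equal(r1$p_value, 1 / 100)  # strong structure: no permutation beats it
})

test_that("group-size and count contracts", {
  bm <- make_amova_fixture()
  d2 <- squared_euclidean(bm)
  expect_error(amova_oneway(d2, setNames(c("A", "A", "A", "B"),
                                         rownames(bm$values)), n_perm = 0),
               "fewer than 2")
  expect_error(amova_oneway(d2, setNames(rep("A", 4), rownames(bm$values)),
                            n_perm = 0), "at least 2 groups")
})

test_that("study-sized design yields the textbook degrees of freedom", {
  sim <- simulate_band_matrix(sim_config(seed = 74, primers = c(SSR = 3),
                                         bands_per_primer = c(3, 5)))
  grp <- setNames(sim$metadata$accession, sim$metadata$sample_id)
  res <- amova_oneway(squared_euclidean(sim$matrix), grp, n_perm = 0)
  expect_equal(res$table$df[1:2], c(19, 176))
})

test_that("by-country AMOVA restricts and groups correctly", {
  sim <- simulate_band_matrix(sim_config(n_pops = 4, samples_per_pop = 10,
                                         primers = c(SSR = 6),
                                         divergence = 0.3, seed = 75,
                                         study_labels = FALSE))
  md <- sim$metadata
  # two synthetic subspecies; the first spans two countries
  md$subspecies <- rep(c("alpha", "beta"), each = 20)
  md$country <- rep(c("C1", "C2", "C3", "C3"), each = 10)
  res <- amova_by_country(sim$matrix, md, "alpha", n_perm = 99, seed = 6)
  expect_equal(res$table$df[1], 1)
  expect_lte(res$p_value, 0.05)
  expect_gt(res$phi, 0)
  expect_error(amova_by_country(sim$matrix, md, "beta"), "C3")
  expect_error(amova_by_country(sim$matrix, md, "gamma"), "no samples")
})
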
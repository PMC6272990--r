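test_that("construction validates cells, ids and maps", {
  v <- matrix(0L, 2, 3, dimnames = list(c("s1", "s2"), c("b1", "b2", "b3")))
  bm <- band_matrix(v, c(b1 = "P1", b2 = "P1", b3 = "P2"),
                    c(P1 = "SSR", P2 = "IT-ISJ"))
  expect_s3_class(bm, "band_matrix")
  expect_identical(sum(bm$values), 0L)
  expect_identical(dim(bm), c(2L, 3L))

  v2 <- v; v2[2, 3] <- 2L
  expect_error(band_matrix(v2, c(b1 = "P1", b2 = "P1", b3 = "P2"),
                           c(P1 = "SSR")), "s2.*b3")
  vna <- v; vna[1, 1] <- NA_integer_
  expect_error(band_matrix(vna, c(b1 = "P1", b2 = "P1", b3 = "P2"),
                           c(P1 = "SSR", P2 = "IT-ISJ")), "missing")
  vd <- v; rownames(vd) <- c("s1", "s1")
  expect_error(band_matrix(vd, c(b1 = "P1", b2 = "P1", b3 = "P2"),
                           c(P1 = "SSR", P2 = "IT-ISJ")), "duplicate")
  expect_error(band_matrix(v, c(b1 = "P1", b2 = "P1"),
                           c(P1 = "SSR")), "without a primer")
  expect_error(band_matrix(v, c(b1 = "P1", b2 = "P1", b3 = "P2"),
                           c(P1 = "SSR")), "marker-system")
})

test_that("reader rejects non-binary cells with coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tb1\tb2", "primer\tP1\tP1", "s1\t0\t1", "s2\t0\t2"), f)
  expect_error(read_band_matrix(f), "'2'.*s2.*b2")
})

test_that("write -> read round trip is bit-identical", {
  sim <- simulate_band_matrix(sim_config(n_pops = 3, samples_per_pop = 4,
                                         primers = c(SSR = 2, `IT-ISJ` = 2),
                                         bands_per_primer = c(3, 5),
                                         seed = 42, study_labels = FALSE))
  for (ext in c(".tsv", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    fs <- withr::local_tempfile(fileext = ext)
    write_band_matrix(sim$matrix, f, fs)
    back <- read_band_matrix(f, fs)
    expect_identical(back$values, sim$matrix$values)
    expect_identical(back$band_primer, sim$matrix$band_primer)
    expect_identical(back$primer_system, sim$matrix$primer_system)
    f2 <- withr::local_tempfile(fileext = ext)
    write_band_matrix(back, f2)
    expect_identical(readLines(f2), readLines(f))
  }
})

test_that("polymorphism summary counts bands by definition", {
  # one primer with presence frequencies 0, 0.5, 1: only the middle band is
  # polymorphic
  v <- rbind(c(0, 1, 1), c(0, 0, 1))
  bm <- tiny_bm(v)
  ps <- polymorphism_summary(bm)
  expect_equal(ps$TNB, 3L)
  expect_equal(ps$NPB, 1L)
  expect_equal(ps$PPB, 100 / 3)

  # fully polymorphic panel
  bm2 <- tiny_bm(rbind(c(1, 0), c(0, 1)))
  expect_equal(polymorphism_summary(bm2)$PPB, 100)

  # single monomorphic band
  bm3 <- tiny_bm(cbind(c(1, 1)))
  expect_equal(polymorphism_summary(bm3)$NPB, 0L)
  expect_equal(polymorphism_summary(bm3)$PPB, 0)

  expect_error(polymorphism_summary(bm3[1, ]), "at least 2 samples")
})

test_that("summary invariants: TNB sums to band total, PPB order-invariant", {
  set.seed(101)
  for (rep in 1:5) {
    bm <- random_bm(8, 20, per_primer = 4)
    ps <- polymorphism_summary(bm)
    expect_identical(sum(ps$TNB), ncol(bm$values))
    # reorder samples and bands within primers
    perm_s <- sample(nrow(bm$values))
    perm_b <- unlist(lapply(unique(bm$band_primer), function(p)
      sample(which(bm$band_primer == p))))
    bm2 <- bm[perm_s, perm_b]
    ps2 <- polymorphism_summary(bm2)
    expect_equal(ps2[order(ps2$primer), c("TNB", "NPB", "PPB")],
                 ps[order(ps$primer), c("TNB", "NPB", "PPB")],
                 ignore_attr = TRUE)
  }
})

test_that("metadata validation enforces the accession map", {
  md <- data.frame(sample_id = c("a", "b"), accession = c("A1", "A1"),
                   subspecies = c("x", "y"), country = "c", range = "r",
                   climate = "k")
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_metadata(f), "more than one subspecies")
  md$subspecies <- "x"
  write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(read_sample_metadata(f))
  bm <- tiny_bm(matrix(c(1L, 0L), 2, 1, dimnames = list(c("a", "zzz"), "b1")))
  expect_error(read_sample_metadata(f, bm), "zzz")
})
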
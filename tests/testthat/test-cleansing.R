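test_that("iterative outlier removal follows the z-score arithmetic", {
  # [0 x 9, 100]: population sd 30, z(100) = 3 > 2 -> dropped in one pass
  res <- remove_outliers(c(rep(0, 9), 100))
  expect_equal(res$values, rep(0, 9))
  expect_equal(res$indices, 1:9)
  expect_equal(res$n_iterations, 1L)

  # all-equal input: unchanged, warning
  expect_warning(res2 <- remove_outliers(rep(7, 20)), "identical")
  expect_equal(res2$values, rep(7, 20))
  expect_equal(res2$n_iterations, 0L)
})

test_that("injected extreme outliers are always removed", {
  g <- gen_outlier_sample(n = 10000, seed = 61, n_outliers = 50,
                          magnitude = 10)
  res <- remove_outliers(g$x)
  expect_length(intersect(res$indices, g$truth_indices), 0L)
  # the kept set satisfies its own z bound
  z <- abs(res$values - mean(res$values)) /
    sqrt(mean((res$values - mean(res$values))^2))
  expect_lte(max(z), 2)
  expect_false(res$min_keep_hit)
})

test_that("min_keep bounds the removal and is reported", {
  x <- c(rnorm(20), seq(100, 1000, length.out = 20))
  res <- remove_outliers(x, z_thresh = 0.5, min_keep = 30)
  expect_gte(length(res$indices), 30L)
  x2 <- c(rep(0, 5), 1:20 * 100)
  res2 <- remove_outliers(x2, z_thresh = 0.1, min_keep = 20)
  expect_equal(length(res2$indices), 20L)
  expect_true(res2$min_keep_hit)
  expect_error(remove_outliers(1:10, min_keep = 10), "below length")
})

test_that("kept set is a subset and grows with the threshold", {
  set.seed(62)
  x <- rnorm(500, sd = 3) + c(rep(0, 490), rep(30, 10))
  prev <- integer(0)
  for (z in c(1.5, 2, 3, 5)) {
    res <- remove_outliers(x, z_thresh = z)
    expect_true(all(res$indices %in% seq_along(x)))
    expect_gte(length(res$indices), 0.2 * length(x))
    if (length(prev)) expect_true(all(prev %in% res$indices))
    prev <- res$indices
  }
})

test_that("a variance-inflated channel is flagged, identical channels are not", {
  g <- gen_multichannel(n_channels = 32, seed = 63, bad = 11L, factor = 5)
  rep_ <- identify_bad_channels(g$rec, band = c(4, 30))
  expect_identical(rep_$bad, g$truth)
  expect_gt(abs(rep_$power_z[11]), 3)

  flat <- recording(matrix(rep(sin(1:1000 / 10), each = 32), nrow = 32,
                           byrow = FALSE), fs = 100)
  expect_warning(r2 <- identify_bad_channels(flat, c(4, 30)), "identical")
  expect_no_flags(r2)

  g2 <- gen_multichannel(n_channels = 16, seed = 64, bad = 2L, factor = 8)
  r3 <- identify_bad_channels(g2$rec, c(4, 30), z_thresh = 1e9)
  expect_no_flags(r3)
})

test_that("overrides beat the z-score and are recorded", {
  g <- gen_multichannel(n_channels = 16, seed = 65, bad = 4L, factor = 6)
  rep_ <- identify_bad_channels(g$rec, c(4, 30),
                                overrides = c(ch4 = "good", ch9 = "bad"))
  expect_false("ch4" %in% rep_$bad)
  expect_true("ch9" %in% rep_$bad)
  td <- tidy(rep_)
  expect_equal(td$source[td$channel %in% c("ch4", "ch9")],
               c("override", "override"))
  expect_error(identify_bad_channels(g$rec, c(4, 30),
                                     overrides = c(zz = "bad")), "unknown")
  expect_error(identify_bad_channels(g$rec, c(4, 30),
                                     overrides = c(ch1 = "meh")), "good")
})

test_that("bad-channel detection is permutation-equivariant", {
  g <- gen_multichannel(n_channels = 12, seed = 66, bad = c(3L, 8L),
                        factor = 5)
  rep_a <- identify_bad_channels(g$rec, c(4, 30))
  perm <- sample(12)
  permuted <- recording(g$rec$data[perm, ], fs = g$rec$fs,
                        labels = g$rec$labels[perm])
  rep_b <- identify_bad_channels(permuted, c(4, 30))
  expect_setequal(rep_b$bad, rep_a$bad)
  expect_equal(rep_b$power_z, rep_a$power_z[perm], tolerance = 1e-12)
})

test_that("channel restoration averages neighbors in the stated order", {
  # chain A-B-C, B bad
  adj3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  rec3 <- recording(rbind(rep(1, 10), rnorm(10), rep(3, 10)), fs = 10,
                    labels = c("A", "B", "C"))
  out <- restore_channels(rec3, "B", adj3)
  expect_equal(out$data[2, ], rep(2, 10))
  expect_identical(out$data[c(1, 3), ], rec3$data[c(1, 3), ])

  # chain A-B-C-D, B and C bad: tie on good-neighbor count -> B (lower
  # index) first, so B = A = 1, then C = mean(B_restored, D) = 3
  adj4 <- matrix(0, 4, 4)
  adj4[cbind(1:3, 2:4)] <- 1
  adj4 <- adj4 + t(adj4)
  rec4 <- recording(rbind(rep(1, 8), rnorm(8), rnorm(8), rep(5, 8)),
                    fs = 10, labels = c("A", "B", "C", "D"))
  out4 <- restore_channels(rec4, c("B", "C"), adj4)
  expect_equal(out4$data[2, ], rep(1, 8))
  expect_equal(out4$data[3, ], rep(3, 8))

  # isolated bad pair with no good neighbor anywhere -> error names them
  adj_iso <- matrix(0, 3, 3)
  adj_iso[1, 2] <- adj_iso[2, 1] <- 1
  rec_iso <- recording(matrix(rnorm(30), 3), fs = 10)
  expect_error(restore_channels(rec_iso, c("ch1", "ch2"), adj_iso),
               "unrestorable.*ch1, ch2")
  expect_error(restore_channels(rec3, "Z", adj3), "unknown")
  expect_error(restore_channels(rec3, "B", matrix(0:1, 2, 2)[c(1, 2, 1), c(1, 2, 1)]),
               "symmetric|dimensions|diagonal")
})

test_that("adjacency matrices round-trip through CSV with validation", {
  adj <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  dimnames(adj) <- list(c("A", "B", "C"), c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(adj, path)
  back <- read_adjacency(path)
  expect_equal(unname(back * 1), unname(adj))
  bad <- adj; bad[1, 1] <- 1
  expect_error(write_adjacency(bad, path), "diagonal")
})
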
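# Synthetic data generation, image thresholding, IDX reading, event
# framing and weight-map rendering.

test_that("pattern generator follows the prototype/bit-flip model", {
  ps0 <- synth_patterns(noise = 0, n_per_class = 6, seed = 1)
  for (mu in 1:4) {
    rows <- which(ps0$labels == mu)
    for (i in seq_along(rows)) {
      proto <- ps0$prototypes[[mu]][((i - 1) %% 2) + 1, ]
      expect_equal(unname(ps0$X[rows[i], ]), proto)
    }
  }
  # flip statistics: Hamming distance to prototype ~ Binomial(d, noise)
  ps <- synth_patterns(n_classes = 2, d = 100, n_per_class = 200,
                       prototypes = 1, noise = 0.1, seed = 2)
  dist <- vapply(seq_len(nrow(ps$X)), function(p)
    sum(ps$X[p, ] != ps$prototypes[[ps$labels[p]]][1, ]), numeric(1))
  expect_lt(abs(mean(dist) - 10), 3 * sqrt(100 * 0.1 * 0.9 / length(dist)))
  # determinism under a seed
  a <- synth_patterns(seed = 33); b <- synth_patterns(seed = 33)
  expect_identical(a, b)
  expect_error(synth_patterns(noise = 0.6), "noise")
  # per-class sample counts and noise levels
  ph <- synth_patterns(n_per_class = c(10, 5, 5, 5), noise = c(0.3, 0, 0, 0),
                       prototypes = 1, seed = 9)
  expect_equal(unname(table(ph$labels)), c(10, 5, 5, 5), ignore_attr = TRUE)
  clean <- ph$X[ph$labels == 2, ]
  expect_true(all(clean == matrix(ph$prototypes[[2]][1, ], 5, 64, byrow = TRUE)))
})

test_that("image thresholding flattens row-major at the requested cut", {
  img <- matrix(0, 28, 28)
  expect_equal(sum(threshold_image(img, 0.5)), 0)
  expect_length(threshold_image(img), 784)
  img[2, 2] <- 10                      # row 2, col 2 -> index 29 + 1 = 30
  v <- threshold_image(img, 5)
  expect_equal(which(v == 1), (2 - 1) * 28 + 2)
  expect_equal(sum(threshold_image(img, max(img))), 0)
})

test_that("IDX reader decodes images and labels written in the binary format", {
  # write a tiny 2-image IDX file and a label file, then read them back
  imgs <- list(matrix(as.integer(0:24 %% 256), 5, 5, byrow = TRUE),
               matrix(200L, 5, 5))
  path_i <- tempfile(); path_l <- tempfile()
  con <- file(path_i, "wb")
  writeBin(as.integer(c(0, 0, 8, 3)), con, size = 1)
  writeBin(c(2L, 5L, 5L), con, size = 4, endian = "big")
  for (im in imgs) writeBin(as.integer(t(im)), con, size = 1)
  close(con)
  con <- file(path_l, "wb")
  writeBin(as.integer(c(0, 0, 8, 1)), con, size = 1)
  writeBin(2L, con, size = 4, endian = "big")
  writeBin(c(3L, 7L), con, size = 1)
  close(con)
  got <- read_idx(path_i)
  expect_length(got, 2)
  expect_equal(got[[1]], imgs[[1]])
  expect_equal(got[[2]], imgs[[2]])
  expect_equal(read_idx(path_l), c(3L, 7L))
})

test_that("event framing conserves counts and respects the window", {
  img <- matrix(0, 8, 8); img[3, 5] <- 6
  ev <- synth_events(img, duration = 1000, seed = 5)
  frame <- events_to_frame(ev)
  expect_equal(sum(frame), nrow(ev))
  expect_equal(sum(frame[-3, ]), 0)
  expect_equal(sum(frame[, -5]), 0)
  # empty stream gives the zero image
  e0 <- synth_events(matrix(0, 4, 4), duration = 100, seed = 6)
  expect_equal(sum(events_to_frame(e0)), 0)
  # a window keeps exactly the in-window events
  half <- events_to_frame(ev, window = c(0, 500))
  expect_equal(sum(half), sum(ev$t <= 500))
  expect_error(events_to_frame(ev, window = c(5, 5)), "empty")
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$x, ev$x)
  expect_equal(back$t, ev$t, tolerance = 1e-8)
  expect_equal(attr(back, "dims"), attr(ev, "dims"))
})

test_that("max-activity cropping agrees with a brute-force scan", {
  brute <- function(frame, patch) {
    best <- -Inf; br <- 1; bc <- 1
    for (r in seq_len(nrow(frame) - patch + 1)) {
      for (cc in seq_len(ncol(frame) - patch + 1)) {
        tot <- sum(frame[r:(r + patch - 1), cc:(cc + patch - 1)])
        if (tot > best) { best <- tot; br <- r; bc <- cc }
      }
    }
    list(row = br, col = bc, total = best)
  }
  set.seed(111)
  for (i in 1:20) {
    frame <- matrix(rpois(256, 1), 16, 16)
    patch <- sample(c(2, 3, 5), 1)
    got <- crop_max_activity(frame, patch)
    want <- brute(frame, patch)
    expect_equal(got[c("row", "col", "total")], want)
  }
  # ties resolve top-left; whole-image patch is the identity
  uni <- matrix(1, 6, 6)
  expect_equal(crop_max_activity(uni, 3)[c("row", "col")], list(row = 1, col = 1))
  expect_equal(crop_max_activity(uni, 6)$patch, uni)
  # a single hot pixel is inside the winning patch
  hot <- matrix(0, 16, 16); hot[9, 4] <- 5
  got <- crop_max_activity(hot, 3)
  expect_true(got$row <= 9 && 9 <= got$row + 2)
  expect_true(got$col <= 4 && 4 <= got$col + 2)
  expect_error(crop_max_activity(hot, 20), "larger")
})

test_that("weight maps reshape row-major and average dendrite rows", {
  w <- numeric(784); w[30] <- 3          # 0-based afferent 29
  mp <- render_weight_map(w, 28)
  expect_equal(mp[2, 2], 3)
  expect_equal(sum(mp), 3)
  expect_equal(render_weight_map(numeric(16)), matrix(0, 4, 4))
  W <- rbind(w, w, w)
  expect_equal(render_weight_map(W, 28), mp)
  expect_error(render_weight_map(numeric(10)), "compatible")
})
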
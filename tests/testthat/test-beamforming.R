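test_that("focusing on an equidistant point returns the common signal", {
  # four mics on a square, focus on the axis: zero relative delays
  g <- array_geometry(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
  withr::with_seed(3, s <- rnorm(4000))
  rec <- as_recording(matrix(s, 4000, 4), 8000)
  bf <- delay_and_sum(rec, g, c(0, 0, 6))
  expect_equal(bf$samples, s, tolerance = 1e-12)
})

test_that("delay-and-sum matches the shift-and-average oracle on integer delays", {
  fs <- 8000
  v <- 343
  withr::with_seed(4, src <- rnorm(3000))
  for (rep in 1:3) {
    d_int <- withr::with_seed(rep, sort(sample(1:40, 5)))   # samples
    x <- matrix(0, 3200, 5)
    for (j in 1:5) x[d_int[j] + seq_along(src), j] <- src
    # mics placed so that run times equal those integer delays
    g <- array_geometry(cbind(0, 0, -d_int * v / fs))
    rec <- as_recording(x, fs)
    bf <- delay_and_sum(rec, g, c(0, 0, 0))
    # oracle: advance each channel by its relative integer delay, average
    oracle <- shift_average(x, d_int - min(d_int))
    interior <- 100:2800
    expect_lt(max(abs(bf$samples[interior] - oracle[interior])) /
                max(abs(oracle)), 1e-6)
    # and the focused output reproduces the source (shifted by min delay)
    expect_lt(max(abs(bf$samples[min(d_int) + (100:2800)] - src[100:2800])) /
                max(abs(src)), 1e-6)
  }
})

test_that("off-source focus loses coherent energy", {
  cl <- test_call(0.7, 27, duration = 1, seed = 6, sample_rate = 8000)
  row <- dplyr::mutate(sample_call_population(0, 1, seed = 2),
                       call = list(cl))
  sc <- single_call_scene(row, noise_spl = -Inf)
  sim <- simulate_scene(sc, seed = 1)
  on <- delay_and_sum(sim$rec, sc$array, c(sim$truth$x, sim$truth$y, sim$truth$z),
                      sc$propagation, window = c(0.3, 0.8))
  off <- delay_and_sum(sim$rec, sc$array, c(1.8, -1.2, 8),
                       sc$propagation, window = c(0.3, 0.8))
  expect_lt(sqrt(mean(off$samples^2)), sqrt(mean(on$samples^2)))
})

test_that("effective SPL follows the closed form and is linear in amplitude", {
  t <- (0:47999) / 48000
  s <- sin(2 * pi * 100 * t)                     # 1 Pa amplitude
  expect_equal(effective_spl(s), 20 * log10((1 / sqrt(2)) / 20e-6),
               tolerance = 1e-4)
  expect_equal(round(effective_spl(s), 2), 90.97)
  expect_equal(effective_spl(2 * s) - effective_spl(s), 20 * log10(2),
               tolerance = 1e-6)
  expect_identical(effective_spl(numeric(100)), -Inf)
})

test_that("acoustic maps localize a single source and scale linearly", {
  row <- dplyr::mutate(sample_call_population(1, 0, seed = 12),
                       call = list(test_call(2.0, 20, duration = 1.2, spl = 60,
                                             seed = 7, sample_rate = 8000)))
  sc <- single_call_scene(row, noise_spl = 30)
  sim <- simulate_scene(sc, seed = 2)
  mp <- acoustic_map(sim$rec, sc$array, sc$plane, sc$propagation,
                     window = c(0.35, 0.85), highpass = 100)
  cell <- sqrt((sc$plane$width / (sc$plane$nx - 1))^2 +
                 (sc$plane$height / (sc$plane$ny - 1))^2)
  expect_lt(sqrt((mp$peak$x - sim$truth$x)^2 + (mp$peak$y - sim$truth$y)^2),
            cell + 1e-9)
  expect_equal(mp$peak$spl, max(mp$grid$spl))

  # doubling all channel amplitudes lifts every pixel by 6.02 dB
  rec2 <- as_recording(sim$rec$samples * 2, sim$rec$sample_rate)
  mp2 <- acoustic_map(rec2, sc$array, sc$plane, sc$propagation,
                      window = c(0.35, 0.85), highpass = 100)
  expect_equal(mp2$grid$spl - mp$grid$spl,
               rep(20 * log10(2), nrow(mp$grid)), tolerance = 1e-6)
})

test_that("lag-domain and direct map computations agree", {
  row <- dplyr::mutate(sample_call_population(0, 1, seed = 13),
                       call = list(test_call(0.7, 27, duration = 1, spl = 70,
                                             seed = 8, sample_rate = 8000)))
  sc <- single_call_scene(row, noise_spl = 40, nx = 8, ny = 6)
  sim <- simulate_scene(sc, seed = 3)
  m1 <- acoustic_map(sim$rec, sc$array, sc$plane, sc$propagation,
                     window = c(0.3, 0.8), method = "lag")
  m2 <- acoustic_map(sim$rec, sc$array, sc$plane, sc$propagation,
                     window = c(0.3, 0.8), method = "direct")
  expect_lt(max(abs(m1$grid$spl - m2$grid$spl)), 0.15)
  expect_equal(which.max(m1$grid$spl), which.max(m2$grid$spl))
})

test_that("movie frame counts follow the frame rate", {
  rec <- as_recording(matrix(sin(2 * pi * 150 * (1:16000) / 8000), 16000, 2), 8000)
  g <- array_geometry(rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))
  pl <- image_plane(nx = 3, ny = 2)
  f25 <- movie_frames(rec, g, pl, frame_rate = 25)
  expect_length(f25, 50)
  expect_length(movie_frames(rec, g, pl, frame_rate = 5), 10)
  # stationary signal: all frames equal within tolerance
  peaks <- vapply(f25, function(f) f$peak$spl, numeric(1))
  expect_lt(diff(range(peaks[2:49])), 0.1)
  expect_error(movie_frames(rec, g, pl, frame_rate = 0), "positive")
})

test_that("emission allocation follows the peak/disk/margin rule", {
  fake_map <- function(spl_at, base = 30, bump = 10) {
    pl <- image_plane(nx = 21, ny = 15)
    grid <- plane_grid(pl)
    grid$spl <- base
    i <- which.min((grid$x - spl_at[1])^2 + (grid$y - spl_at[2])^2)
    grid$spl[i] <- base + bump
    structure(list(grid = grid, plane = pl, window = c(0, 1),
                   peak = as.list(grid[which.max(grid$spl),
                                       c("ix", "iy", "x", "y", "spl")])),
              class = "acoustic_map")
  }
  nasal_pos <- c(0, -0.4); oral_pos <- c(0, 0.4)
  expect_equal(classify_emission(fake_map(nasal_pos), nasal_pos, oral_pos)$label,
               "nasal")
  expect_equal(classify_emission(fake_map(oral_pos), nasal_pos, oral_pos)$label,
               "oral")
  expect_equal(classify_emission(fake_map(c(1.8, 1.2)), nasal_pos, oral_pos)$label,
               "ambiguous")
  # sub-margin contrast is ambiguous even when the peak sits in a disk
  expect_equal(classify_emission(fake_map(nasal_pos, bump = 0.01),
                                 nasal_pos, oral_pos)$label, "ambiguous")
  expect_error(classify_emission(fake_map(nasal_pos), c(0, -0.1), c(0, 0.1)),
               "overlap")
})

test_that("diffuse noise-only scenes are not allocated", {
  g <- build_star_array()
  pl <- image_plane(nx = 16, ny = 12)
  x <- withr::with_seed(9, matrix(rnorm(8000 * 48, 0, rumblecam:::db_to_pa(40)),
                                  8000, 48))
  rec <- as_recording(x, 8000)
  mp <- acoustic_map(rec, g, pl, window = c(0.1, 0.9), highpass = 100)
  out <- classify_emission(mp, c(0, -0.4, 8), c(0, 0.4, 8))
  expect_equal(out$label, "ambiguous")
  # diffuse field: low spatial contrast
  expect_lt(mp$peak$spl - median(mp$grid$spl), 3)
})

test_that("peak call SPL reads the mid-call frame and recovers calibration", {
  row <- dplyr::mutate(sample_call_population(1, 0, seed = 14),
                       call = list(test_call(2.0, 20, duration = 1.2, spl = 52,
                                             seed = 15, sample_rate = 8000)))
  sc <- single_call_scene(row, noise_spl = 20, nx = 6, ny = 5)
  sim <- simulate_scene(sc, seed = 4)
  frames <- movie_frames(sim$rec, sc$array, sc$plane, sc$propagation,
                         frame_rate = 5)
  got <- peak_call_spl(frames, c(0, sim$truth$duration))
  expect_lt(abs(got - 52), 1.5)
  expect_error(peak_call_spl(frames, c(100, 101)), "midpoint")
})
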
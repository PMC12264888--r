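test_that("region table satisfies the homotopic-atlas invariants", {
  for (n in c(8, 48, 384)) {
    rt <- region_table(n)
    expect_equal(nrow(rt), n)
    expect_equal(as.vector(table(rt$hemisphere)), c(n / 2, n / 2))
    expect_setequal(rt$index, 0:(n - 1))
    # homotope mapping is an involution across hemispheres
    mt <- match(rt$homotope_id, rt$region_id)
    expect_true(all(rt$hemisphere[mt] != rt$hemisphere))
    expect_equal(rt$homotope_id[mt], rt$region_id)
  }
  expect_error(region_table(7), "even")
  bad <- region_table(8)
  bad$homotope_id[1] <- 2       # left region pointing at a left region
  expect_error(validate_region_table(bad), "hemisphere|bijection|involution")
})

test_that("fixture parcellation tiles the grid with mirrored equal blocks", {
  rt <- region_table(8)
  vol <- build_parcellation_volume(rt, dim = c(8L, 8L, 8L))
  counts <- table(vol)
  expect_equal(length(counts), 8L)
  expect_true(all(counts == 512 / 8))
  # right-hemisphere block of a region is the x-mirror of its homotope
  left1 <- which(vol == 1, arr.ind = TRUE)
  homo1 <- rt$homotope_id[rt$region_id == 1]
  mirrored <- left1
  mirrored[, 1] <- dim(vol)[1] + 1 - left1[, 1]
  expect_true(all(vol[mirrored] == homo1))
})

test_that("regional damage extraction matches a brute-force voxel loop", {
  rt <- region_table(8)
  parc <- build_parcellation_volume(rt, dim = c(8L, 8L, 8L))
  # empty lesion
  expect_equal(unname(region_damage_from_mask(array(0, dim(parc)), parc, rt)),
               rep(0, 8))
  # mask exactly covering region 3
  mask <- array(0, dim(parc)); mask[parc == 3] <- 1
  d <- region_damage_from_mask(mask, parc, rt)
  expect_equal(unname(d[rt$name[rt$region_id == 3]]), 100)
  expect_equal(sum(d), 100)
  # half of region 3 at value 1 -> 50%
  vox <- which(parc == 3)
  mask2 <- array(0, dim(parc)); mask2[vox[seq_len(length(vox) / 2)]] <- 1
  d2 <- region_damage_from_mask(mask2, parc, rt)
  expect_equal(unname(d2[rt$name[rt$region_id == 3]]), 50)
  # probabilistic mask vs explicit voxel loop, exact agreement
  set.seed(5)
  pm <- array(runif(length(parc)), dim(parc))
  dp <- region_damage_from_mask(pm, parc, rt)
  brute <- sapply(rt$region_id[order(rt$index)], function(id) {
    s <- 0; cnt <- 0
    for (v in seq_along(parc)) {
      if (parc[v] == id) { s <- s + pm[v]; cnt <- cnt + 1 }
    }
    100 * s / cnt
  })
  expect_equal(unname(dp), unname(brute))
  expect_true(all(dp >= 0 & dp <= 100))
  # error contracts
  expect_error(region_damage_from_mask(array(0, c(4, 4, 4)), parc, rt),
               "grid")
  parc2 <- parc; parc2[parc2 == 5] <- 1
  expect_error(region_damage_from_mask(mask, parc2, rt), "absent.*5")
})

test_that("connectome vectorization is a row-major bijection off the diagonal", {
  A3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  expect_equal(as.vector(vectorize_connectome(A3)), c(1, 2, 3))
  # row-major order distinguishes itself at n = 4
  A4 <- matrix(0, 4, 4)
  pr <- upper_pairs(4)
  A4[pr] <- 1:6; A4 <- A4 + t(A4)
  expect_equal(as.vector(vectorize_connectome(A4)), 1:6)
  expect_equal(pr[2, ], c(i = 1, j = 3))   # (1,2),(1,3),(1,4),(2,3)...
  # roundtrip property over random symmetric matrices
  set.seed(11)
  for (n in c(5, 17, 40)) {
    M <- matrix(rnorm(n * n), n, n); M <- M + t(M)
    v <- vectorize_connectome(M)
    expect_length(v, n * (n - 1) / 2)
    back <- devectorize_connectome(v, n)
    expect_equal(back[upper.tri(back)], M[upper.tri(M)])
    expect_equal(back, t(back))
  }
  expect_equal(length(vectorize_connectome(diag(384) * 0)), 73536)
  # asymmetry beyond tolerance errors with the magnitude
  B <- matrix(rnorm(9), 3, 3)
  expect_error(vectorize_connectome(B), "asymmetric")
})

test_that("TIV normalization divides and is scale invariant", {
  expect_equal(tiv_normalize(c(150, 300), 1500), c(0.1, 0.2))
  expect_error(tiv_normalize(c(1, 2), 0), "positive")
  expect_error(tiv_normalize(c(1, 2), -3), "positive")
  set.seed(2)
  v <- runif(10, 1, 100); k <- runif(1, 0.1, 10); t <- 1234
  expect_equal(tiv_normalize(k * v, k * t), tiv_normalize(v, t))
})

test_that("pALF is the banded share of the amplitude spectrum", {
  n <- 200; dt <- 1                      # Nyquist 0.5 Hz, bin width 0.005
  tt <- seq_len(n)
  inband <- sin(2 * pi * 0.02 * tt)      # 0.02 Hz, inside 0.01-0.08
  outband <- sin(2 * pi * 0.2 * tt)
  expect_gt(palf_ratio(cbind(inband), dt), 0.99)
  expect_lt(palf_ratio(cbind(outband), dt), 0.01)
  # two equal tones, one in / one out -> 0.5, checked against a direct
  # discrete-spectrum oracle
  two <- inband + outband
  r <- palf_ratio(cbind(two), dt)
  amp <- Mod(fft(two))[2:(n / 2 + 1)]
  freqs <- (1:(n / 2)) / (n * dt)
  oracle <- sum(amp[freqs >= 0.01 & freqs <= 0.08]) / sum(amp)
  expect_equal(unname(r), oracle)
  expect_equal(unname(r), 0.5, tolerance = 1e-6)
  # bounded in [0,1] and invariant to positive rescaling of the series
  set.seed(3)
  TS <- matrix(rnorm(n * 4), n, 4)
  r1 <- palf_ratio(TS, dt)
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_equal(palf_ratio(37.5 * TS, dt), r1)
  expect_error(palf_ratio(TS, dt, band = c(0.1, 0.6)), "Nyquist")
  expect_error(palf_ratio(TS[1, , drop = FALSE], dt), "2 time points")
})

test_that("dataset assembly intersects, aligns and reports subjects", {
  m1 <- matrix(1:8, 4, 2, dimnames = list(c("A", "B", "C", "E"), c("r1", "r2")))
  m2 <- matrix(11:18, 4, 2, dimnames = list(c("B", "C", "D", "E"), c("r1", "r2")))
  beh <- data.frame(subject_id = c("A", "B", "C", "D", "E"),
                    spontaneous_speech = 1:5, naming = 1:5,
                    repetition = 1:5, auditory_comprehension = 1:5)
  out <- assemble_dataset(list(lesion = m1, md = m2), beh)
  expect_equal(out$report$subjects, c("B", "C", "E"))
  expect_equal(out$report$dropped$lesion, "A")
  expect_equal(out$report$dropped$md, "D")
  expect_equal(rownames(out$modalities$lesion), c("B", "C", "E"))
  # too small an intersection is an error
  expect_error(assemble_dataset(list(lesion = m1[c(1, 2), ], md = m2), beh),
               "fewer than 3")
  # identical ids: order preserved
  out2 <- assemble_dataset(list(a = m1, b = m1), beh[c(1:3, 5), ])
  expect_equal(out2$report$subjects, c("A", "B", "C", "E"))
  # shuffled rows stay aligned: sentinel subject carries a marked value
  m3 <- m1[c("C", "A", "E", "B"), ]
  m3["B", "r1"] <- 999
  out3 <- assemble_dataset(list(a = m1, b = m3), beh[c(1:3, 5), ])
  expect_equal(out3$modalities$b["B", "r1"], 999)
  expect_equal(rownames(out3$modalities$a), rownames(out3$modalities$b))
  # contracts
  dup <- rbind(beh, beh[1, ])
  expect_error(assemble_dataset(list(a = m1), dup), "duplicate")
  m4 <- matrix(1, 2, 2, dimnames = list(c("X", "Y"), c("r1", "r2")))
  expect_error(assemble_dataset(list(a = m1, b = m4), beh), "no subjects")
})
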
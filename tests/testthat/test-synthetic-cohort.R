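test_that("AQ scoring rule doubles the subtest sum and respects bounds", {
  expect_equal(aq_score(0, 0, 0, 0), 0)
  expect_equal(aq_score(20, 10, 10, 10), 100)
  expect_equal(aq_score(c(10, 5), c(5, 2), c(5, 2), c(5, 1)), c(50, 20))
  expect_error(aq_score(21, 5, 5, 5), "spontaneous_speech")
  expect_error(aq_score(10, -1, 5, 5), "naming")
})

test_that("behaviour generator hits its calibration targets at large n", {
  spec <- cohort_spec()
  beh <- generate_behaviour(spec, n = 5000, seed = 1)
  sc <- beh$scores
  tg <- subtest_targets_default()
  expect_true(all(sc >= 0))
  expect_true(all(sweep(sc, 2, tg$max, "<=")))
  expect_lt(abs(mean(sc[, 1]) - 11.4), 0.25)
  expect_true(all(abs(colMeans(sc) - tg$mean) / tg$mean < 0.02))
  cc <- cor(sc)
  expect_true(all(abs(cc[upper.tri(cc)] -
                        subtest_correlations_default()[upper.tri(cc)]) < 0.03))
  # deterministic under a fixed seed
  beh2 <- generate_behaviour(spec, n = 5000, seed = 1)
  expect_identical(beh$scores, beh2$scores)
  expect_identical(beh$severity, beh2$severity)
})

test_that("identity correlation target yields independent subtests", {
  spec <- cohort_spec(subtest_correlations = diag(4))
  sc <- generate_behaviour(spec, n = 5000, seed = 2)$scores
  cc <- cor(sc)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.05))
})

test_that("severity links lesion extent, and extremes behave as designed", {
  spec <- small_spec(seed = 4, noise = noiseless_noise())
  # minimal severity, zero noise: empty lesion row
  les <- generate_lesions(spec, severity = c(-Inf, Inf), seed = 1)
  tpos <- match(spec$territory, spec$regions$region_id)
  expect_equal(unname(les$values[1, ]), rep(0, 48))
  # maximal severity: every territory region >= 90% damaged
  expect_true(all(les$values[2, tpos] >= 90))
  expect_true(all(les$values[, -tpos] == 0))
  # cohort level: territory damage tracks severity (n = 500)
  spec2 <- small_spec(seed = 5, n = 500)
  beh <- generate_behaviour(spec2)
  les2 <- generate_lesions(spec2, beh$severity, seed = 6)
  expect_gt(cor(rowMeans(les2$values[, tpos]), beh$severity), 0.7)
  # adjacent territory regions are positively correlated in damage
  adj <- sapply(seq_len(length(tpos) - 1), function(i)
    cor(les2$values[, tpos[i]], les2$values[, tpos[i + 1]]))
  expect_true(all(adj > 0))
})

test_that("derived modalities follow their damage links", {
  spec <- small_spec(seed = 7, n = 6, noise = noiseless_noise())
  zero <- modality_matrix("lesion",
                          matrix(0, 6, 48,
                                 dimnames = list(sprintf("sub-%03d", 1:6),
                                                 spec$regions$name)))
  mods <- derive_modalities(spec, zero, seed = 1)
  bl <- modality_baselines()
  for (r in seq_len(nrow(bl))) {
    m <- bl$modality[r]
    expect_true(all(mods[[m]]$values == bl$base[r]),
                label = paste("healthy baseline for", m))
  }
  expect_true(all(mods$i3mT1$values == 0))
  # full damage of one endpoint region attenuates its edges to <= 10%
  dmg <- zero$values; dmg[, 1] <- 100
  mods2 <- derive_modalities(spec, modality_matrix("lesion", dmg), seed = 1)
  healthy <- mods$sc$values[1, ]
  pr <- upper_pairs(48)
  inc <- pr[, 1] == 1 | pr[, 2] == 1
  expect_true(all(mods2$sc$values[1, inc] <= 0.1 * healthy[inc]))
  # monotone links over a cohort: MD rises, FA falls with damage (n = 500)
  spec3 <- small_spec(seed = 8, n = 500)
  beh <- generate_behaviour(spec3)
  les <- generate_lesions(spec3, beh$severity, seed = 2)
  mods3 <- derive_modalities(spec3, les, seed = 3)
  tpos <- match(spec3$territory, spec3$regions$region_id)
  for (j in tpos[1:6]) {
    expect_gt(cor(les$values[, j], mods3$md$values[, j]), 0)
    expect_lt(cor(les$values[, j], mods3$fa$values[, j]), 0)
  }
  expect_error(modality_matrix("nope", matrix(0, 2, 2)), "unknown modality")
})

test_that("planted unique effects act on the right subtest residual", {
  spec <- small_spec(seed = 9, n = 500)
  co <- generate_cohort(spec)
  rt <- spec$regions
  sc <- co$behaviour$scores
  sev <- co$ground_truth$severity
  # partial correlation (controlling severity) of an AC-unique MD feature
  # is strongest with AC
  ac_region <- rt$name[match(spec$unique_regions$auditory_comprehension[1],
                             rt$region_id)]
  mdv <- co$modalities$md$values[, ac_region]
  pcor <- function(x, y, z) {
    rx <- residuals(lm(x ~ z)); ry <- residuals(lm(y ~ z))
    cor(rx, ry)
  }
  pc <- sapply(colnames(sc), function(st) pcor(mdv, sc[, st], sev))
  expect_equal(names(which.max(abs(pc))), "auditory_comprehension")
  expect_lt(pc[["auditory_comprehension"]], 0)   # MD up, score down
  # zero unique effect leaves the residual uncorrelated
  spec0 <- small_spec(seed = 10, n = 500,
                      effect_sizes = list(shared = 0.5,
                                          unique = c(spontaneous_speech = 0,
                                                     naming = 0,
                                                     repetition = 0,
                                                     auditory_comprehension = 0)))
  co0 <- generate_cohort(spec0)
  md0 <- co0$modalities$md$values[, ac_region]
  pc0 <- pcor(md0, co0$behaviour$scores[, "auditory_comprehension"],
              co0$ground_truth$severity)
  expect_lt(abs(pc0), 0.15)
})

test_that("cohorts are reproducible and respect type invariants", {
  spec <- small_spec(seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$behaviour$scores, b$behaviour$scores)
  for (m in names(a$modalities))
    expect_identical(a$modalities[[m]]$values, b$modalities[[m]]$values)
  # range/finiteness invariants across random specifications
  set.seed(77)
  for (i in 1:8) {
    sp <- small_spec(seed = i, n = sample(10:30, 1))
    co <- generate_cohort(sp)
    sc <- co$behaviour$scores
    expect_true(all(is.finite(sc)) && all(sc >= 0) &&
                  all(sweep(sc, 2, sp$subtest_targets$max, "<=")))
    expect_true(all(co$modalities$lesion$values >= 0 &
                      co$modalities$lesion$values <= 100))
    expect_true(all(co$modalities$i3mT1$values >= 0 &
                      co$modalities$i3mT1$values <= 1))
    expect_true(all(abs(co$modalities$fc$values) <= 1))
    expect_true(all(co$modalities$sc$values >= 0))
    for (m in names(co$modalities))
      expect_true(all(is.finite(co$modalities[[m]]$values)), label = m)
  }
  # specification validation holds over many random constructions
  for (i in 1:400) {
    n <- sample(c(8L, 24L, 48L), 1)
    sp <- cohort_spec(n_subjects = sample(5:100, 1),
                      regions = region_table(n), seed = i)
    expect_s3_class(sp, "cohort_spec")
  }
  # invalid targets are rejected
  Rbad <- diag(4); Rbad[1, 2] <- 1.2; Rbad[2, 1] <- 1.2
  expect_error(cohort_spec(subtest_correlations = Rbad), "\\[-1, 1\\]")
  expect_error(cohort_spec(shared_regions = c(1, 2),
                           unique_regions = list(spontaneous_speech = 1,
                                                 naming = 3, repetition = 4,
                                                 auditory_comprehension = 5)),
               "disjoint")
})
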
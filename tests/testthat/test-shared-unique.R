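fake_selection <- function(modality, retained) {
  structure(list(modality = modality, retained = retained,
                 ranking = data.frame(feature = retained,
                                      vip = seq_along(retained) + 1.5,
                                      rank = seq_along(retained))),
            class = "vip_selection")
}

test_that("consensus counting and monotone shrinkage behave", {
  rt <- region_table(8)
  sels <- list(
    lesion = fake_selection("lesion", c("L_R001", "L_R002")),
    md     = fake_selection("md", c("L_R001", "L_R003")),
    fa     = fake_selection("fa", c("L_R001")),
    cbf    = fake_selection("cbf", c("L_R001", "L_R002"))
  )
  cs <- consensus_shared(sels, rt, min_models = 2)
  expect_equal(cs$counts$count[cs$counts$region == "L_R001"], 4L)
  expect_setequal(cs$regions, c("L_R001", "L_R002"))
  # selected in every model -> in every consensus set
  for (t in 1:4)
    expect_true("L_R001" %in% consensus_shared(sels, rt, min_models = t)$regions)
  # impossible threshold -> empty set
  expect_length(consensus_shared(sels, rt, min_models = 5)$regions, 0)
  # monotone: raising the threshold can only shrink the set
  for (t in 1:3)
    expect_true(all(consensus_shared(sels, rt, min_models = t + 1)$regions %in%
                      consensus_shared(sels, rt, min_models = t)$regions))
  expect_error(consensus_shared(sels[1], rt, 2), "at least 2")
})

test_that("edge selections aggregate to regions by incident count", {
  rt <- region_table(8)
  edges <- c("L_R001|L_R002", "L_R001|L_R003", "L_R001|R_R001", "L_R002|R_R002")
  expect_setequal(edge_selection_to_regions(edges, rt, min_incident = 2),
                  c("L_R001", "L_R002"))
  expect_setequal(edge_selection_to_regions(edges, rt, min_incident = 1),
                  c("L_R001", "L_R002", "L_R003", "R_R001", "R_R002"))
  expect_length(edge_selection_to_regions(character(0), rt), 0)
  sels <- list(sc = fake_selection("sc", edges),
               lesion = fake_selection("lesion", "L_R001"))
  cs <- consensus_shared(sels, rt, min_models = 2)
  expect_equal(cs$regions, "L_R001")
})

test_that("identical beta maps across subtests yield no unique regions", {
  set.seed(41)
  rt <- region_table(8)
  X <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, rt$name))
  y <- X %*% rnorm(8) + rnorm(20, 0, 0.2)
  Y4 <- cbind(a = drop(y), b = drop(y), c = drop(y), d = drop(y))
  m <- fit_plsr(X, Y4, n_components = 3)
  uq <- call_unique_regions(list(lesion = m, md = m), rt)
  expect_equal(nrow(uq$map), 0)
})

test_that("single-modality support is excluded at the default threshold", {
  set.seed(42)
  rt <- region_table(8)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, rt$name))
  # one modality where each response has its own driver feature; a
  # second modality carrying no signal at all
  Y <- cbind(a = X[, 2] + rnorm(60, 0, 0.2),
             b = X[, 4] + rnorm(60, 0, 0.2),
             c = X[, 6] + rnorm(60, 0, 0.2),
             d = X[, 8] + rnorm(60, 0, 0.2))
  m_sig <- fit_plsr(X, Y, n_components = 4)
  X0 <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, rt$name))
  m_noise <- fit_plsr(X0, Y, n_components = 4)
  uq1 <- call_unique_regions(list(md = m_sig, fa = m_noise), rt,
                             min_modalities = 2)
  expect_false("L_R002" %in% uq1$map$region &&
                 any(uq1$map$region == "L_R002" & uq1$map$n_modalities < 2))
  # with the same signal in both modalities the region is called for a
  uq2 <- call_unique_regions(list(md = m_sig, fa = m_sig), rt,
                             min_modalities = 2)
  row <- uq2$map[uq2$map$region == "L_R002", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$subtest, "a")
})

test_that("unique calling is invariant to positive rescaling of feature units", {
  spec <- small_spec(seed = 43, n = 40)
  co <- generate_cohort(spec)
  rt <- spec$regions
  Y <- co$behaviour$scores
  m1 <- fit_plsr(co$modalities$md$values, Y, n_components = 5)
  m2 <- fit_plsr(co$modalities$md$values * 1000, Y, n_components = 5)
  u1 <- call_unique_regions(list(md = m1, fa = m1), rt)
  u2 <- call_unique_regions(list(md = m2, fa = m2), rt)
  expect_equal(u1$map, u2$map)
  expect_equal(u1$support, u2$support)
})

test_that("all-zero beta matrices are skipped with a warning", {
  set.seed(44)
  rt <- region_table(8)
  X <- matrix(rnorm(160), 20, 8, dimnames = list(NULL, rt$name))
  Y <- cbind(a = rnorm(20), b = rnorm(20), c = rnorm(20), d = rnorm(20))
  m <- fit_plsr(X, Y, n_components = 2)
  m0 <- m
  m0$W[] <- 0; m0$Q[] <- 0   # degenerate model
  w <- capture_warnings(uq <- call_unique_regions(list(md = m, fa = m0), rt))
  expect_true(any(grepl("all-zero", w)))
  expect_error(suppressWarnings(call_unique_regions(list(fa = m0), rt)),
               "no usable")
})

test_that("residual variance decomposition matches the normal equations", {
  set.seed(45)
  n <- 6
  lesion <- matrix(runif(n * 3, 0, 80), n, 3,
                   dimnames = list(sprintf("s%d", 1:n), c("A", "B", "C")))
  md <- matrix(rnorm(n * 2, 1, 0.2), n, 2,
               dimnames = list(rownames(lesion), c("U1", "U2")))
  Y <- cbind(spontaneous_speech = rnorm(n, 10, 3),
             naming = rnorm(n, 5, 2),
             repetition = rnorm(n, 5, 2),
             auditory_comprehension = rnorm(n, 7, 1.5))
  rownames(Y) <- rownames(lesion)
  cohort <- list(modalities = list(lesion = modality_matrix("lesion", lesion),
                                   md = modality_matrix("md", md)),
                 behaviour = data.frame(subject_id = rownames(Y), Y))
  map <- data.frame(region = c("U1", "U2"),
                    subtest = c("naming", "naming"),
                    n_modalities = c(2L, 2L))
  vd <- residual_variance_analysis(cohort, c("A", "B"), map)
  # closed-form normal-equations oracle for stage 1
  M <- cbind(1, lesion[, c("A", "B")] / 100)
  for (j in 1:4) {
    y <- Y[, j]
    bh <- solve(crossprod(M), crossprod(M, y))
    res <- y - M %*% bh
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(vd$table$shared_r2[j], r2, tolerance = 1e-10)
    if (colnames(Y)[j] == "naming") {
      Mu <- cbind(1, md)
      bu <- solve(crossprod(Mu), crossprod(Mu, res))
      ru <- res - Mu %*% bu
      dr2 <- 1 - sum(ru^2) / sum((res - mean(res))^2)
      expect_equal(vd$table$unique_delta_r2[j], dr2, tolerance = 1e-10)
    }
  }
  # subtests with no unique regions explain zero extra variance
  expect_equal(vd$table$unique_delta_r2[vd$table$subtest == "repetition"], 0)
})

test_that("orthogonalized unique predictors add no residual variance", {
  set.seed(46)
  n <- 86
  shared <- matrix(runif(n * 4, 0, 100), n, 4,
                   dimnames = list(sprintf("s%d", 1:n), paste0("S", 1:4)))
  y <- shared %*% c(-0.02, -0.03, -0.01, -0.02) + rnorm(n, 10, 1)
  res1 <- residuals(lm(y ~ I(shared / 100)))
  # build MD features orthogonal to the stage-1 residuals
  raw <- matrix(rnorm(n * 3), n, 3)
  mdo <- raw - res1 %*% t(crossprod(raw, res1)) / sum(res1^2)
  colnames(mdo) <- paste0("U", 1:3)
  rownames(mdo) <- rownames(shared)
  Y <- cbind(spontaneous_speech = drop(y), naming = rnorm(n, 5, 2),
             repetition = rnorm(n, 5, 2), auditory_comprehension = rnorm(n, 7, 1))
  cohort <- list(modalities = list(lesion = modality_matrix("lesion", shared),
                                   md = modality_matrix("md", mdo + 2)),
                 behaviour = data.frame(subject_id = rownames(shared), Y))
  map <- data.frame(region = paste0("U", 1:3),
                    subtest = "spontaneous_speech", n_modalities = 2L)
  vd <- residual_variance_analysis(cohort, paste0("S", 1:4), map)
  expect_lt(vd$table$unique_delta_r2[1], 0.02)
})

test_that("collinear shared predictors fall back to a pseudoinverse fit", {
  set.seed(47)
  n <- 20
  a <- runif(n, 0, 80)
  lesion <- cbind(A = a, B = 2 * a, C = runif(n, 0, 80))  # exactly collinear
  rownames(lesion) <- sprintf("s%d", 1:n)
  Y <- cbind(spontaneous_speech = rnorm(n, 10, 3), naming = rnorm(n, 5, 2),
             repetition = rnorm(n, 5, 2), auditory_comprehension = rnorm(n, 7, 1))
  cohort <- list(modalities = list(lesion = modality_matrix("lesion", lesion),
                                   md = modality_matrix("md", lesion * 0.01 + 1)),
                 behaviour = data.frame(subject_id = rownames(lesion), Y))
  map <- data.frame(region = character(0), subtest = character(0),
                    n_modalities = integer(0))
  w <- capture_warnings(
    vd <- residual_variance_analysis(cohort, c("A", "B", "C"), map))
  expect_gte(length(w), 1)
  expect_true(all(grepl("pseudoinverse|ill-conditioned", w)))
  expect_true(all(vd$table$shared_r2 >= 0 & vd$table$shared_r2 <= 1))
})
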
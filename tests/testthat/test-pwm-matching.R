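# PWM construction, Kullback-Leibler divergence, shuffling and matching.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## build a 20 x P intensity matrix concentrated on the given residues
toyIntensities <- function(residues, value = 100) {
  m <- matrix(0, 20, length(residues), dimnames = list(aa20,
              as.character(seq_along(residues))))
  for (j in seq_along(residues)) m[residues[j], j] <- value
  m
}

test_that("intensity-derived PWMs normalize with pseudocount per the scheme", {
  m <- toyIntensities(c("R", "K"))
  pwm <- pwmFromIntensities(m, pseudocount = 0.01)
  expect_equal(colSums(pwmMatrix(pwm)), c(`1` = 1, `2` = 1), tolerance = 1e-12)
  expect_equal(pwmMatrix(pwm)["R", 1], 100.01 / 100.2, tolerance = 1e-12)
  expect_equal(pwmMatrix(pwm)["A", 1], 0.01 / 100.2, tolerance = 1e-12)
  ## worked 3-value column: (2,1,1)+0.01 over its total
  m2 <- m
  m2[c("R", "K", "H"), 1] <- c(2, 1, 1)
  m2[, 2] <- 0
  pwm2 <- pwmFromIntensities(m2, pseudocount = 0.01)
  expect_equal(pwmMatrix(pwm2)["R", 1], 2.01 / 4.2, tolerance = 1e-12)
  ## an all-zero column becomes uniform under pseudocount alone
  expect_equal(unname(pwmMatrix(pwm2)[, 2]), rep(0.05, 20), tolerance = 1e-12)
  expect_error(pwmFromIntensities(m2, pseudocount = 0), "all-zero")
})

test_that("window-derived PWMs count residues with pad exclusion", {
  w <- uniformWindows(10, "S")
  substr(w, 4, 4) <- c(rep("R", 8), rep("K", 2))
  pwm <- pwmFromWindows(w, pseudocount = 0)
  expect_equal(pwmMatrix(pwm)["R", "-3"], 0.8)
  expect_equal(pwmMatrix(pwm)["K", "-3"], 0.2)
  pwm2 <- pwmFromWindows(w, pseudocount = 0.5)
  expect_equal(pwmMatrix(pwm2)["R", "-3"], 8.5 / 20)
  expect_equal(pwmMatrix(pwm2)["K", "-3"], 2.5 / 20)
  expect_equal(sum(pwmMatrix(pwm2)[, "-3"]), 1, tolerance = 1e-12)
  ## pads at a position shrink its effective count
  w2 <- w
  substr(w2[1:5], 1, 1) <- "-"
  pwm3 <- pwmFromWindows(w2, pseudocount = 0)
  expect_equal(sum(pwmMatrix(pwm3)[, "-6"]), 1, tolerance = 1e-12)
  substr(w2, 1, 1) <- "-"
  expect_error(pwmFromWindows(w2, pseudocount = 0), "-6")
  ## a single window gives point-mass columns
  pwm4 <- pwmFromWindows(w[1], pseudocount = 0)
  expect_true(all(apply(pwmMatrix(pwm4), 2, max) == 1))
})

test_that("KLD matches hand computations on two-symbol toys", {
  mk <- function(p1) {
    m <- matrix(c(p1, 1 - p1, rep(0, 18)), ncol = 1,
                dimnames = list(aa20, "1"))
    phosphoKinNet:::.newPWM(m, 1L, 0)
  }
  expect_equal(kld(mk(0.5), mk(0.5)), 0.0)
  expect_equal(kld(mk(0.5), mk(0.25)),
               0.5 * log2(2) + 0.5 * log2(2 / 3), tolerance = 1e-12)
  expect_equal(kld(mk(0.5), mk(0.25)), 0.207518, tolerance = 1e-5)
  expect_equal(kld(mk(0.75), mk(0.25)), 0.5 * log2(3), tolerance = 1e-12)
  expect_equal(kld(mk(0.75), mk(0.25)), 0.792481, tolerance = 1e-5)
  expect_error(kld(mk(0.5), mk(1.0)), "zero")
})

test_that("KLD is non-negative, zero iff equal, and equals the loop oracle", {
  set.seed(601)
  for (i in 1:50) {
    set.seed(600 + i)
    p <- samplePWM(3, 1)
    q <- samplePWM(3, 1)
    d <- kld(p, q)
    expect_gte(d, 0)
    expect_gt(d, 0)          # two independent Dirichlet draws never coincide
    expect_equal(d, kldOracle(pwmMatrix(p), pwmMatrix(q)), tolerance = 1e-12)
    expect_equal(kld(p, p), 0)
  }
})

test_that("KLD is computed over the position intersection only", {
  set.seed(602)
  p <- samplePWM(12, 1, positions = setdiff(-6:6, 0))
  q <- samplePWM(9, 1, positions = setdiff(-5:4, 0))
  d <- kld(p, q)
  pm <- pwmMatrix(p)[, as.character(setdiff(-5:4, 0))]
  qm <- pwmMatrix(q)
  expect_equal(d, kldOracle(pm, qm), tolerance = 1e-12)
  r <- samplePWM(2, 1, positions = c(9L, 10L))
  expect_error(kld(p, r), "no positions|share no")
})

test_that("shuffling preserves column multisets, sums and position labels", {
  set.seed(603)
  pwm <- pwmFromIntensities(toyIntensities(c("R", "K", "L")) +
                              matrix(runif(60), 20), 0.01)
  shuf <- shufflePWM(pwm)
  expect_identical(pwmPositions(shuf), pwmPositions(pwm))
  expect_equal(colSums(pwmMatrix(shuf)), colSums(pwmMatrix(pwm)))
  expect_equal(sort(as.vector(pwmMatrix(shuf))),
               sort(as.vector(pwmMatrix(pwm))))
  ## per-column multisets survive as a set across columns
  shuf_cols <- apply(pwmMatrix(shuf), 2, sort)
  orig_cols <- apply(pwmMatrix(pwm), 2, sort)
  expect_true(all(apply(shuf_cols, 2, function(cc)
    any(apply(orig_cols, 2, function(oc) isTRUE(all.equal(cc, oc)))))))
  set.seed(42); s1 <- shufflePWM(pwm)
  set.seed(42); s2 <- shufflePWM(pwm)
  expect_identical(pwmMatrix(s1), pwmMatrix(s2))
})

test_that("empirical FDR follows the strict-smaller counting rule", {
  set.seed(604)
  kin <- samplePWM(12, 0.05, positions = setdiff(-6:6, 0))
  kin_int <- pwmMatrix(kin) * 100
  dimnames(kin_int) <- list(aa20, as.character(pwmPositions(kin)))
  lib <- list(K1 = pwmFromIntensities(kin_int, 0.01))
  ## module PWM identical to the kinase PWM: observed KLD 0, no null below
  res <- matchKinases(list(m1 = lib$K1), lib, params = matchParams(
    nShuffles = 200, rngSeed = 5))
  expect_equal(res$kld_bits, 0)
  expect_equal(res$n_null_smaller, 0)
  expect_equal(res$fdr, 0)
  expect_true(res$passed)
  expect_equal(res$null_size, 200)
  ## a near-uniform module PWM scores worse than most shuffles of a sharp PWM
  set.seed(605)
  flat <- pwmFromWindows(uniformWindows(200, "S"), pseudocount = 0.01)
  res2 <- matchKinases(list(m2 = flat), lib, params = matchParams(
    nShuffles = 200, rngSeed = 5))
  expect_gte(res2$fdr, 0)
  expect_lte(res2$fdr, 1)
  expect_equal(res2$fdr, res2$n_null_smaller / res2$null_size)
})

test_that("a planted module matches its own kinase against decoys", {
  set.seed(606)
  positions <- setdiff(-6:6, 0)
  kin_pwms <- setNames(lapply(1:8, function(i) samplePWM(12, 0.05,
                                                         positions = positions)),
                       paste0("K", 1:8))
  lib <- KinaseLibrary(lapply(kin_pwms, function(p) {
    m <- pwmMatrix(p) * 100
    dimnames(m) <- list(aa20, as.character(positions))
    m
  }))
  ## module windows sampled from K3's PWM
  target <- "K3"
  windows <- phosphoKinNet:::.sampleWindows(kin_pwms[[target]], 40, "S")
  mod_pwm <- pwmFromWindows(windows, pseudocount = 0.01)
  res <- matchKinases(list(mod = mod_pwm), lib,
                      params = matchParams(nShuffles = 250, rngSeed = 7))
  best <- res$kinase[which.min(res$kld_bits)]
  expect_identical(best, target)
  expect_true(res$passed[res$kinase == target])
  expect_equal(res$null_size[1], 250 * 8)
})

test_that("candidates absent from the library are reported unmatched", {
  set.seed(607)
  kin <- samplePWM(12, 0.5, positions = setdiff(-6:6, 0))
  lib <- KinaseLibrary(list(K1 = {
    m <- pwmMatrix(kin) * 100
    dimnames(m) <- list(aa20, as.character(setdiff(-6:6, 0)))
    m
  }))
  mod <- pwmFromWindows(uniformWindows(30, "S"), pseudocount = 0.01)
  expect_warning(res <- matchKinases(list(m1 = mod), lib,
                                     candidates = list(m1 = c("K1", "K9")),
                                     params = matchParams(nShuffles = 50)),
                 "K9")
  expect_true(is.na(res$kld_bits[res$kinase == "K9"]))
  expect_false(res$passed[res$kinase == "K9"])
})
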
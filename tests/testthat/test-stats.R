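uniform6 <- function(trts) {
  m <- matrix(1 / 6, nrow = length(trts), ncol = 6,
              dimnames = list(trts, LETTERS[1:6]))
  m
}

test_that("outcome encoding is one-hot in fixed category order", {
  z <- encode_outcomes(c("F", "A", "C"))
  expect_equal(z[1, ], c(A = 0L, B = 0L, C = 0L, D = 0L, E = 0L, F = 1L))
  expect_equal(rowSums(z), c(1, 1, 1), ignore_attr = TRUE)
  big <- encode_outcomes(rep(LETTERS[1:6], each = 200))
  expect_equal(unname(colSums(big)), rep(200L, 6))
  expect_error(encode_outcomes(c("A", "Z")), "unknown letter")
})

test_that("treatment-only fit is saturated: probabilities equal proportions", {
  p <- rbind(Control = c(.3, .2, .15, .15, .1, .1),
             Low = c(.05, .1, .1, .15, .2, .4),
             High = (1:6) / 21)
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 200, seed = 11)
  fit <- fit_multinomial(d, "treatment", reference = "F")
  est <- estimate_probabilities(fit)
  emp <- prop.table(table(d$treatment, d$letter), 1)
  expect_lt(max(abs(est[rownames(emp), colnames(emp)] - emp)), 1e-6)
  expect_lt(max(abs(rowSums(est) - 1)), 1e-10)
})

test_that("symmetric data give zero coefficients and uniform probabilities", {
  d <- data.frame(letter = rep(LETTERS[1:6], 30), treatment = "Control")
  fit <- fit_multinomial(d, "treatment", reference = "F")
  expect_lt(max(abs(fit$coefficients)), 1e-6)
  expect_equal(unname(estimate_probabilities(fit)[1, ]), rep(1 / 6, 6),
               tolerance = 1e-8)
})

test_that("fitted probabilities recover the generating distribution", {
  p <- rbind(Control = c(.25, .2, .2, .15, .1, .1),
             T1 = c(.1, .1, .15, .2, .2, .25))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 500, seed = 21)
  fit <- fit_multinomial(d, "treatment", reference = "F")
  est <- estimate_probabilities(fit)
  expect_lt(max(abs(est[rownames(p), colnames(p)] - p)), 0.05)
})

test_that("our Newton fit agrees with an independent optimizer", {
  skip_if_not_installed("nnet")
  p <- rbind(Control = c(.3, .2, .15, .15, .1, .1),
             T1 = c(.05, .1, .1, .15, .2, .4))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 300, seed = 5)
  fit <- fit_multinomial(d, "treatment", reference = "F")
  dd <- transform(d, letter = factor(letter, levels = c("F", LETTERS[1:5])),
                  treatment = relevel(factor(treatment), "Control"))
  nf <- nnet::multinom(letter ~ treatment, data = dd, trace = FALSE,
                       reltol = 1e-14)
  expect_equal(fit$logLik, as.numeric(logLik(nf)), tolerance = 1e-6)
  expect_equal(fit$aic, AIC(nf), tolerance = 1e-4)
  # coefficient cross-check (nnet rows = categories, ours columns)
  expect_equal(unname(t(coef(nf))), unname(fit$coefficients), tolerance = 1e-4)
})

test_that("likelihood never decreases across Newton iterations", {
  # exercised implicitly by step-halving; verify convergence on a
  # moderately separated dataset and that the score is solved
  p <- rbind(Control = c(.6, .2, .05, .05, .05, .05),
             T1 = c(.05, .05, .05, .05, .2, .6))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 400, seed = 9)
  fit <- fit_multinomial(d, "treatment", reference = "F")
  expect_true(fit$converged)
  est <- estimate_probabilities(fit)
  emp <- prop.table(table(d$treatment, d$letter), 1)
  expect_lt(max(abs(est[rownames(emp), colnames(emp)] - emp)), 1e-6)
})

test_that("AIC model comparison picks the generating structure", {
  set.seed(1)
  # treatment-driven: plates within a treatment share probabilities
  p <- rbind(Control = c(.4, .25, .15, .1, .05, .05),
             T1 = c(.05, .05, .1, .15, .25, .4),
             T2 = c(.15, .25, .25, .15, .1, .1))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 200, seed = 31)
  ft <- fit_multinomial(d, "treatment", reference = "F")
  fp <- fit_multinomial(d, "plate", reference = "F")
  expect_equal(attr(compare_models(ft, fp), "chosen"), "treatment")

  # plate-driven: two plates of the same treatment differ strongly
  pp <- rbind(P1 = c(.5, .2, .1, .1, .05, .05),
              P2 = c(.05, .05, .1, .1, .2, .5),
              P3 = c(.3, .3, .2, .1, .05, .05),
              P4 = c(.05, .1, .2, .3, .3, .05))
  colnames(pp) <- LETTERS[1:6]
  dp <- simulate_outcomes(pp, 150, seed = 32, n_plates_per_treatment = 1)
  dp$plate <- dp$treatment
  dp$treatment <- c(P1 = "Control", P2 = "Control", P3 = "T1", P4 = "T1")[dp$plate]
  ft2 <- fit_multinomial(dp, "treatment", reference = "F")
  fp2 <- fit_multinomial(dp, "plate", reference = "F")
  expect_equal(attr(compare_models(ft2, fp2), "chosen"), "plate")

  # AIC formula and mismatched data rejection
  expect_equal(aic(ft), 2 * ft$n_params - 2 * ft$logLik)
  small <- fit_multinomial(d[1:120, ], "treatment", reference = "F")
  expect_error(compare_models(ft, small), "same number")
})

test_that("probabilities are invariant to the reference category", {
  p <- rbind(Control = c(.3, .2, .15, .15, .1, .1),
             T1 = c(.1, .15, .2, .2, .2, .15))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 300, seed = 41)
  est_f <- estimate_probabilities(fit_multinomial(d, "treatment", reference = "F"))
  est_a <- estimate_probabilities(fit_multinomial(d, "treatment", reference = "A"))
  expect_lt(max(abs(est_f - est_a)), 1e-8)
})

test_that("Wald contrasts behave at the null, in sign, and for i = i'", {
  p <- rbind(Control = c(.15, .15, .2, .2, .15, .15),
             T1 = c(.4, .1, .15, .05, .15, .15))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 400, seed = 51)
  fit <- fit_multinomial(d, "treatment", reference = "F")
  same <- wald_contrast(fit, "A", "T1", "T1")
  expect_equal(same$estimate, 0)
  expect_equal(same$p, 1)
  # T1 has more A relative to F than Control: positive contrast
  pos <- wald_contrast(fit, "A", "T1", "Control")
  expect_gt(pos$estimate, 0)
  expect_lt(pos$p, 0.05)
  # antisymmetry
  neg <- wald_contrast(fit, "A", "Control", "T1")
  expect_equal(neg$estimate, -pos$estimate)
  expect_equal(neg$p, pos$p)
  # contrasts table covers all pairs x non-reference types
  ct <- all_contrasts(fit)
  expect_equal(nrow(ct), 5 * 1)
})

test_that("Wald contrast p-values are invariant to the reference category", {
  p <- rbind(Control = c(.3, .2, .15, .15, .1, .1),
             T1 = c(.1, .15, .2, .2, .2, .15))
  colnames(p) <- LETTERS[1:6]
  d <- simulate_outcomes(p, 300, seed = 61)
  f1 <- fit_multinomial(d, "treatment", reference = "F")
  f2 <- fit_multinomial(d, "treatment", reference = "E")
  c1 <- wald_contrast(f1, "A", "T1", "Control")
  # under reference E the "A vs F" log-odds contrast is alpha_A - alpha_F
  c2a <- wald_contrast(f2, "A", "T1", "Control")
  c2f <- wald_contrast(f2, "F", "T1", "Control")
  expect_equal(c1$estimate, c2a$estimate - c2f$estimate, tolerance = 1e-6)
})

test_that("reference choice favours the most uniformly distributed category", {
  d <- data.frame(
    letter = c(rep("A", 10), rep("B", 30), rep("C", 10),
               rep("A", 30), rep("B", 30), rep("C", 10)),
    treatment = rep(c("Control", "T1"), c(50, 70)))
  # B: counts (30, 30) perfectly uniform; C: (10, 10) uniform too;
  # A: (10, 30) skewed. Chi-square: B = 0, C = 0, A > 0; tie -> alphabetical
  expect_equal(choose_reference(d), "B")

  d2 <- data.frame(letter = c(rep("A", 5), rep("B", 5), rep("B", 7)),
                   treatment = c(rep("Control", 10), rep("T1", 7)))
  # A has a zero cell under T1; only B qualifies
  expect_equal(choose_reference(d2), "B")

  # every category has a zero cell: fall back with warning
  d4 <- data.frame(letter = c(rep("A", 3), rep("B", 2)),
                   treatment = c("x", "x", "x", "y", "y"))
  expect_warning(ref <- choose_reference(d4), "zero")
  expect_equal(ref, "A")
})

test_that("quasi-separation warns and ridge stabilizes", {
  d <- data.frame(letter = c(rep("F", 98), "A", "B",
                             rep(LETTERS[1:6], length.out = 100)),
                  treatment = rep(c("High", "Control"), each = 100))
  expect_warning(fit_multinomial(d, "treatment", reference = "F", ridge = 1e-6),
                 "quasi-separation")
  fit <- suppressWarnings(
    fit_multinomial(d, "treatment", reference = "F", ridge = 1e-6))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
})
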
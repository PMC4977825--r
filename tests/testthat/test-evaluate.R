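test_that("squared deviation matches direct computation", {
  dn <- list(c("g1", "g2"), c("e1", "e2"))
  a <- matrix(c(0.5, 1, 0, 0.25), 2, 2, dimnames = dn)
  ref <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = dn)
  sd_ <- squared_deviation(a, ref)
  expect_equal(sd_$d2[1, 1], 0.25)
  expect_equal(sd_$d2[2, 2], 0.0625)
  # identical matrices: zero deviation everywhere
  z <- squared_deviation(ref, ref)
  expect_true(all(z$d2 == 0) && all(z$d_experiment == 0))
  # brute-force per-experiment oracle on a random pair
  set.seed(81)
  A <- matrix(runif(600), 20, 30)
  R <- matrix(rbinom(600, 1, 0.5), 20, 30)
  dimnames(A) <- dimnames(R) <- list(paste0("g", 1:20), paste0("e", 1:30))
  got <- squared_deviation(A, R)$d_experiment
  want <- vapply(1:30, function(j) sqrt(mean((A[, j] - R[, j])^2)), 0)
  expect_equal(unname(got), want)
  # missing reference cells are skipped
  R[1, 1] <- NA
  expect_true(is.na(squared_deviation(A, R)$d2[1, 1]))
  expect_error(squared_deviation(A, R * NA), "no overlapping")
})

test_that("consistency scores agree with the piecewise definition", {
  dn <- list("g1", paste0("e", 1:5))
  a <- matrix(c(0.7, 0.3, 0.5, 0.9, 0.2), 1, 5, dimnames = dn)
  ref <- matrix(c(1, 1, 0, 0, 0), 1, 5, dimnames = dn)
  cc <- consistency(a, ref)
  expect_equal(unname(cc$c[1, ]), c(1, 0, 0.5, 0, 1))
  expect_error(consistency(a, ref + 0.5), "binary")
  # sensitivity/specificity equal subset means of c by brute force
  set.seed(82)
  A <- matrix(runif(400), 20, 20)
  R <- matrix(rbinom(400, 1, 0.4), 20, 20)
  dimnames(A) <- dimnames(R) <- list(paste0("g", 1:20), paste0("e", 1:20))
  cc <- consistency(A, R)
  expect_equal(cc$sensitivity, mean(cc$c[R == 1]))
  expect_equal(cc$specificity, mean(cc$c[R == 0]))
  expect_true(cc$mean >= 0 && cc$mean <= 1)
})

test_that("confidence strata partition the unit interval", {
  expect_identical(stratify_confidence(0.9), "high")
  expect_identical(stratify_confidence(0.05), "high")
  expect_identical(stratify_confidence(0.5), "low")
  expect_identical(stratify_confidence(0.4), "low")  # boundary repair
  expect_identical(stratify_confidence(0.3), "medium")
  expect_identical(stratify_confidence(0.75), "medium")
  # every value maps to exactly one stratum
  grid <- seq(0, 1, by = 0.001)
  labs <- stratify_confidence(grid)
  expect_true(all(labs %in% c("high", "medium", "low")))
  expect_false(anyNA(labs))
  # matrix input keeps shape
  m <- matrix(c(0.1, 0.5, 0.7, 0.85), 2, 2)
  expect_identical(dim(stratify_confidence(m)), dim(m))
})

test_that("operon consistency classes follow the conflict bands", {
  map <- operon_map(list(op1 = c("g1", "g2"), op2 = c("g3", "g4"),
                         single = "g5"))
  dn <- list(paste0("g", 1:5), c("e1", "e2", "e3"))
  a <- matrix(0.5, 5, 3, dimnames = dn)
  a[c("g1", "g2"), 1] <- c(0.9, 0.1)    # conflict
  a[c("g1", "g2"), 2] <- c(0.9, 0.85)   # both confident active
  a[c("g3", "g4"), 1] <- c(0.55, 0.45)  # uncertain but not conflicting
  a[c("g3", "g4"), 3] <- c(0.7, 0.3)    # conflict
  oc <- operon_consistency(a, map)
  expect_false("single" %in% oc$operon)  # singletons excluded
  get <- function(op, e) oc$class[oc$operon == op & oc$experiment == e]
  expect_identical(get("op1", "e1"), "inconsistent")
  expect_identical(get("op1", "e2"), "very_consistent")
  expect_identical(get("op2", "e1"), "consistent")
  expect_identical(get("op2", "e3"), "inconsistent")
  # classes partition operon-experiment combinations
  expect_identical(nrow(oc), 6L)
})

test_that("correct-and-consistent fraction matches brute force", {
  map <- operon_map(list(op1 = c("g1", "g2")))
  dn <- list(c("g1", "g2"), paste0("e", 1:4))
  alpha <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2, 4, dimnames = dn)
  # perfect estimates: fraction 1
  expect_equal(correct_and_consistent(alpha * 0.98 + 0.01, map, alpha), 1)
  # unresolved estimates cannot be correct
  half <- matrix(0.5, 2, 4, dimnames = dn)
  expect_equal(correct_and_consistent(half, map, alpha), 0)
  # random fixture vs direct enumeration
  set.seed(83)
  a <- matrix(runif(8), 2, 4, dimnames = dn)
  want <- mean(vapply(1:4, function(j) {
    v <- a[, j]
    if (any(v > 0.6) && any(v < 0.4)) return(FALSE)
    m <- mean(v)
    if (m == 0.5) return(FALSE)
    all(alpha[, j] == as.integer(m > 0.5))
  }, logical(1)))
  expect_equal(correct_and_consistent(a, map, alpha), want)
})

test_that("pathway component test is a Welch t-test on per-experiment means", {
  dn <- list(paste0("g", 1:4), paste0("e", 1:6))
  a <- matrix(runif(24), 4, 6, dimnames = dn)
  comps <- list(c1 = c("g1", "g2"), empty = "gX")
  groups <- list(paste0("e", 1:3), paste0("e", 4:6))
  expect_warning(res <- pathway_component_test(a, comps, groups), "no genes")
  expect_identical(res$component, "c1")
  # closed-form oracle for the 3 + 3 case
  pm <- colMeans(a[c("g1", "g2"), ])
  x <- pm[1:3]; y <- pm[4:6]
  se <- sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(res$statistic, (mean(x) - mean(y)) / se)
  expect_equal(res$p_value, t.test(x, y)$p.value)
  # identical groups: t = 0
  res0 <- pathway_component_test(a, list(c1 = c("g1", "g2")),
                                 list(paste0("e", 1:3), paste0("e", 1:3)))
  expect_equal(res0$statistic, 0)
  # power: a clear shift is detected
  set.seed(84)
  shift <- matrix(rnorm(2 * 100, 0.4, 0.05), 2, 100)
  base <- cbind(shift, shift + 0.2)
  dimnames(base) <- list(c("g1", "g2"), paste0("e", 1:200))
  resp <- pathway_component_test(base, list(c1 = c("g1", "g2")),
                                 list(paste0("e", 1:100), paste0("e", 101:200)))
  expect_lt(resp$p_value, 1e-6)
})

test_that("flux association is a Fisher-z Pearson correlation on sqrt fluxes", {
  # q identical to sqrt-flux: r = 1
  fl <- c(0.5, 1.2, 2.5, 4.1, 7.3)
  expect_equal(flux_association(sqrt(fl), fl)$r, 1)
  # hand-sized fixture vs the direct formula
  q <- c(0.1, 0.4, 0.5, 0.8, 0.9)
  fa <- flux_association(q, fl)
  expect_equal(fa$r, cor(q, sqrt(fl)))
  expect_equal(fa$conf_int, as.numeric(cor.test(q, sqrt(fl))$conf.int))
  expect_identical(fa$n, 5L)
  # independent pairs: near-zero correlation
  set.seed(85)
  fa0 <- flux_association(runif(500), rexp(500))
  expect_lt(abs(fa0$r), 0.15)
  # sqrt_q applies the transform to expression-derived scores
  fa_t <- flux_association(q, fl, sqrt_q = TRUE)
  expect_equal(fa_t$r, cor(sqrt(q), sqrt(fl)))
  expect_error(flux_association(1:2, 1:2), "at least 3")
})
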
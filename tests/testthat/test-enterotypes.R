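test_that("Jensen-Shannon distance matches hand computation and bounds", {
  two <- function(a, b) {
    m <- AbundanceMatrix(cbind(s1 = a, s2 = b), kind = "relative")
    jsdMatrix(m)["s1", "s2"]
  }
  expect_equal(two(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(two(c(1, 0), c(0, 1)), 1)          # disjoint support
  expect_equal(two(c(1, 0), c(0.5, 0.5)), 0.55792, tolerance = 1e-5)
  # metric properties on random profiles
  set.seed(6)
  p <- matrix(stats::rexp(5 * 6), 5, 6,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  p <- sweep(p, 2, colSums(p), "/")
  D <- jsdMatrix(AbundanceMatrix(p, kind = "relative"))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(0, 6))
  # triangle inequality spot check
  for (i in 1:4) for (j in (i + 1):5) for (k in (j + 1):6)
    expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
})

test_that("PAM recovers separated blobs and degenerates sensibly", {
  set.seed(9)
  x <- c(stats::rnorm(6, 0, 0.1), stats::rnorm(6, 5, 0.1))
  D <- as.matrix(stats::dist(x))
  dimnames(D) <- list(paste0("s", 1:12), paste0("s", 1:12))
  fit <- pamCluster(D, 2)
  expect_equal(length(unique(fit$labels[1:6])), 1L)
  expect_equal(length(unique(fit$labels[7:12])), 1L)
  expect_false(fit$labels[1] == fit$labels[7])
  # exhaustive medoid-pair oracle: no pair beats PAM's objective
  best <- Inf
  for (a in 1:11) for (b in (a + 1):12)
    best <- min(best, sum(pmin(D[, a], D[, b])))
  expect_equal(fit$objective, best, tolerance = 1e-12)
  # k = n: every sample its own medoid, zero cost
  all_self <- pamCluster(D, 12)
  expect_equal(all_self$objective, 0)
  expect_error(pamCluster(D, 13), "exceed")
})

test_that("PAM partitions are invariant to sample order", {
  st <- defaultStudy()$taxon_study
  D <- jsdMatrix(st$genus)
  f1 <- pamCluster(D, 2)
  set.seed(10)
  perm <- sample(nrow(D))
  f2 <- pamCluster(D[perm, perm], 2)
  agree <- f1$labels[rownames(D)[perm]]
  expect_true(abs(stats::cor(agree, f2$labels)) > 0.999)
})

test_that("CH index ranks cluster counts and respects its bounds", {
  x <- c(stats::rnorm(8, 0, 0.05), stats::rnorm(8, 10, 0.05))
  D <- as.matrix(stats::dist(x))
  lab2 <- rep(1:2, each = 8)
  lab3 <- c(rep(1, 4), rep(3, 4), rep(2, 8))
  expect_gt(chIndex(D, lab2), chIndex(D, lab3))
  expect_gte(chIndex(D, lab3), 0)
  # identical points: no between-cluster dispersion
  D0 <- matrix(0, 6, 6)
  expect_equal(chIndex(D0, rep(1:2, 3)), 0)
  expect_error(chIndex(D, rep(1, 16)), "at least 2")
})

test_that("CH model selection finds planted cluster counts", {
  # three separated blobs in 10 dimensions (splitting a multivariate blob
  # along one axis gains too little within-mass to fool the CH criterion)
  set.seed(200)
  d <- 10
  centers <- matrix(stats::rnorm(3 * d, 0, 4), 3, d)
  x <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(stats::rnorm(8 * d), 8, d), 2, centers[b, ], "+")))
  D <- as.matrix(stats::dist(x))
  dimnames(D) <- list(paste0("s", 1:24), paste0("s", 1:24))
  sel <- selectK(D, 2:6)
  expect_equal(sel$k_selected, 3)
  # two-enterotype genus study
  st <- defaultStudy()$taxon_study
  sel2 <- selectK(jsdMatrix(st$genus), 2:8)
  expect_equal(sel2$k_selected, 2)
})

test_that("Fisher exact test agrees with enumeration for all totals <= 12", {
  for (n in 2:12) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        for (a in max(0, r1 + c1 - n):min(r1, c1)) {
          tab <- matrix(c(a, c1 - a, r1 - a, n - r1 - c1 + a), 2, 2)
          if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
          p <- fisherExactTest(tab)
          expect_equal(p, enumFisherP(tab), tolerance = 1e-12)
          expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("Fisher exact worked examples", {
  expect_equal(fisherExactTest(matrix(c(3, 0, 0, 3), 2, 2)), 0.1)
  expect_equal(fisherExactTest(matrix(c(5, 5, 5, 5), 2, 2)), 1)
  expect_equal(fisherExactTest(matrix(c(25, 41, 25, 9), 2, 2)),
               0.001358, tolerance = 1e-3)
  expect_error(fisherExactTest(matrix(c(0, 0, 1, 1), 2, 2)), "margin")
})

test_that("association step reports contingency, p and dominant taxa", {
  st <- defaultStudy()$taxon_study
  lab <- st$truth$enterotype_label
  assoc <- enterotypeAssociation(lab, st$meta, st$genus)
  expect_equal(sum(assoc$contingency), 100)
  expect_equal(round(assoc$fisher_p, 3), 0.001)
  expect_identical(unname(assoc$dominant_taxa), c("Bacteroides", "Prevotella"))
  # balanced table gives p = 1
  bal <- twoGroupMeta(4, 4)
  lab_bal <- stats::setNames(rep(1:2, 4), bal$sample_id)
  expect_equal(enterotypeAssociation(lab_bal, bal)$fisher_p, 1)
})

test_that("end-to-end enterotype detection recovers the planted mixture", {
  st <- defaultStudy()$taxon_study
  et <- detectEnterotypes(st$genus, st$meta)
  expect_s4_class(et, "EnterotypeResult")
  expect_equal(et@kSelected, 2L)
  truth <- st$truth$enterotype_label[names(enterotypeLabels(et))]
  ari <- mclust::adjustedRandIndex(enterotypeLabels(et), truth)
  expect_gte(ari, 0.9)
  expect_setequal(et@dominantTaxa, c("Bacteroides", "Prevotella"))
})
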
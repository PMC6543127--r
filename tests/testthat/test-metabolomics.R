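makePeaks <- function(areas, compounds = NULL, mode = "ES+",
                      compartment = "serum") {
  data.frame(
    feature_id = paste0("ft", seq_len(nrow(areas))),
    compound_name = if (is.null(compounds))
      paste0("cmpd", seq_len(nrow(areas))) else compounds,
    mode = mode, compartment = compartment,
    rt_min = seq_len(nrow(areas)), mass_da = 100 + seq_len(nrow(areas)),
    areas, check.names = FALSE)
}

test_that("total-area normalisation hits 1e6 per sample and is idempotent", {
  areas <- matrix(c(2, 3, 5, 1, 1, 2), 3, 2,
                  dimnames = list(NULL, c("s1", "s2")))
  pk <- makePeaks(as.data.frame(areas))
  norm <- normalizeTotal(pk)
  expect_equal(peakAreas(norm)[, "s1"], c(2e5, 3e5, 5e5),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(peakAreas(norm))), c(1e6, 1e6),
               tolerance = 1e-9)
  expect_equal(peakAreas(normalizeTotal(norm)), peakAreas(norm))
  bad <- pk; bad$s1 <- 0
  expect_error(normalizeTotal(bad), "s1")
})

test_that("PLS-DA on a single perfect feature aligns scores with the class", {
  set.seed(41)
  y <- factor(rep(c("control", "case"), each = 6),
              levels = c("control", "case"))
  X <- cbind(f1 = ifelse(y == "case", 1, -1))
  rownames(X) <- paste0("s", 1:12)
  fit <- plsdaFit(X, y, A = 1, scale = FALSE)
  t1 <- fit@scores[, 1]
  yc <- ifelse(y == "case", 1, -1)
  expect_equal(abs(stats::cor(t1, yc)), 1, tolerance = 1e-12)
  # explained response variance is total
  yhat <- fit@scores %*% fit@q
  expect_equal(as.numeric(yhat), yc - mean(yc), tolerance = 1e-10)
})

test_that("NIPALS scores are mutually orthogonal and match the PLS1 oracle", {
  set.seed(42)
  X <- matrix(stats::rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:8)))
  y <- factor(rep(c("a", "b"), 5))
  fit <- plsdaFit(X, y, A = 2)
  expect_lt(abs(sum(fit@scores[, 1] * fit@scores[, 2])),
            1e-8 * sqrt(sum(fit@scores[, 1]^2) * sum(fit@scores[, 2]^2)))
  # first component against an independently coded power-iteration solution
  for (seed in 1:5) {
    set.seed(seed)
    Xr <- matrix(stats::rnorm(80), 10, 8,
                 dimnames = list(paste0("s", 1:10), paste0("f", 1:8)))
    yr <- factor(rep(c("a", "b"), 5))
    f1 <- plsdaFit(Xr, yr, A = 1)
    w_oracle <- powerIterationW1(Xr, ifelse(yr == "b", 1, -1))
    cosine <- abs(sum(f1@weights[, 1] * w_oracle))
    expect_gte(cosine, 1 - 1e-8)
  }
})

test_that("constant features are dropped with a warning before scaling", {
  set.seed(43)
  X <- cbind(matrix(stats::rnorm(24), 12, 2), const = 5)
  colnames(X) <- c("f1", "f2", "const")
  rownames(X) <- paste0("s", 1:12)
  y <- factor(rep(c("a", "b"), 6))
  expect_warning(fit <- plsdaFit(X, y, A = 1), "constant")
  expect_false("const" %in% rownames(fit@weights))
})

test_that("VIP scores satisfy the closed form and the mean-square identity", {
  # A = 1: VIP reduces to sqrt(p) * |w|
  set.seed(44)
  X <- matrix(stats::rnorm(40), 20, 2,
              dimnames = list(paste0("s", 1:20), c("f1", "f2")))
  y <- rep(c("a", "b"), 10)
  X[, 2] <- ifelse(y == "b", 1.5, 0) + stats::rnorm(20, 0, 0.5)
  fit <- plsdaFit(X, y, A = 1)
  vip <- vipScores(fit)
  expect_equal(unname(vip), sqrt(2) * abs(unname(fit@weights[, 1])),
               tolerance = 1e-12)
  # hand case from the closed form
  expect_equal(sqrt(2) * c(0.6, 0.8), c(0.8485281, 1.1313708),
               tolerance = 1e-6)
  # mean of VIP^2 is exactly 1 for any fitted model
  for (A in 1:3) {
    set.seed(A + 50)
    Xr <- matrix(stats::rnorm(15 * 9), 15, 9,
                 dimnames = list(paste0("s", 1:15), paste0("f", 1:9)))
    fr <- plsdaFit(Xr, rep(c("a", "b"), length.out = 15), A = A)
    expect_equal(mean(vipScores(fr)^2), 1, tolerance = 1e-12)
  }
})

test_that("VIP is equivariant under feature permutation", {
  set.seed(45)
  X <- matrix(stats::rnorm(20 * 6), 20, 6,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:6)))
  y <- rep(c("a", "b"), 10)
  vip <- vipScores(plsdaFit(X, y, A = 2))
  perm <- c(4, 1, 6, 2, 5, 3)
  vip_p <- vipScores(plsdaFit(X[, perm], y, A = 2))
  expect_equal(vip_p, vip[colnames(X)[perm]], tolerance = 1e-10)
})

test_that("OPLS orthogonal scores are orthogonal to the response", {
  set.seed(46)
  n <- 20
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  yc <- ifelse(y == "case", 1, -1)
  struct <- stats::rnorm(n)  # structured variation unrelated to y
  X <- cbind(outer(yc, c(1, 0.5, 0)), outer(struct, c(0, 1, 1))) +
    matrix(stats::rnorm(n * 6, 0, 0.2), n, 6)
  colnames(X) <- paste0("f", 1:6); rownames(X) <- paste0("s", 1:n)
  fit <- oplsdaFit(X, y, n_orthogonal = 1)
  to <- fit@orthoScores[, 1]
  expect_lt(abs(sum(to * yc)), 1e-8 * sqrt(sum(to^2) * sum(yc^2)))
  # orthogonal filtering cannot reduce explained response variance
  pls1 <- plsdaFit(X, y, A = 1)
  r2y <- function(m) {
    yc0 <- yc - mean(yc)
    1 - sum((yc0 - m@scores %*% m@q)^2) / sum(yc0^2)
  }
  expect_gte(r2y(fit), r2y(pls1) - 1e-10)
})

test_that("zero orthogonal components reduce OPLS to one-component PLS", {
  set.seed(47)
  X <- matrix(stats::rnorm(16 * 5), 16, 5,
              dimnames = list(paste0("s", 1:16), paste0("f", 1:5)))
  y <- rep(c("a", "b"), 8)
  o <- oplsdaFit(X, y, n_orthogonal = 0)
  p <- plsdaFit(X, y, A = 1)
  expect_equal(o@weights, p@weights, tolerance = 1e-12)
  expect_equal(o@scores, p@scores, tolerance = 1e-12)
  expect_equal(o@q, p@q, tolerance = 1e-12)
})

test_that("metabolite selection is the VIP>1 AND p<0.05 conjunction", {
  st <- defaultStudy()
  norm <- normalizeTotal(st$metabolome$tables$serum$pos)
  tab <- differentialMetabolites(norm, st$taxon_study$meta)
  expect_true(all(tab$selected ==
                    (!is.na(tab$vip) & tab$vip > 1 & tab$p < 0.05)))
  # a significant-p but low-VIP feature is rejected
  low_vip <- tab$p < 0.05 & !is.na(tab$vip) & tab$vip <= 1
  if (any(low_vip)) expect_false(any(tab$selected[low_vip]))
  expect_true(all(tab$fc > 0))
  expect_equal(tab$log2fc, log2(tab$fc))
})

test_that("planted metabolite effects are recovered", {
  st <- defaultStudy()
  meta <- st$taxon_study$meta
  truth <- st$metabolome$truth$differential_metabolites$serum
  diffs <- lapply(lapply(st$metabolome$tables$serum, normalizeTotal),
                  differentialMetabolites, meta = meta)
  merged <- mergeModes(diffs$pos, diffs$neg)
  sel <- merged$compound_name[merged$selected]
  expect_gte(mean(names(truth) %in% sel), 0.8)
  expect_gte(mean(sel %in% names(truth)), 0.8)
})

test_that("mode merging keeps the lower-p detection per compound", {
  pos <- data.frame(feature_id = c("p1", "p2"),
                    compound_name = c("A", "B"), mode = "ES+",
                    compartment = "serum", vip = c(1.5, 1.2),
                    p = c(0.01, 0.20), fc = c(2, 1.1),
                    log2fc = log2(c(2, 1.1)), selected = c(TRUE, FALSE))
  neg <- data.frame(feature_id = c("n1", "n2"),
                    compound_name = c("A", "C"), mode = "ES-",
                    compartment = "serum", vip = c(1.4, 0.8),
                    p = c(0.03, 0.50), fc = c(1.8, 0.9),
                    log2fc = log2(c(1.8, 0.9)), selected = c(TRUE, FALSE))
  merged <- mergeModes(pos, neg)
  expect_setequal(merged$compound_name, c("A", "B", "C"))
  expect_identical(merged$mode[merged$compound_name == "A"], "ES+")
  dup <- rbind(pos, pos)
  expect_error(mergeModes(dup, neg), "duplicated within mode")
})

test_that("cross-compartment concordance counts shared signed compounds", {
  mk <- function(names_, l2fc, selected)
    data.frame(feature_id = paste0("f", seq_along(names_)),
               compound_name = names_, mode = "ES+", compartment = "x",
               vip = 2, p = 0.01, fc = 2^l2fc, log2fc = l2fc,
               selected = selected)
  serum <- mk(c("A", "B", "C", "D"), c(1, -1, 2, 1), c(TRUE, TRUE, TRUE, FALSE))
  feces <- mk(c("A", "B", "E"), c(2, 1, 1), c(TRUE, TRUE, TRUE))
  cc <- crossCompartment(serum, feces)
  expect_setequal(cc$shared, c("A", "B"))
  expect_identical(cc$concordant, "A")
  expect_true(all(cc$concordant %in% cc$shared))
  # disjoint compound sets
  cc0 <- crossCompartment(mk("X", 1, TRUE), mk("Y", 1, TRUE))
  expect_length(cc0$shared, 0)
  expect_length(cc0$concordant, 0)
})

test_that("first PLS component agrees with mixOmics on a shared fit", {
  skip_if_not_installed("mixOmics")
  set.seed(48)
  X <- matrix(stats::rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("s", 1:30), paste0("f", 1:12)))
  y <- factor(rep(c("a", "b"), 15))
  X[, 1] <- ifelse(y == "b", 1, 0) + stats::rnorm(30, 0, 0.5)
  mine <- plsdaFit(X, y, A = 1)
  ref <- mixOmics::plsda(X, y, ncomp = 1, scale = TRUE)
  cosine <- abs(stats::cor(mine@scores[, 1], ref$variates$X[, 1]))
  expect_gte(cosine, 1 - 1e-6)
})
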
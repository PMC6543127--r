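# shared fixtures; heavyweight objects are memoised so several test files
# can reuse one default synthetic study
.fixture_env <- new.env(parent = emptyenv())

defaultStudy <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- simulateStudy(simulationConfig(seed = 42L))
  .fixture_env$study
}

defaultCAGs <- function() {
  if (is.null(.fixture_env$cags)) {
    st <- defaultStudy()
    .fixture_env$cags <- buildCAGs(st$gene_study$genes,
                                   st$gene_study$gene_lengths,
                                   st$gene_study$hits, st$gene_study$meta)
  }
  .fixture_env$cags
}

# small abundance matrix with reproducible random values
randomAbundance <- function(nf = 6, ns = 4, seed = 1, kind = "count") {
  set.seed(seed)
  m <- matrix(stats::rexp(nf * ns), nf, ns,
              dimnames = list(paste0("f", seq_len(nf)),
                              paste0("s", seq_len(ns))))
  AbundanceMatrix(m, kind = kind)
}

twoGroupMeta <- function(n_case, n_control) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n_case + n_control)),
             group = rep(c("case", "control"), c(n_case, n_control)))
}

# independent brute-force oracles -------------------------------------------

# two-sided Wilcoxon rank-sum p by complete enumeration of group assignments
enumWilcoxonP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(n, nx)
  stats_all <- apply(idx, 2L, function(i) sum(r[i]))
  mu <- nx * (n + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# BH step-up from the definition
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(pmin(p[o][i:m] * m / (i:m), 1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided Fisher exact p by complete table enumeration at fixed margins
enumFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(a_range, function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1))
  }, numeric(1))
  obs <- prob[a_range == tab[1, 1]]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# AUC as the exhaustive concordant-pair proportion
pairCountAUC <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Spearman rho from average ranks, straight from the definition
rankRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n as a matrix (rows), recursive construction
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- combinat_perms(n - 1)
    vals <- setdiff(seq_len(n), i)
    cbind(i, matrix(vals[sub], nrow(sub)))
  }))
}

# first PLS1 weight by power iteration on X'y y'X
powerIterationW1 <- function(X, y) {
  Xc <- scale(X)
  yc <- y - mean(y)
  M <- tcrossprod(crossprod(Xc, yc))  # X'y y'X
  w <- rep(1 / sqrt(ncol(Xc)), ncol(Xc))
  for (i in 1:500) {
    w_new <- M %*% w
    w_new <- w_new / sqrt(sum(w_new^2))
    if (sum((w_new - w)^2) < 1e-24) break
    w <- w_new
  }
  as.numeric(w)
}
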
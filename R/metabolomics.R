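.peakMetaCols <- c("feature_id", "compound_name", "mode", "compartment",
                   "rt_min", "mass_da")

#' Extract the peak-area matrix from a peak table
#'
#' @param peaks peak-table data.frame: metadata columns feature_id,
#'   compound_name, mode, compartment, rt_min, mass_da followed by one
#'   numeric column per sample.
#' @return features x samples matrix (rownames = feature ids).
#' @export
peakAreas <- function(peaks) {
  sample_cols <- setdiff(names(peaks), .peakMetaCols)
  m <- as.matrix(peaks[, sample_cols, drop = FALSE])
  rownames(m) <- peaks$feature_id
  m
}

#' Read / write a peak table TSV
#'
#' @param path TSV path.
#' @return peak-table data.frame.
#' @export
readPeakTable <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.peakMetaCols, names(pt))
  if (length(missing))
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(pt$feature_id)) stop("duplicate feature_id")
  areas <- peakAreas(pt)
  if (any(areas < 0)) stop("negative peak areas")
  pt
}

#' @rdname readPeakTable
#' @param peaks peak-table data.frame.
#' @export
writePeakTable <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Total-area normalisation of LC-MS peak tables
#'
#' Scales every sample so its total peak area is 1,000,000: each ion's area
#' is divided by the sample's total and multiplied by 1e6. Idempotent; a
#' zero-total sample is rejected by name.
#'
#' @param peaks peak-table data.frame.
#' @param total target per-sample total (default 1e6).
#' @return the normalised peak table.
#' @export
normalizeTotal <- function(peaks, total = 1e6) {
  areas <- peakAreas(peaks)
  tot <- colSums(areas)
  if (any(tot <= 0))
    stop("zero-total sample(s): ",
         paste(colnames(areas)[tot <= 0], collapse = ", "))
  scaled <- sweep(areas, 2L, tot, "/") * total
  peaks[, colnames(areas)] <- scaled
  peaks
}

# column-wise autoscaling; constant columns are dropped with a warning
.autoscale <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  keep <- sc > 0
  if (!all(keep))
    warning("constant feature(s) dropped before scaling: ",
            paste(head(colnames(X)[!keep], 3), collapse = ", "))
  X <- X[, keep, drop = FALSE]
  list(X = sweep(sweep(X, 2L, ctr[keep]), 2L, sc[keep], "/"),
       center = ctr[keep], scale = sc[keep],
       dropped = colnames(X)[FALSE], dropped_ids = names(ctr)[!keep])
}

.encodeResponse <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("two classes required")
  if (any(table(y) < 2)) stop("need >= 2 samples per class")
  list(code = ifelse(y == levels(y)[2], 1, -1), levels = levels(y))
}

#' PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis: NIPALS PLS1 on column-wise
#' mean-centred, unit-variance-scaled X against the centred +/-1 class
#' response, deflating X after each component. With a single response the
#' NIPALS weight update converges in one pass; the iteration cap and
#' tolerance are retained for the general update.
#'
#' @param X samples x features numeric matrix.
#' @param y two-level class labels aligned with rows of X (second factor
#'   level is coded +1).
#' @param A number of predictive components.
#' @param scale autoscale features (unit variance) or centre only.
#' @param tol,maxit NIPALS convergence controls.
#' @return A [PLSModel-class].
#' @export
plsdaFit <- function(X, y, A = 2, scale = TRUE, tol = 1e-10, maxit = 500) {
  X <- as.matrix(X)
  resp <- .encodeResponse(y)
  if (A > min(dim(X))) stop("A exceeds the rank bound of X")
  prep <- if (scale) .autoscale(X) else {
    ctr <- colMeans(X)
    list(X = sweep(X, 2L, ctr), center = ctr,
         scale = stats::setNames(rep(1, ncol(X)), colnames(X)),
         dropped_ids = character())
  }
  Xc <- prep$X
  yc <- resp$code - mean(resp$code)
  p <- ncol(Xc); n <- nrow(Xc)
  W <- P <- matrix(0, p, A, dimnames = list(colnames(Xc), NULL))
  Tm <- matrix(0, n, A, dimnames = list(rownames(X), NULL))
  qv <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)[, 1]
    if (sqrt(sum(w^2)) < tol) {
      # response variance exhausted; truncate the model
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      qv <- qv[seq_len(a - 1)]
      break
    }
    for (it in seq_len(maxit)) {
      w <- w / sqrt(sum(w^2))
      t <- Xc %*% w
      w_new <- crossprod(Xc, yc)[, 1]  # PLS1: fixed point after one pass
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sum((w_new - w)^2) < tol^2) { w <- w_new; break }
      w <- w_new
    }
    t <- (Xc %*% w)[, 1]
    tt <- sum(t^2)
    qv[a] <- sum(t * yc) / tt
    pa <- crossprod(Xc, t)[, 1] / tt
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t
    Xc <- Xc - tcrossprod(t, pa)
  }
  new("PLSModel", weights = W, scores = Tm, loadings = P, q = qv,
      orthoWeights = matrix(0, p, 0), orthoScores = matrix(0, n, 0),
      orthoLoadings = matrix(0, p, 0),
      center = prep$center, scale = prep$scale,
      yMean = mean(resp$code), classLevels = resp$levels,
      droppedFeatures = prep$dropped_ids)
}

#' Variable importance in projection (VIP)
#'
#' VIP_j = sqrt( p * sum_a SS_a w_aj^2 / sum_a SS_a ) with
#' SS_a = q_a^2 t_a' t_a and p the feature count; the mean of VIP^2 is
#' exactly 1, so VIP > 1 marks features contributing more than average.
#'
#' @param model a fitted [PLSModel-class].
#' @return named numeric VIP per feature.
#' @export
vipScores <- function(model) {
  W <- model@weights
  if (!ncol(W)) stop("model has no predictive components")
  ss <- model@q^2 * colSums(model@scores^2)
  if (sum(ss) <= 0) stop("zero explained response variance")
  p <- nrow(W)
  vip <- sqrt(p * as.numeric(W^2 %*% ss) / sum(ss))
  stats::setNames(vip, rownames(W))
}

#' OPLS-DA by the Trygg-Wold orthogonal filter
#'
#' Orthogonal projections to latent structures: for each orthogonal
#' component the PLS weight is computed, the loading's response-orthogonal
#' remainder is extracted (w_orth = p - (w'p) w), X is deflated by the
#' resulting score/loading pair, and finally one predictive PLS1 component
#' is fitted on the filtered X. The orthogonal scores are uncorrelated with
#' the response by construction. With \code{n_orthogonal = 0} the fit
#' reduces to single-component PLS-DA.
#'
#' @param X samples x features matrix.
#' @param y two-level class labels.
#' @param n_orthogonal number of orthogonal components.
#' @param scale autoscale features before fitting.
#' @return A [PLSModel-class] with one predictive component and the
#'   orthogonal component set.
#' @export
oplsdaFit <- function(X, y, n_orthogonal = 1, scale = TRUE) {
  X <- as.matrix(X)
  resp <- .encodeResponse(y)
  if (n_orthogonal >= min(dim(X)))
    stop("n_orthogonal must be below the rank bound of X")
  prep <- if (scale) .autoscale(X) else {
    ctr <- colMeans(X)
    list(X = sweep(X, 2L, ctr), center = ctr,
         scale = stats::setNames(rep(1, ncol(X)), colnames(X)),
         dropped_ids = character())
  }
  Xc <- prep$X
  yc <- resp$code - mean(resp$code)
  p <- ncol(Xc); n <- nrow(Xc)
  Wo <- Po <- matrix(0, p, n_orthogonal, dimnames = list(colnames(Xc), NULL))
  To <- matrix(0, n, n_orthogonal, dimnames = list(rownames(X), NULL))
  for (a in seq_len(n_orthogonal)) {
    w <- crossprod(Xc, yc)[, 1]
    w <- w / sqrt(sum(w^2))
    t <- (Xc %*% w)[, 1]
    pa <- crossprod(Xc, t)[, 1] / sum(t^2)
    wo <- pa - sum(w * pa) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      Wo <- Wo[, seq_len(a - 1), drop = FALSE]
      Po <- Po[, seq_len(a - 1), drop = FALSE]
      To <- To[, seq_len(a - 1), drop = FALSE]
      break
    }
    wo <- wo / nwo
    to <- (Xc %*% wo)[, 1]
    po <- crossprod(Xc, to)[, 1] / sum(to^2)
    Wo[, a] <- wo; Po[, a] <- po; To[, a] <- to
    Xc <- Xc - tcrossprod(to, po)
  }
  # predictive component on the orthogonality-filtered X
  w <- crossprod(Xc, yc)[, 1]
  w <- w / sqrt(sum(w^2))
  t <- (Xc %*% w)[, 1]
  tt <- sum(t^2)
  qv <- sum(t * yc) / tt
  pa <- crossprod(Xc, t)[, 1] / tt
  new("PLSModel",
      weights = matrix(w, p, 1, dimnames = list(colnames(Xc), NULL)),
      scores = matrix(t, n, 1, dimnames = list(rownames(X), NULL)),
      loadings = matrix(pa, p, 1, dimnames = list(colnames(Xc), NULL)),
      q = qv, orthoWeights = Wo, orthoScores = To, orthoLoadings = Po,
      center = prep$center, scale = prep$scale,
      yMean = mean(resp$code), classLevels = resp$levels,
      droppedFeatures = prep$dropped_ids)
}

#' Differential metabolites by VIP and univariate p
#'
#' Fits PLS-DA on the normalised peak areas, computes VIP scores, tests each
#' feature with a two-sided Welch t-test, and selects features with VIP > 1
#' and p < 0.05. Fold change is the ratio of group means
#' (case over control).
#'
#' @param peaks normalised peak-table data.frame ([normalizeTotal()]).
#' @param meta sample metadata (sample_id, group with case/control).
#' @param A PLS components for the VIP (default 2).
#' @param vip_min,p_max selection thresholds.
#' @return data.frame: feature_id, compound_name, mode, compartment, vip,
#'   p, fc, log2fc, selected.
#' @export
differentialMetabolites <- function(peaks, meta, A = 2, vip_min = 1,
                                    p_max = 0.05) {
  areas <- peakAreas(peaks)
  grp <- meta$group[match(colnames(areas), meta$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata")
  case <- grp == "case"
  model <- suppressWarnings(
    plsdaFit(t(areas), factor(grp, levels = c("control", "case")), A = A))
  vip <- rep(NA_real_, nrow(areas))
  names(vip) <- rownames(areas)
  vv <- vipScores(model)
  vip[names(vv)] <- vv
  pvals <- apply(areas, 1L, function(row)
    stats::t.test(row[case], row[!case])$p.value)
  mean_case <- rowMeans(areas[, case, drop = FALSE])
  mean_control <- rowMeans(areas[, !case, drop = FALSE])
  fc <- mean_case / mean_control
  data.frame(
    feature_id = peaks$feature_id, compound_name = peaks$compound_name,
    mode = peaks$mode, compartment = peaks$compartment,
    vip = unname(vip), p = unname(pvals), fc = unname(fc),
    log2fc = log2(unname(fc)),
    selected = !is.na(vip) & vip > vip_min & pvals < p_max,
    row.names = NULL)
}

#' Merge ionisation modes, keeping the lower-p detection
#'
#' For compounds detected in both ES+ and ES-, the row from the mode with
#' the lower univariate p is retained; compounds seen in a single mode pass
#' through. Rows without a compound name (unidentified features) pass
#' through untouched. A compound duplicated within one mode is an upstream
#' error.
#'
#' @param pos,neg differential-metabolite tables
#'   ([differentialMetabolites()]) for ES+ and ES-.
#' @return merged table; one row per named compound.
#' @export
mergeModes <- function(pos, neg) {
  tabs <- rbind(pos, neg)
  named <- tabs[nzchar(tabs$compound_name) & !is.na(tabs$compound_name), ,
                drop = FALSE]
  for (md in unique(named$mode)) {
    dup <- duplicated(named$compound_name[named$mode == md])
    if (any(dup))
      stop("compound duplicated within mode ", md, ": ",
           named$compound_name[named$mode == md][dup][1])
  }
  keep <- unlist(lapply(split(seq_len(nrow(named)), named$compound_name),
                        function(i) i[which.min(named$p[i])]))
  out <- rbind(named[keep, , drop = FALSE],
               tabs[!nzchar(tabs$compound_name) | is.na(tabs$compound_name), ,
                    drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Serum-feces concordance of differential metabolites
#'
#' Compounds selected in both compartments (shared, by compound name), the
#' subset whose log2 fold changes agree in sign (concordant), and a
#' heat-matrix of per-compartment standardised log2 fold changes over the
#' shared compounds (each compartment's column scaled to mean 0, SD 1
#' across compounds).
#'
#' @param serum,feces merged differential tables per compartment.
#' @return list(shared, concordant, heat) - two name vectors and a
#'   compounds x 2 matrix.
#' @export
crossCompartment <- function(serum, feces) {
  sel_s <- serum[serum$selected, , drop = FALSE]
  sel_f <- feces[feces$selected, , drop = FALSE]
  shared <- intersect(sel_s$compound_name, sel_f$compound_name)
  ls <- sel_s$log2fc[match(shared, sel_s$compound_name)]
  lf <- sel_f$log2fc[match(shared, sel_f$compound_name)]
  concordant <- shared[sign(ls) == sign(lf)]
  heat <- if (length(shared) > 1) {
    cbind(serum = as.numeric(scale(ls)), feces = as.numeric(scale(lf)))
  } else matrix(numeric(), 0, 2, dimnames = list(NULL, c("serum", "feces")))
  if (length(shared) > 1) rownames(heat) <- shared
  list(shared = shared, concordant = concordant, heat = heat)
}
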
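#' Simulation configuration for synthetic case-control studies
#'
#' Builds and validates the parameter list consumed by the study generators
#' ([generateGeneStudy()], [generateTaxonStudy()],
#' [generateMetabolomeStudy()], [generateClinicalTable()]). Defaults emulate
#' a 50-case / 50-control gut-metagenome cohort: three planted co-abundance
#' blocks of 60 genes at within-block correlation 0.95, case enterotype mix
#' 82%/18% versus 50%/50% in controls, fourfold planted differential
#' effects, and a metabolome with 27 compounds differential in both
#' compartments of which 16 share the effect sign.
#'
#' @param n_case,n_control samples per group.
#' @param n_genes total genes in the gene study (planted blocks + noise).
#' @param n_planted_cags number of planted co-abundance blocks.
#' @param cag_size_range integer(2), inclusive range of block sizes.
#' @param within_cag_correlation target pairwise correlation of log depths
#'   within a block (latent factor + gene noise construction).
#' @param factor_sd log-scale SD of the shared per-block latent factor.
#' @param effect_size fold-change multiplier applied to case samples for
#'   planted differential features (blocks, genera, metabolites).
#' @param noise_sd log-scale SD of gene-specific measurement noise.
#' @param n_effect_cags how many planted blocks carry a group effect
#'   (alternating sign); defaults to all of them.
#' @param n_genera number of genera in the taxon study.
#' @param n_diff_taxa number of genera carrying a planted group effect.
#' @param enterotype_mix named fractions of case/control samples assigned to
#'   the Bacteroides-dominant enterotype.
#' @param n_metabolites LC-MS features per compartment and ionisation mode.
#' @param n_shared_differential compounds planted differential in both serum
#'   and feces.
#' @param n_concordant of those, how many share the effect sign.
#' @param n_compartment_only_diff extra compounds differential in exactly one
#'   compartment.
#' @param metabolite_effect fold-change multiplier for planted metabolites.
#' @param metabolite_noise_sd log-scale SD of peak-area noise.
#' @param n_linked taxon-coupled metabolites (microbe-metabolite links).
#' @param linkage_coef linear coupling strength on the log scale.
#' @param hit_fraction fraction of each planted block's genes given an
#'   alignment hit to its synthetic source genome.
#' @param detection_limit depth below which a gene is reported as absent
#'   (0), emulating the detection floor of real depth profiles; set to 0
#'   for fully dense matrices.
#' @param seed integer RNG seed; identical seeds give identical studies.
#'
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_case = 50L, n_control = 50L,
                             n_genes = 800L, n_planted_cags = 3L,
                             cag_size_range = c(60L, 60L),
                             within_cag_correlation = 0.95,
                             factor_sd = 0.6,
                             effect_size = 4,
                             noise_sd = 0.1,
                             n_effect_cags = n_planted_cags,
                             n_genera = 60L, n_diff_taxa = 20L,
                             enterotype_mix = c(case = 0.82, control = 0.50),
                             n_metabolites = 300L,
                             n_shared_differential = 27L,
                             n_concordant = 16L,
                             n_compartment_only_diff = 20L,
                             metabolite_effect = 3,
                             metabolite_noise_sd = 0.4,
                             n_linked = 8L,
                             linkage_coef = 0.8,
                             hit_fraction = 0.95,
                             detection_limit = 0.25,
                             seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_genes = as.integer(n_genes),
              n_planted_cags = as.integer(n_planted_cags),
              cag_size_range = as.integer(cag_size_range),
              within_cag_correlation = within_cag_correlation,
              factor_sd = factor_sd, effect_size = effect_size,
              noise_sd = noise_sd, n_effect_cags = as.integer(n_effect_cags),
              n_genera = as.integer(n_genera),
              n_diff_taxa = as.integer(n_diff_taxa),
              enterotype_mix = enterotype_mix,
              n_metabolites = as.integer(n_metabolites),
              n_shared_differential = as.integer(n_shared_differential),
              n_concordant = as.integer(n_concordant),
              n_compartment_only_diff = as.integer(n_compartment_only_diff),
              metabolite_effect = metabolite_effect,
              metabolite_noise_sd = metabolite_noise_sd,
              n_linked = as.integer(n_linked), linkage_coef = linkage_coef,
              hit_fraction = hit_fraction,
              detection_limit = detection_limit, seed = as.integer(seed))
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_genes, cfg$n_genera,
              cfg$n_metabolites)
  if (any(counts <= 0)) stop("all counts must be positive")
  fr <- c(cfg$within_cag_correlation, cfg$enterotype_mix, cfg$hit_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$metabolite_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (cfg$detection_limit < 0) stop("detection_limit must be non-negative")
  if (length(cfg$cag_size_range) != 2L ||
      cfg$cag_size_range[1] > cfg$cag_size_range[2])
    stop("cag_size_range must be an increasing pair")
  if (cfg$cag_size_range[2] >= cfg$n_genes)
    stop("cag_size_range upper bound must be below n_genes")
  if (cfg$n_planted_cags * cfg$cag_size_range[2] > cfg$n_genes)
    stop("planted blocks cannot exceed n_genes in total")
  if (cfg$n_effect_cags > cfg$n_planted_cags)
    stop("n_effect_cags cannot exceed n_planted_cags")
  if (cfg$n_concordant > cfg$n_shared_differential)
    stop("n_concordant cannot exceed n_shared_differential")
  if (!all(c("case", "control") %in% names(cfg$enterotype_mix)))
    stop("enterotype_mix needs named 'case' and 'control' entries")
  class(cfg) <- "SimulationConfig"
  cfg
}

# sample ids and groups are a pure function of the config (no RNG) so every
# generator emits the same cohort
.sampleMetadata <- function(config) {
  n <- config$n_case + config$n_control
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("case", "control"), c(config$n_case, config$n_control)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic gene-level metagenome study
#'
#' Plants \code{n_planted_cags} co-abundance blocks: genes within a block
#' share a lognormal latent factor per sample, so their depth profiles are
#' correlated at the configured level; a configured subset of blocks carries
#' an alternating-sign group effect (case depth multiplied by
#' \code{effect_size} or its reciprocal). The remaining genes are
#' independent noise. Each planted block's genes are assigned (at rate
#' \code{hit_fraction}) to one synthetic species genome in the alignment hit
#' table, at identities/overlaps that satisfy the species-level tracer-gene
#' rule. Gene lengths are uniform on [300, 3000] nt.
#'
#' @param config a [simulationConfig()].
#' @return list with elements \code{genes} (depth [AbundanceMatrix-class]),
#'   \code{gene_lengths} (named numeric, nt), \code{hits} (hit-table
#'   data.frame), \code{meta} (sample metadata) and \code{truth} (ground
#'   truth: \code{cag_membership}, \code{differential_genes} with sign,
#'   block taxa).
#' @export
generateGeneStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  meta <- .sampleMetadata(config)
  n <- nrow(meta)
  case <- meta$group == "case"
  r <- config$within_cag_correlation
  tau <- config$factor_sd
  # total within-block log-noise variance achieving the target correlation,
  # split between block noise and shared measurement noise
  sig2 <- max(tau^2 * (1 / max(r, 1e-12) - 1) - config$noise_sd^2, 0)
  size_pool <- seq(config$cag_size_range[1], config$cag_size_range[2])
  sizes <- if (config$n_planted_cags > 0)
    size_pool[sample.int(length(size_pool), config$n_planted_cags,
                         replace = TRUE)] else integer()
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  logd <- matrix(0, config$n_genes, n,
                 dimnames = list(gene_ids, meta$sample_id))
  membership <- character()
  diff_genes <- character()
  diff_sign <- integer()
  block_taxa <- data.frame(cluster = character(), species = character(),
                           genus = character(), sign = integer(),
                           stringsAsFactors = FALSE)
  idx <- 0L
  signs <- rep_len(c(1L, -1L), config$n_planted_cags)
  for (b in seq_len(config$n_planted_cags)) {
    g <- idx + seq_len(sizes[b]); idx <- idx + sizes[b]
    f <- stats::rnorm(n, 0, tau)
    carries <- b <= config$n_effect_cags
    if (carries)
      f[case] <- f[case] + signs[b] * log(config$effect_size)
    base <- stats::rnorm(sizes[b], 0, 0.5)
    noise <- matrix(stats::rnorm(sizes[b] * n, 0, sqrt(sig2)), sizes[b], n)
    logd[g, ] <- base + rep(f, each = sizes[b]) + noise
    membership[gene_ids[g]] <- sprintf("block_%d", b)
    if (carries) {
      diff_genes <- c(diff_genes, gene_ids[g])
      diff_sign <- c(diff_sign, rep(signs[b], sizes[b]))
    }
    block_taxa <- rbind(block_taxa, data.frame(
      cluster = sprintf("block_%d", b),
      species = sprintf("Species_%d", b), genus = sprintf("Genus_%d", b),
      sign = if (carries) signs[b] else 0L, stringsAsFactors = FALSE))
  }
  if (idx < config$n_genes) {
    g <- (idx + 1L):config$n_genes
    logd[g, ] <- stats::rnorm(length(g), 0, 0.5) +
      matrix(stats::rnorm(length(g) * n, 0, 0.8), length(g), n)
  }
  logd <- logd + matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                        config$n_genes, n)
  depth <- exp(logd)
  depth[depth < config$detection_limit] <- 0
  genes <- AbundanceMatrix(depth, kind = "depth")
  gene_lengths <- stats::setNames(
    as.numeric(sample(300:3000, config$n_genes, replace = TRUE)), gene_ids)
  hits <- .syntheticHitTable(membership, block_taxa, config)
  truth <- list(cag_membership = membership,
                differential_genes = stats::setNames(diff_sign, diff_genes),
                block_taxa = block_taxa)
  list(genes = genes, gene_lengths = gene_lengths, hits = hits,
       meta = meta, truth = truth)
}

.syntheticHitTable <- function(membership, block_taxa, config) {
  rows <- list()
  for (b in seq_len(nrow(block_taxa))) {
    genes <- names(membership)[membership == block_taxa$cluster[b]]
    hit <- genes[stats::runif(length(genes)) <= config$hit_fraction]
    if (!length(hit)) next
    nt <- stats::runif(length(hit), 96, 99.5)
    aa <- stats::runif(length(hit), 90, 99)
    ov <- stats::runif(length(hit), 0.75, 0.95)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = rep(hit, 2L),
      target_taxon = rep(c(block_taxa$species[b], block_taxa$genus[b]),
                         each = length(hit)),
      level = rep(c("species", "genus"), each = length(hit)),
      nt_identity = rep(nt, 2L), aa_identity = rep(aa, 2L),
      query_overlap = rep(ov, 2L), stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), target_taxon = character(),
               level = character(), nt_identity = numeric(),
               aa_identity = numeric(), query_overlap = numeric())
}

# fixed genus -> phylum map used by the taxon generator; extra genera beyond
# the named ones cycle through Firmicutes and Bacteroidetes
.genusCatalogue <- function(n_genera) {
  named <- c(Bacteroides = "Bacteroidetes", Prevotella = "Bacteroidetes",
             Alistipes = "Bacteroidetes", Parabacteroides = "Bacteroidetes",
             Blautia = "Firmicutes", Dorea = "Firmicutes",
             Streptococcus = "Firmicutes", Enterococcus = "Firmicutes",
             Veillonella = "Firmicutes", Coprobacillus = "Firmicutes",
             Ruminococcus = "Firmicutes", Faecalibacterium = "Firmicutes",
             Roseburia = "Firmicutes", Eubacterium = "Firmicutes",
             Oscillibacter = "Firmicutes", Butyricicoccus = "Firmicutes",
             Flavonifractor = "Firmicutes", Bilophila = "Proteobacteria",
             Escherichia = "Proteobacteria", Bifidobacterium = "Actinobacteria")
  if (n_genera < 2L) stop("need at least 2 genera")
  if (n_genera <= length(named)) return(named[seq_len(n_genera)])
  extra_n <- n_genera - length(named)
  extra <- stats::setNames(
    rep_len(c("Firmicutes", "Bacteroidetes"), extra_n),
    sprintf("Genus_%03d", seq_len(extra_n)))
  c(named, extra)
}

#' Generate a synthetic taxon-profile study with two enterotypes
#'
#' Each sample's genus profile is a Dirichlet draw from one of two parameter
#' vectors that differ only in which genus carries the dominant mass:
#' Bacteroides (enterotype 1) or Prevotella (enterotype 2). Per-group
#' enterotype proportions follow \code{enterotype_mix} (exact counts).
#' \code{n_diff_taxa} genera (excluding the two drivers) carry an
#' alternating-sign group effect of \code{effect_size}; profiles are
#' re-normalised afterwards, so every column sums to 1. The species table
#' splits each genus into 1-3 species; the phylum table aggregates genera
#' through a fixed genus-to-phylum map containing Firmicutes and
#' Bacteroidetes.
#'
#' @param config a [simulationConfig()].
#' @return list with relative [AbundanceMatrix-class] elements \code{genus},
#'   \code{species}, \code{phylum}, plus \code{meta} and \code{truth}
#'   (\code{enterotype_label} per sample, \code{differential_genera} with
#'   sign, the genus-to-phylum map).
#' @export
generateTaxonStudy <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1000L)
  meta <- .sampleMetadata(config)
  n <- nrow(meta)
  catalogue <- .genusCatalogue(config$n_genera)
  genera <- names(catalogue)
  # baseline Dirichlet mass: power-law tail over the non-driver genera
  alpha0 <- 2 / seq_along(genera)^0.7
  names(alpha0) <- genera
  # planted differential genera sit in the detectable mid-abundance range:
  # up-shifted genera get mass 1 and down-shifted mass effect_size * 1, so
  # the expected compositional mass moved up equals the mass moved down and
  # non-planted genera stay null in relative abundance
  pool <- setdiff(genera, c("Bacteroides", "Prevotella"))
  diff_taxa <- pool[seq_len(min(config$n_diff_taxa, length(pool)))]
  signs <- stats::setNames(rep_len(c(1L, -1L), length(diff_taxa)), diff_taxa)
  e <- config$effect_size
  alpha0[diff_taxa] <- ifelse(signs > 0, 1, max(e, 1))
  a1 <- a2 <- alpha0
  a1["Bacteroides"] <- 30; a1["Prevotella"] <- 0.5
  a2["Prevotella"] <- 30; a2["Bacteroides"] <- 0.5
  ent <- integer(n)
  for (grp in c("case", "control")) {
    ids <- which(meta$group == grp)
    n1 <- round(config$enterotype_mix[[grp]] * length(ids))
    ent[ids] <- rep(c(1L, 2L), c(n1, length(ids) - n1))
  }
  prof <- vapply(seq_len(n), function(i) {
    a <- if (ent[i] == 1L) a1 else a2
    g <- stats::rgamma(length(a), shape = a, rate = 1)
    g / sum(g)
  }, numeric(length(genera)))
  dimnames(prof) <- list(genera, meta$sample_id)
  # planted group effects, alternating sign
  case <- meta$group == "case"
  for (tx in diff_taxa)
    prof[tx, case] <- prof[tx, case] * e^signs[[tx]]
  prof <- sweep(prof, 2L, colSums(prof), "/")
  genus <- AbundanceMatrix(prof, kind = "relative")
  # species: split each genus into 1-3 species with fixed proportions
  set.seed(config$seed + 2000L)
  n_sp <- sample(1:3, length(genera), replace = TRUE)
  sp_rows <- list(); sp_names <- character(); sp_genus <- character()
  for (i in seq_along(genera)) {
    w <- stats::rgamma(n_sp[i], shape = 3); w <- w / sum(w)
    sp_rows[[i]] <- outer(w, prof[i, ])
    sp_names <- c(sp_names, sprintf("%s_sp%d", genera[i], seq_len(n_sp[i])))
    sp_genus <- c(sp_genus, rep(genera[i], n_sp[i]))
  }
  sp <- do.call(rbind, sp_rows)
  dimnames(sp) <- list(sp_names, meta$sample_id)
  species <- AbundanceMatrix(sp, kind = "relative")
  phy <- rowsum(prof, group = unname(catalogue))
  phylum <- AbundanceMatrix(phy, kind = "relative")
  # an imbalanced enterotype mix makes the two driver genera genuinely
  # differential (more Bacteroides-dominant samples among cases pulls
  # Bacteroides up and Prevotella down); the ground truth records that
  mix_diff <- config$enterotype_mix[["case"]] - config$enterotype_mix[["control"]]
  driver_signs <- if (mix_diff > 0) c(Bacteroides = 1L, Prevotella = -1L)
    else if (mix_diff < 0) c(Bacteroides = -1L, Prevotella = 1L)
    else stats::setNames(integer(), character())
  truth <- list(
    enterotype_label = stats::setNames(ent, meta$sample_id),
    differential_genera = c(signs, driver_signs),
    planted_genera = signs,
    genus_phylum_map = catalogue,
    species_genus_map = stats::setNames(sp_genus, sp_names))
  list(genus = genus, species = species, phylum = phylum, meta = meta,
       truth = truth)
}

#' Generate synthetic LC-MS peak tables for serum and feces
#'
#' Emits one peak table per compartment (serum, feces) and ionisation mode
#' (ES+, ES-) over the taxon study's samples. Peak areas are lognormal.
#' Planted structure: \code{n_shared_differential} compounds carry a group
#' effect in both compartments (\code{n_concordant} with the same sign,
#' the rest opposite), \code{n_compartment_only_diff} compounds are
#' differential in exactly one compartment, and \code{n_linked} compounds
#' are linearly coupled (on the log scale, plus noise) to planted
#' differential genera. Compounds keep one \code{compound_name} across
#' compartments and modes; a third of compounds are detected in both modes
#' so the lower-p mode-merging rule is exercised.
#'
#' @param config a [simulationConfig()].
#' @param taxon_study output of [generateTaxonStudy()] (same sample set).
#' @return list with \code{tables} (nested list
#'   \code{$serum$pos/$neg}, \code{$feces$pos/$neg} of peak-table
#'   data.frames), \code{meta}, and \code{truth} (differential compounds
#'   with sign per compartment, shared/concordant name sets, taxon links).
#' @export
generateMetabolomeStudy <- function(config, taxon_study) {
  stopifnot(inherits(config, "SimulationConfig"))
  meta <- taxon_study$meta
  set.seed(config$seed + 3000L)
  n <- nrow(meta)
  case <- meta$group == "case"
  n_met <- config$n_metabolites
  n_sh <- config$n_shared_differential
  n_co <- config$n_concordant
  n_only <- config$n_compartment_only_diff
  n_pool <- n_met + n_only  # distinct compounds per compartment
  cmpd <- sprintf("cmpd_%04d", seq_len(n_pool + n_only))
  # layout of the compound pool:
  #   1..n_sh                      differential in both compartments
  #   next n_only                  serum-only differential
  #   next n_only                  feces-only differential
  #   rest                         null
  sh <- cmpd[seq_len(n_sh)]
  serum_only <- cmpd[n_sh + seq_len(n_only)]
  feces_only <- cmpd[n_sh + n_only + seq_len(n_only)]
  sh_sign_serum <- rep_len(c(1L, -1L), n_sh)
  sh_sign_feces <- sh_sign_serum
  if (n_sh > n_co)
    sh_sign_feces[(n_co + 1L):n_sh] <- -sh_sign_feces[(n_co + 1L):n_sh]
  eff <- list(
    serum = stats::setNames(c(sh_sign_serum, rep_len(c(1L, -1L), n_only)),
                            c(sh, serum_only)),
    feces = stats::setNames(c(sh_sign_feces, rep_len(c(1L, -1L), n_only)),
                            c(sh, feces_only)))
  # taxon links: couple the first n_linked shared compounds to planted genera
  link_taxa <- names(taxon_study$truth$differential_genera)
  n_link <- min(config$n_linked, n_sh, length(link_taxa))
  links <- data.frame(taxon = link_taxa[seq_len(n_link)],
                      compound = sh[seq_len(n_link)],
                      sign = 1L, stringsAsFactors = FALSE)
  rt <- stats::setNames(stats::runif(length(cmpd), 0.5, 15), cmpd)
  mass <- stats::setNames(stats::runif(length(cmpd), 80, 900), cmpd)
  both_modes <- stats::setNames(stats::runif(length(cmpd)) < 1 / 3, cmpd)
  mode_of <- stats::setNames(
    sample(c("ES+", "ES-"), length(cmpd), replace = TRUE), cmpd)
  genus_v <- abundances(taxon_study$genus)
  tables <- list(serum = list(), feces = list())
  for (comp in c("serum", "feces")) {
    pool <- c(sh, if (comp == "serum") serum_only else feces_only)
    nulls <- setdiff(cmpd, c(sh, serum_only, feces_only))
    pool <- c(pool, nulls[seq_len(n_met - length(pool))])
    base <- stats::setNames(stats::rnorm(length(pool), 10, 1), pool)
    logA <- matrix(base, length(pool), n,
                   dimnames = list(pool, meta$sample_id))
    e <- eff[[comp]]
    for (cm in names(e))
      logA[cm, case] <- logA[cm, case] + e[[cm]] * log(config$metabolite_effect)
    for (j in seq_len(nrow(links))) {
      z <- scale(log(genus_v[links$taxon[j], ] + 1e-8))[, 1]
      logA[links$compound[j], ] <- logA[links$compound[j], ] +
        config$linkage_coef * links$sign[j] * z
    }
    logA <- logA + matrix(
      stats::rnorm(length(pool) * n, 0, config$metabolite_noise_sd),
      length(pool), n)
    areas <- exp(logA)
    for (md in c("ES+", "ES-")) {
      feats <- pool[mode_of[pool] == md | both_modes[pool]]
      pt <- data.frame(
        feature_id = sprintf("%s_%s_%04d", comp,
                             if (md == "ES+") "pos" else "neg",
                             seq_along(feats)),
        compound_name = feats, mode = md, compartment = comp,
        rt_min = rt[feats], mass_da = mass[feats],
        stringsAsFactors = FALSE, row.names = NULL)
      pt <- cbind(pt, as.data.frame(areas[feats, , drop = FALSE],
                                    row.names = NULL))
      tables[[comp]][[if (md == "ES+") "pos" else "neg"]] <- pt
    }
  }
  truth <- list(
    differential_metabolites = eff,
    shared_names = sh,
    concordant_names = sh[sh_sign_serum == sh_sign_feces],
    links = links)
  list(tables = tables, meta = meta, truth = truth)
}

#' Generate a synthetic baseline clinical table
#'
#' Draws group-specific covariates in the layout of a case-control baseline
#' characteristics table: age (years), sex, body mass index, total
#' cholesterol, triglyceride and LDL cholesterol (mmol/L). Total cholesterol
#' defaults to the normal summaries 4.13 +/- 1.05 (case) versus
#' 4.82 +/- 0.96 (control); sex defaults to male proportions 32/50 versus
#' 41/50. Skewed covariates are lognormal. Deterministic under the seed.
#'
#' @param config a [simulationConfig()].
#' @param params optional overrides: a list with per-variable
#'   \code{list(case = c(mean, sd), control = c(mean, sd), dist = ...)}.
#' @return sample metadata data.frame with clinical columns appended.
#' @export
generateClinicalTable <- function(config, params = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  defaults <- list(
    age = list(case = c(65, 9), control = c(55, 6), dist = "normal"),
    bmi = list(case = c(26.3, 3.4), control = c(25.1, 3.2), dist = "normal"),
    total_cholesterol = list(case = c(4.13, 1.05), control = c(4.82, 0.96),
                             dist = "normal"),
    triglyceride = list(case = c(0.35, 0.45), control = c(0.15, 0.50),
                        dist = "lognormal"),
    ldl_cholesterol = list(case = c(0.82, 0.40), control = c(0.84, 0.30),
                           dist = "lognormal"),
    sex_male = list(case = 32 / 50, control = 41 / 50, dist = "binary"))
  if (!is.null(params)) defaults[names(params)] <- params
  set.seed(config$seed + 4000L)
  meta <- .sampleMetadata(config)
  for (v in names(defaults)) {
    p <- defaults[[v]]
    col <- numeric(nrow(meta))
    for (grp in c("case", "control")) {
      i <- meta$group == grp
      col[i] <- switch(p$dist,
        normal = stats::rnorm(sum(i), p[[grp]][1], p[[grp]][2]),
        lognormal = stats::rlnorm(sum(i), p[[grp]][1], p[[grp]][2]),
        binary = stats::rbinom(sum(i), 1L, p[[grp]][1]))
    }
    if (p$dist == "binary") {
      meta[[sub("_male$", "", v)]] <- ifelse(col == 1, "male", "female")
    } else meta[[v]] <- col
  }
  meta
}

#' Generate a complete synthetic study
#'
#' Runs every generator under one configuration and, optionally, writes all
#' tables in the package's TSV formats plus a ground-truth JSON sidecar.
#'
#' @param config a [simulationConfig()].
#' @param out_dir optional output directory; created if missing.
#' @return list with \code{gene_study}, \code{taxon_study},
#'   \code{metabolome}, \code{clinical} and \code{config}.
#' @export
simulateStudy <- function(config = simulationConfig(), out_dir = NULL) {
  gene_study <- generateGeneStudy(config)
  taxon_study <- generateTaxonStudy(config)
  metabolome <- generateMetabolomeStudy(config, taxon_study)
  clinical <- generateClinicalTable(config)
  study <- list(gene_study = gene_study, taxon_study = taxon_study,
                metabolome = metabolome, clinical = clinical,
                config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeAbundanceMatrix(gene_study$genes, file.path(out_dir, "genes.tsv"))
    utils::write.table(
      data.frame(gene_id = names(gene_study$gene_lengths),
                 length_nt = gene_study$gene_lengths),
      file.path(out_dir, "gene_lengths.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_study$hits, file.path(out_dir, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (rk in c("genus", "species", "phylum"))
      writeAbundanceMatrix(taxon_study[[rk]],
                           file.path(out_dir, paste0(rk, ".tsv")))
    for (comp in names(metabolome$tables))
      for (md in names(metabolome$tables[[comp]]))
        utils::write.table(metabolome$tables[[comp]][[md]],
                           file.path(out_dir, sprintf("%s_%s.tsv", comp, md)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    writeSampleMetadata(clinical, file.path(out_dir, "meta.tsv"))
    truth <- list(gene = gene_study$truth, taxon = taxon_study$truth,
                  metabolome = metabolome$truth)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}
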
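test_that("marker genes are a subset of input and vanish under the null", {
  st <- defaultStudy()$gene_study
  m <- markerGenes(st$genes, st$meta)
  expect_true(all(m %in% featureIds(st$genes)))
  null_st <- generateGeneStudy(simulationConfig(seed = 21L, n_genes = 300L,
                                                n_planted_cags = 0L,
                                                cag_size_range = c(2L, 3L)))
  m0 <- markerGenes(null_st$genes, null_st$meta)
  expect_lte(length(m0), 3)
  planted <- names(st$truth$differential_genes)
  expect_gte(mean(planted %in% m), 0.9)
})

test_that("canopy clustering recovers planted blocks exactly", {
  st <- defaultStudy()$gene_study
  markers <- markerGenes(st$genes, st$meta)
  cl <- canopyCluster(st$genes[markers, ])
  expect_length(cl$cags, 3)
  truth <- st$truth$cag_membership
  for (cg in cl$cags) {
    purity <- max(table(truth[cg], useNA = "ifany")) / length(cg)
    expect_gte(purity, 0.95)
  }
})

test_that("a 40-gene block is reported but never becomes a CAG", {
  cfg <- simulationConfig(seed = 22L, n_genes = 300L, n_planted_cags = 1L,
                          cag_size_range = c(40L, 40L))
  st <- generateGeneStudy(cfg)
  block <- names(st$truth$cag_membership)
  cl <- canopyCluster(st$genes[block, ])
  expect_length(cl$cags, 0)
  expect_gte(length(cl$small_clusters), 1)
  expect_setequal(unlist(cl$small_clusters), block)
})

test_that("canopy clustering is invariant to gene order", {
  st <- defaultStudy()$gene_study
  markers <- markerGenes(st$genes, st$meta)
  cl1 <- canopyCluster(st$genes[markers, ])
  set.seed(23)
  perm <- sample(markers)
  cl2 <- canopyCluster(st$genes[perm, ])
  norm <- function(cl) unname(lapply(cl$cags, sort))
  expect_setequal(norm(cl1), norm(cl2))
  tiny <- AbundanceMatrix(matrix(1:4, 2, 2))
  expect_error(canopyCluster(tiny), "fewer than 3")
})

test_that("CAG abundance is the length-weighted mean depth", {
  v <- matrix(c(2, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  genes <- AbundanceMatrix(v, kind = "depth")
  lens <- c(g1 = 100, g2 = 300)
  expect_equal(unname(cagAbundance(c("g1", "g2"), genes, lens)), 3.5)
  expect_equal(unname(cagAbundance(c("g2", "g1"), genes, lens)), 3.5)
  # equal lengths reduce to the plain mean
  expect_equal(unname(cagAbundance(c("g1", "g2"), genes,
                                   c(g1 = 500, g2 = 500))), 3)
  # linear in depth
  genes2 <- AbundanceMatrix(v * 7, kind = "depth")
  expect_equal(unname(cagAbundance(c("g1", "g2"), genes2, lens)), 7 * 3.5)
  expect_error(cagAbundance(c("g1", "gX"), genes, lens), "missing")
})

test_that("tracer-gene taxonomy rules fire at their thresholds", {
  genes <- paste0("g", 1:10)
  mk <- function(ids, taxon, level, nt, aa = 90, ov = 0.8)
    data.frame(gene_id = ids, target_taxon = taxon, level = level,
               nt_identity = nt, aa_identity = aa, query_overlap = ov)
  # 9/10 genes at 96% nt and 75% overlap: species call
  sp <- assignTaxonomy(genes, mk(genes[1:9], "S1", "species", 96, ov = 0.75))
  expect_identical(sp, list(taxon = "S1", level = "species"))
  # 8/10 genes at 86/86: genus call
  ge <- assignTaxonomy(genes, mk(genes[1:8], "G1", "genus", 86, aa = 86))
  expect_identical(ge, list(taxon = "G1", level = "genus"))
  # 7/10 qualifying genes: below both rules
  un <- assignTaxonomy(genes, rbind(
    mk(genes[1:7], "S1", "species", 96, ov = 0.75),
    mk(genes[1:7], "G1", "genus", 86, aa = 86)))
  expect_identical(un$level, "unassigned")
  # identity/overlap below threshold never counts
  low <- assignTaxonomy(genes, mk(genes, "S1", "species", 94, ov = 0.9))
  expect_identical(low$level, "unassigned")
  empty <- data.frame(gene_id = character(), target_taxon = character(),
                      level = character(), nt_identity = numeric(),
                      aa_identity = numeric(), query_overlap = numeric())
  expect_identical(assignTaxonomy(genes, empty)$level, "unassigned")
})

test_that("adding hits never demotes a species-level call", {
  genes <- paste0("g", 1:10)
  hits <- data.frame(gene_id = genes[1:9], target_taxon = "S1",
                     level = "species", nt_identity = 97,
                     aa_identity = 95, query_overlap = 0.8)
  base <- assignTaxonomy(genes, hits)
  expect_identical(base$level, "species")
  extra <- rbind(hits, data.frame(gene_id = genes[10], target_taxon = "S2",
                                  level = "species", nt_identity = 99,
                                  aa_identity = 99, query_overlap = 0.9))
  again <- assignTaxonomy(genes, extra)
  expect_identical(again$level, "species")
  expect_identical(again$taxon, "S1")
})

test_that("odds-ratio score follows the 2x2 presence construction", {
  meta <- twoGroupMeta(50, 50)
  ab <- stats::setNames(numeric(100), meta$sample_id)
  ab[c(1:40, 51:60)] <- 1  # present in 40/50 cases, 10/50 controls
  res <- oddsRatioScore(ab, meta)
  expect_equal(res$odds_ratio, 16)
  expect_identical(res$enrichment, "case_enriched")
  # identical presence: neutral
  ab2 <- stats::setNames(rep(c(1, 0), 50), meta$sample_id)
  expect_identical(oddsRatioScore(ab2, meta)$enrichment, "neutral")
  # swapping group labels inverts the ratio
  meta_swap <- meta
  meta_swap$group <- ifelse(meta$group == "case", "control", "case")
  expect_equal(oddsRatioScore(ab, meta_swap)$odds_ratio, 1 / 16)
  # zero cell triggers the Haldane-Anscombe correction
  ab3 <- stats::setNames(c(rep(1, 50), rep(0, 50)), meta$sample_id)
  res3 <- oddsRatioScore(ab3, meta)
  expect_equal(res3$odds_ratio, (50.5 * 50.5) / (0.5 * 0.5))
})

test_that("end-to-end CAG stage recovers structure and enrichment signs", {
  cs <- defaultCAGs()
  st <- defaultStudy()$gene_study
  expect_s4_class(cs, "CAGSet")
  expect_length(cagMembership(cs), 3)
  # every planted effect block maps to one CAG with the matching OR sign
  truth <- st$truth
  for (i in seq_len(nrow(truth$block_taxa))) {
    blk <- truth$block_taxa$cluster[i]
    genes_b <- names(truth$cag_membership)[truth$cag_membership == blk]
    hit <- which(vapply(cagMembership(cs), function(g)
      mean(g %in% genes_b) >= 0.95, logical(1)))
    expect_length(hit, 1)
    enr <- cagEnrichment(cs)$enrichment[hit]
    expect_identical(enr, if (truth$block_taxa$sign[i] > 0)
      "case_enriched" else "case_depleted")
    expect_identical(cagTaxonomy(cs)$taxon[hit], truth$block_taxa$species[i])
    expect_identical(cagTaxonomy(cs)$level[hit], "species")
  }
})

test_that("co-occurrence network keeps only strong significant edges", {
  set.seed(24)
  n <- 50
  base <- stats::rnorm(n)
  v <- rbind(a = base + stats::rnorm(n, 0, 0.1),
             b = base + stats::rnorm(n, 0, 0.1),
             c = stats::rnorm(n), d = stats::rnorm(n))
  colnames(v) <- paste0("s", 1:n)
  net <- cooccurrenceNetwork(v)
  expect_true(any(net$source == "a" & net$target == "b"))
  expect_false(any(net$source %in% c("c", "d") & net$target %in% c("c", "d")))
  # exactly comonotone features: rho 1
  v2 <- rbind(x = 1:10, y = (1:10)^3)
  colnames(v2) <- paste0("s", 1:10)
  net2 <- cooccurrenceNetwork(v2)
  expect_equal(net2$rho, 1)
  # constant feature excluded with a warning
  v3 <- rbind(v2, z = rep(1, 10))
  expect_warning(cooccurrenceNetwork(v3), "constant")
})

test_that("independent features produce edges within the false-positive budget", {
  set.seed(25)
  v <- matrix(stats::rnorm(40 * 50), 40, 50,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:50)))
  net <- cooccurrenceNetwork(v, rho_min = 0.5, alpha = 0.05)
  # |rho| >= 0.5 at n = 50 is itself a ~4-sigma event under independence
  expect_lte(nrow(net), 3)
})
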
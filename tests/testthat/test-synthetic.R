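test_that("generators are bit-identical under a fixed seed", {
  cfg <- simulationConfig(seed = 7L, n_genes = 200L,
                          cag_size_range = c(20L, 30L), n_planted_cags = 3L)
  a <- generateGeneStudy(cfg)
  b <- generateGeneStudy(cfg)
  expect_identical(abundances(a$genes), abundances(b$genes))
  expect_identical(a$hits, b$hits)
  ta <- generateTaxonStudy(cfg); tb <- generateTaxonStudy(cfg)
  expect_identical(abundances(ta$genus), abundances(tb$genus))
  ma <- generateMetabolomeStudy(cfg, ta)
  mb <- generateMetabolomeStudy(cfg, tb)
  expect_identical(ma$tables$serum$pos, mb$tables$serum$pos)
  expect_identical(generateClinicalTable(cfg), generateClinicalTable(cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(n_genes = 50L, cag_size_range = c(60L, 60L)),
               "below n_genes")
  expect_error(simulationConfig(n_genes = 150L, n_planted_cags = 3L,
                                cag_size_range = c(40L, 60L)),
               "exceed n_genes")
  expect_error(simulationConfig(within_cag_correlation = 1.5), "fractions")
  expect_error(simulationConfig(n_case = 0L), "positive")
  expect_error(simulationConfig(n_concordant = 30L,
                                n_shared_differential = 27L),
               "n_concordant")
})

test_that("perfect correlation and zero noise give exact scalar multiples", {
  cfg <- simulationConfig(seed = 3L, n_genes = 100L, n_planted_cags = 1L,
                          cag_size_range = c(20L, 20L),
                          within_cag_correlation = 1, noise_sd = 0,
                          detection_limit = 0)
  st <- generateGeneStudy(cfg)
  block <- names(st$truth$cag_membership)
  v <- abundances(st$genes)[block, ]
  ratios <- v[-1, , drop = FALSE] / rep(v[1, ], each = length(block) - 1)
  expect_equal(apply(ratios, 1L, stats::sd), rep(0, length(block) - 1),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("planted blocks reach the configured co-abundance correlation", {
  st <- defaultStudy()$gene_study
  v <- abundances(st$genes)
  for (b in unique(st$truth$cag_membership)) {
    genes <- names(st$truth$cag_membership)[st$truth$cag_membership == b]
    cc <- stats::cor(t(v[genes[1:15], ]))
    expect_gt(mean(cc[upper.tri(cc)]), 0.9)
  }
})

test_that("hit table assigns at least 90% of each block to one species", {
  st <- defaultStudy()$gene_study
  sp_hits <- st$hits[st$hits$level == "species", ]
  for (b in unique(st$truth$cag_membership)) {
    genes <- names(st$truth$cag_membership)[st$truth$cag_membership == b]
    hit_counts <- table(sp_hits$target_taxon[sp_hits$gene_id %in% genes])
    expect_gte(max(hit_counts) / length(genes), 0.9)
  }
  expect_true(all(st$hits$nt_identity >= 0 & st$hits$nt_identity <= 100))
  expect_true(all(st$hits$query_overlap >= 0 & st$hits$query_overlap <= 1))
})

test_that("gene lengths lie in the 300-3000 nt range", {
  gl <- defaultStudy()$gene_study$gene_lengths
  expect_true(all(gl >= 300 & gl <= 3000))
})

test_that("taxon profiles are normalised and follow the enterotype mix", {
  st <- defaultStudy()$taxon_study
  for (rk in c("genus", "species", "phylum"))
    expect_equal(unname(colSums(abundances(st[[rk]]))),
                 rep(1, ncol(st[[rk]])), tolerance = 1e-12)
  lab <- st$truth$enterotype_label
  grp <- st$meta$group[match(names(lab), st$meta$sample_id)]
  expect_equal(sum(lab == 1 & grp == "case"), 41)    # 82% of 50
  expect_equal(sum(lab == 1 & grp == "control"), 25) # 50% of 50
})

test_that("phylum table is the aggregation of genera through the map", {
  st <- defaultStudy()$taxon_study
  map <- st$truth$genus_phylum_map
  expect_true(all(c("Firmicutes", "Bacteroidetes") %in% map))
  agg <- rowsum(abundances(st$genus), group = unname(map))
  expect_equal(abundances(st$phylum)[rownames(agg), ], agg)
})

test_that("metabolome tables share samples, stay positive and plant 27/16", {
  st <- defaultStudy()
  met <- st$metabolome
  for (comp in c("serum", "feces")) {
    for (md in c("pos", "neg")) {
      areas <- peakAreas(met$tables[[comp]][[md]])
      expect_true(all(areas > 0))
      expect_identical(colnames(areas), st$taxon_study$meta$sample_id)
    }
  }
  expect_length(met$truth$shared_names, 27)
  expect_length(met$truth$concordant_names, 16)
  expect_true(all(met$truth$concordant_names %in% met$truth$shared_names))
})

test_that("clinical draws match the configured summaries within 3 SE", {
  cfg <- simulationConfig(seed = 11L)
  clin <- generateClinicalTable(cfg)
  chol_case <- clin$total_cholesterol[clin$group == "case"]
  chol_ctrl <- clin$total_cholesterol[clin$group == "control"]
  expect_lt(abs(mean(chol_case) - 4.13), 3 * 1.05 / sqrt(50))
  expect_lt(abs(mean(chol_ctrl) - 4.82), 3 * 0.96 / sqrt(50))
  expect_true(all(c("age", "sex", "bmi") %in% names(clin)))
})

test_that("generated tables round-trip through the writers", {
  dir <- withr::local_tempdir()
  st <- simulateStudy(simulationConfig(seed = 5L, n_genes = 120L,
                                       n_planted_cags = 1L,
                                       cag_size_range = c(55L, 55L),
                                       n_metabolites = 60L,
                                       n_shared_differential = 10L,
                                       n_concordant = 6L,
                                       n_compartment_only_diff = 5L),
                      out_dir = dir)
  genes <- readAbundanceMatrix(file.path(dir, "genes.tsv"), kind = "depth")
  expect_equal(abundances(genes), abundances(st$gene_study$genes),
               tolerance = 1e-12)
  genus <- readAbundanceMatrix(file.path(dir, "genus.tsv"),
                               kind = "relative")
  expect_equal(abundances(genus), abundances(st$taxon_study$genus),
               tolerance = 1e-9)
  pt <- readPeakTable(file.path(dir, "serum_pos.tsv"))
  expect_equal(peakAreas(pt), peakAreas(st$metabolome$tables$serum$pos),
               tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
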
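#' Run the full case-control analysis pipeline
#'
#' Orchestrates every stage over a study (as produced by [simulateStudy()]
#' or assembled from files with the readers in this package):
#' ecology -> enterotypes -> differential abundance -> clinical table ->
#' CAGs -> classifier -> metabolomics -> integration. Each stage writes its
#' tables under \code{out_dir/<stage>/} plus a machine-readable
#' \code{summary.json}; a run log records the seed and parameter values.
#' All randomness derives from \code{seed}, so two runs with identical
#' inputs and seed produce identical numeric outputs. A failing stage
#' aborts with the stage named.
#'
#' @param study list with elements \code{gene_study}, \code{taxon_study},
#'   \code{metabolome}, \code{clinical} (see [simulateStudy()]).
#' @param out_dir output directory (created; one sub-directory per stage).
#' @param seed integer seed for the stochastic stages.
#' @param alpha significance threshold (q for differential stages).
#' @param rarefaction_iterations random draws per rarefaction point.
#' @param k_range candidate enterotype counts.
#' @param ks candidate feature counts for the classifier CV curve.
#' @param ntree random-forest size.
#' @param trials,folds cross-validation design.
#' @param n_grid_taxa,n_grid_compounds integration grid sizes (top
#'   differential genera x shared serum metabolites).
#' @return (invisibly) a named list with every stage's in-memory result.
#' @export
runPipeline <- function(study, out_dir, seed = 1, alpha = 0.05,
                        rarefaction_iterations = 100, k_range = 2:10,
                        ks = c(5, 10, 20, 50, 70, 100, 200, 500, 1000),
                        ntree = 500, trials = 5, folds = 10,
                        n_grid_taxa = 10, n_grid_compounds = 16) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- study$taxon_study$meta
  results <- list()
  log_lines <- c(sprintf("gutflow %s", as.character(utils::packageVersion("gutflow"))),
                 sprintf("seed=%d alpha=%g rarefaction_iterations=%d ntree=%d trials=%d folds=%d",
                         seed, alpha, rarefaction_iterations, ntree, trials,
                         folds))
  stage <- function(name, fun) {
    dir.create(file.path(out_dir, name), showWarnings = FALSE)
    tryCatch(fun(file.path(out_dir, name)),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_json <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)

  results$ecology <- stage("ecology", function(dir) {
    rep <- diversityReport(study$gene_study$genes, study$taxon_study$genus,
                           study$taxon_study$phylum)
    grp <- meta$group[match(rep$sample_id, meta$sample_id)]
    tests <- lapply(c(gene_count = "gene_count", shannon = "shannon",
                      chao = "chao", pielou = "pielou",
                      fb_ratio = "fb_ratio"),
                    function(v) compareGroups(rep[[v]], grp,
                                              "kruskal_wallis")$p)
    curve <- rarefactionCurve(study$gene_study$genes,
                              iterations = rarefaction_iterations,
                              seed = seed)
    write_tsv(rep, file.path(dir, "diversity.tsv"))
    write_tsv(data.frame(m = curve$m, mean_genes = curve$mean_genes),
              file.path(dir, "rarefaction.tsv"))
    write_json(tests, file.path(dir, "summary.json"))
    list(report = rep, group_p = tests, rarefaction = curve)
  })

  results$enterotypes <- stage("enterotypes", function(dir) {
    et <- detectEnterotypes(study$taxon_study$genus, meta, k_range)
    write_tsv(data.frame(sample_id = names(enterotypeLabels(et)),
                         enterotype = enterotypeLabels(et)),
              file.path(dir, "labels.tsv"))
    write_tsv(data.frame(k = as.integer(names(chCurve(et))),
                         ch = chCurve(et)),
              file.path(dir, "ch_curve.tsv"))
    write_json(list(k_selected = et@kSelected,
                    dominant_taxa = et@dominantTaxa,
                    contingency = et@contingency,
                    fisher_p = et@fisherP),
               file.path(dir, "summary.json"))
    et
  })

  results$differential <- stage("differential", function(dir) {
    diff <- differentialFeatures(study$taxon_study$genus, meta, alpha)
    write_tsv(diff, file.path(dir, "genus_differential.tsv"))
    sig <- diff$feature_id[diff$significant]
    if (length(sig)) {
      z <- zscoreRows(abundances(study$taxon_study$genus)[sig, ,
                                                          drop = FALSE])
      write_tsv(data.frame(feature_id = rownames(z), z,
                           check.names = FALSE),
                file.path(dir, "zscores.tsv"))
    }
    clin <- clinicalSummary(study$clinical)
    write_tsv(clin, file.path(dir, "clinical.tsv"))
    write_json(list(n_tested = nrow(diff), n_significant = length(sig)),
               file.path(dir, "summary.json"))
    list(genus = diff, clinical = clin)
  })

  results$cags <- stage("cags", function(dir) {
    cs <- buildCAGs(study$gene_study$genes, study$gene_study$gene_lengths,
                    study$gene_study$hits, meta, alpha)
    memb <- data.frame(
      gene_id = unlist(cagMembership(cs), use.names = FALSE),
      cag_id = rep(names(cagMembership(cs)), lengths(cagMembership(cs))))
    write_tsv(memb, file.path(dir, "membership.tsv"))
    write_tsv(data.frame(cag_id = rownames(abundances(cs)), abundances(cs),
                         check.names = FALSE),
              file.path(dir, "abundance.tsv"))
    write_tsv(cagTaxonomy(cs), file.path(dir, "taxonomy.tsv"))
    write_tsv(cagEnrichment(cs), file.path(dir, "odds_ratio.tsv"))
    enriched <- cagEnrichment(cs)$cag_id[
      cagEnrichment(cs)$enrichment != "neutral"]
    edges <- if (length(enriched) >= 2)
      cooccurrenceNetwork(abundances(cs)[enriched, , drop = FALSE])
    else data.frame(source = character(), target = character(),
                    rho = numeric(), p = numeric(), q = numeric())
    write_tsv(edges, file.path(dir, "network_edges.tsv"))
    write_json(list(n_cags = length(cagMembership(cs)),
                    n_small_clusters = length(cs@smallClusters),
                    enrichment = as.list(table(cagEnrichment(cs)$enrichment))),
               file.path(dir, "summary.json"))
    list(cags = cs, network = edges)
  })

  results$classifier <- stage("classifier", function(dir) {
    rep <- trainCagClassifier(results$cags$cags, meta, ks = ks,
                              trials = trials, folds = folds,
                              ntree = ntree, seed = seed)
    write_tsv(rep@probabilities, file.path(dir, "probabilities.tsv"))
    write_tsv(rep@cvCurve, file.path(dir, "cv_curve.tsv"))
    write_tsv(rep@importance, file.path(dir, "importance.tsv"))
    write_json(list(k_selected = rep@kSelected,
                    train_auc = rep@trainAUC, train_ci = rep@trainCI,
                    test_auc = rep@testAUC, test_ci = rep@testCI),
               file.path(dir, "summary.json"))
    rep
  })

  results$metabolomics <- stage("metabolomics", function(dir) {
    merged <- list()
    norm <- list()
    for (comp in names(study$metabolome$tables)) {
      norm[[comp]] <- lapply(study$metabolome$tables[[comp]], normalizeTotal)
      diffs <- lapply(norm[[comp]], differentialMetabolites, meta = meta)
      merged[[comp]] <- mergeModes(diffs$pos, diffs$neg)
      write_tsv(merged[[comp]],
                file.path(dir, paste0(comp, "_differential.tsv")))
    }
    cc <- crossCompartment(merged$serum, merged$feces)
    if (nrow(cc$heat))
      write_tsv(data.frame(compound = rownames(cc$heat), cc$heat),
                file.path(dir, "concordance_heat.tsv"))
    write_json(list(n_selected_serum = sum(merged$serum$selected),
                    n_selected_feces = sum(merged$feces$selected),
                    n_shared = length(cc$shared),
                    n_concordant = length(cc$concordant)),
               file.path(dir, "summary.json"))
    list(merged = merged, normalized = norm, cross = cc)
  })

  results$integration <- stage("integration", function(dir) {
    diff <- results$differential$genus
    top_taxa <- head(diff$feature_id[order(diff$q)], n_grid_taxa)
    cc <- results$metabolomics$cross
    compounds <- head(if (length(cc$concordant)) cc$concordant else
                        cc$shared, n_grid_compounds)
    if (length(compounds) < 1) {
      write_json(list(note = "no shared differential compounds"),
                 file.path(dir, "summary.json"))
      return(NULL)
    }
    serum_merged <- results$metabolomics$merged$serum
    serum_peaks <- do.call(rbind, results$metabolomics$normalized$serum)
    rows <- serum_peaks[match(
      serum_merged$feature_id[match(compounds,
                                    serum_merged$compound_name)],
      serum_peaks$feature_id), , drop = FALSE]
    grid <- correlationGrid(study$taxon_study$genus, rows, top_taxa,
                            compounds)
    write_tsv(data.frame(taxon = rownames(grid$rho), grid$rho,
                         check.names = FALSE),
              file.path(dir, "rho.tsv"))
    write_tsv(data.frame(taxon = rownames(grid$p), grid$p,
                         check.names = FALSE),
              file.path(dir, "p.tsv"))
    write_tsv(data.frame(taxon = rownames(grid$stars), grid$stars,
                         check.names = FALSE),
              file.path(dir, "stars.tsv"))
    edges <- which(grid$stars != "", arr.ind = TRUE)
    write_tsv(data.frame(source = rownames(grid$rho)[edges[, 1]],
                         target = colnames(grid$rho)[edges[, 2]],
                         rho = grid$rho[edges], p = grid$p[edges]),
              file.path(dir, "edge_list.tsv"))
    write_json(list(n_taxa = length(top_taxa),
                    n_compounds = length(compounds),
                    n_starred = sum(grid$stars != "")),
               file.path(dir, "summary.json"))
    grid
  })

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
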
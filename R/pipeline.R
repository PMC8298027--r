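#' Summarize a phenotype table
#'
#' Per trait: n (non-missing records), mean, sample SD (n - 1 denominator),
#' min and max — the layout of a phenotypic summary table.
#'
#' @param pt phenotype `data.frame`.
#' @param traits trait column names; defaults to all numeric columns except
#'   `age`.
#' @return `data.frame` with columns `trait`, `n`, `mean`, `sd`, `min`,
#'   `max`. For a trait with zero records the statistics are `NA`.
#' @export
summarize_phenotypes <- function(pt, traits = NULL) {
  if (is.null(traits)) {
    num <- vapply(pt, is.numeric, logical(1))
    traits <- setdiff(names(pt)[num], c("age", "id"))
  }
  if (length(traits) < 1) stop("no traits to summarize")
  rows <- lapply(traits, function(tr) {
    x <- pt[[tr]]
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(data.frame(trait = tr, n = 0L, mean = NA_real_, sd = NA_real_,
                        min = NA_real_, max = NA_real_))
    data.frame(trait = tr, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               min = min(x), max = max(x))
  })
  do.call(rbind, rows)
}

#' Run the full genomic-evaluation pipeline on simulated data
#'
#' Simulates the configured population, applies genotype QC (call-rate filter
#' and mean imputation), builds the genomic and pedigree relationship
#' matrices, estimates heritabilities (and genetic correlations of the first
#' trait with each other trait), runs replicated cross-validation for GBLUP
#' and pedigree BLUP, and performs the population-structure analysis
#' (neighbor-joining tree of unrelated generation-1 individuals, F_ST across
#' its major clusters). Report files are written to `out_dir`:
#' `phenotype_summary.csv`, `heritability.csv`, `cv_accuracy.csv`,
#' `predicted_observed.csv`, `tree.nwk`, `fst.txt` and `manifest.txt`.
#' Report tables are rounded to 2 decimals; the scatter data keep full
#' precision. Reruns with the same config are byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param call_rate call-rate threshold for marker QC.
#' @param k,replicates cross-validation settings.
#' @param cv_trait trait used for cross-validation (default: first trait).
#' @param popgen_n number of unrelated generation-1 individuals for the
#'   population-structure analysis (capped at the family count).
#' @param n_clusters clusters cut from the NJ tree for F_ST.
#' @return (invisibly) a list with the in-memory results: `summary`,
#'   `heritability`, `cv`, `popgen`, and the simulated `data`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("run"),
                         call_rate = 0.5, k = 5L, replicates = 5L,
                         cv_trait = NULL, popgen_n = 50L, n_clusters = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(stage, ...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, ..., "\n",
        file = log_path, append = TRUE)
  }
  stage <- "simulate"
  res <- tryCatch({
    log_line(stage, "seed", config$seed)
    data <- simulate_dataset(config)
    pheno <- data$phenotypes

    stage <- "qc"
    gm <- impute_mean(call_rate_filter(data$genotypes, call_rate))
    gm_measured <- geno_matrix(
      gm$calls[as.character(pheno$id), , drop = FALSE], imputed = TRUE)
    log_line(stage, ncol(gm$calls), "markers after QC")

    stage <- "summary"
    summ <- summarize_phenotypes(pheno, config$trait_names)
    write_report(round_df(summ, 2), file.path(out_dir,
                                              "phenotype_summary.csv"))

    stage <- "relationships"
    G <- grm_vanraden(gm_measured)
    A <- nrm(data$pedigree)

    stage <- "reml"
    herit <- lapply(config$trait_names, function(tr) {
      dm <- build_design(pheno, tr)
      vc <- reml_univariate(dm, G)
      data.frame(trait = tr, kinship = "G_vanraden", sigma2_a = vc$sigma2_a,
                 sigma2_e = vc$sigma2_e, h2 = vc$h2, se_h2 = vc$se_h2,
                 r_g = NA_real_, se_rg = NA_real_, logL = vc$logL,
                 iterations = vc$iterations, converged = vc$converged)
    })
    herit <- do.call(rbind, herit)
    if (length(config$trait_names) > 1) {
      dm1 <- build_design(pheno, config$trait_names[1])
      for (tr in config$trait_names[-1]) {
        biv <- reml_bivariate(dm1, build_design(pheno, tr), G)
        herit$r_g[herit$trait == tr] <- biv$r_g
        herit$se_rg[herit$trait == tr] <- biv$se_rg
      }
    }
    write_report(round_df(herit, 2), file.path(out_dir, "heritability.csv"))

    stage <- "cross-validation"
    if (is.null(cv_trait)) cv_trait <- config$trait_names[1]
    cv_g <- cross_validate(pheno, cv_trait, gm = gm_measured,
                           method = "gblup", k = k,
                           replicates = replicates, seed = config$seed)
    cv_a <- cross_validate(pheno, cv_trait, pedigree = data$pedigree,
                           method = "ablup", k = k,
                           replicates = replicates, seed = config$seed)
    cv_tab <- data.frame(trait = cv_trait,
                         method = c("GBLUP", "BLUP"),
                         r2_mean = c(cv_g$r2_mean, cv_a$r2_mean),
                         r2_best = c(cv_g$r2_best, cv_a$r2_best),
                         r_mean = c(cv_g$r_mean, cv_a$r_mean))
    write_report(round_df(cv_tab, 2), file.path(out_dir, "cv_accuracy.csv"))
    write_report(cv_g$records, file.path(out_dir, "predicted_observed.csv"))

    stage <- "popgen"
    n_fam <- length(unique(paste(data$pedigree$sire, data$pedigree$dam,
                                 sep = "_")[data$pedigree$generation == 1]))
    sel <- select_unrelated(data$pedigree, n = min(popgen_n, n_fam),
                            generation = 1L, seed = config$seed)
    gm_sel <- geno_matrix(data$genotypes$calls[sel, , drop = FALSE])
    D <- pairwise_divergence(gm_sel)
    tree <- neighbor_joining(D)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    clusters <- cut_tree_clusters(tree, n_clusters)
    fst_val <- fst(gm_sel, clusters)
    pi_val <- nucleotide_diversity(gm_sel)
    writeLines(c(sprintf("pi_total %.6f", pi_val),
                 sprintf("fst %.4f", fst_val),
                 sprintf("clusters %d", n_clusters)),
               file.path(out_dir, "fst.txt"))

    stage <- "manifest"
    manifest <- c(
      paste("package oysterGS", as.character(utils::packageVersion("oysterGS"))),
      paste("seed", config$seed),
      paste("families_gen1", config$families_gen1),
      paste("offspring_gen1", paste(config$offspring_gen1, collapse = "-")),
      paste("families_gen2", config$families_gen2),
      paste("offspring_gen2", paste(config$offspring_gen2, collapse = "-")),
      paste("n_markers", config$n_markers),
      paste("traits", paste(config$trait_names, collapse = ",")),
      paste("call_rate", call_rate),
      paste("cv_k", k), paste("cv_replicates", replicates),
      paste("popgen_n", min(popgen_n, n_fam)),
      paste("n_clusters", n_clusters))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
    list(summary = summ, heritability = herit, cv = cv_tab,
         popgen = list(pi = pi_val, fst = fst_val, tree = tree,
                       clusters = clusters),
         data = data, out_dir = out_dir)
  }, error = function(e) {
    log_line(stage, "FAILED:", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  log_line("done")
  invisible(res)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

write_report <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
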
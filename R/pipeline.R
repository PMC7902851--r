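#' Pipeline configuration
#'
#' @param data a [synthetic_spec()] (the dataset is generated), or a named
#'   list of input paths: `tps`, `sliders`, `taxa`, `tree`, `ages`
#'   (optional), `constraints` (optional), `arms` (optional CSV; when
#'   absent, moment arms are taken from the taxon table's arm columns).
#' @param out_dir output directory for the report tables.
#' @param n_perm permutations for all tests (999 by default; pass 9999 for
#'   full-scale runs).
#' @param n_pcs PCs fed to the discriminant (default 7).
#' @param lambda Pagel's lambda for the discriminant (default 0.08), or
#'   `"grid"` to select by [select_lambda()].
#' @param fda_classes classes kept for the discriminant (default omits
#'   omnivores, which are not well separated in jaw-shape morphospace).
#' @param slide,slide_criterion semi-landmark sliding switches for the GPA.
#' @param use_tree_in_anova GLS-transform the shape ANOVA by the
#'   time-tree's Brownian covariance.
#' @param seed integer seed governing every random element.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(data, out_dir, n_perm = 999, n_pcs = 7,
                            lambda = 0.08,
                            fda_classes = c("insectivore", "carnivore",
                                            "herbivore"),
                            slide = TRUE,
                            slide_criterion = "procdist",
                            use_tree_in_anova = TRUE,
                            seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  list(data = data, out_dir = out_dir, n_perm = as.integer(n_perm),
       n_pcs = as.integer(n_pcs), lambda = lambda,
       fda_classes = fda_classes, slide = slide,
       slide_criterion = slide_criterion,
       use_tree_in_anova = use_tree_in_anova, seed = as.integer(seed))
}

load_pipeline_inputs <- function(data) {
  if (inherits(data, "synthetic_spec")) {
    ds <- synth_dataset(data)
    return(list(configs = ds$configs, taxa = ds$taxa, tree = ds$tree,
                arms = ds$arms, ground_truth = ds$ground_truth))
  }
  curves <- if (!is.null(data$sliders)) read_slider_descriptor(data$sliders)
  configs <- read_tps(data$tps, curves = curves)
  taxa <- read_taxon_table(data$taxa)
  tr <- read_newick_with_ages(data$tree, data$ages, data$constraints)
  tree <- timescale_equal(tr$tree, tr$tip_ages, tr$constraints)
  arms <- if (!is.null(data$arms)) utils::read.csv(data$arms) else {
    cols <- c("taxon_id", "inlever_masseter", "inlever_temporalis",
              "outlever_tip", "outlever_m1")
    if (!all(cols %in% names(taxa)))
      stop("no arms file and taxon table lacks moment-arm columns")
    taxa[, cols]
  }
  list(configs = configs, taxa = taxa, tree = tree,
       arms = validate_moment_arms(arms), ground_truth = NULL)
}

#' Run the full jaw-ecomorphology analysis
#'
#' Stage order: joint superimposition of all taxa (GPA with sliding), PCA
#' morphospace of the training (extant) subset with projection of the
#' predict (fossil) subset, mechanical-advantage table, permutation tests of
#' diet-group separation (pairwise Procrustes ANOVA on shape, one-way
#' PERMANOVAs on each MA variable at both bite points), and phylogenetic
#' flexible discriminant analysis with dietary posteriors for the predict
#' taxa. All tables are written as CSV under `config$out_dir` together with
#' a provenance manifest; the same tables are returned invisibly.
#'
#' PC1 is oriented, for reporting, so that herbivores score negative (short
#' jaws at the negative end); whether a flip was applied is recorded in the
#' manifest, never silent.
#'
#' @param config from [pipeline_config()].
#' @return (invisibly) a `run_report` list with every table.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(sprintf("failed_stage: %s", name),
                   sprintf("error: %s", conditionMessage(e))),
                 file.path(config$out_dir, "error_manifest.txt"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("load", load_pipeline_inputs(config$data))
  taxa <- inputs$taxa
  training_ids <- taxa$taxon_id[taxa$role == "training"]
  predict_ids <- taxa$taxon_id[taxa$role == "predict"]

  aligned <- stage("align",
    gpa(inputs$configs, slide = config$slide,
        criterion = config$slide_criterion))

  msp <- stage("pca", {
    idx_tr <- match(training_ids, aligned$taxon_ids)
    m <- fit_pca(aligned$coords[, , idx_tr, drop = FALSE], ids = training_ids)
    diet_tr <- taxa$diet_class[match(training_ids, taxa$taxon_id)]
    herb_mean <- mean(m$scores[diet_tr == "herbivore", "PC1"])
    m$pc1_flipped <- is.finite(herb_mean) && herb_mean > 0
    if (m$pc1_flipped) {
      m$loadings[, 1] <- -m$loadings[, 1]
      m$scores[, 1] <- -m$scores[, 1]
    }
    m
  })
  fossil_scores <- stage("project", {
    idx_pr <- match(predict_ids, aligned$taxon_ids)
    if (length(idx_pr))
      project_shapes(msp, aligned$coords[, , idx_pr, drop = FALSE],
                     ids = predict_ids)
    else matrix(numeric(0), 0, ncol(msp$scores),
                dimnames = list(NULL, colnames(msp$scores)))
  })

  ma <- stage("ma", ma_table(inputs$arms))

  stats_tabs <- stage("stats", {
    diet_tr <- taxa$diet_class[match(training_ids, taxa$taxon_id)]
    idx_tr <- match(training_ids, aligned$taxon_ids)
    Y <- flatten_shapes(aligned$coords[, , idx_tr, drop = FALSE])
    rownames(Y) <- training_ids
    cov <- if (config$use_tree_in_anova)
      brownian_cov(prune_tree(inputs$tree, training_ids)) else NULL
    shape_pairwise <- pairwise_shape_tests(
      Y, diet_tr, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 11), cov = cov)
    ma_tr <- ma[match(training_ids, ma$taxon_id), ]
    perm_block <- function(col, sub_seed) {
      res <- permanova_oneway(ma_tr[[col]], diet_tr, n_perm = config$n_perm,
                              seed = derive_seed(config$seed, sub_seed),
                              pairwise = TRUE)
      cbind(variable = col, F_overall = res$overall$F,
            p_overall = res$overall$p, res$pairwise)
    }
    list(shape_pairwise = shape_pairwise,
         permanova_tip = rbind(perm_block("MAM_tip", 21),
                               perm_block("MAT_tip", 22)),
         permanova_m1 = rbind(perm_block("MAM_m1", 23),
                              perm_block("MAT_m1", 24)))
  })

  pfda_res <- stage("pfda", {
    diet <- stats::setNames(taxa$diet_class, taxa$taxon_id)
    fda_train <- training_ids[diet[training_ids] %in% config$fda_classes]
    fda_ids <- c(fda_train, predict_ids)
    scores_all <- rbind(msp$scores[fda_train, , drop = FALSE],
                        fossil_scores[predict_ids, , drop = FALSE])
    tree_fda <- prune_tree(inputs$tree, fda_ids)
    labels <- diet[fda_train]
    cfg <- list(n_pcs = config$n_pcs, classes = sort(config$fda_classes))
    if (identical(config$lambda, "grid")) {
      sel <- select_lambda(scores_all, labels, tree_fda, config = cfg)
      cfg$lambda <- sel$lambda
    } else cfg$lambda <- config$lambda
    fit_pfda(scores_all, labels, tree_fda, config = cfg)
  })

  report <- stage("report", {
    out <- config$out_dir
    wr <- function(df, f) utils::write.csv(df, file.path(out, f),
                                           row.names = FALSE)
    scores_df <- data.frame(taxon_id = rownames(msp$scores),
                            round(msp$scores, 10))
    wr(scores_df, "training_scores.csv")
    wr(data.frame(taxon_id = rownames(fossil_scores),
                  round(fossil_scores, 10)), "fossil_scores.csv")
    wr(data.frame(PC = seq_along(msp$eigenvalues),
                  eigenvalue = msp$eigenvalues,
                  variance_fraction = msp$variance_fractions),
       "eigenvalues.csv")
    wr(ma, "mechanical_advantage.csv")
    all_scores <- rbind(msp$scores[, 1, drop = FALSE],
                        fossil_scores[, 1, drop = FALSE])
    ma_pc1 <- merge(ma, data.frame(taxon_id = rownames(all_scores),
                                   PC1 = all_scores[, 1]), by = "taxon_id")
    wr(ma_pc1, "ma_vs_pc1.csv")
    wr(stats_tabs$shape_pairwise, "shape_anova_pairwise.csv")
    wr(stats_tabs$permanova_tip, "permanova_tip_uncorrected_p.csv")
    wr(stats_tabs$permanova_m1, "permanova_m1_uncorrected_p.csv")
    post_df <- data.frame(taxon_id = pfda_res$taxon_ids,
                          role = ifelse(pfda_res$is_training, "training",
                                        "predict"),
                          pfda_res$scores, pfda_res$posterior,
                          predicted = pfda_res$predicted)
    wr(post_df, "pfda_posteriors.csv")
    manifest <- c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("jawmorph"))),
      sprintf("seed: %d", config$seed),
      sprintf("n_perm: %d", config$n_perm),
      sprintf("n_pcs: %d", config$n_pcs),
      sprintf("lambda: %s", pfda_res$config$lambda),
      sprintf("slide: %s (%s)", config$slide, config$slide_criterion),
      sprintf("tree_in_anova: %s", config$use_tree_in_anova),
      sprintf("pc1_flipped: %s", msp$pc1_flipped),
      sprintf("n_training: %d", length(training_ids)),
      sprintf("n_predict: %d", length(predict_ids)),
      sprintf("gpa_iterations: %d", aligned$iterations_used),
      sprintf("training_rate: %.6f", pfda_res$training_rate))
    writeLines(manifest, file.path(out, "manifest.txt"))
    structure(
      list(config = config, aligned = aligned, morphospace = msp,
           fossil_scores = fossil_scores, ma = ma, stats = stats_tabs,
           pfda = pfda_res, ground_truth = inputs$ground_truth,
           manifest = manifest),
      class = "run_report")
  })
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d training + %d predict taxa; training rate %.1f%%; tables in %s\n",
              sum(!grepl("^fossil", rownames(x$morphospace$scores))),
              nrow(x$fossil_scores), 100 * x$pfda$training_rate,
              x$config$out_dir))
  invisible(x)
}
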
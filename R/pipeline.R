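#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with defaults matching the study
#' settings: depth >= 20, MF PolyPhen classes, copy-neutral window
#' [-0.2, 0.2] with >= 10 probes, >= 2 MF mutations per sample, k = 5
#' clusters on the first two principal components, survival cluster-size
#' gate 10, CART complexity parameter 0.1 with 10-fold cross-validation.
#'
#' @param mutations,segments,clinical Input tables: file paths or data
#'   frames in the layouts produced by the `read_*` functions.
#' @param dialect Mutation-table column dialect (used when `mutations` is a
#'   path); default [gdc_maf_dialect()].
#' @param min_depth,mean_lo,mean_hi,min_probes,min_mf,cap Filter-chain
#'   settings; see [run_filter_chain()].
#' @param grid_points,bw,scale_constant,percent Shape-parameter settings;
#'   see [compute_m_peak()] and [compute_m_math()].
#' @param k,standardize,n_components Clustering settings; see
#'   [fit_cohort_clusters()].
#' @param min_cluster_size,covariates Survival settings; see [fit_cox()].
#' @param cp,min_leaf,folds Tree settings; see [fit_cart()] and
#'   [cross_validate()].
#' @param seed Single seed fanned out deterministically to every stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mutations, segments, clinical,
                            dialect = gdc_maf_dialect(),
                            min_depth = 20, mean_lo = -0.2, mean_hi = 0.2,
                            min_probes = 10, min_mf = 2, cap = TRUE,
                            grid_points = 512, bw = "nrd0",
                            scale_constant = 1.4826, percent = FALSE,
                            k = 5, standardize = TRUE, n_components = 2,
                            min_cluster_size = 10,
                            covariates = c("age", "gender", "stage"),
                            cp = 0.1, min_leaf = 5, folds = 10, seed = 1) {
  structure(
    list(mutations = mutations, segments = segments, clinical = clinical,
         dialect = dialect, min_depth = min_depth, mean_lo = mean_lo,
         mean_hi = mean_hi, min_probes = min_probes, min_mf = min_mf,
         cap = cap, grid_points = grid_points, bw = bw,
         scale_constant = scale_constant, percent = percent, k = k,
         standardize = standardize, n_components = n_components,
         min_cluster_size = min_cluster_size, covariates = covariates,
         cp = cp, min_leaf = min_leaf, folds = folds, seed = seed),
    class = "pipeline_config"
  )
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes filter -> shape -> cluster -> survival -> cohort statistics ->
#' decision tree, writing every report table, the persisted cluster model
#' and tree rendering, and a run manifest (settings, seed, per-stage counts,
#' md5 checksums of outputs) to `out_dir`. Reruns with the same inputs and
#' seed produce byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results: `filter`,
#'   `profile`, `model`, `labels`, `survival`, `stats`, `tree`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  muts <- run_stage("load", {
    res <- load_input(config$mutations, read_mutations, dialect = config$dialect)
    if (is.list(res) && !is.data.frame(res)) res$mutations else res
  })
  segs <- run_stage("load", load_input(config$segments, read_segments))
  clin <- run_stage("load", load_input(config$clinical, read_clinical))

  filt <- run_stage("filter", run_filter_chain(
    muts, segs, clin, min_depth = config$min_depth, mean_lo = config$mean_lo,
    mean_hi = config$mean_hi, min_probes = config$min_probes,
    min_mf = config$min_mf, cap = config$cap
  ))
  write_tsv(filt$report, file.path(out_dir, "filter_report.tsv"))

  prof <- run_stage("profile", profile_cohort(
    filt$vaf_sets, grid_points = config$grid_points, bw = config$bw,
    scale_constant = config$scale_constant, percent = config$percent
  ))
  params <- prof$params
  params$cancer_type <- clin$cancer_type[match(params$sample_id, clin$sample_id)]
  write_tsv(params[, c("sample_id", "cancer_type", "m_peak", "m_count",
                       "m_math", "n_mf")],
            file.path(out_dir, "shape_params.tsv"))
  cors <- as.data.frame(prof$correlations)
  cors <- cbind(parameter = rownames(cors), cors)
  write_tsv(cors, file.path(out_dir, "parameter_correlations.tsv"))

  model <- run_stage("cluster", fit_cohort_clusters(
    params, k = config$k, standardize = config$standardize,
    n_components = config$n_components,
    seed = derive_seed(config$seed, "cluster")
  ))
  labels <- model$labels
  label_df <- data.frame(sample_id = names(labels), cluster = as.integer(labels),
                         stringsAsFactors = FALSE)
  write_tsv(label_df, file.path(out_dir, "cluster_labels.tsv"))
  save_cohort_model(model, file.path(out_dir, "cohort_model.json"))
  write_tsv(
    data.frame(component = paste0("PC", 1:3),
               explained_variance_fraction = model$pca$explained),
    file.path(out_dir, "pca_variance.tsv")
  )

  surv <- run_stage("survive", {
    cl <- clin[match(names(labels), clin$sample_id), , drop = FALSE]
    covs <- cl[, intersect(config$covariates, names(cl)), drop = FALSE]
    hr_mat <- cox_hr_matrix(cl$survival_days, cl$event, as.integer(labels),
                            covariates = covs,
                            min_cluster_size = config$min_cluster_size)
    ref_sel <- select_reference_cluster(hr_mat)
    adjusted <- fit_cox(cl$survival_days, cl$event, as.integer(labels),
                        reference = as.integer(ref_sel$reference),
                        covariates = covs,
                        min_cluster_size = config$min_cluster_size)
    univ <- univariate_cluster_cox(cl$survival_days, cl$event,
                                   as.integer(labels),
                                   reference = as.integer(ref_sel$reference),
                                   min_cluster_size = config$min_cluster_size)
    km <- km_estimate(cl$survival_days, cl$event, as.integer(labels))
    list(reference = ref_sel, adjusted = adjusted, univariate = univ, km = km)
  })
  hr_tab <- rbind(
    cbind(model = "adjusted", reference = surv$adjusted$reference,
          surv$adjusted$table),
    cbind(model = "univariate", reference = surv$univariate$reference,
          surv$univariate$table)
  )
  write_tsv(hr_tab, file.path(out_dir, "hazard_ratios.tsv"))
  write_tsv(surv$km, file.path(out_dir, "km_curves.tsv"))

  stat <- run_stage("stats", {
    mf <- filter_mf(filter_depth(muts, config$min_depth))
    mf <- mf[mf$sample_id %in% names(labels), , drop = FALSE]
    mf$cluster <- labels[mf$sample_id]
    spectrum <- do.call(rbind, lapply(sort(unique(mf$cluster)), function(cl) {
      sp <- mutation_spectrum(mf[mf$cluster == cl, , drop = FALSE])
      data.frame(cluster = cl, class = names(sp$counts),
                 count = as.integer(sp$counts), fraction = sp$fractions,
                 stringsAsFactors = FALSE)
    }))
    cnv <- do.call(rbind, lapply(names(labels), function(sid) {
      data.frame(sample_id = sid, cluster = as.integer(labels[sid]),
                 cnv_abundance = cnv_abundance(
                   segs[segs$sample_id == sid, , drop = FALSE]),
                 stringsAsFactors = FALSE)
    }))
    genes <- per_gene_mf_frequency(mf, labels)
    cl <- clin[match(names(labels), clin$sample_id), , drop = FALSE]
    cl$cluster <- as.integer(labels)
    tests <- list()
    if (any(!is.na(cl$age))) {
      tests$age <- compare_continuous(cl$age, cl$cluster)
    }
    for (v in c("gender", "stage")) {
      if (v %in% names(cl) && any(!is.na(cl[[v]]))) {
        tab <- table(cl[[v]], cl$cluster)
        tests[[v]] <- tryCatch(
          compare_categorical(tab, seed = derive_seed(config$seed, "stats")),
          error = function(e) NULL
        )
      }
    }
    tests <- Filter(Negate(is.null), tests)
    raw_p <- vapply(tests, `[[`, numeric(1), "p")
    test_tab <- data.frame(
      comparison = names(tests),
      test_used = vapply(tests, `[[`, character(1), "test_used"),
      raw_p = raw_p, adjusted_p = adjust_bh(raw_p), stringsAsFactors = FALSE
    )
    list(spectrum = spectrum, cnv = cnv, genes = genes, tests = test_tab)
  })
  write_tsv(stat$spectrum, file.path(out_dir, "mutation_spectrum.tsv"))
  write_tsv(stat$cnv, file.path(out_dir, "cnv_abundance.tsv"))
  write_tsv(stat$genes$top, file.path(out_dir, "top_genes.tsv"))
  write_tsv(stat$tests, file.path(out_dir, "clinical_tests.tsv"))

  tree <- run_stage("classify", {
    fit <- fit_cart(params, as.integer(labels), cp = config$cp,
                    min_leaf = config$min_leaf)
    cv <- cross_validate(params, as.integer(labels), folds = config$folds,
                         seed = derive_seed(config$seed, "classify"),
                         cp = config$cp, min_leaf = config$min_leaf)
    list(fit = fit, cv = cv)
  })
  writeLines(render_tree(tree$fit), file.path(out_dir, "decision_tree.txt"))
  write_tsv(
    data.frame(fold = seq_along(tree$cv$fold_accuracy),
               accuracy = tree$cv$fold_accuracy),
    file.path(out_dir, "cv_accuracy.tsv")
  )

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("ithshape")),
    seed = config$seed,
    settings = config[setdiff(names(config),
                              c("mutations", "segments", "clinical", "dialect"))],
    counts = list(
      n_samples_input = length(unique(muts$sample_id)),
      n_samples_profiled = nrow(params),
      n_mutations_input = nrow(muts),
      n_clusters = config$k,
      cv_mean_accuracy = tree$cv$mean
    ),
    outputs = as.list(tools::md5sum(sort(outputs)))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(filter = filt, profile = prof, model = model,
                 labels = labels, survival = surv, stats = stat,
                 tree = tree, manifest = manifest))
}
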
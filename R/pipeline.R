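#' Derive a per-stage seed from the run seed
#'
#' A fixed splitting rule, so e.g. changing the GA configuration never
#' perturbs the synthetic data. Always below 2^31.
#'
#' @param seed integer run seed.
#' @param stage small integer stage index.
#' @return integer stage seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 7919) %% 2147483629)
}

#' Pipeline run configuration
#'
#' @param modality `"uv"` or `"ftir"` (selects the default synthetic
#'   generator when no dataset is supplied).
#' @param method `"both"`, `"spa"` or `"ga"`.
#' @param seed run seed; expanded to per-stage seeds via [stage_seed()].
#' @param output_dir directory for run artifacts (created if missing).
#' @param preprocess a [preprocess_config()].
#' @param train_fraction per-class Kennard-Stone training fraction.
#' @param spa an [spa_config()].
#' @param ga_combos list of `c(population, generations)` pairs to try; the
#'   best-cost run is flagged. Default: the single 100/100 combination; pass
#'   `list(c(100,100), c(200,200), c(300,300))` for the full sweep.
#' @param average_replicates collapse replicates to per-sample means before
#'   multivariate analysis (default TRUE).
#' @param dataset optional [spectral_dataset] to analyse instead of
#'   simulating one.
#' @return a `run_config` object.
#' @export
run_config <- function(modality = c("uv", "ftir"),
                       method = c("both", "spa", "ga"),
                       seed = 1L, output_dir = tempfile("chemodisc_run_"),
                       preprocess = preprocess_config(),
                       train_fraction = 2 / 3,
                       spa = spa_config(),
                       ga_combos = list(c(100L, 100L)),
                       average_replicates = TRUE,
                       dataset = NULL) {
  structure(list(modality = match.arg(modality), method = match.arg(method),
                 seed = as.integer(seed), output_dir = output_dir,
                 preprocess = preprocess, train_fraction = train_fraction,
                 spa = spa, ga_combos = ga_combos,
                 average_replicates = average_replicates, dataset = dataset),
            class = "run_config")
}

#' Run the full discrimination pipeline
#'
#' simulate (unless a dataset is supplied) -> average replicates ->
#' preprocess -> PCA/HCA exploration -> per-class Kennard-Stone split ->
#' SPA-LDA and/or GA-LDA variable selection -> evaluation (LOO-CV + test
#' figures of merit). All artifacts (CSV/JSON/Newick) are written once into
#' `cfg$output_dir`; a manifest records the configuration, artifact
#' checksums and versions. Deterministic given `cfg$seed`.
#'
#' For exploratory analysis the data are globally mean-centered; for the
#' supervised stages centering is fitted on the training partition and
#' applied to the test partition.
#'
#' @param cfg a [run_config()].
#' @return the manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)
  wjson <- function(x, f) jsonlite::write_json(x, out(f), auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE)
  log_line <- function(...) message(sprintf(...))

  # -- stage 1: data ---------------------------------------------------
  if (is.null(cfg$dataset)) {
    gen_cfg <- if (cfg$modality == "uv") {
      uv_default_config(seed = stage_seed(cfg$seed, 1L))
    } else {
      ftir_default_config(seed = stage_seed(cfg$seed, 1L))
    }
    gen <- generate_dataset(gen_cfg)
    ds <- gen$dataset
    wjson(gen$ground_truth, "ground_truth.json")
    log_line("simulate: %d spectra on %d %s points", nrow(ds$intensities),
             length(ds$axis), cfg$modality)
  } else {
    ds <- cfg$dataset
  }
  write_dataset(ds, out("dataset.csv"))

  samples <- if (cfg$average_replicates) average_replicates(ds) else ds

  # -- stage 2: exploratory (global centering) -------------------------
  expl <- preprocess_dataset(samples, cfg$preprocess)$dataset
  pc <- pca(center_if_needed(expl$intensities), k = 2L)
  dendro <- hca(expl)
  purity <- two_group_separation(dendro, expl$classes)
  utils::write.csv(
    data.frame(sample_id = expl$sample_ids, class = expl$classes,
               PC1 = pc$scores[, 1], PC2 = pc$scores[, 2]),
    out("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(axis = expl$axis, PC1 = pc$loadings[, 1],
               PC2 = pc$loadings[, 2]),
    out("pca_loadings.csv"), row.names = FALSE)
  wjson(list(explained_variance_ratio = pc$explained_variance_ratio,
             hca_two_group_purity = purity,
             hca_linkage = dendro$linkage),
        "exploratory.json")
  dendrogram_newick(dendro, out("dendrogram.nwk"))
  wjson(list(merge = dendro$merge, height = dendro$height,
             labels = dendro$labels, sizes = dendro$sizes),
        "dendrogram.json")
  log_line("explore: PC1 %.2f%%, PC2 %.2f%%, HCA purity %.3f",
           pc$explained_variance_ratio[1], pc$explained_variance_ratio[2],
           purity)

  # -- stage 3: split (train-fitted centering for supervised stages) ---
  cfg_nocenter <- cfg$preprocess; cfg_nocenter$center <- "none"
  class(cfg_nocenter) <- "preprocess_config"
  pre <- preprocess_dataset(samples, cfg_nocenter)$dataset
  split <- stratified_split(pre, cfg$train_fraction)
  train_raw <- subset_rows(pre, split$train_indices)
  test_raw <- subset_rows(pre, split$test_indices)
  mc <- mean_center(train_raw$intensities)
  train <- train_raw; train$intensities <- mc$centered
  test <- test_raw
  test$intensities <- sweep(test_raw$intensities, 2L, mc$means)
  wjson(list(train_indices = split$train_indices,
             test_indices = split$test_indices,
             train_sample_ids = train$sample_ids,
             test_sample_ids = test$sample_ids,
             per_class_train_counts = as.list(split$per_class_train_counts)),
        "split.json")
  log_line("split: %d train / %d test (per class: %s)",
           length(split$train_indices), length(split$test_indices),
           paste(names(split$per_class_train_counts),
                 split$per_class_train_counts, collapse = ", ", sep = "="))

  # -- stage 4: variable selection + evaluation ------------------------
  methods <- switch(cfg$method, both = c("spa", "ga"), cfg$method)
  results <- list()
  for (m in methods) {
    if (m == "spa") {
      sel <- spa_select(train, cfg$spa)
      sel$ga_combo <- NULL
    } else {
      runs <- lapply(seq_along(cfg$ga_combos), function(i) {
        combo <- cfg$ga_combos[[i]]
        ga_select(train, ga_config(population = combo[1],
                                   generations = combo[2],
                                   seed = stage_seed(cfg$seed, 10L + i)))
      })
      costs <- vapply(runs, `[[`, numeric(1), "cost")
      sizes <- vapply(runs, function(r) length(r$selected_indices),
                      integer(1))
      bi <- order(costs, sizes)[1]  # best cost, then parsimony
      sel <- runs[[bi]]
      sel$ga_combo <- cfg$ga_combos[[bi]]
      sel$all_combo_costs <- costs
    }
    rep_ <- evaluate_split(train, test, sel$selected_indices)
    wjson(list(method = toupper(m),
               selected_indices = sel$selected_indices,
               axis_values = train$axis[sel$selected_indices],
               cost = sel$cost, trace = sel$trace,
               ga_combo = sel$ga_combo,
               ga_combo_costs = sel$all_combo_costs,
               cv = list(confusion = unclass(rep_$cv$confusion),
                         fom = unclass(rep_$cv$fom)),
               test = if (!rep_$test_absent) {
                 list(confusion = unclass(rep_$test$confusion),
                      fom = unclass(rep_$test$fom))
               } else NULL,
               fisher = rep_$fisher),
          sprintf("selection_%s.json", m))
    utils::write.csv(rep_$scores, out(sprintf("scores_%s.csv", m)),
                     row.names = FALSE)
    results[[m]] <- list(selection = sel, report = rep_)
    log_line("%s: %d vars, LOO cost %.3f, cv acc %.1f%%, test acc %s",
             toupper(m), length(sel$selected_indices), sel$cost,
             rep_$cv$fom$accuracy,
             if (rep_$test_absent) "NA" else
               sprintf("%.1f%%", rep_$test$fom$accuracy))
  }

  files <- list.files(cfg$output_dir, full.names = TRUE)
  manifest <- list(
    config = list(modality = cfg$modality, method = cfg$method,
                  seed = cfg$seed, train_fraction = cfg$train_fraction,
                  preprocess = unclass(cfg$preprocess),
                  spa = unclass(cfg$spa), ga_combos = cfg$ga_combos,
                  average_replicates = cfg$average_replicates),
    versions = list(chemodisc = as.character(utils::packageVersion("chemodisc")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    checksums = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  wjson(manifest, "manifest.json")
  invisible(c(manifest, list(results = results,
                             exploratory = list(pca = pc, dendro = dendro,
                                                purity = purity),
                             split = split)))
}

# exploratory PCA expects centered input; center defensively when the
# preprocessing config disabled it
center_if_needed <- function(x, tol = 1e-8) {
  if (max(abs(colMeans(x))) > tol * max(1, max(abs(x)))) {
    sweep(x, 2L, colMeans(x))
  } else {
    x
  }
}

#' Render a run directory as a markdown report
#'
#' Tables of explained variance, HCA purity, selected variables with their
#' axis positions, Fisher-weight class attribution and nearest band
#' annotation, and figures of merit (cross-validated and test, in both
#' class orientations). Deterministic: rendering twice gives identical
#' output.
#'
#' @param run_dir a completed [run_pipeline()] output directory.
#' @param path optional file to write the markdown to.
#' @return the report as a character vector of lines.
#' @export
render_report <- function(run_dir, path = NULL) {
  need <- function(f) {
    fp <- file.path(run_dir, f)
    if (!file.exists(fp)) stop("missing run artifact: ", f, call. = FALSE)
    fp
  }
  manifest <- jsonlite::read_json(need("manifest.json"))
  expl <- jsonlite::read_json(need("exploratory.json"))
  modality <- manifest$config$modality
  unit <- if (modality == "uv") "nm" else "cm-1"
  lines <- c(
    sprintf("# Discrimination run report (%s)", modality),
    "",
    "## Exploratory analysis",
    "",
    sprintf("- PC1 explained variance: %.2f%%",
            expl$explained_variance_ratio[[1]]),
    sprintf("- PC2 explained variance: %.2f%%",
            expl$explained_variance_ratio[[2]]),
    sprintf("- HCA (%s linkage) two-group purity: %.3f",
            expl$hca_linkage, expl$hca_two_group_purity),
    ""
  )
  for (m in c("spa", "ga")) {
    f <- file.path(run_dir, sprintf("selection_%s.json", m))
    if (!file.exists(f)) next
    sel <- jsonlite::read_json(f, simplifyVector = TRUE)
    ann <- annotate_variables(sel$axis_values, modality)
    lines <- c(lines,
      sprintf("## %s-LDA", sel$method), "",
      sprintf("- selected %d variable(s); LOO selection cost %.4f",
              length(sel$selected_indices), sel$cost),
      if (length(sel$ga_combo) == 2) {
        sprintf("- best GA combination: population %d / generations %d",
                sel$ga_combo[[1]], sel$ga_combo[[2]])
      },
      "",
      sprintf("| %s | Fisher weight | attributed class | assignment |", unit),
      "|---|---|---|---|",
      sprintf("| %g | %s | %s | %s |",
              sel$fisher$axis_value,
              ifelse(sel$fisher$infinite, "Inf",
                     sprintf("%.3f", sel$fisher$weight)),
              sel$fisher$attributed_class, ann$assignment),
      "",
      fom_table(sel$cv$fom, sel$cv$confusion, "LOO-CV"),
      if (!is.null(sel$test)) {
        fom_table(sel$test$fom, sel$test$confusion, "test")
      },
      ""
    )
  }
  lines <- as.character(lines[!vapply(lines, is.null, logical(1))])
  if (!is.null(path)) writeLines(lines, path)
  lines
}

fom_table <- function(fom, cc, label) {
  swapped <- list(sensitivity = fom$specificity,
                  specificity = fom$sensitivity, accuracy = fom$accuracy)
  c(sprintf("### Figures of merit (%s)", label),
    "",
    "| orientation | SEN (%) | SPE (%) | ACC (%) |",
    "|---|---|---|---|",
    sprintf("| positive = first label | %.2f | %.2f | %.2f |",
            fom$sensitivity, fom$specificity, fom$accuracy),
    sprintf("| swapped | %.2f | %.2f | %.2f |",
            swapped$sensitivity, swapped$specificity, swapped$accuracy),
    sprintf("- confusion: TP=%d TN=%d FP=%d FN=%d",
            cc$TP, cc$TN, cc$FP, cc$FN),
    "")
}
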
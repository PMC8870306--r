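#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Every stochastic stage consumes
#' a seed derived deterministically from `seed` and the stage name. The
#' defaults describe the bundled smoke setup: a simulated cohort, t-SNE
#' template at g = 32, merged RGB maps and a reduced ResNet.
#'
#' @param seed Master seed.
#' @param out_dir Run directory (created; outputs under `data/`,
#'   `templates/`, `maps/`, `models/`, `reports/`).
#' @param simulate `NULL` or a list overriding [simulation_config()] fields;
#'   `NULL` requires `inputs` paths.
#' @param inputs Optional list of file paths (`expression`, `cna`, `mrna`,
#'   `clinical`) read instead of simulating.
#' @param select List: `top_k`, `max_subset`, `folds`, `bins`.
#' @param embed List: `method` ("tsne" or "som"), `grid_size`, plus optional
#'   method parameters (`perplexity`, `iterations`, `som_grid`, `epochs`).
#' @param render List: `mode` ("merged" or "concatenated"), `clip_sigma`.
#' @param augment List: `target_per_class` (`NULL` = size of largest class),
#'   `alpha_min`, `alpha_max`.
#' @param model List: `classifier` ("resnet" or "vgg"), `preset`, `epochs`,
#'   `batch_size`, `learning_rate`, `validation_fraction`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("gsnpi_run_"),
                            simulate = list(), inputs = NULL,
                            select = list(), embed = list(), render = list(),
                            augment = list(), model = list()) {
  defaults <- list(
    select = list(top_k = 50L, max_subset = 15L, folds = 5L, bins = 10L),
    embed = list(method = "tsne", grid_size = 32L, perplexity = NULL,
                 iterations = 1000L, som_grid = NULL, epochs = 100L),
    render = list(mode = "merged", clip_sigma = 3),
    augment = list(target_per_class = NULL, alpha_min = 15, alpha_max = 18),
    model = list(classifier = "resnet", preset = "reduced", epochs = 20L,
                 batch_size = 32L, learning_rate = 1e-3,
                 validation_fraction = 0.2)
  )
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              simulate = simulate, inputs = inputs,
              select = utils::modifyList(defaults$select, select),
              embed = utils::modifyList(defaults$embed, embed),
              render = utils::modifyList(defaults$render, render),
              augment = utils::modifyList(defaults$augment, augment),
              model = utils::modifyList(defaults$model, model))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

PIPELINE_STAGES <- c("simulate", "align", "select", "embed", "render",
                     "split", "augment", "train", "evaluate", "survival")

#' Run the end-to-end GSN classification pipeline
#'
#' Executes: simulate (or load) -> complete-case alignment -> hybrid feature
#' selection per omic -> gene embedding + template -> normalization +
#' map rendering -> stratified train/validation split -> elastic augmentation
#' of the training set -> CNN training -> evaluation -> Kaplan-Meier curves
#' per NPI level. Writes artifacts under the run directory and returns a run
#' manifest. Any stage failure aborts with the stage name; artifacts written
#' by earlier stages are retained.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return A list of class `run_manifest`: `stages` tibble (stage, seed,
#'   outputs, seconds), `eval` (final [evaluate()] report), `history`,
#'   `selected` (named gene lists), `km` (per-level curves), `config`,
#'   `model`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  for (sub in c("data", "templates", "maps", "models", "reports")) {
    dir.create(file.path(out, sub), recursive = TRUE, showWarnings = FALSE)
  }
  stage_rows <- list()
  artifacts <- list()
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_rows[[stage]] <<- tibble::tibble(
      stage = stage, seed = derive_seed(config$seed, stage),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = paste(res$outputs %||% character(0), collapse = ";")
    )
    res$value
  }

  study <- run_stage("simulate", function() {
    if (!is.null(config$inputs)) {
      mats <- list(
        expression = read_omics_matrix(config$inputs$expression, omic_name = "expression"),
        cna = read_omics_matrix(config$inputs$cna, omic_name = "cna"),
        mrna = read_omics_matrix(config$inputs$mrna, omic_name = "mrna")
      )
      clin <- read_clinical_table(config$inputs$clinical)
      list(value = list(matrices = mats, clinical = clin), outputs = NULL)
    } else {
      sim_args <- utils::modifyList(config$simulate,
                                    list(seed = derive_seed(config$seed, "simulate")))
      st <- simulate_study(do.call(simulation_config, sim_args))
      paths <- character(0)
      for (nm in names(st$matrices)) {
        p <- file.path(out, "data", paste0(nm, ".tsv"))
        write_omics_matrix(st$matrices[[nm]], p)
        paths <- c(paths, p)
      }
      cp <- file.path(out, "data", "clinical.csv")
      write_clinical_table(st$clinical, cp)
      list(value = st, outputs = c(paths, cp))
    }
  })

  aligned <- run_stage("align", function() {
    al <- align_complete_cases(study$matrices, study$clinical)
    al$clinical <- npi_score(al$clinical)
    list(value = al, outputs = NULL)
  })
  labels <- aligned$clinical$npi_level

  sel <- run_stage("select", function() {
    cs <- config$select
    seed <- derive_seed(config$seed, "select")
    res <- lapply(names(aligned$matrices), function(nm) {
      m <- aligned$matrices[[nm]]
      select_features(m, labels, top_k = cs$top_k, max_subset = cs$max_subset,
                      folds = cs$folds, seed = seed, bins = cs$bins,
                      shift = nm == "cna")
    })
    names(res) <- names(aligned$matrices)
    p <- file.path(out, "reports", "selected_genes.csv")
    utils::write.csv(
      dplyr::bind_rows(lapply(names(res), function(nm) {
        tibble::tibble(omic = nm, gene_id = res[[nm]]$best_subset)
      })), p, row.names = FALSE)
    list(value = res, outputs = p)
  })

  mode <- config$render$mode
  templates <- run_stage("embed", function() {
    ce <- config$embed
    seed <- derive_seed(config$seed, "embed")
    make_template <- function(m, genes) {
      gv <- unclass(m)[genes, , drop = FALSE]
      emb <- if (ce$method == "tsne") {
        perp <- ce$perplexity %||% min(5, length(genes) - 1)
        tsne_embed(gv, tsne_config(perplexity = perp,
                                   iterations = ce$iterations, seed = seed))
      } else {
        gr <- ce$som_grid %||% max(2L, ceiling(sqrt(length(genes))))
        som_embed(gv, som_config(grid_rows = gr, grid_cols = gr,
                                 epochs = ce$epochs, seed = seed))
      }
      build_template(emb, ce$grid_size)
    }
    if (mode == "merged") {
      # merged maps share the expression layer's selected genes
      genes <- sel$expression$best_subset
      missing <- unique(unlist(lapply(aligned$matrices, function(m)
        setdiff(genes, rownames(m)))))
      if (length(missing)) {
        warning("dropping template gene(s) absent from an omic: ",
                paste(missing, collapse = ", "))
        genes <- setdiff(genes, missing)
      }
      tpl <- make_template(aligned$matrices$expression, genes)
      p <- file.path(out, "templates", "merged.json")
      write_template(tpl, p)
      list(value = tpl, outputs = p)
    } else {
      tpls <- lapply(names(aligned$matrices), function(nm) {
        make_template(aligned$matrices[[nm]], sel[[nm]]$best_subset)
      })
      names(tpls) <- names(aligned$matrices)
      ps <- vapply(names(tpls), function(nm) {
        p <- file.path(out, "templates", paste0(nm, ".json"))
        write_template(tpls[[nm]], p)
        p
      }, character(1))
      list(value = tpls, outputs = ps)
    }
  })

  images <- run_stage("render", function() {
    norm <- list(
      expression = normalize_omics(aligned$matrices$expression, normalization_spec()),
      cna = normalize_omics(aligned$matrices$cna,
                            normalization_spec(apply_log = FALSE)),
      mrna = normalize_omics(aligned$matrices$mrna, normalization_spec())
    )
    imgs <- render_cohort(aligned$clinical, templates, norm, mode = mode,
                          clip_sigma = config$render$clip_sigma)
    manifest <- tibble::tibble(sample_id = aligned$clinical$sample_id,
                               npi_level = as.character(labels))
    p <- file.path(out, "maps", "manifest.csv")
    utils::write.csv(manifest, p, row.names = FALSE)
    list(value = imgs, outputs = p)
  })

  split <- run_stage("split", function() {
    labs <- factor(as.character(labels))
    val <- stratified_holdout(labs, config$model$validation_fraction,
                              derive_seed(config$seed, "split"))
    list(value = val, outputs = NULL)
  })

  train_imgs <- run_stage("augment", function() {
    tr <- images[!split]
    target <- config$augment$target_per_class
    if (is.null(target)) {
      tr_labels <- as.character(labels[!split])
      target <- max(table(tr_labels))
    }
    ec <- elastic_config(alpha_min = config$augment$alpha_min,
                         alpha_max = config$augment$alpha_max,
                         seed = derive_seed(config$seed, "augment"))
    balanced <- if (mode == "merged") {
      balance_dataset(tr, target, ec)
    } else {
      balance_concatenated(tr, target, ec)
    }
    list(value = balanced, outputs = NULL)
  })

  model <- run_stage("train", function() {
    cm <- config$model
    g <- config$embed$grid_size
    n_classes <- nlevels(droplevels(factor(as.character(labels))))
    spec <- if (mode == "merged") {
      if (cm$classifier == "resnet") {
        build_resnet(n_classes, c(g, g, 3L), cm$preset)
      } else {
        build_vgg(n_classes, c(g, g, 3L), cm$preset)
      }
    } else {
      branch <- function() {
        if (cm$classifier == "resnet") build_resnet(n_classes, c(g, g, 1L), cm$preset)
        else build_vgg(n_classes, c(g, g, 1L), cm$preset)
      }
      build_concatenated(list(branch(), branch(), branch()))
    }
    fit <- train(spec, train_imgs,
                 train_config(epochs = cm$epochs, batch_size = cm$batch_size,
                              learning_rate = cm$learning_rate,
                              validation_fraction = cm$validation_fraction,
                              seed = derive_seed(config$seed, "train")),
                 validation = images[split])
    p <- file.path(out, "models", "history.csv")
    utils::write.csv(fit$history, p, row.names = FALSE)
    list(value = fit, outputs = p)
  })

  eval_report <- run_stage("evaluate", function() {
    rep <- evaluate(model, images[split])
    p <- file.path(out, "reports", "eval.csv")
    utils::write.csv(rep, p, row.names = FALSE)
    list(value = rep, outputs = p)
  })

  km <- run_stage("survival", function() {
    if (!all(c("relapse_time_months", "relapse_event") %in% names(aligned$clinical))) {
      return(list(value = NULL, outputs = NULL))
    }
    curves <- km_by_level(aligned$clinical)
    p <- file.path(out, "reports", "km_curves.csv")
    utils::write.csv(curves, p, row.names = FALSE)
    list(value = curves, outputs = p)
  })

  manifest <- structure(list(
    stages = dplyr::bind_rows(stage_rows[PIPELINE_STAGES]),
    eval = eval_report,
    history = model$history,
    selected = lapply(sel, function(s) s$best_subset),
    km = km,
    model = model,
    images = images,
    split = split,
    config = config
  ), class = "run_manifest")
  utils::write.csv(manifest$stages, file.path(out, "reports", "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# Class-balance a concatenated dataset (per-sample named lists of per-omic
# images): the same augmentation seed/alpha is applied to each omic map.
balance_concatenated <- function(samples, target_per_class, config) {
  labels <- vapply(samples, function(s) as.character(s[[1]]$label), character(1))
  classes <- sort(unique(labels))
  set.seed(derive_seed(config$seed, "balance"))
  out <- list()
  for (cl in classes) {
    members <- samples[labels == cl]
    if (!length(members)) stop("empty class: ", cl, call. = FALSE)
    if (length(members) > target_per_class) {
      members <- members[sort(sample.int(length(members), target_per_class))]
    } else if (length(members) < target_per_class) {
      deficit <- target_per_class - length(members)
      src <- sample.int(length(members), deficit, replace = TRUE)
      alphas <- stats::runif(deficit, config$alpha_min, config$alpha_max)
      seeds <- sample.int(.Machine$integer.max - 1L, deficit)
      extra <- lapply(seq_len(deficit), function(i) {
        lapply(members[[src[i]]], elastic_transform, alpha = alphas[i],
               sigma = config$sigma, seed = seeds[i])
      })
      members <- c(members, extra)
    }
    out <- c(out, members)
  }
  out
}

#' Summarize a completed run manifest
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return A markdown character string (selected genes per omic, evaluation
#'   table, stage timings), invisibly also written to
#'   `reports/summary.md` under the run directory.
#' @export
report <- function(manifest) {
  if (!inherits(manifest, "run_manifest")) stop("not a run manifest", call. = FALSE)
  if (is.null(manifest$eval)) stop("manifest missing the 'evaluate' stage", call. = FALSE)
  lines <- c("# GSN-NPI pipeline report", "",
             "## Selected genes per omic", "")
  for (nm in names(manifest$selected)) {
    lines <- c(lines, paste0("- **", nm, "** (", length(manifest$selected[[nm]]),
                             "): ", paste(manifest$selected[[nm]], collapse = ", ")))
  }
  ev <- manifest$eval
  hist_last <- manifest$history[nrow(manifest$history), ]
  lines <- c(lines, "", "## Performance", "",
             "| Acc | Val_Acc | Loss | Val_Loss | AUC | Val_AUC |",
             "|-----|---------|------|----------|-----|---------|",
             sprintf("| %.4f | %.4f | %.4f | %.4f | %.4f | %.4f |",
                     hist_last$acc, ev$acc, hist_last$loss, ev$loss,
                     hist_last$auc, ev$auc),
             "", "## Stages", "")
  lines <- c(lines, sprintf("- %s (%.1f s)", manifest$stages$stage,
                            manifest$stages$seconds))
  txt <- paste(lines, collapse = "\n")
  p <- file.path(manifest$config$out_dir, "reports", "summary.md")
  try(writeLines(txt, p), silent = TRUE)
  invisible(txt)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", nrow(x$stages), " stages; val_acc ",
      sprintf("%.3f", x$eval$acc), ", val_auc ",
      sprintf("%.3f", x$eval$auc), "\n", sep = "")
  invisible(x)
}
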
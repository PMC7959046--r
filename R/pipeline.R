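#' Default pipeline configuration
#'
#' Nested configuration of the end-to-end pipeline: cohort simulation, graph
#' construction, node-classifier training, optional uncertainty refinement,
#' Mapper summary, Tumor Invasion Scores, and cohort association. Every stage
#' draws its randomness from a seed derived from the single global `seed`.
#'
#' @param seed global integer seed.
#' @return nested named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L) {
  structure(
    list(
      seed = as.integer(seed),
      simulate = list(
        nPatients = 10L, slidesPerPatient = 2L,
        gridRows = 20L, gridCols = 20L,
        dim = 16L, classSeparation = 3, noiseSd = 3, spatialSmoothing = 1,
        pocketRate = 0.05, frontRoughness = 1, withinPatientSd = 0.05,
        depthMin = 0.05, depthMax = 0.85
      ),
      graph = list(k = 8L),
      gnn = list(
        n_conv_layers = 4L, hidden_dim = 16L, attention_heads = 2L,
        dropedge_p = 0.2, dropout_p = 0.1, learning_rate = 5e-3,
        max_epochs = 20L, aggregate = "mean",
        trainPatients = 2L, valPatients = 1L
      ),
      refine = list(enabled = TRUE, nDraws = 20L, pruneQuantile = 0.9),
      mapper = list(
        lensMethod = "pca", lensDim = 2L, nIntervals = 10L, g = 0.3,
        histBins = 10L
      ),
      tis = list(normalize = "per_patch"),
      associate = list(
        mode = "tis", interactions = "main", nFolds = 10L, nBoot = 1000L
      )
    ),
    class = "PipelineConfig"
  )
}

# Reject unknown keys (recursively) against the default template.
validatePipelineConfig <- function(config, template = pipelineConfig()) {
  checkLevel <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown)) {
      stop(sprintf(
        "unknown configuration key(s) at %s: %s", path,
        paste(unknown, collapse = ", ")
      ))
    }
    for (nm in names(cfg)) {
      if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]]))) {
        checkLevel(cfg[[nm]], tpl[[nm]], paste0(path, "$", nm))
      }
    }
  }
  checkLevel(config, template, "config")
  merged <- template
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      for (sub in names(config[[nm]])) merged[[nm]][[sub]] <- config[[nm]][[sub]]
    } else {
      merged[[nm]] <- config[[nm]]
    }
  }
  merged
}

#' Read / write a pipeline configuration
#'
#' YAML round trip; unknown keys are rejected against the [pipelineConfig()]
#' schema and omitted keys filled with defaults.
#'
#' @param path YAML file.
#' @param config a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  validatePipelineConfig(raw)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stageSeed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, graph = 202L, train = 303L, predict = 404L,
    refine = 505L, mapper = 606L, tis = 707L, associate = 808L
  )
  (as.integer(seed) * 1009L + offsets[[stage]]) %% 2000000011L
}

runStage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Simulates a cohort (or reuses a provided one), builds whole-slide graphs,
#' trains the graph attention node classifier on a patient-level split,
#' predicts tissue classes for every slide, optionally refines the predictions
#' via Monte-Carlo uncertainty pruning and label propagation, summarizes every
#' slide with Mapper, computes per-slide Tumor Invasion Scores, and associates
#' them with stage by grouped cross-validated logistic regression. All
#' declared artifacts are written under `outDir`, together with a manifest
#' recording the seeds and an MD5 hash per artifact.
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @param cohort optional pre-built [SyntheticCohort-class]; skips simulation.
#' @return invisible list with the main in-memory results (`cohort`, `model`,
#'   `labels`, `tisMatrix`, `association`, `manifest`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, cohort = NULL) {
  config <- validatePipelineConfig(unclass(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  addArtifact <- function(p) artifacts <<- c(artifacts, p)

  # -- simulate ---------------------------------------------------------------
  sim <- config$simulate
  classNames <- colonClasses()
  cfg <- slideConfig(
    gridRows = sim$gridRows, gridCols = sim$gridCols,
    pocketRate = sim$pocketRate, frontRoughness = sim$frontRoughness
  )
  if (is.null(cohort)) {
    cohort <- runStage("simulate", {
      model <- embeddingModel(
        dim = sim$dim, classNames = classNames,
        classSeparation = sim$classSeparation, noiseSd = sim$noiseSd,
        spatialSmoothing = sim$spatialSmoothing
      )
      generateCohort(
        nPatients = sim$nPatients, slidesPerPatient = sim$slidesPerPatient,
        config = cfg, model = model,
        depthSampler = function(n) stats::runif(n, sim$depthMin, sim$depthMax),
        withinPatientSd = sim$withinPatientSd,
        seed = stageSeed(config$seed, "simulate")
      )
    })
  }
  man <- cohort@manifest
  data.table::fwrite(man, file.path(outDir, "cohort_manifest.csv"))
  addArtifact(file.path(outDir, "cohort_manifest.csv"))

  # -- graphs -----------------------------------------------------------------
  graphs <- runStage("graph", {
    lapply(cohort@slides, function(s) buildSlideGraph(s, k = config$graph$k))
  })

  # -- train ------------------------------------------------------------------
  gnn <- config$gnn
  patients <- unique(man$patient_id)
  trainP <- patients[seq_len(gnn$trainPatients)]
  valP <- patients[gnn$trainPatients + seq_len(gnn$valPatients)]
  trainIx <- which(man$patient_id %in% trainP)
  valIx <- which(man$patient_id %in% valP)
  model <- runStage("train", {
    gc <- gatConfig(
      n_conv_layers = gnn$n_conv_layers, hidden_dim = gnn$hidden_dim,
      attention_heads = gnn$attention_heads, dropedge_p = gnn$dropedge_p,
      dropout_p = gnn$dropout_p, learning_rate = gnn$learning_rate,
      max_epochs = gnn$max_epochs, aggregate = gnn$aggregate,
      seed = stageSeed(config$seed, "train")
    )
    fitNodeClassifier(graphs[trainIx], graphs[valIx], gc)
  })
  saveRDS(model, file.path(outDir, "gnn_model.rds"))
  data.table::fwrite(model@trainLog, file.path(outDir, "training_log.csv"))
  addArtifact(file.path(outDir, "training_log.csv"))

  # -- predict ----------------------------------------------------------------
  preds <- runStage("predict", {
    lapply(graphs, function(g) predictProba(model, g))
  })
  hardLabels <- lapply(preds, function(p) max.col(p, ties.method = "first"))
  predTable <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    data.frame(
      slide_id = slideId(g), row = nodeCoords(g)[, 1L], col = nodeCoords(g)[, 2L],
      predicted = classNames[hardLabels[[i]]]
    )
  }))
  data.table::fwrite(predTable, file.path(outDir, "predicted_labels.csv"))
  addArtifact(file.path(outDir, "predicted_labels.csv"))

  # -- refine (optional) ------------------------------------------------------
  finalLabels <- hardLabels
  if (isTRUE(config$refine$enabled)) {
    finalLabels <- runStage("refine", {
      out <- vector("list", length(graphs))
      rseed <- stageSeed(config$seed, "refine")
      refRows <- list()
      for (i in seq_along(graphs)) {
        dr <- posteriorDraws(model, graphs[[i]],
          T = config$refine$nDraws,
          seed = (rseed + i) %% 2000000011L
        )
        sc <- uncertaintyScores(dr)
        ref <- suppressWarnings(pruneAndPropagate(
          graphs[[i]], hardLabels[[i]], sc,
          pruneQuantile = config$refine$pruneQuantile
        ))
        out[[i]] <- as.integer(ref)
        g <- graphs[[i]]
        refRows[[i]] <- data.frame(
          slide_id = slideId(g),
          row = nodeCoords(g)[, 1L], col = nodeCoords(g)[, 2L],
          original_label = classNames[hardLabels[[i]]],
          refined_label = classNames[as.integer(ref)],
          entropy = sc$entropy, variance = sc$variance
        )
      }
      data.table::fwrite(do.call(rbind, refRows), file.path(outDir, "refined_labels.csv"))
      addArtifact(file.path(outDir, "refined_labels.csv"))
      out
    })
  }

  # -- mapper + tis -----------------------------------------------------------
  K <- length(classNames)
  tumorIdx <- match("cancer", classNames)
  mp <- config$mapper
  tisRows <- runStage("mapper", {
    dir.create(file.path(outDir, "mapper"), showWarnings = FALSE)
    rows <- matrix(NA_real_, length(graphs), K, dimnames = list(names(cohort@slides), classNames))
    for (i in seq_along(graphs)) {
      Z <- extractEmbeddings(model, graphs[[i]])
      mg <- buildMapperGraph(Z,
        lensMethod = mp$lensMethod, lensDim = mp$lensDim,
        nIntervals = mp$nIntervals, g = mp$g, histBins = mp$histBins,
        seed = stageSeed(config$seed, "mapper")
      )
      I <- interminglingMatrix(mg, finalLabels[[i]], K = K, normalize = config$tis$normalize)
      rows[i, ] <- tumorInvasionScore(I, tumorIdx)
      if (i <= 2L) { # representative Mapper exports
        writeMapperGraphML(
          mg, file.path(outDir, "mapper", paste0(slideId(graphs[[i]]), ".graphml")),
          labels = finalLabels[[i]], classNames = classNames
        )
        writeMapperJSON(
          mg, file.path(outDir, "mapper", paste0(slideId(graphs[[i]]), ".json")),
          labels = finalLabels[[i]], classNames = classNames
        )
      }
    }
    rows
  })
  tisDf <- data.frame(slide_id = rownames(tisRows), tisRows, row.names = NULL)
  data.table::fwrite(tisDf, file.path(outDir, "tis.csv"))
  addArtifact(file.path(outDir, "tis.csv"))

  # -- associate --------------------------------------------------------------
  assoc <- runStage("associate", {
    counts <- do.call(rbind, lapply(finalLabels, regionCountFeatures, K = K, classNames = classNames))
    design <- suppressWarnings(buildDesign(
      tis = tisRows, counts = counts, y = man$stage, patientId = man$patient_id,
      mode = config$associate$mode, interactions = config$associate$interactions
    ))
    cv <- cvLogisticAuc(design,
      nFolds = config$associate$nFolds,
      nBoot = config$associate$nBoot,
      seed = stageSeed(config$seed, "associate")
    )
    eff <- clusteredEffectSummary(design, seed = stageSeed(config$seed, "associate"))
    list(auc = cv$auc, se = cv$se, effects = eff)
  })
  jsonlite::write_json(
    list(
      auc = assoc$auc, se = assoc$se,
      effects = assoc$effects
    ),
    file.path(outDir, "association.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  addArtifact(file.path(outDir, "association.json"))
  data.table::fwrite(assoc$effects, file.path(outDir, "effects.csv"))
  addArtifact(file.path(outDir, "effects.csv"))

  # -- manifest ---------------------------------------------------------------
  manifest <- list(
    package = as.character(utils::packageVersion("slideTIS")),
    seed = config$seed,
    stageSeeds = lapply(
      c("simulate", "graph", "train", "predict", "refine", "mapper", "tis", "associate"),
      function(s) stageSeed(config$seed, s)
    ),
    artifacts = as.list(unname(tools::md5sum(artifacts)))
  )
  names(manifest$artifacts) <- basename(artifacts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    cohort = cohort, model = model, labels = finalLabels,
    tisMatrix = tisRows, association = assoc, manifest = manifest
  ))
}
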
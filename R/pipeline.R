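#' Default pipeline configuration
#'
#' Returns the full configuration tree with every tunable of the
#' analysis. Unknown keys passed to [run_pipeline()] are rejected before
#' any computation.
#'
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    input = NULL,                      # directory written by write_population()
    synthetic = list(n_patients = 45L, resolution = 20L,
                     sigma_dig = 0.3, rho_pair = 0.75, side_effect = 0),
    exclusions = NULL,                 # data.frame(patient_id, side, reason)
    transfer = list(surface_tol = 0.5),
    slide = list(tol = 1e-6, max_iter = 10L, reference = "template"),
    gpa = list(tol = 1e-10, max_iter = 100L),
    anova = list(n_perm = 999L),
    stats = list(alpha = 0.05, p_adjust = "none"),
    hcpc = list(kmin = 2L, kmax = 10L, consolidate = FALSE),
    stability = list(reps = 100L, m = 5L, sizes = NULL)  # NULL = auto
  )
}

.validate_config <- function(config) {
  def <- default_pipeline_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    .mc_stop("unknown config key(s): %s", paste(bad, collapse = ", "),
             class = "validation_error")
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && !is.null(config[[nm]])) {
      sub_bad <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (nm %in% c("synthetic", "exclusions")) sub_bad <- character(0)
      if (length(sub_bad))
        .mc_stop("unknown config key(s) under %s: %s", nm,
                 paste(sub_bad, collapse = ", "), class = "validation_error")
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[nm] <- config[nm]
    }
  }
  cfg <- def
  if (cfg$hcpc$kmax < cfg$hcpc$kmin)
    .mc_stop("hcpc.kmax < hcpc.kmin", class = "validation_error")
  if (!cfg$slide$reference %in% c("template", "mean"))
    .mc_stop("slide.reference must be 'template' or 'mean'",
             class = "validation_error")
  if (!cfg$stats$p_adjust %in% c("none", "BH"))
    .mc_stop("stats.p_adjust must be 'none' or 'BH'",
             class = "validation_error")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .mc_stop("yaml package not available; use a JSON config",
               class = "validation_error")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    .mc_stop("config must be .yaml/.yml/.json: %s", path,
             class = "validation_error")
  }
  .validate_config(cfg)
}

#' Run the full morphotype-discovery pipeline
#'
#' Stages, in order: load or generate the population; mirror left-side
#' specimens to the right-side convention; apply exclusions; TPS
#' semi-landmark transfer and bending-energy sliding per specimen; GPA;
#' permutation Procrustes ANOVA of side (sides are combined only when
#' non-significant, otherwise a warning is raised and per-side analyses
#' are attached); sensitivity re-run of the side test excluding
#' unmatched-side specimens; shape PCA with elbow selection and
#' resampling stability; Ward clustering on the retained PCs with
#' automatic cluster count and a 3-index vote; MANOVA / per-axis ANOVA /
#' Tukey characterization; demographics and patient pair summaries.
#'
#' @param config partial configuration (see
#'   [default_pipeline_config()]), or a path readable by
#'   [read_pipeline_config()].
#' @return a `pipeline_report` list; also written to `config$out_dir`
#'   when set (see [write_report()]).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- .validate_config(config)
  seed <- as.integer(cfg$seed)
  log_msg <- function(stage, fmt, ...)
    message(sprintf("[morphocavity:%s] %s", stage, sprintf(fmt, ...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .mc_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e),
               class = "compute_error")
    })
  }

  ## -- data ---------------------------------------------------------------
  pop <- stage("load", {
    if (!is.null(cfg$input)) {
      read_population(cfg$input)
    } else {
      sp <- do.call(population_spec, c(cfg$synthetic, list(seed = seed)))
      generate_population(sp)
    }
  })
  template <- pop$template
  log_msg("load", "%d specimens, %d patients (seed %d)",
          length(pop$specimens), nrow(pop$cohort), seed)

  ## -- mirroring + exclusions --------------------------------------------
  pop$specimens <- lapply(pop$specimens, function(sp) {
    if (identical(sp$side, "left")) {
      sp$mesh <- mirror_sagittal(sp$mesh)
      sp$landmarks <- mirror_sagittal(sp$landmarks)
      sp$digitized_fixed <- mirror_sagittal(sp$digitized_fixed)
    }
    sp
  })
  excl <- stage("exclusions", exclude_specimens(pop$records,
                                                cfg$exclusions))
  keep <- excl$records$specimen_id
  log_msg("exclusions", "%d -> %d specimens (%d excluded)",
          excl$n_input, excl$n_retained, excl$n_input - excl$n_retained)
  spec_ids <- vapply(pop$specimens, function(s) s$landmarks$specimen_id, "")
  specimens <- pop$specimens[spec_ids %in% keep]
  spec_ids <- spec_ids[spec_ids %in% keep]

  ## -- transfer + sliding -------------------------------------------------
  B <- bending_energy_matrix(rbind(template$fixed_landmarks,
                                   template$semilandmarks))
  slid <- stage("sliding", lapply(specimens, function(sp) {
    init <- transfer_semilandmarks(template, sp$mesh, sp$digitized_fixed,
                                   specimen_id = sp$landmarks$specimen_id,
                                   surface_tol = cfg$transfer$surface_tol)
    slide_semilandmarks(template, init, sp$mesh, tol = cfg$slide$tol,
                        max_iter = cfg$slide$max_iter, B = B)
  }))
  configs <- lapply(slid, `[[`, "configuration")
  energies <- vapply(slid, function(s) s$energy_trace[length(s$energy_trace)],
                     numeric(1))
  log_msg("sliding", "median final bending energy %.4g", stats::median(energies))

  ## -- GPA + side test ----------------------------------------------------
  aligned <- stage("gpa", gpa(configs, tol = cfg$gpa$tol,
                              max_iter = cfg$gpa$max_iter))
  rec <- excl$records[match(spec_ids, excl$records$specimen_id), ]
  side_test <- stage("side_test",
                     procrustes_anova(aligned, rec$side,
                                      n_perm = cfg$anova$n_perm,
                                      seed = seed + 1L))
  log_msg("side_test", "Goodall F = %.3f, p = %.3f", side_test$F, side_test$p)
  side_significant <- side_test$p <= cfg$stats$alpha
  if (side_significant)
    warning(sprintf(paste0("side effect significant (p = %.3f): sides are ",
                           "also analyzed separately"), side_test$p))

  # sensitivity: drop specimens whose patient has only one retained side
  matched <- names(which(table(rec$patient_id) == 2L))
  sens_idx <- rec$patient_id %in% matched
  sensitivity <- if (length(unique(rec$side[sens_idx])) == 2L) {
    sub <- structure(list(aligned = aligned$aligned[sens_idx, , ,
                                                    drop = FALSE]),
                     class = "aligned_sample")
    stage("sensitivity",
          procrustes_anova(sub, rec$side[sens_idx],
                           n_perm = cfg$anova$n_perm, seed = seed + 2L))
  } else NULL

  ## -- PCA + stability ----------------------------------------------------
  pca <- stage("pca", shape_pca(aligned))
  m <- select_components_elbow(pca$explained_ratio)
  log_msg("pca", "elbow retains %d PCs (%.1f%% variance)", m,
          100 * sum(pca$explained_ratio[1:m]))
  n <- length(configs)
  sizes <- cfg$stability$sizes %||%
    unique(pmin(seq(20L, max(21L, n), by = 10L), n))
  sizes <- sizes[sizes >= 3 & sizes <= n]
  stability <- if (length(sizes)) {
    stage("stability",
          pca_stability_resampling(aligned, sizes, reps = cfg$stability$reps,
                                   m = cfg$stability$m, seed = seed + 3L))
  } else NULL

  ## -- clustering ---------------------------------------------------------
  cluster_block <- function(al, pc, mm, tag) {
    scores <- pc$scores[, seq_len(mm), drop = FALSE]
    wt <- ward_tree(scores)
    sel <- select_cluster_count(wt, cfg$hcpc$kmin,
                                min(cfg$hcpc$kmax, nrow(scores) - 1L))
    vote <- cluster_count_vote(scores, cfg$hcpc$kmin,
                               min(cfg$hcpc$kmax, nrow(scores) - 1L))
    labels <- cut_ward_tree(wt, sel$k)
    if (isTRUE(cfg$hcpc$consolidate)) {
      ctr <- rowsum(scores, labels) / as.vector(table(labels))
      km <- stats::kmeans(scores, centers = ctr)
      labels <- km$cluster
    }
    list(tree = wt, selection = sel, vote = vote, labels = labels)
  }
  clus <- stage("hcpc", cluster_block(aligned, pca, m, "combined"))
  labels <- setNames(clus$labels, spec_ids)
  log_msg("hcpc", "k = %d (low confidence: %s); vote: %s", clus$selection$k,
          clus$selection$low_confidence,
          paste(clus$vote$choices, collapse = "/"))

  by_side <- NULL
  if (side_significant) {
    by_side <- lapply(split(seq_len(n), rec$side), function(idx) {
      al <- structure(list(aligned = aligned$aligned[idx, , , drop = FALSE]),
                      class = "aligned_sample")
      pc <- shape_pca(al)
      mm <- select_components_elbow(pc$explained_ratio)
      cb <- stage("hcpc_side", cluster_block(al, pc, mm, "side"))
      list(k = cb$selection$k, labels = setNames(cb$labels, spec_ids[idx]))
    })
  }

  ## -- characterization ---------------------------------------------------
  # MANOVA needs >= 4 specimens per cluster, ANOVA/Tukey >= 2; with very
  # small samples the affected table is skipped rather than aborting
  min_cluster <- min(table(labels))
  characterization <- stage("characterization", list(
    manova = if (min_cluster >= 4L)
      manova_per_landmark(aligned, labels, p_adjust = cfg$stats$p_adjust)
      else NULL,
    anova = if (min_cluster >= 2L)
      anova_per_axis(aligned, labels, p_adjust = cfg$stats$p_adjust)
      else NULL,
    tukey = if (min_cluster >= 2L)
      tukey_pairwise(aligned, labels, alpha = cfg$stats$alpha) else NULL,
    min_cluster_size = min_cluster))
  if (min_cluster < 4L)
    warning(sprintf("smallest cluster has %d specimens; %s skipped",
                    min_cluster,
                    if (min_cluster < 2L) "MANOVA/ANOVA/Tukey"
                    else "MANOVA"))

  ## -- cohort summaries ---------------------------------------------------
  pairs <- stage("pairs", pair_clusters_by_patient(labels, excl$records))
  demographics <- stage("demographics",
                        demographics_table(labels, excl$records, pop$cohort))

  ari <- if (!is.null(pop$labels))
    adjusted_rand_index(pop$labels[spec_ids], labels) else NULL

  report <- structure(list(
    config = cfg,
    counts = list(n_input = excl$n_input, n_retained = excl$n_retained,
                  n_patients = nrow(pop$cohort)),
    sliding = list(final_energies = unname(energies),
                   iterations = vapply(slid, `[[`, 0L, "iterations")),
    side_test = side_test[c("F", "p", "n_perm")],
    sensitivity = if (!is.null(sensitivity))
      sensitivity[c("F", "p", "n_perm")] else NULL,
    pca = list(explained_ratio = pca$explained_ratio, retained = m,
               cum_explained_retained = sum(pca$explained_ratio[1:m])),
    stability = stability,
    clustering = list(k = clus$selection$k,
                      low_confidence = clus$selection$low_confidence,
                      vote = as.list(clus$vote$choices),
                      inertia = as.list(clus$selection$W),
                      labels = as.list(labels)),
    by_side = by_side,
    characterization = characterization,
    pairs = list(table = pairs$pairs, total_patients = pairs$total_patients,
                 at_least_one = setNames(
                   lapply(sort(unique(labels)), function(k)
                     at_least_one_membership(pairs, k)),
                   paste0("cluster_", sort(unique(labels))))),
    demographics = demographics[c("table", "p_values", "missing")],
    ground_truth_ari = ari,
    seed = seed), class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write a pipeline report bundle
#'
#' `report.json` (summary numbers) plus tidy CSV tables under `tables/`.
#' Output is byte-deterministic for a fixed config and seed.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  if (is.null(report) || !length(report))
    .mc_stop("empty report", class = "validation_error")
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  summary <- report[setdiff(names(report),
                            c("characterization", "stability"))]
  summary$config$exclusions <- NULL
  summary$config$out_dir <- NULL       # path-free: keeps bytes reproducible
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, "tables", name),
                     row.names = FALSE)
  if (!is.null(report$characterization$manova))
    wr(report$characterization$manova, "manova.csv")
  if (!is.null(report$characterization$anova))
    wr(report$characterization$anova, "anova.csv")
  if (!is.null(report$characterization$tukey))
    wr(report$characterization$tukey, "tukey.csv")
  wr(report$pairs$table, "pairs.csv")
  wr(report$demographics$table, "demographics.csv")
  if (!is.null(report$stability)) wr(report$stability, "pca_stability.csv")
  invisible(out_dir)
}

#' Write a population to disk in the formats the readers accept
#'
#' One ASCII STL and one landmark CSV per specimen, plus `records.csv`,
#' `cohort.csv`, `labels.csv` (ground truth) and the template files.
#'
#' @param pop result of [generate_population()].
#' @param dir output directory.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in pop$specimens) {
    id <- sp$landmarks$specimen_id
    write_mesh_stl(sp$mesh, file.path(dir, paste0(id, ".stl")))
    write_landmarks(sp$landmarks, file.path(dir, paste0(id, ".csv")), "csv")
    utils::write.csv(as.data.frame(sp$digitized_fixed),
                     file.path(dir, paste0(id, "_fixed.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(pop$records),
                   file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(pop$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  if (!is.null(pop$labels))
    utils::write.csv(data.frame(specimen_id = names(pop$labels),
                                cluster = unname(pop$labels)),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  tpl <- pop$template
  write_mesh_stl(tpl$mesh, file.path(dir, "template.stl"))
  write_landmarks(template_configuration(tpl),
                  file.path(dir, "template.csv"), "csv")
  invisible(dir)
}

#' Read a population directory written by [write_population()]
#' @param dir directory path.
#' @export
read_population <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  class(records) <- c("specimen_records", "data.frame")
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  labels <- NULL
  lf <- file.path(dir, "labels.csv")
  if (file.exists(lf)) {
    ldf <- utils::read.csv(lf, stringsAsFactors = FALSE)
    labels <- setNames(ldf$cluster, ldf$specimen_id)
  }
  specimens <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$specimen_id[i]
    fx <- as.matrix(utils::read.csv(file.path(dir, paste0(id, "_fixed.csv"))))
    list(mesh = read_mesh(file.path(dir, paste0(id, ".stl"))),
         landmarks = read_landmarks(file.path(dir, paste0(id, ".csv")),
                                    "csv", specimen_id = id),
         digitized_fixed = unname(fx),
         side = records$side[i])
  })
  # template: rebuild the definition from its landmark file and mesh
  tpl_cfg <- read_landmarks(file.path(dir, "template.csv"), "csv",
                            specimen_id = "template")
  fixed <- tpl_cfg$coordinates[tpl_cfg$patch_ids == 0L, , drop = FALSE]
  template <- list(mesh = read_mesh(file.path(dir, "template.stl")),
                   fixed_landmarks = fixed,
                   semilandmarks = tpl_cfg$coordinates[tpl_cfg$patch_ids > 0L,
                                                       , drop = FALSE],
                   patch_ids = tpl_cfg$patch_ids[tpl_cfg$patch_ids > 0L])
  list(specimens = specimens, records = records, cohort = cohort,
       labels = labels, template = template, spec = NULL)
}
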
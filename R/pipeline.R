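# Run configuration and the end-to-end demo pipeline.

#' Build a validated run configuration
#'
#' Collects every threshold of the pipeline in one object. Defaults are
#' the study constants: FDR 0.01 for disease selection (0.001 for
#' stringent cohorts), FDR 0.01 for age genes, commonality over at
#' least 2 datasets, 65-year age cutoff, 1.4-fold background filter,
#' 1000 permutations, strong/weak thresholds 0.01/0.05, 2-fold DEGs at
#' model-DEG FDR 0.1, network coverage > 0.5, degree bins of >= 10
#' genes, TFBS relative score 0.9 over a (-2000, +500] promoter window.
#'
#' @param seed master seed (mandatory; every permutation step derives a
#'   named substream from it).
#' @param fdr_ad,fdr_ad_stringent,fdr_age,min_datasets,age_min,
#'   background_factor,B,alpha_strong,alpha_weak,fold,deg_fdr,
#'   coverage_min,degree_min_count,tfbs_min_rel,tfbs_window,
#'   adjacent_fraction study constants (see description).
#' @param n_datasets,n_genes,n_case,n_control,delta,model_rhos,
#'   n_network_nodes,n_pathways synthetic-data sizes for simulated runs.
#' @param batch_adjust apply batch standardization when datasets are
#'   merged.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed,
                       fdr_ad = 0.01, fdr_ad_stringent = 0.001,
                       fdr_age = 0.01, min_datasets = 2L, age_min = 65,
                       background_factor = 1.4, B = 1000L,
                       alpha_strong = 0.01, alpha_weak = 0.05,
                       fold = 2, deg_fdr = 0.1, coverage_min = 0.5,
                       degree_min_count = 10L, tfbs_min_rel = 0.9,
                       tfbs_window = c(-2000L, 500L),
                       adjacent_fraction = 0.9,
                       n_datasets = 3L, n_genes = 600L,
                       n_case = 10L, n_control = 10L, delta = 1.5,
                       model_rhos = c(concordant = 1, partial = 0.5,
                                      unrelated = 0),
                       n_network_nodes = 500L, n_pathways = 20L,
                       batch_adjust = TRUE) {
  if (missing(seed)) stop("a master seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(fdr_ad > 0, fdr_ad < 1, fdr_age > 0, fdr_age < 1,
            min_datasets >= 1L, age_min >= 0, background_factor >= 0,
            B >= 100L, alpha_strong <= alpha_weak, fold >= 1,
            coverage_min >= 0, coverage_min < 1,
            tfbs_min_rel >= 0, tfbs_min_rel <= 1,
            adjacent_fraction > 0, adjacent_fraction <= 1)
  structure(cfg, class = "run_config")
}

# Restrict a dataset to samples at or above the age cutoff (cases and
# controls); samples with unknown age are dropped.
apply_age_cutoff <- function(ds, age_min) {
  keep <- !is.na(ds$meta$age) & ds$meta$age >= age_min
  if (sum(keep) < 4L) stop("too few samples at or above age ", age_min)
  expression_dataset(ds$values[, keep, drop = FALSE],
                     ds$meta[keep, , drop = FALSE],
                     background = if (is.null(ds$background)) NULL else
                       ds$background[, keep, drop = FALSE])
}

#' Run the full pipeline on simulated inputs
#'
#' Executes simulate, preprocess (background filter, quantile
#' normalization, age cutoff), signature construction (two-class and
#' quantitative SAM, commonality, age-gene subtraction), pathway
#' activity with differential selection, network characterization
#' (distance matrix, signature-adjacent pathways), and model evaluation
#' (expression and pathway scores, DEG network adjacency, report
#' table), writing all result tables plus a machine-readable manifest
#' to `out_dir`. Rerunning with the same configuration produces
#' byte-identical tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results
#'   (`signature`, `accounting`, `differential`, `distance`,
#'   `adjacent_up`, `adjacent_down`, `scores`, `report`, `truth`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- gen_human_datasets(
      n_datasets = config$n_datasets, n_genes = config$n_genes,
      n_case = config$n_case, n_control = config$n_control,
      delta = config$delta, seed = config$seed)
    truth <- sim$truth
    om <- gen_orthology(truth)
    net <- gen_network(truth, n_nodes = config$n_network_nodes,
                       hub_bias = TRUE, seed = config$seed)
    pw <- gen_pathways(truth, n_pathways = config$n_pathways,
                       frac_repressor = 0.1, seed = config$seed)

    stage <- "preprocess"
    prep <- lapply(sim$datasets, function(ds) {
      ds <- filter_background(ds, config$background_factor)
      ds$values <- quantile_normalize(ds$values)
      ds
    })

    stage <- "signature"
    ad_results <- lapply(seq_along(prep), function(i) {
      sam_two_class(apply_age_cutoff(prep[[i]], config$age_min),
                    n_perm = config$B,
                    seed = substream_seed(config$seed, paste0("sam2c", i)),
                    fdr = config$fdr_ad)
    })
    age_results <- lapply(seq_along(prep), function(i) {
      ds <- prep[[i]]
      ctrl <- ds$meta$group == "control"
      ctrl_ds <- expression_dataset(ds$values[, ctrl, drop = FALSE],
                                    ds$meta[ctrl, , drop = FALSE])
      sam_quantitative(ctrl_ds, n_perm = config$B,
                       seed = substream_seed(config$seed, paste0("samq", i)),
                       fdr = config$fdr_age)
    })
    ad_up <- select_common(ad_results, fdr = config$fdr_ad,
                           min_datasets = config$min_datasets,
                           direction = "up")
    ad_down <- select_common(ad_results, fdr = config$fdr_ad,
                             min_datasets = config$min_datasets,
                             direction = "down")
    age_up <- select_common(age_results, fdr = config$fdr_age,
                            min_datasets = config$min_datasets,
                            direction = "up")
    age_down <- select_common(age_results, fdr = config$fdr_age,
                              min_datasets = config$min_datasets,
                              direction = "down")
    refined <- refine_signature(ad_up, ad_down, age_up, age_down,
                                provenance = c(attr(ad_up, "provenance"),
                                               attr(ad_down, "provenance")))
    sig <- refined$signature

    stage <- "pathway_activity"
    ref_ds <- apply_age_cutoff(prep[[1L]], config$age_min)
    act <- activity_matrix(ref_ds, pw$collection, pw$roles)
    diff_pw <- differential_pathways(
      act, ref_ds$meta$group, alpha = config$alpha_weak, B = config$B,
      seed = substream_seed(config$seed, "diffpw"))
    human_up <- diff_pw$pathway[diff_pw$selected & diff_pw$direction == "up"]
    human_down <- diff_pw$pathway[diff_pw$selected & diff_pw$direction == "down"]

    stage <- "network"
    sets <- c(pw$collection, list(sig_up = sig$up, sig_down = sig$down))
    dm <- distance_matrix(net, sets, coverage_min = config$coverage_min)
    take_row <- function(label) {
      if (!label %in% rownames(dm$matrix)) {
        message("signature set ", label,
                " failed network coverage; no adjacent pathways")
        return(numeric())
      }
      row <- dm$matrix[label, setdiff(colnames(dm$matrix),
                                      c("sig_up", "sig_down"))]
      row[is.finite(row)]
    }
    adjacent_up <- adjacent_pathways(take_row("sig_up"),
                                     value = config$adjacent_fraction)
    adjacent_down <- adjacent_pathways(take_row("sig_down"),
                                       value = config$adjacent_fraction)

    stage <- "model_eval"
    scores <- list()
    deg_sets <- list()
    for (i in seq_along(config$model_rhos)) {
      nm <- names(config$model_rhos)[i] %||% paste0("model", i)
      prof <- gen_animal_model(
        truth, rho = config$model_rhos[[i]],
        seed = substream_seed(config$seed, paste0("model", i)),
        model = nm)
      ratios_h <- prof$ratios
      names(ratios_h) <- unname(om[names(ratios_h)])
      prof_h <- log_ratio_profile(ratios_h, model = nm, tissue = prof$tissue)
      scores[[paste0(nm, "_expr")]] <- score_expression(
        prof_h, sig, B = config$B,
        seed = substream_seed(config$seed, paste0("scoreexpr", i)),
        alpha_strong = config$alpha_strong, alpha_weak = config$alpha_weak)
      model_act <- vapply(names(pw$collection), function(p)
        activity_score(ratios_h, pw$collection[[p]],
                       set_repressors(pw$roles, p)), numeric(1))
      if (length(human_up) && length(human_down) &&
          length(human_up) + length(human_down) >= 5L)
        scores[[paste0(nm, "_pw")]] <- score_pathways(
          model_act, human_up, human_down, B = config$B,
          seed = substream_seed(config$seed, paste0("scorepw", i)),
          alpha_strong = config$alpha_strong,
          alpha_weak = config$alpha_weak, model = nm, tissue = prof$tissue)
      deg_sets[[nm]] <- unlist(select_degs(prof_h, mode = "fold",
                                           threshold = config$fold),
                               use.names = FALSE)
    }
    network_calls <- lapply(seq_along(deg_sets), function(i) {
      adj <- tryCatch(
        deg_pathway_adjacency(
          net, deg_sets[[i]], adjacent_up, pw$collection,
          B = config$B,
          seed = substream_seed(config$seed, paste0("degadj", i)),
          value = config$adjacent_fraction,
          coverage_min = config$coverage_min),
        error = function(e) NULL)
      if (is.null(adj)) return("none")
      if (adj$p <= config$alpha_strong) "strong"
      else if (adj$p <= config$alpha_weak) "weak" else "none"
    })
    names(network_calls) <- paste(names(deg_sets), "brain")
    report <- summarize_models(scores, network_calls)

    stage <- "write"
    write_signature(sig, file.path(out_dir, "signature.tsv"),
                    file.path(out_dir, "signature_provenance.json"))
    write_tsv_stable(refined$accounting, file.path(out_dir, "accounting.tsv"))
    write_tsv_stable(data.frame(pathway = rownames(act$activity),
                                act$activity, check.names = FALSE),
                     file.path(out_dir, "activity.tsv"))
    write_tsv_stable(diff_pw, file.path(out_dir, "differential_pathways.tsv"))
    write_tsv_stable(data.frame(set = rownames(dm$matrix), dm$matrix,
                                check.names = FALSE),
                     file.path(out_dir, "distance_matrix.tsv"))
    writeLines(adjacent_up, file.path(out_dir, "adjacent_pathways_up.txt"))
    writeLines(adjacent_down, file.path(out_dir, "adjacent_pathways_down.txt"))
    score_df <- do.call(rbind, lapply(scores, function(s)
      data.frame(model = s$model, tissue = s$tissue, measure = s$measure,
                 mean_up = s$mean_up, mean_down = s$mean_down,
                 p_up = s$p_up, p_down = s$p_down, class = s$class)))
    write_tsv_stable(score_df, file.path(out_dir, "model_scores.tsv"))
    write_tsv_stable(report, file.path(out_dir, "report.tsv"))
    write_truth(truth, file.path(out_dir, "truth.json"))
    manifest <- config
    class(manifest) <- NULL
    jsonlite::write_json(
      list(config = manifest,
           package_version = as.character(utils::packageVersion("neuroconcord"))),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)

    list(signature = sig, accounting = refined$accounting,
         differential = diff_pw, distance = dm,
         adjacent_up = adjacent_up, adjacent_down = adjacent_down,
         scores = scores, report = report, truth = truth)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
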
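# End-to-end orchestration: simulate -> PCA -> PLS-DA -> permutation test ->
# N-PLS-DA -> clustergram, with every stage consuming and producing flat
# files so stages can be rerun independently.

#' Default pipeline run configuration
#'
#' @param out_dir output directory.
#' @param generator a \code{\link{jamu_config}} (set to NULL to read existing
#'   tables from \code{usage_path} / \code{activity_path}).
#' @param usage_path,activity_path input tables when not simulating.
#' @param ncomp PLS / N-PLS components.
#' @param n_perm,alpha permutation-test controls.
#' @param threshold activity-weight significance cutoff.
#' @param seed master seed for all stochastic stages.
#' @return \code{run_config} list.
#' @export
run_config <- function(out_dir, generator = jamu_config(), usage_path = NULL,
                       activity_path = NULL, ncomp = 5, n_perm = 99,
                       alpha = 0.05, threshold = 0.3, seed = 1) {
  structure(list(out_dir = out_dir, generator = generator,
                 usage_path = usage_path, activity_path = activity_path,
                 ncomp = ncomp, n_perm = n_perm, alpha = alpha,
                 threshold = threshold, seed = seed),
            class = "run_config")
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data (simulate or load), PCA biplot of the
#' plant-by-efficacy frequency table, PLS-DA with confusion matrix,
#' permutation test for main-ingredient plants, N-PLS-DA activity
#' significance, and the Ward clustergram.  Every written artifact is
#' recorded in the returned manifest with an MD5 content hash; identical
#' configurations reproduce identical hashes.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param quiet suppress progress messages.
#' @return data frame manifest (stage, file, md5), invisibly also written to
#'   \code{manifest.tsv}.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0); stages <- character(0)
  emit <- function(stage, file) {
    stages <<- c(stages, stage); paths <<- c(paths, file)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
    })
    stage_msg(quiet, "stage %-12s done in %.1fs", stage,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  dat <- run_stage("data", {
    if (!is.null(cfg$generator)) {
      sim <- simulate_formulary(cfg$generator)
      f_usage <- file.path(cfg$out_dir, "usage.tsv")
      f_act <- file.path(cfg$out_dir, "activity.tsv")
      f_truth <- file.path(cfg$out_dir, "ground_truth.json")
      write_usage_table(sim$usage, sim$labels, f_usage)
      write_activity_table(sim$activity, f_act)
      jsonlite::write_json(sim$truth, f_truth, pretty = TRUE)
      emit("data", f_usage); emit("data", f_act); emit("data", f_truth)
      sim
    } else {
      tab <- read_usage_table(cfg$usage_path)
      list(usage = tab$usage, labels = tab$labels,
           activity = read_activity_table(cfg$activity_path))
    }
  })
  classes <- levels(dat$labels)

  run_stage("pca", {
    freq <- build_frequency_matrix(dat$usage, dat$labels)
    pca <- fit_pca(freq)
    bp <- biplot_coords(pca)
    f_eval <- file.path(cfg$out_dir, "pca_eigenvalues.tsv")
    utils::write.table(data.frame(component = seq_along(pca$values),
                                  eigenvalue = pca$values,
                                  cum_var = cumsum(pca$values) / sum(pca$values)),
                       f_eval, sep = "\t", quote = FALSE, row.names = FALSE)
    f_bp <- file.path(cfg$out_dir, "biplot_coords.tsv")
    utils::write.table(rbind(
      data.frame(id = rownames(freq), role = "point",
                 dim1 = bp$points[, 1], dim2 = bp$points[, 2]),
      data.frame(id = classes, role = "vector",
                 dim1 = bp$vectors[, 1], dim2 = bp$vectors[, 2])),
      f_bp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("pca", f_eval); emit("pca", f_bp)
  })

  plsda <- run_stage("plsda", {
    fit <- fit_plsda(dat$usage, dat$labels, cfg$ncomp)
    cm <- confusion(dat$labels, predict(fit, dat$usage))
    f_cm <- file.path(cfg$out_dir, "confusion.tsv")
    write_confusion(cm, f_cm)
    emit("plsda", f_cm)
    fit
  })

  run_stage("permtest", {
    res <- plsda_permutation_test(dat$usage, dat$labels, cfg$ncomp,
                                  n_perm = cfg$n_perm, alpha = cfg$alpha,
                                  seed = cfg$seed)
    sig <- significant_plants(res)
    f_p <- file.path(cfg$out_dir, "pvalues.tsv")
    utils::write.table(cbind(plant_id = rownames(res$p_values),
                             as.data.frame(res$p_values, check.names = FALSE)),
                       f_p, sep = "\t", quote = FALSE, row.names = FALSE)
    f_sum <- file.path(cfg$out_dir, "significant_plants.tsv")
    utils::write.table(data.frame(efficacy = names(sig$counts_per_class),
                                  n_significant = as.integer(sig$counts_per_class)),
                       f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("permtest", f_p); emit("permtest", f_sum)
  })

  sig_mat <- run_stage("npls", {
    X3 <- build_tensor(dat$usage, dat$activity)
    sm <- activity_significance(X3, dat$labels, ncomp = 2,
                                threshold = cfg$threshold)
    f_sig <- file.path(cfg$out_dir, "activity_significance.tsv")
    utils::write.table(cbind(activity_id = rownames(sm$S),
                             as.data.frame(sm$S, check.names = FALSE)),
                       f_sig, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("npls", f_sig)
    sm
  })

  run_stage("clustergram", {
    cg <- clustergram(sig_mat)
    f_rows <- file.path(cfg$out_dir, "activity_tree.nwk")
    f_cols <- file.path(cfg$out_dir, "efficacy_tree.nwk")
    f_mat <- file.path(cfg$out_dir, "clustergram_matrix.tsv")
    writeLines(to_newick(cg$row_tree), f_rows)
    writeLines(to_newick(cg$col_tree), f_cols)
    utils::write.table(cbind(activity_id = rownames(cg$matrix),
                             as.data.frame(cg$matrix, check.names = FALSE)),
                       f_mat, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("clustergram", f_rows); emit("clustergram", f_cols); emit("clustergram", f_mat)
  })

  manifest <- data.frame(stage = stages, file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
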
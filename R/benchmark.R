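#' End-to-end density benchmark on synthetic scenes
#'
#' Reproduces the full survey workflow on ground-truthed synthetic data:
#' a training batch of scenes is generated and reduced to a labelled object
#' table, the count network is trained with recursive feature elimination,
#' and the fitted model is applied to a disjoint test batch whose estimated
#' densities are compared with the generator's ground truth.
#'
#' @param n_train,n_test number of training and test scenes.
#' @param densities sowing densities cycled over the scenes (seeds per m2).
#' @param seed master seed; scene seeds and split seeds derive from it.
#' @param k_n hidden nodes for the count network.
#' @param reps 90/10 splits inside the feature elimination.
#' @param segment_length_mm,resolution_mm scene geometry (defaults match
#'   [scene_spec()]).
#' @return List: `results` (data.frame with per-test-scene true and estimated
#'   density and relative error in percent), `mean_relative_error_pct`,
#'   `rfe` (the feature-elimination trace and final model), `n_train_objects`.
#' @export
benchmark_density <- function(n_train = 50, n_test = 30,
                              densities = c(100, 200, 300, 400, 600),
                              seed = 1L, k_n = 2L, reps = 5L,
                              segment_length_mm = 450, resolution_mm = 0.6) {
  dens_at <- function(i) densities[(i - 1) %% length(densities) + 1]
  train_specs <- lapply(seq_len(n_train), function(i)
    scene_spec(sowing_density_seeds_m2 = dens_at(i),
               segment_length_mm = segment_length_mm,
               resolution_mm = resolution_mm,
               seed = derive_seed(seed, 1000 + i)))
  tab <- generate_training_set(train_specs)
  rfe <- recursive_feature_elimination(tab, tab$true_count, k_n = k_n,
                                       reps = reps, seed = derive_seed(seed, 7L))
  config <- list(row_spacing_mm = 175, segment_length_mm = segment_length_mm,
                 resolution_mm = resolution_mm)
  res <- do.call(rbind, lapply(seq_len(n_test), function(i) {
    sc <- generate_scene(scene_spec(sowing_density_seeds_m2 = dens_at(i),
                                    segment_length_mm = segment_length_mm,
                                    resolution_mm = resolution_mm,
                                    seed = derive_seed(seed, 2000 + i)))
    out <- run_pipeline(sc, model = rfe$model, config = config)
    data.frame(scene = i, sowing_density = dens_at(i),
               density_true = sc$truth$density_true_m2,
               density_est = out$density$plants_per_m2,
               n_rows_detected = out$density$n_rows_counted,
               n_objects = out$density$n_objects)
  }))
  res$relative_error_pct <- relative_error(res$density_est, res$density_true)
  list(results = res,
       mean_relative_error_pct = mean(res$relative_error_pct),
       rfe = rfe, n_train_objects = nrow(tab))
}

#' Held-out plants-per-object benchmark at low sowing densities
#'
#' Builds a labelled object table from synthetic scenes at low sowing
#' densities, runs the feature elimination (whose repeated 90/10 splits give
#' the held-out error of every subset size), and reports the mean held-out
#' RMSE of the retained feature subset, together with the full trace.
#'
#' @param n_scenes number of scenes.
#' @param densities sowing densities cycled over scenes.
#' @inheritParams benchmark_density
#' @return List: `rmse` (held-out RMSE of the chosen subset, plants/object),
#'   `rfe`, `n_objects`, `table`.
#' @export
benchmark_counts <- function(n_scenes = 40, densities = c(100, 200, 300),
                             seed = 1L, k_n = 2L, reps = 5L,
                             segment_length_mm = 450, resolution_mm = 0.6) {
  specs <- lapply(seq_len(n_scenes), function(i)
    scene_spec(sowing_density_seeds_m2 = densities[(i - 1) %% length(densities) + 1],
               segment_length_mm = segment_length_mm,
               resolution_mm = resolution_mm,
               seed = derive_seed(seed, 3000 + i)))
  tab <- generate_training_set(specs)
  rfe <- recursive_feature_elimination(tab, tab$true_count, k_n = k_n,
                                       reps = reps, seed = derive_seed(seed, 8L))
  list(rmse = rfe$trace$rmse[rfe$trace$n == rfe$chosen_n],
       rfe = rfe, n_objects = nrow(tab), table = tab)
}
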
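#' Desk-scale alignment benchmark
#'
#' Runs the package's standard diagnostic protocol: a two-hidden-layer ReLU
#' network trained on a teacher-network classification task with each of the
#' requested algorithms, recording the backward-forward alignment angle and
#' norm ratio per layer and epoch. This is the desk-scale analogue of the
#' classic 784-512-512-10 MNIST protocol; the characteristic angles it
#' produces are not dataset-specific (the PFA path angle at expansion ratio
#' 10 is the random-matrix value `acos(1/sqrt(1 + lambda)) ~ 17.5` degrees,
#' approached once weight decay has washed out the initializations).
#'
#' The weight-decay schedule is per algorithm: PFA/PFA-o/KP use the two-phase
#' schedule (`wd_initial` while the initializations wash out, then
#' `wd_main`), because erasing `W0` and `R0` is what drives the product
#' pathway into alignment; FA and SF have no plastic feedback to align, and
#' use the constant small decay `wd_main` throughout (a large early decay
#' would artificially align FA's forward weights to its fixed feedback).
#'
#' @param seed Master seed (task, initializations and data order all derive
#'   from it).
#' @param algorithms Algorithms to run.
#' @param input_dim,n_classes,n_train,n_test Teacher-task shape.
#' @param hidden Hidden-layer sizes.
#' @param epochs,batch_size,lr Optimization protocol.
#' @param wd_initial,wd_main,wd_switch_epoch Two-phase decay (see above).
#' @param expansion_ratio PFA expansion ratio `1/lambda`.
#' @return A list with `fits` (named list of `pfa_fit`) and `summary` (tibble
#'   with one row per algorithm and layer at the final epoch: `angle_deg`,
#'   `norm_ratio`, `final_test_accuracy`, `final_train_loss`).
#' @export
alignment_benchmark <- function(seed = 1,
                                algorithms = c("pfa", "pfa_o", "fa", "sf"),
                                input_dim = 100, n_classes = 10,
                                n_train = 3000, n_test = 1000,
                                hidden = c(256, 256), epochs = 40,
                                batch_size = 64, lr = 0.1,
                                wd_initial = 1e-2, wd_main = 1e-4,
                                wd_switch_epoch = 5, expansion_ratio = 10) {
  data <- gen_teacher_task(input_dim, n_classes, n_train, teacher_depth = 2,
                           seed = substream_seed(seed, "data"), n_test = n_test)
  fits <- list()
  rows <- list()
  for (alg in algorithms) {
    two_phase <- alg %in% c("pfa", "pfa_o", "kp")
    cfg <- train_config(algorithm = alg, epochs = epochs,
                        batch_size = batch_size, lr = lr,
                        wd_initial = if (two_phase) wd_initial else wd_main,
                        wd_main = wd_main, wd_switch_epoch = wd_switch_epoch,
                        expansion_ratio = expansion_ratio, seed = seed,
                        hidden = hidden)
    fit <- train_network(data, cfg)
    fits[[alg]] <- fit
    g <- glance(fit)
    last <- fit$metrics[fit$metrics$epoch == epochs, ]
    if (nrow(last)) {
      last$final_test_accuracy <- g$final_test_accuracy
      last$final_train_loss <- g$final_train_loss
      rows[[alg]] <- last
    }
  }
  list(fits = fits, summary = dplyr::bind_rows(rows))
}

#' Desk-scale sparse-feedback benchmark
#'
#' Compares final test accuracy of algorithms under heavy feedback sparsity
#' (entries of `B`, and `R` for PFA, fixed to zero). The protocol is chosen
#' so the property it probes can express itself at desk scale: a
#' capacity-tight network (at `p = 0.9` the sparse feedback into a narrow
#' layer leaves a Poisson(`(1-p) * n_classes`)-sized fraction of FA's hidden
#' units with no error signal at all, while PFA's product pathway `RB` stays
#' dense thanks to the expanded intermediate population), and
#' convergence-length training (the ordering concerns converged accuracy;
#' PFA's attenuated sparse errors need more steps to bootstrap).
#'
#' @param seed Master seed.
#' @param sparsity_levels Sparsity levels `p` to sweep.
#' @param algorithms Algorithms to compare.
#' @param n_seeds Replicate runs per cell.
#' @param input_dim,n_classes,n_train,n_test,hidden,epochs,batch_size,lr
#'   Protocol knobs (defaults are the package's standard sparse benchmark).
#' @param expansion_ratio PFA expansion ratio.
#' @return The tidy sweep table from [run_sparsity_sweep()].
#' @export
sparsity_benchmark <- function(seed = 1, sparsity_levels = 0.9,
                               algorithms = c("fa", "pfa"), n_seeds = 5,
                               input_dim = 16, n_classes = 8, n_train = 1500,
                               n_test = 500, hidden = 12, epochs = 200,
                               batch_size = 50, lr = 0.3,
                               expansion_ratio = 10) {
  data <- gen_teacher_task(input_dim, n_classes, n_train, teacher_depth = 2,
                           seed = substream_seed(seed, "data"), n_test = n_test)
  cfg <- train_config(epochs = epochs, batch_size = batch_size, lr = lr,
                      wd_initial = 1e-3, wd_main = 1e-4,
                      expansion_ratio = expansion_ratio, hidden = hidden)
  run_sparsity_sweep(data, cfg, sparsity_levels = sparsity_levels,
                     algorithms = algorithms,
                     seeds = (seed %% 1000000) * 100 + seq_len(n_seeds))
}
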
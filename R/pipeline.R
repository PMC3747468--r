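# High-level pipeline: train both surrogates, sweep the weight, extract and
# validate the knee, compare reference screws, and write run artifacts.

#' Train the bending and pullout surrogates
#'
#' Multi-restart training of both surrogate networks on a learning/testing
#' split, with an error report in physical units.
#'
#' @param data Labeled designs with a `split` column, by default the
#'   packaged design/response table ([load_table1()]).
#' @param n_restarts Restarts per target.
#' @param update_mode Passed to [train_config()].
#' @param seed Master seed; the pullout target uses `seed + 500` so the two
#'   targets draw independent restart initializations.
#' @param space A [design_space()].
#' @return List with `bending` and `pullout` (trained
#'   [surrogate_net][init_network()]s) and `mae`: a data frame of
#'   learning/testing mean absolute percentage errors per target.
#' @export
fit_surrogates <- function(data = load_table1(), n_restarts = 100L,
                           update_mode = "batch", seed = 1L,
                           space = design_space()) {
  learning <- data[data$split == "learning", ]
  testing <- data[data$split == "testing", ]
  nets <- list()
  for (tgt in c("bending", "pullout")) {
    cfg <- train_config(tgt, n_restarts = n_restarts,
                        update_mode = update_mode,
                        seed = if (tgt == "bending") seed else seed + 500L)
    nets[[tgt]] <- multi_restart_train(learning, testing, cfg, space)
  }
  mae <- do.call(rbind, lapply(c("bending", "pullout"), function(tgt) {
    data.frame(target = tgt,
               learning = mae_percent(nets[[tgt]], learning, space),
               testing = mae_percent(nets[[tgt]], testing, space))
  }))
  list(bending = nets$bending, pullout = nets$pullout, mae = mae)
}

#' Sweep, filter, and validate the bending/pullout trade-off
#'
#' Full optimization stage: weight sweep, nondominated filtering, knee
#' extraction, and dominance validation against uniform random designs.
#'
#' @param ctx A [fitness_context()] built from trained surrogates.
#' @param weights Weight grid, default 0 to 1 in steps of 0.01.
#' @param ga_cfg Base [ga_config()]; per-weight seeds derive from its seed.
#' @param knee_threshold Knee criterion on `|f_bending - f_pullout|`.
#' @param n_validate Random designs for dominance validation.
#' @return List with `candidates` (the full sweep archive), `front`, `knee`,
#'   `knee_summary`, and `validation` (see [dominance_validation()]).
#' @export
optimize_designs <- function(ctx, weights = seq(0, 1, by = 0.01),
                             ga_cfg = ga_config(), knee_threshold = 0.02,
                             n_validate = 10000L) {
  candidates <- weight_sweep(ctx, ga_cfg, weights)
  front <- nondominated_filter(candidates)
  knee <- knee_region(front, knee_threshold)
  list(candidates = candidates, front = front, knee = knee,
       knee_summary = if (nrow(knee) > 0) knee_summary(knee) else NULL,
       validation = dominance_validation(front, ctx, n_validate,
                                         seed = ga_cfg$seed + 9999L))
}

#' Position reference screws relative to the knee region
#'
#' Scores the packaged reference screws on the front's objective scale and
#' reports, for each, whether it is weakly dominated by a knee solution and
#' its nearest distance to the knee in objective space.
#'
#' @param ctx A [fitness_context()].
#' @param knee Knee point set from [knee_region()].
#' @param screws Reference screws, default [load_table2()].
#' @param source Passed to [score_reference_screws()].
#' @return The scored data frame with extra columns `dominated_by_knee` and
#'   `dist_to_knee`.
#' @export
compare_reference_screws <- function(ctx, knee, screws = load_table2(),
                                     source = "fe") {
  if (nrow(knee) == 0L) stop("knee region is empty; nothing to compare against")
  scored <- score_reference_screws(ctx, screws, source)
  scored$dominated_by_knee <- vapply(seq_len(nrow(scored)), function(i) {
    any(knee$f_bending >= scored$f_bending[i] &
          knee$f_pullout >= scored$f_pullout[i] &
          (knee$f_bending > scored$f_bending[i] |
             knee$f_pullout > scored$f_pullout[i]))
  }, logical(1))
  scored$dist_to_knee <- vapply(seq_len(nrow(scored)), function(i) {
    min(sqrt((knee$f_bending - scored$f_bending[i])^2 +
               (knee$f_pullout - scored$f_pullout[i])^2))
  }, numeric(1))
  scored
}

#' Run the whole optimization pipeline and write its artifacts
#'
#' Trains both surrogates, sweeps the weight grid, extracts and validates
#' the knee, scores the reference screws, and writes everything under
#' `out_dir`: serialized surrogate models, the front CSV (with an `in_knee`
#' column), a JSON knee summary, the reference screw report, and an echo of
#' the configuration for provenance. All outputs are deterministic functions
#' of `seed` and the configuration.
#'
#' @param out_dir Output directory, created if missing.
#' @param seed Master seed.
#' @param data Labeled design/response table.
#' @param weights Weight grid.
#' @param n_restarts Training restarts per target.
#' @param knee_threshold Knee criterion.
#' @param n_validate Dominance-validation sample size.
#' @return Invisibly, a list with all stage results (`surrogates`, `ctx`,
#'   `opt`, `references`, `paths`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, data = load_table1(),
                         weights = seq(0, 1, by = 0.01), n_restarts = 100L,
                         knee_threshold = 0.02, n_validate = 10000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  surr <- fit_surrogates(data, n_restarts = n_restarts, seed = seed)
  ctx <- fitness_context(surr$bending, surr$pullout)
  opt <- optimize_designs(ctx, weights, ga_config(seed = seed + 1000L),
                          knee_threshold, n_validate)
  refs <- if (nrow(opt$knee) > 0) {
    compare_reference_screws(ctx, opt$knee)
  } else {
    score_reference_screws(ctx)
  }

  paths <- list(
    bending_model = file.path(out_dir, "surrogate_bending.json"),
    pullout_model = file.path(out_dir, "surrogate_pullout.json"),
    mae = file.path(out_dir, "surrogate_mae.csv"),
    front = file.path(out_dir, "pareto_front.csv"),
    knee = file.path(out_dir, "knee_summary.json"),
    references = file.path(out_dir, "reference_screws.csv"),
    config = file.path(out_dir, "config.json")
  )
  write_surrogate(surr$bending, paths$bending_model)
  write_surrogate(surr$pullout, paths$pullout_model)
  utils::write.csv(surr$mae, paths$mae, row.names = FALSE)
  front <- opt$front
  front$in_knee <- abs(front$f_bending - front$f_pullout) < knee_threshold
  utils::write.csv(front, paths$front, row.names = FALSE)
  jsonlite::write_json(c(opt$knee_summary,
                         list(dominance_fraction = opt$validation$fraction)),
                       paths$knee, auto_unbox = TRUE, digits = NA)
  utils::write.csv(refs, paths$references, row.names = FALSE)
  jsonlite::write_json(list(seed = seed, weights = weights,
                            n_restarts = n_restarts,
                            knee_threshold = knee_threshold,
                            n_validate = n_validate),
                       paths$config, auto_unbox = TRUE, digits = NA)
  invisible(list(surrogates = surr, ctx = ctx, opt = opt,
                 references = refs, paths = paths))
}

#' Plot a Pareto front with knee and reference screws
#'
#' @param front Front data frame (`f_bending`, `f_pullout`).
#' @param knee Optional knee subset, drawn emphasized.
#' @param references Optional scored reference screws (`name`, objectives).
#' @param cloud Optional random-design sample (e.g.
#'   `dominance_validation(...)$sample`) drawn as background.
#' @return A `ggplot` object (requires the `ggplot2` package).
#' @export
plot_pareto_front <- function(front, knee = NULL, references = NULL,
                              cloud = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pareto_front requires the 'ggplot2' package")
  }
  gg <- ggplot2::ggplot()
  if (!is.null(cloud)) {
    gg <- gg + ggplot2::geom_point(
      data = cloud, ggplot2::aes(.data$f_bending, .data$f_pullout),
      colour = "grey80", size = 0.3)
  }
  gg <- gg + ggplot2::geom_point(
    data = front, ggplot2::aes(.data$f_bending, .data$f_pullout),
    colour = "steelblue", size = 1)
  if (!is.null(knee) && nrow(knee) > 0) {
    gg <- gg + ggplot2::geom_point(
      data = knee, ggplot2::aes(.data$f_bending, .data$f_pullout),
      colour = "red", size = 2)
  }
  if (!is.null(references)) {
    gg <- gg + ggplot2::geom_point(
      data = references, ggplot2::aes(.data$f_bending, .data$f_pullout),
      shape = 4, size = 3) +
      ggplot2::geom_text(
        data = references,
        ggplot2::aes(.data$f_bending, .data$f_pullout, label = .data$name),
        hjust = -0.1, vjust = -0.4, size = 3)
  }
  gg + ggplot2::labs(x = "normalized bending objective",
                     y = "normalized pullout objective")
}
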
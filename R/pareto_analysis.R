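# Weight sweep, nondominated filtering, knee extraction, and dominance
# validation of the bending/pullout trade-off front.

#' Sweep the aggregation weight and collect candidate Pareto points
#'
#' Runs one seeded GA per weight. Besides each run's final best design, the
#' returned archive also contains every per-generation elite, which densifies
#' the front at no extra cost: those elites were already evaluated.
#'
#' @param ctx A [fitness_context()].
#' @param ga_cfg A [ga_config()]; its `weight` is overridden, and run `i`
#'   uses seed `ga_cfg$seed + i` for reproducibility.
#' @param weights Ordered vector of weights in `[0, 1]`; default a 0.01-step
#'   grid, fine enough to resolve the knee interval at its reported
#'   precision.
#' @param archive Include per-generation elites (default `TRUE`) or only the
#'   per-weight final solutions.
#' @return A data frame of candidate points: `weight`, the six structural
#'   variables, `f_bending`, `f_pullout`, logical `final`, and `generations`
#'   (the producing run's length; `NA` for archived elites). Failed GA runs
#'   are skipped with a warning.
#' @export
weight_sweep <- function(ctx, ga_cfg = ga_config(),
                         weights = seq(0, 1, by = 0.01), archive = TRUE) {
  stopifnot(all(weights >= 0 & weights <= 1))
  out <- vector("list", length(weights))
  for (i in seq_along(weights)) {
    cfg <- ga_cfg
    cfg$weight <- weights[i]
    cfg$seed <- ga_cfg$seed + i
    res <- tryCatch(run_ga(ctx, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      warning("GA failed at weight ", weights[i], ": ", conditionMessage(res))
      next
    }
    pts <- if (archive) {
      unique(res$trace[, c(SCREW_VARS, "f_bending", "f_pullout")])
    } else {
      NULL
    }
    final <- data.frame(t(res$best_design),
                        f_bending = unname(res$best_objectives["f_bending"]),
                        f_pullout = unname(res$best_objectives["f_pullout"]))
    if (!is.null(pts)) {
      is_final <- pts$f_bending == final$f_bending &
        pts$f_pullout == final$f_pullout & pts$bp == final$bp
      pts <- pts[!is_final, , drop = FALSE]
    }
    block <- rbind(cbind(final, final = TRUE, generations = res$generations),
                   if (!is.null(pts) && nrow(pts) > 0)
                     cbind(pts, final = FALSE, generations = NA_integer_))
    block <- cbind(weight = weights[i], block)
    out[[i]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter a point set down to its nondominated (Pareto) subset
#'
#' A point is dominated if some other point is at least as good in both
#' objectives and strictly better in one; exact ties are both retained.
#' Output is ordered by `f_bending` descending (so `f_pullout` is
#' non-decreasing along the front).
#'
#' @param points Data frame with columns `f_bending` and `f_pullout` (other
#'   columns are carried through).
#' @return The nondominated subset of `points`.
#' @export
nondominated_filter <- function(points) {
  if (nrow(points) == 0L) return(points)
  ord <- order(-points$f_bending, -points$f_pullout)
  pts <- points[ord, , drop = FALSE]
  keep <- logical(nrow(pts))
  best_fp <- -Inf
  last_fb <- NA_real_
  last_fp <- NA_real_
  for (i in seq_len(nrow(pts))) {
    fb <- pts$f_bending[i]
    fp <- pts$f_pullout[i]
    if (fp > best_fp) {
      keep[i] <- TRUE
      best_fp <- fp
      last_fb <- fb
      last_fp <- fp
    } else if (identical(fb, last_fb) && identical(fp, last_fp)) {
      keep[i] <- TRUE  # exact duplicate of a kept point
    }
  }
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the knee region of a Pareto front
#'
#' The knee is the balanced part of the front where the two normalized
#' objectives differ by less than the threshold (default 2% absolute on the
#' `[0, 1]` objective scale).
#'
#' @param front A nondominated point set from [nondominated_filter()].
#' @param threshold Knee criterion on `|f_bending - f_pullout|`.
#' @return The knee subset; warns when empty.
#' @export
knee_region <- function(front, threshold = 0.02) {
  knee <- front[abs(front$f_bending - front$f_pullout) < threshold, ,
                drop = FALSE]
  if (nrow(knee) == 0L) warning("knee region is empty at threshold ", threshold)
  knee
}

#' Summarize the knee region variable ranges
#'
#' @param knee A knee point set from [knee_region()].
#' @return List with the weight interval and per-variable `[min, max]`
#'   intervals over the knee solutions.
#' @export
knee_summary <- function(knee) {
  stopifnot(nrow(knee) >= 1L)
  c(list(n = nrow(knee), weight = range(knee$weight)),
    lapply(as.data.frame(knee)[SCREW_VARS], range))
}

#' Validate a Pareto front against random designs
#'
#' Samples designs uniformly in the box, scores them under the shared
#' normalization, and reports the fraction weakly dominated by (or equal to)
#' some front member.
#'
#' @param front Nondominated point set.
#' @param ctx The [fitness_context()] the front was computed under.
#' @param n_random Number of random designs.
#' @param seed RNG seed for the sample.
#' @return List with `fraction` dominated and the scored sample
#'   (`sample`: designs plus objective values).
#' @export
dominance_validation <- function(front, ctx, n_random = 10000L, seed = 1L) {
  stopifnot(n_random >= 1L)
  set.seed(seed)
  sp <- ctx$space
  xs <- sapply(SCREW_VARS, function(v) {
    stats::runif(n_random, sp$lower[[v]], sp$upper[[v]])
  })
  f <- objective_values(ctx, xs)
  if (nrow(front) == 0L) {
    return(list(fraction = 0, sample = data.frame(xs, f)))
  }
  # sort front by f_bending descending; cummax of f_pullout gives, for any
  # bending level, the best pullout achievable by a front member at least
  # that good in bending
  fb <- sort(front$f_bending, decreasing = TRUE)
  fp_cm <- cummax(front$f_pullout[order(-front$f_bending)])
  # number of front members with f_bending >= candidate value
  idx <- length(fb) - findInterval(f[, "f_bending"], rev(fb), left.open = TRUE)
  dominated <- idx >= 1L & f[, "f_pullout"] <= fp_cm[pmax(idx, 1L)]
  list(fraction = mean(dominated), sample = data.frame(xs, f))
}

#' Score reference screws against the front's objective scale
#'
#' Projects measured reference screws (see [load_table2()]) onto the
#' normalized objective plane of a fitness context. By default their
#' recorded finite-element responses are normalized directly
#' (`source = "fe"`); `source = "surrogate"` instead predicts responses from
#' the trained surrogates, extrapolating outside the design box where
#' necessary. Cylindrical cores are scored with `bp` at its upper bound.
#' Out-of-box geometries are flagged `extrapolated` in either mode: the
#' design box does not cover them, so their scores are projections, not
#' interpolations.
#'
#' @param ctx A [fitness_context()].
#' @param screws Data frame from [load_table2()].
#' @param source `"fe"` (recorded responses) or `"surrogate"` (predicted).
#' @return Data frame: `name`, `f_bending`, `f_pullout`, `extrapolated`.
#' @export
score_reference_screws <- function(ctx, screws = load_table2(),
                                   source = c("fe", "surrogate")) {
  source <- match.arg(source)
  x <- as_design_matrix(screws[, SCREW_VARS])
  x[is.na(x[, "bp"]), "bp"] <- ctx$space$upper[["bp"]]
  clip01 <- function(z) pmin(pmax(z, 0), 1)
  if (source == "fe") {
    mts <- screws$mts_fe
    trf <- screws$trf_fe
  } else {
    mts <- ctx$predict_bending(x)
    trf <- ctx$predict_pullout(x)
  }
  data.frame(
    name = screws$name,
    f_bending = clip01((ctx$mts_range[2] - mts) / diff(ctx$mts_range)),
    f_pullout = clip01((trf - ctx$trf_range[1]) / diff(ctx$trf_range)),
    extrapolated = !screws$in_box | screws$cylindrical,
    stringsAsFactors = FALSE
  )
}
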
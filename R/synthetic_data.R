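# Closed-form pseudo finite-element generator. Stands in for the 3-D FE
# analyses so that surrogate training, GA search, and knee extraction can be
# tested end-to-end against known ground truth, with no FE solver. It makes
# no claim of mechanical fidelity.

# Default coefficients: least-squares fits of each parametric form to the 25
# orthogonal-array design/response pairs, frozen as constants (the bending
# fit is sign-constrained so the stated monotonicities hold over the whole
# box; see inst/scripts/fit_pseudo_fe.R for the derivation).
PSEUDO_BENDING_COEF <- c(
  intercept = 570.5583652, bp = 33.06459767, id = -0.5, prr = -105.9777431,
  prr2 = 52.73887157, p = -45.45266647, pha = 0.4531432885,
  tw = -87.36066532, bp_id = -5.386600244
)
PSEUDO_PULLOUT_COEF <- c(
  intercept = 26.55494519, bp = 0.01810418462, id = 0.2386662273,
  prr = -5.342121457, p = 15.09137541, p2 = -2.032653061,
  pha = -0.08114180838, tw = -4.874364372, id_p = -0.9091959354
)

#' Parameters of the pseudo finite-element response surfaces
#'
#' Each response is a sum of per-variable affine terms, one quadratic term
#' (root radius for bending, pitch for pullout) and one pairwise interaction
#' (taper-start x core diameter for bending, core diameter x pitch for
#' pullout): the simplest family that is non-linear enough to require the
#' surrogate's hidden layer yet admits closed-form optima for recovery
#' tests. Default coefficients reproduce the qualitative structure of the
#' recorded FE responses (bending stress grows with `bp` and falls with `id`
#' and `prr`; pullout force falls with `id` and `pha`).
#'
#' @param noise_sd Relative (multiplicative Gaussian) noise level; 0 makes
#'   the generator deterministic.
#' @param seed Integer seed used by [generate_dataset()].
#' @param bending,pullout Named coefficient vectors; override to reshape the
#'   surfaces.
#' @return A list of class `pseudo_fe_params`.
#' @export
pseudo_fe_params <- function(noise_sd = 0, seed = 1L,
                             bending = PSEUDO_BENDING_COEF,
                             pullout = PSEUDO_PULLOUT_COEF) {
  stopifnot(noise_sd >= 0)
  structure(list(noise_sd = noise_sd, seed = as.integer(seed),
                 bending = bending, pullout = pullout),
            class = "pseudo_fe_params")
}

#' Pseudo-FE bending response (maximum tensile stress, MPa)
#'
#' Deterministic closed-form surface; callers add noise via
#' [generate_dataset()].
#'
#' @param d A design or n x 6 design matrix.
#' @param params A [pseudo_fe_params()].
#' @return Numeric vector of stresses (MPa), strictly positive over the box.
#' @export
pseudo_bending <- function(d, params = pseudo_fe_params()) {
  x <- as_design_matrix(d)
  co <- params$bending
  unname(drop(co["intercept"] + co["bp"] * x[, "bp"] + co["id"] * x[, "id"] +
         co["prr"] * x[, "prr"] + co["prr2"] * x[, "prr"]^2 +
         co["p"] * x[, "p"] + co["pha"] * x[, "pha"] + co["tw"] * x[, "tw"] +
         co["bp_id"] * x[, "bp"] * x[, "id"]))
}

#' Pseudo-FE pullout response (total reaction force, N)
#'
#' @inheritParams pseudo_bending
#' @return Numeric vector of forces (N), strictly positive over the box.
#' @export
pseudo_pullout <- function(d, params = pseudo_fe_params()) {
  x <- as_design_matrix(d)
  co <- params$pullout
  unname(drop(co["intercept"] + co["bp"] * x[, "bp"] + co["id"] * x[, "id"] +
         co["prr"] * x[, "prr"] + co["p"] * x[, "p"] + co["p2"] * x[, "p"]^2 +
         co["pha"] * x[, "pha"] + co["tw"] * x[, "tw"] +
         co["id_p"] * x[, "id"] * x[, "p"]))
}

#' Closed-form optimum of a pseudo-FE surface over the design box
#'
#' Because each surface is affine in every variable except one quadratic
#' term and one bilinear interaction, its box optimum lies on a finite
#' candidate set: every variable at a bound, except the quadratic variable
#' which may also sit at its (possibly interaction-shifted) stationary
#' point. This routine enumerates that candidate set exactly; it is the
#' ground truth for optimizer recovery tests.
#'
#' @param params A [pseudo_fe_params()].
#' @param response `"bending"` or `"pullout"`.
#' @param sense `"min"` or `"max"`.
#' @param space A [design_space()].
#' @return List with `design` (named vector) and `value`.
#' @export
pseudo_optimum <- function(params, response = c("bending", "pullout"),
                           sense = c("min", "max"), space = design_space()) {
  response <- match.arg(response)
  sense <- match.arg(sense)
  lo <- space$lower
  hi <- space$upper
  cand <- lapply(SCREW_VARS, function(v) c(lo[[v]], hi[[v]]))
  names(cand) <- SCREW_VARS
  if (response == "bending") {
    co <- params$bending
    vtx <- -co[["prr"]] / (2 * co[["prr2"]])
    if (is.finite(vtx) && vtx > lo[["prr"]] && vtx < hi[["prr"]]) {
      cand$prr <- c(cand$prr, vtx)
    }
    f <- function(x) pseudo_bending(x, params)
  } else {
    co <- params$pullout
    for (idv in c(lo[["id"]], hi[["id"]])) {
      vtx <- -(co[["p"]] + co[["id_p"]] * idv) / (2 * co[["p2"]])
      if (is.finite(vtx) && vtx > lo[["p"]] && vtx < hi[["p"]]) {
        cand$p <- c(cand$p, vtx)
      }
    }
    f <- function(x) pseudo_pullout(x, params)
  }
  grid <- as.matrix(expand.grid(cand))
  vals <- f(grid)
  i <- if (sense == "min") which.min(vals) else which.max(vals)
  list(design = grid[i, ], value = vals[i])
}

#' Generate a labeled synthetic design/response dataset
#'
#' Emits the same layout as the packaged design/response table, so generated
#' datasets are drop-in replacements for it: the 25 orthogonal-array designs
#' first (when `n >= 25`), then designs sampled uniformly in the box, each
#' labeled with both pseudo-FE responses plus multiplicative Gaussian noise
#' of relative standard deviation `params$noise_sd`.
#'
#' @param n Number of designs.
#' @param params A [pseudo_fe_params()]; its `seed` drives both the random
#'   designs and the noise.
#' @param split_rule `"array_first"` marks the array rows as the learning
#'   set and the random rows as the testing set; `"all_learning"` marks
#'   every row learning.
#' @param space A [design_space()].
#' @return Data frame with columns `no`, the six structural variables,
#'   `mts_fe`, `trf_fe`, `split`.
#' @export
generate_dataset <- function(n, params = pseudo_fe_params(),
                             split_rule = c("array_first", "all_learning"),
                             space = design_space()) {
  stopifnot(n >= 1L)
  split_rule <- match.arg(split_rule)
  set.seed(params$seed)
  arr <- l25_array(space)
  n_arr <- min(n, nrow(arr))
  x <- arr[seq_len(n_arr), , drop = FALSE]
  if (n > n_arr) {
    xr <- sapply(SCREW_VARS, function(v) {
      stats::runif(n - n_arr, space$lower[[v]], space$upper[[v]])
    })
    x <- rbind(x, matrix(xr, ncol = 6L, dimnames = list(NULL, SCREW_VARS)))
  }
  noisy <- function(y) {
    if (params$noise_sd == 0) y
    else y * (1 + stats::rnorm(length(y), 0, params$noise_sd))
  }
  split <- if (split_rule == "array_first") {
    ifelse(seq_len(n) <= n_arr, "learning", "testing")
  } else {
    rep("learning", n)
  }
  data.frame(no = seq_len(n), x,
             mts_fe = noisy(pseudo_bending(x, params)),
             trf_fe = noisy(pseudo_pullout(x, params)),
             split = factor(split, levels = c("learning", "testing")))
}
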
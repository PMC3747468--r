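#' @useDynLib screwopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Six structural variables of a pedicle screw, in canonical order:
# bp  beginning position of the conical angle [mm]
# id  inner (core) diameter at the screw tip  [mm]
# prr proximal root radius                    [mm]
# p   thread pitch                            [mm]
# pha proximal half angle                     [deg]
# tw  thread width                            [mm]
SCREW_VARS <- c("bp", "id", "prr", "p", "pha", "tw")

# Outer diameter is fixed for the whole design family, never a variable.
OUTER_DIAMETER_MM <- 7

#' Screw design space
#'
#' The box of admissible values for the six structural variables of a conical
#' pedicle screw with a fixed 7 mm outer diameter, together with the number of
#' levels used by the orthogonal-array experiment design (five per variable).
#'
#' @param n_levels Number of equally spaced levels per variable used when
#'   constructing the orthogonal-array design. Default 5.
#' @return An object of class `design_space`: a list with numeric vectors
#'   `lower` and `upper` (named by variable) and the integer `n_levels`.
#' @examples
#' sp <- design_space()
#' sp$lower
#' @export
design_space <- function(n_levels = 5L) {
  structure(
    list(
      lower = c(bp = 0, id = 3.8, prr = 0.4, p = 2.6, pha = 5, tw = 0.1),
      upper = c(bp = 36, id = 5.5, prr = 1.0, p = 4.0, pha = 20, tw = 0.3),
      n_levels = as.integer(n_levels)
    ),
    class = "design_space"
  )
}

#' Construct a screw design
#'
#' @param bp,id,prr,p,pha,tw The six structural variables (mm, except `pha`
#'   in degrees). See [design_space()] for admissible ranges.
#' @return A named numeric vector of length 6 in canonical variable order.
#' @examples
#' screw_design(bp = 0, id = 3.8, prr = 0.4, p = 3.3, pha = 5, tw = 0.1)
#' @export
screw_design <- function(bp, id, prr, p, pha, tw) {
  d <- c(bp = bp, id = id, prr = prr, p = p, pha = pha, tw = tw)
  stopifnot(is.numeric(d), length(d) == 6L, all(is.finite(d)))
  d
}

# Coerce a design (named vector or data.frame/matrix of designs) to an
# n x 6 matrix with canonical column order.
as_design_matrix <- function(d) {
  if (is.null(dim(d))) {
    d <- matrix(d, nrow = 1, dimnames = list(NULL, names(d)))
  }
  d <- as.matrix(d)
  if (!all(SCREW_VARS %in% colnames(d))) {
    if (ncol(d) == 6L) {
      colnames(d) <- SCREW_VARS
    } else {
      stop("design must have the six columns ", paste(SCREW_VARS, collapse = ", "))
    }
  }
  storage.mode(d) <- "double"
  d[, SCREW_VARS, drop = FALSE]
}

#' Normalize designs to the [-1, 1] cube
#'
#' Maps each structural variable linearly so that its lower bound becomes -1
#' and its upper bound +1, the input scaling used by the neural surrogates.
#'
#' @param d A single design (named vector) or an n x 6 matrix/data frame of
#'   designs.
#' @param space A [design_space()].
#' @param check Check that all values are within the box (default `TRUE`).
#'   Scoring of out-of-box reference screws disables the check and flags the
#'   result as extrapolated instead.
#' @return A matrix of the same shape with values in `[-1, 1]`
#'   (or beyond, when `check = FALSE`).
#' @export
normalize_inputs <- function(d, space = design_space(), check = TRUE) {
  x <- as_design_matrix(d)
  if (check) {
    for (v in SCREW_VARS) {
      bad <- x[, v] < space$lower[[v]] - 1e-9 | x[, v] > space$upper[[v]] + 1e-9
      if (any(bad)) {
        stop(sprintf("variable '%s' out of bounds [%g, %g]: %g",
                     v, space$lower[[v]], space$upper[[v]], x[which(bad)[1], v]))
      }
    }
  }
  ctr <- (space$upper + space$lower) / 2
  hw <- (space$upper - space$lower) / 2
  sweep(sweep(x, 2, ctr[SCREW_VARS]), 2, hw[SCREW_VARS], "/")
}

#' Invert [normalize_inputs()]
#'
#' @param xn Matrix (or named vector) of normalized coordinates in `[-1, 1]`.
#' @inheritParams normalize_inputs
#' @return Matrix of designs in physical units.
#' @export
denormalize_inputs <- function(xn, space = design_space()) {
  x <- as_design_matrix(xn)
  ctr <- (space$upper + space$lower) / 2
  hw <- (space$upper - space$lower) / 2
  sweep(sweep(x, 2, hw[SCREW_VARS], "*"), 2, ctr[SCREW_VARS], "+")
}

#' Five-level grids of the orthogonal-array experiment design
#'
#' Each structural variable is divided into five equally spaced levels
#' spanning its bounds; the 25-run orthogonal array combines these levels so
#' that every pair of levels of any two variables occurs equally often.
#' Levels are rounded to two decimals, the precision at which the design
#' table is recorded, so array rows round-trip exactly.
#'
#' @param space A [design_space()].
#' @return A named list with one numeric vector of `space$n_levels` values per
#'   variable.
#' @examples
#' build_l25_levels()$id  # 3.80 4.23 4.65 5.08 5.50
#' @export
build_l25_levels <- function(space = design_space()) {
  # half-up rounding (4.225 -> 4.23), matching how the design table was
  # recorded; base round() rounds half to even and would give 4.22. The
  # epsilon absorbs representation error in the level spacing (1.7/4 is not
  # exactly representable), which would otherwise drop 4.225 just below the
  # rounding boundary.
  half_up <- function(x, digits = 2) {
    floor(x * 10^digits + 0.5 + sqrt(.Machine$double.eps)) / 10^digits
  }
  out <- lapply(SCREW_VARS, function(v) {
    half_up(seq(space$lower[[v]], space$upper[[v]], length.out = space$n_levels))
  })
  names(out) <- SCREW_VARS
  out
}

#' The 25-run orthogonal array of screw designs
#'
#' The balanced five-level fractional factorial used as the learning set:
#' writing the run index as `(i, j)` with `i, j` in `0..4`, the six
#' variables take level indices `(i, j, (i+j) mod 5, (2i+j) mod 5,
#' (3i+j) mod 5, (4i+j) mod 5)`, which reproduces the recorded array
#' row-for-row.
#'
#' @param space A [design_space()].
#' @return A 25 x 6 design matrix in physical units (levels at the
#'   2-decimal precision of [build_l25_levels()]).
#' @export
l25_array <- function(space = design_space()) {
  lv <- build_l25_levels(space)
  ij <- expand.grid(j = 0:4, i = 0:4)
  idx <- cbind(ij$i, ij$j, (ij$i + ij$j) %% 5, (2 * ij$i + ij$j) %% 5,
               (3 * ij$i + ij$j) %% 5, (4 * ij$i + ij$j) %% 5)
  out <- sapply(seq_len(6L), function(k) lv[[k]][idx[, k] + 1L])
  colnames(out) <- SCREW_VARS
  out
}

#' Default geometric feasibility rules
#'
#' Feasibility beyond the box bounds: the thread depth implied by the fixed
#' 7 mm outer diameter must be positive, and the root radius must fit within
#' one pitch after subtracting the thread flats. The rule set is an ordinary
#' named list of predicate functions taking a design matrix, so stricter
#' manufacturing rules can be appended by the user.
#'
#' @return Named list of functions; each takes an n x 6 design matrix and
#'   returns a logical vector (`TRUE` = feasible).
#' @export
default_constraint_rules <- function() {
  list(
    thread_depth_positive = function(x) {
      (OUTER_DIAMETER_MM - x[, "id"]) / 2 > x[, "tw"]
    },
    root_radius_fits_pitch = function(x) {
      2 * x[, "prr"] < x[, "p"] - 2 * x[, "tw"]
    }
  )
}

#' Check geometric feasibility of screw designs
#'
#' Applies the box bounds and the geometric rule set. Never throws for an
#' infeasible design; it reports the first failed rule instead.
#'
#' @param d A design or matrix of designs.
#' @param space A [design_space()].
#' @param rules Rule set, by default [default_constraint_rules()].
#' @return A data frame with logical column `pass` and character column
#'   `reason` (`""` when feasible), one row per design.
#' @export
check_constraints <- function(d, space = design_space(),
                              rules = default_constraint_rules()) {
  x <- as_design_matrix(d)
  n <- nrow(x)
  pass <- rep(TRUE, n)
  reason <- rep("", n)
  for (v in SCREW_VARS) {
    bad <- pass & (x[, v] < space$lower[[v]] - 1e-9 | x[, v] > space$upper[[v]] + 1e-9)
    reason[bad] <- paste0(v, " outside [", space$lower[[v]], ", ", space$upper[[v]], "]")
    pass <- pass & !bad
  }
  for (rn in names(rules)) {
    ok <- rules[[rn]](x)
    bad <- pass & !ok
    reason[bad] <- rn
    pass <- pass & !bad
  }
  data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Load the finite-element design/response table
#'
#' The packaged dataset of 35 screw designs — 25 orthogonal-array learning
#' designs plus 10 randomly placed testing designs — with their
#' finite-element responses: maximum tensile stress under cantilever bending
#' (`mts_fe`, MPa) and total axial reaction force in osteoporotic-bone pullout
#' (`trf_fe`, N). Columns `mts_ann` and `trf_ann` carry the originally
#' reported surrogate predictions, kept for cross-checking error metrics
#' without retraining.
#'
#' @param path Path to the CSV fixture; defaults to the copy installed with
#'   the package.
#' @return A data frame with 35 rows and columns `no`, the six structural
#'   variables, `mts_fe`, `mts_ann`, `trf_fe`, `trf_ann`, and a factor
#'   `split` (`learning` rows 1-25, `testing` rows 26-35).
#' @export
load_table1 <- function(path = system.file("extdata", "table1.csv",
                                           package = "screwopt")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("design/response fixture not found: ", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("no", SCREW_VARS, "mts_fe", "mts_ann", "trf_fe", "trf_ann")
  if (!identical(names(tab), need) || nrow(tab) != 35L ||
      !all(vapply(tab, is.numeric, logical(1)))) {
    stop("corrupt design/response fixture: ", path)
  }
  tab$split <- factor(ifelse(tab$no <= 25, "learning", "testing"),
                      levels = c("learning", "testing"))
  tab
}

#' Load the reference screw table
#'
#' Measured geometries and finite-element responses of four commercial
#' pedicle screws plus the knee-region optimal design, for plotting against
#' the Pareto front. The Viper screw has a cylindrical core, which the
#' conical parameterization cannot express; its `bp` is recorded as `NA` and
#' flagged `cylindrical`. Several commercial geometries fall outside the
#' design box (flagged by `in_box`).
#'
#' @param path Path to the CSV fixture; defaults to the installed copy.
#' @return Data frame with columns `name`, the six structural variables,
#'   `mts_fe`, `trf_fe`, and logical flags `cylindrical` and `in_box`.
#' @export
load_table2 <- function(path = system.file("extdata", "table2.csv",
                                           package = "screwopt")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("reference screw fixture not found: ", path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$cylindrical <- tab$bp == "cylindrical"
  tab$bp <- suppressWarnings(as.numeric(tab$bp))
  sp <- design_space()
  x <- as_design_matrix(tab[, SCREW_VARS])
  x[is.na(x[, "bp"]), "bp"] <- sp$upper[["bp"]]
  tab$in_box <- apply(x, 1L, function(r) {
    all(r >= sp$lower - 1e-9 & r <= sp$upper + 1e-9)
  })
  tab
}
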
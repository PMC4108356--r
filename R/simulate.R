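#' Configuration for the landscape fire-history simulator
#'
#' Describes a synthetic landscape for [simulate_history()]: grid dimensions
#' and cell size, a land-cover layout with per-class discrete lognormal
#' interval parameters, the number of record years to emit, and the burn-in
#' used to wash out initialization transients. Classes are laid out as
#' contiguous column strips proportional to `fraction` unless an explicit
#' `class_map` matrix is given.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param classes data frame with columns `class`, `meanlog`, `sdlog` and
#'   either `fraction` (summing to 1) or nothing if `class_map` is supplied.
#' @param years number of record years to emit (N >= 2).
#' @param start_year calendar year of the first emitted burn mask.
#' @param burn_in years simulated and discarded before the record window.
#' @param cell_size cell edge length in meters.
#' @param t_max hazard lookup horizon; cells older than `t_max` burn with the
#'   hazard at `t_max` (a warning is recorded when this happens).
#' @param class_map optional explicit matrix of class labels
#'   (dim `c(nrow, ncol)`), overriding the strip layout.
#' @param coherence_radius optional radius (in cells) of a majority filter
#'   applied to each year's provisional burn decisions, giving spatially
#'   contiguous burn scars; 0 (default) keeps cells independent. The filter
#'   only approximately preserves per-point marginal behaviour.
#' @param hazard_override optional constant hazard replacing the model hazard
#'   for every class (e.g. 0 for a no-fire control run).
#' @param seed RNG seed recorded in the output metadata.
#' @return A list of class `"fire_sim_config"`.
#' @export
fire_sim_config <- function(nrow, ncol, classes, years = 12L,
                            start_year = 1997L, burn_in = 50L,
                            cell_size = 500, t_max = 100L,
                            class_map = NULL, coherence_radius = 0L,
                            hazard_override = NULL, seed = 1L) {
  stopifnot(nrow >= 1, ncol >= 1, years >= 2, burn_in >= 0, cell_size > 0,
            t_max >= 1)
  if (!is.data.frame(classes) ||
      !all(c("class", "meanlog", "sdlog") %in% names(classes)))
    stop("'classes' must have columns class, meanlog, sdlog")
  if (is.null(class_map)) {
    if (!"fraction" %in% names(classes))
      stop("'classes' needs a 'fraction' column when no class_map is given")
    if (abs(sum(classes$fraction) - 1) > 1e-8)
      stop("class fractions must sum to 1")
  } else {
    stopifnot(is.matrix(class_map),
              identical(dim(class_map), as.integer(c(nrow, ncol))))
    if (!all(unique(as.vector(class_map)) %in% classes$class))
      stop("class_map contains labels missing from 'classes'")
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 classes = classes, years = as.integer(years),
                 start_year = as.integer(start_year),
                 burn_in = as.integer(burn_in), cell_size = cell_size,
                 t_max = as.integer(t_max), class_map = class_map,
                 coherence_radius = as.integer(coherence_radius),
                 hazard_override = hazard_override,
                 seed = as.integer(seed)),
            class = "fire_sim_config")
}

#' Simulate a landscape fire history as a per-class renewal process
#'
#' Each cell carries a fuel age; every simulated year it burns with
#' probability equal to the hazard of burning of its class at its current
#' age, resetting the age to 0 on burning and incrementing it otherwise
#' (ages beyond the hazard horizon reuse the horizon's hazard). Initial ages
#' are drawn from the equilibrium age distribution of the renewal process
#' (probability proportional to the survival distribution, truncated at
#' `t_max`) and a burn-in period is discarded, so the emitted record window
#' is free of initialization transients. Output is reproducible: identical
#' configurations (including the seed) give identical burn masks.
#'
#' @param config a [fire_sim_config()].
#' @return A [fire_history()] whose attribute `sim_meta` records the seed,
#'   parameters and any hazard-horizon warning.
#' @examples
#' cfg <- fire_sim_config(20, 20, data.frame(class = "SS", meanlog = 0.82,
#'                                           sdlog = 0.66, fraction = 1),
#'                        years = 12, burn_in = 30, seed = 7)
#' grid <- simulate_history(cfg)
#' @export
simulate_history <- function(config) {
  stopifnot(inherits(config, "fire_sim_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  cls <- config$classes

  lc <- config$class_map
  if (is.null(lc)) {
    # contiguous column strips proportional to class fractions
    edges <- round(cumsum(cls$fraction) * nc)
    edges[length(edges)] <- nc
    col_class <- rep(cls$class, times = diff(c(0, edges)))
    lc <- matrix(rep(col_class, each = nr), nr, nc)
  }
  cls_idx <- match(as.vector(lc), cls$class)

  tm <- config$t_max
  H <- vapply(seq_len(nrow(cls)), function(i)
    suppressWarnings(hfireint(seq_len(tm), cls$meanlog[i], cls$sdlog[i])),
    numeric(tm))
  H[!is.finite(H)] <- 1  # beyond numerical support: certain burn
  W <- vapply(seq_len(nrow(cls)), function(i)
    sfireint(0:(tm - 1L), cls$meanlog[i], cls$sdlog[i]), numeric(tm))
  if (!is.null(config$hazard_override)) {
    H[] <- config$hazard_override
    W[] <- 1  # uniform initial ages; irrelevant when hazard is constant
  }

  # equilibrium initial ages: P(age = a) proportional to survival(a)
  age <- integer(ncell)
  for (i in seq_len(nrow(cls))) {
    cells <- which(cls_idx == i)
    if (length(cells))
      age[cells] <- sample.int(tm, length(cells), replace = TRUE,
                               prob = W[, i]) - 1L
  }

  total_years <- config$burn_in + config$years
  burns <- array(FALSE, dim = c(nr, nc, config$years))
  horizon_hit <- FALSE
  for (y in seq_len(total_years)) {
    look <- pmin(age + 1L, tm)
    if (any(age + 1L > tm)) horizon_hit <- TRUE
    p <- H[cbind(look, cls_idx)]
    burn <- runif(ncell) < p
    if (config$coherence_radius > 0L)
      burn <- .majority_filter(matrix(burn, nr, nc),
                               config$coherence_radius)
    age <- ifelse(burn, 0L, age + 1L)
    if (y > config$burn_in)
      burns[, , y - config$burn_in] <- matrix(burn, nr, nc)
  }
  if (horizon_hit && is.null(config$hazard_override))
    warning("some cells exceeded the hazard horizon t_max = ", tm,
            "; the hazard at t_max was reused")

  out <- fire_history(burns, lc,
                      years = seq(config$start_year,
                                  length.out = config$years),
                      cell_size = config$cell_size)
  attr(out, "sim_meta") <- list(seed = config$seed, classes = cls,
                                burn_in = config$burn_in, t_max = tm,
                                horizon_exceeded = horizon_hit)
  out
}

# majority vote of provisional burn decisions in a (2r+1)^2 window,
# computed with shifted partial sums; edges use the available window
.majority_filter <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0L, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (dr in -r:r) {
    rs <- intersect(seq_len(nr), seq_len(nr) - dr)
    for (dc in -r:r) {
      cs <- intersect(seq_len(nc), seq_len(nc) - dc)
      acc[rs, cs] <- acc[rs, cs] + m[rs + dr, cs + dc]
      cnt[rs, cs] <- cnt[rs, cs] + 1L
    }
  }
  acc > cnt / 2
}

#' Simulate censored interval samples from record-window point histories
#'
#' Simulates `n_points` independent point fire histories over a record
#' window of `years` years under the discrete lognormal renewal model, with
#' initial fuel ages drawn from the equilibrium age distribution, and
#' converts each history into interval observations by the rule of
#' [point_intervals()]. This reproduces, point by point, the statistical
#' structure of a sample produced by [extract_intervals()] on a simulated
#' landscape, and is the workhorse of calibration studies and of the
#' [hp_test()] bootstrap.
#'
#' @param n_points number of independent points.
#' @param years record-window length N in years.
#' @inheritParams dfireint
#' @return A data frame with columns `point_id`, `length`, `status` and
#'   attribute `record_years = years`.
#' @examples
#' set.seed(9)
#' x <- simulate_intervals(100, 12, meanlog = 0.82, sdlog = 0.66)
#' table(x$status)
#' @export
simulate_intervals <- function(n_points, years, meanlog, sdlog) {
  .check_params(meanlog, sdlog)
  stopifnot(n_points >= 1, years >= 2)
  N <- as.integer(years)
  h <- .support_horizon(meanlog, sdlog)
  Sv <- sfireint(seq_len(h), meanlog, sdlog)           # A(1..h)
  f <- dfireint(seq_len(h), meanlog, sdlog)
  H <- pmin(f / c(1, Sv[-h]), 1)                        # hazard(1..h)
  H[!is.finite(H)] <- 1
  # equilibrium ages 0..h-1 with probability proportional to A(a)
  age <- sample.int(h, n_points, replace = TRUE, prob = c(1, Sv[-h])) - 1L
  burn <- matrix(FALSE, n_points, N)
  for (y in seq_len(N)) {
    p <- H[pmin(age + 1L, h)]
    b <- runif(n_points) < p
    age <- ifelse(b, 0L, age + 1L)
    burn[, y] <- b
  }
  idx <- which(burn, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  pt <- idx[ord, 1L]; yr <- idx[ord, 2L]
  first <- !duplicated(pt)
  last <- !duplicated(pt, fromLast = TRUE)
  same <- diff(pt) == 0L
  gaps <- diff(yr)[same]
  burned_pts <- pt[first]
  never <- setdiff(seq_len(n_points), burned_pts)
  out <- data.frame(
    point_id = c(burned_pts, pt[c(FALSE, same)], pt[last], never),
    length = c(yr[first], gaps, N - yr[last], rep(N, length(never))),
    status = c(rep("left_censored", length(burned_pts)),
               rep("complete", length(gaps)),
               rep("right_censored", sum(last)),
               rep("right_censored", length(never))),
    stringsAsFactors = FALSE)
  out <- out[order(out$point_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "record_years") <- N
  out
}
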
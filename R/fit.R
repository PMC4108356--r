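#' Censored log-likelihood of an interval sample
#'
#' Sum of per-observation log contributions under the discrete lognormal
#' interval model. A complete interval of length t contributes log f(t); a
#' right-censored open interval of length t (a fire was observed, the next
#' one was not) contributes log A(t) = log P(T > t). Both are exact for
#' record-window data.
#'
#' Left-censored observations — the open period of length l from the record
#' start to the first observed fire — are handled in one of two ways. With
#' `stationary = TRUE` (the default) they are treated as exactly observed
#' forward recurrence times of the equilibrium renewal process, contributing
#' log A(l - 1) - log E\[T\]; a point that never burned is the case "forward
#' recurrence beyond the record" and contributes the stationary tail
#' log P(F > N). This is the correct likelihood when the burn record opens on
#' a landscape whose fire process is in equilibrium: the interval straddling
#' the record start is length-biased, and ignoring that biases the fitted
#' mean interval upward. With `stationary = FALSE`, a left-censored length l
#' contributes the naive lower-bound term log A(l - 1) = log P(T >= l) and
#' never-burned points are plain right-censored terms; this matches common
#' practice in fire-history survival analysis but is mildly biased on window
#' data. Censored observations of length 0 (and left-censored observations
#' of length 1 under the naive convention) contribute exactly 0.
#'
#' @param x an interval sample: a data frame with columns `length` (whole
#'   years) and `status` (one of `"complete"`, `"right_censored"`,
#'   `"left_censored"`), as produced by [extract_intervals()], or a numeric
#'   vector of complete interval lengths.
#' @param stationary use the equilibrium-renewal likelihood for left-censored
#'   and never-burned observations?
#' @param record_years length N of the record window in years, used (when
#'   `stationary = TRUE`) to recognize never-burned points: right-censored
#'   observations of length >= N. Defaults to `attr(x, "record_years")` as
#'   set by [extract_intervals()]; when `NULL`, all right-censored terms use
#'   log A(t).
#' @inheritParams dfireint
#' @return The log-likelihood (a single number).
#' @export
fire_loglik <- function(x, meanlog, sdlog, stationary = TRUE,
                        record_years = attr(x, "record_years")) {
  obs <- .as_intervals(x)
  if (nrow(obs) == 0L) stop("empty interval sample")
  if (!any(.is_informative(obs)))
    stop("no informative observations: all censored lengths are 0 ",
         "(or left-censored lengths are <= 1)")
  .loglik_counts(.count_intervals(obs), meanlog, sdlog,
                 stationary = stationary, record_years = record_years)
}

#' Fit the discrete lognormal fire-interval model by maximum likelihood
#'
#' Estimates (meanlog, sdlog) of the discrete lognormal interval distribution
#' from a censored sample of fire-free intervals, maximizing the likelihood of
#' [fire_loglik()]. Optimization is bounded quasi-Newton (`L-BFGS-B`) on the
#' unconstrained parameterization (meanlog, log sdlog), started from the mean
#' and standard deviation of the log complete intervals (the latter floored at
#' 0.1). Samples whose complete intervals are all identical drive sdlog to its
#' lower bound; such fits are flagged `degenerate` and their derived
#' descriptors should not be trusted.
#'
#' @inheritParams fire_loglik
#' @param t_max horizon (years) for the turning-point search in the derived
#'   descriptors.
#' @param sdlog_min lower bound for sdlog during optimization; estimates at
#'   the bound are flagged degenerate.
#' @param control passed to [stats::optim()].
#' @details The default `stationary = TRUE` uses the equilibrium-renewal
#'   likelihood for left-censored and never-burned observations (see
#'   [fire_loglik()]); on burn records sampled from a landscape in
#'   equilibrium this removes the upward bias that the naive lower-bound
#'   treatment of the record-start interval induces.
#' @return An object of class `"firefit"`: a list with components
#'   `coefficients` (named vector `meanlog`, `sdlog`), `loglik`, `counts`
#'   (complete / right-censored / left-censored observations), `median`,
#'   `mode`, `turning_point`, `converged`, `degenerate`, `vcov` (inverse
#'   observed information, `NA` for degenerate fits), `data` (the aggregated
#'   sample) and `call`. Methods: `print`, `summary`, `coef`, `logLik`,
#'   `vcov`, `predict`, `plot`, `simulate`, `residuals`.
#' @examples
#' set.seed(1)
#' x <- rfireint(500, meanlog = 0.82, sdlog = 0.66)
#' fit <- fire_fit(x)
#' coef(fit)
#' predict(fit, t = 1:5, type = "hazard")
#' @export
fire_fit <- function(x, t_max = 100L, stationary = TRUE,
                     record_years = attr(x, "record_years"),
                     sdlog_min = 1e-3, control = list()) {
  cl <- match.call()
  obs <- .as_intervals(x)
  if (nrow(obs) == 0L) stop("empty interval sample")
  counts <- .count_intervals(obs)
  n_complete <- sum(counts$n[counts$status == "complete"])
  if (n_complete < 2L)
    stop("non-identifiable sample: at least 2 complete intervals are ",
         "required (got ", n_complete, ")")
  if (!any(.is_informative(obs)))
    stop("no informative observations in sample")

  core <- .fit_core(counts, sdlog_min = sdlog_min, control = control,
                    stationary = stationary, record_years = record_years)
  # zero-variance samples (a single repeated complete length and nothing
  # else informative) leave sdlog unidentified below the bin width
  zero_var <- sum(counts$status == "complete") == 1L &&
    all(.is_informative(obs) == (obs$status == "complete"))
  core$degenerate <- core$degenerate || zero_var

  desc <- fire_descriptors(core$meanlog, core$sdlog, t_max = t_max)
  vc <- matrix(NA_real_, 2, 2, dimnames = list(c("meanlog", "sdlog"),
                                               c("meanlog", "sdlog")))
  if (!core$degenerate && core$converged) {
    H <- try(optimHess(c(core$meanlog, core$sdlog), function(p) {
      if (p[2] <= 0) return(1e10)
      -.loglik_counts(counts, p[1], p[2], stationary = stationary,
                      record_years = record_years)
    }), silent = TRUE)
    if (!inherits(H, "try-error")) {
      vci <- try(solve(H), silent = TRUE)
      if (!inherits(vci, "try-error")) vc[] <- vci
    }
  }

  structure(list(
    coefficients = c(meanlog = core$meanlog, sdlog = core$sdlog),
    loglik = core$loglik,
    counts = c(complete = n_complete,
               right_censored = sum(counts$n[counts$status == "right_censored"]),
               left_censored = sum(counts$n[counts$status == "left_censored"])),
    median = desc$median, mode = desc$mode,
    turning_point = desc$turning_point,
    converged = core$converged, degenerate = core$degenerate,
    vcov = vc, t_max = as.integer(t_max), sdlog_min = sdlog_min,
    stationary = stationary,
    record_years = if (is.null(record_years)) NULL else
      as.integer(record_years),
    optim = core$optim, data = counts, call = cl
  ), class = "firefit")
}

# workhorse optimizer on aggregated counts; reused by the gof bootstrap
.fit_core <- function(counts, start = NULL, sdlog_min = 1e-3,
                      control = list(), stationary = TRUE,
                      record_years = NULL) {
  tc <- counts$length[counts$status == "complete"]
  wc <- counts$n[counts$status == "complete"]
  if (is.null(start)) {
    lt <- rep(base::log(tc), wc)
    mu0 <- mean(lt)
    s0 <- max(sd(lt), 0.1)
    if (is.na(s0)) s0 <- 0.1
    start <- c(mu0, s0)
  }
  prep <- .prep_counts(counts, stationary = stationary,
                       record_years = record_years)
  nll <- function(par) {
    ll <- .loglik_prep(prep, par[1], exp(par[2]))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ctrl <- utils::modifyList(list(maxit = 200L), control)
  opt <- optim(c(start[1], base::log(start[2])), nll, method = "L-BFGS-B",
               lower = c(-50, base::log(sdlog_min)),
               upper = c(50, base::log(50)), control = ctrl)
  sdl <- exp(opt$par[2])
  list(meanlog = opt$par[1], sdlog = sdl, loglik = -opt$value,
       converged = opt$convergence == 0L,
       degenerate = sdl <= sdlog_min * (1 + 1e-8),
       optim = opt[c("convergence", "counts", "message")])
}

# fast unchecked primitives for the optimizer's hot path -------------------

# log survival, t >= 0 integer vector
.logS_fast <- function(t, meanlog, sdlog) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- pnorm((base::log(t[pos]) - meanlog) / sdlog,
                    lower.tail = FALSE, log.p = TRUE)
  out
}

# log pmf, t >= 1 integer vector
.logf_fast <- function(t, meanlog, sdlog) {
  zhi <- (base::log(t) - meanlog) / sdlog
  zlo <- ifelse(t > 1, (base::log(pmax(t - 1, 1)) - meanlog) / sdlog, -Inf)
  f <- ifelse(zhi <= 0,
              pnorm(zhi) - pnorm(zlo),
              pnorm(zlo, lower.tail = FALSE) -
                pnorm(zhi, lower.tail = FALSE))
  base::log(pmax(f, 0))
}

# integral of the lognormal survival function over (c, Inf):
# E[(X - c)^+] = exp(ml + sl^2/2) * Phi(sl - d) - c * Phi(-d), d = (ln c-ml)/sl
.lnorm_tail_int <- function(c, meanlog, sdlog) {
  d <- (base::log(c) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * pnorm(sdlog - d) -
    c * pnorm(d, lower.tail = FALSE)
}

.LOGT <- base::log(seq_len(4096))  # cached log fuel ages for hot loops

# mean interval and partial survival sums: exact over 1..K, closed-form
# midpoint-rule tail beyond (keeps each likelihood evaluation bounded)
.mean_interval_parts <- function(meanlog, sdlog, K = 128L) {
  S <- pnorm((.LOGT[seq_len(K)] - meanlog) / sdlog, lower.tail = FALSE)
  cumS <- cumsum(S)
  tail <- if (S[K] > 0) .lnorm_tail_int(K + 0.5, meanlog, sdlog) else 0
  list(mu = 1 + cumS[K] + tail, cumS = cumS, K = K)
}

# split an aggregated count table into plain vectors (with precomputed log
# lengths) once per fit, so each likelihood evaluation stays cheap
.prep_counts <- function(counts, stationary = TRUE, record_years = NULL) {
  st <- counts$status
  len <- counts$length
  n <- counts$n
  cc <- st == "complete"
  lc <- st == "left_censored"
  rc <- st == "right_censored" & len > 0
  never <- if (stationary && !is.null(record_years))
    rc & len >= record_years else rc & FALSE
  tc <- len[cc]
  tl <- pmax(len[lc] - 1L, 0L)
  tl_pos <- tl[tl > 0]
  list(ltc = base::log(tc), wc = n[cc],
       ltc1 = ifelse(tc > 1, base::log(pmax(tc - 1L, 1L)), -Inf),
       ltr = base::log(len[rc & !never]), wr = n[rc & !never],
       ltl = base::log(tl_pos), wl_pos = n[lc][tl > 0],
       n_l0 = sum(n[lc][tl == 0]),
       tn = len[never], wn = n[never],
       stationary = stationary,
       K = min(max(128L, record_years %||% 0L), 4096L),
       left_naive = !stationary)
}

.loglik_prep <- function(p, meanlog, sdlog) {
  ll <- 0
  if (length(p$ltc)) {
    zhi <- (p$ltc - meanlog) / sdlog
    zlo <- (p$ltc1 - meanlog) / sdlog
    up <- zhi > 0
    f <- numeric(length(zhi))
    f[!up] <- pnorm(zhi[!up]) - pnorm(zlo[!up])
    f[up] <- pnorm(zlo[up], lower.tail = FALSE) -
      pnorm(zhi[up], lower.tail = FALSE)
    ll <- ll + sum(p$wc * base::log(pmax(f, 0)))
  }
  if (length(p$ltr))
    ll <- ll + sum(p$wr * pnorm((p$ltr - meanlog) / sdlog,
                                lower.tail = FALSE, log.p = TRUE))
  has_left <- length(p$ltl) || p$n_l0 > 0
  if (p$stationary && (has_left || length(p$tn))) {
    # equilibrium forward-recurrence terms need the mean interval
    mp <- .mean_interval_parts(meanlog, sdlog, K = p$K)
    log_mu <- base::log(mp$mu)
    if (length(p$ltl))
      ll <- ll + sum(p$wl_pos * (pnorm((p$ltl - meanlog) / sdlog,
                                       lower.tail = FALSE, log.p = TRUE) -
                                   log_mu))
    ll <- ll - p$n_l0 * log_mu
    if (length(p$tn)) {
      # P(F > N) = (mu - sum_{d=1}^{N} A(d-1)) / mu
      N <- pmin(p$tn, mp$K)
      tail_mass <- pmax(mp$mu - (1 + ifelse(N > 1, mp$cumS[N - 1L], 0)),
                        1e-300)
      ll <- ll + sum(p$wn * (base::log(tail_mass) - log_mu))
    }
  } else if (p$left_naive && length(p$ltl)) {
    # naive lower-bound terms: log A(l - 1)
    ll <- ll + sum(p$wl_pos * pnorm((p$ltl - meanlog) / sdlog,
                                    lower.tail = FALSE, log.p = TRUE))
  }
  ll
}

# log-likelihood on an aggregated (length, status, n) table
.loglik_counts <- function(counts, meanlog, sdlog, stationary = TRUE,
                           record_years = NULL) {
  .loglik_prep(.prep_counts(counts, stationary = stationary,
                            record_years = record_years), meanlog, sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.valid_status <- c("complete", "right_censored", "left_censored")

.as_intervals <- function(x) {
  if (is.numeric(x)) {
    x <- data.frame(length = x, status = "complete")
  }
  if (!is.data.frame(x) || !all(c("length", "status") %in% names(x)))
    stop("'x' must be a data frame with columns 'length' and 'status', ",
         "or a numeric vector of complete interval lengths")
  status <- as.character(x$status)
  if (!all(status %in% .valid_status))
    stop("'status' values must be one of: ",
         paste(.valid_status, collapse = ", "))
  len <- x$length
  if (any(!is.finite(len)) || any(len != floor(len)) || any(len < 0))
    stop("interval lengths must be non-negative whole years")
  if (any(len[status == "complete"] < 1))
    stop("complete intervals must have length >= 1")
  data.frame(length = as.integer(len), status = status,
             x[setdiff(names(x), c("length", "status"))],
             stringsAsFactors = FALSE)
}

.is_informative <- function(obs) {
  (obs$status == "complete") |
    (obs$status == "right_censored" & obs$length >= 1L) |
    (obs$status == "left_censored" & obs$length >= 2L)
}

.count_intervals <- function(obs) {
  out <- lapply(unique(obs$status), function(s) {
    tb <- table(obs$length[obs$status == s])
    data.frame(length = as.integer(names(tb)), status = s,
               n = as.integer(tb), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
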
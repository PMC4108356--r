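#' Multi-year burned-area record on a common grid
#'
#' Container for a time series of annual burn masks plus a land-cover map
#' sharing one grid geometry. `burns` is a logical array with dimensions
#' (rows, columns, years); `land_cover` a character or factor matrix with the
#' same spatial dimensions; `years` the contiguous calendar years of the
#' record (length >= 2); `cell_size` the grid resolution in meters.
#'
#' @param burns logical array, dim = c(nrow, ncol, n_years).
#' @param land_cover matrix of land-cover labels, dim = c(nrow, ncol).
#' @param years integer vector of contiguous calendar years.
#' @param cell_size cell edge length in meters.
#' @return An object of class `"fire_history"`.
#' @export
fire_history <- function(burns, land_cover, years, cell_size) {
  if (!is.array(burns) || length(dim(burns)) != 3L || !is.logical(burns))
    stop("'burns' must be a logical array with dim (rows, cols, years)")
  if (!is.matrix(land_cover) ||
      !identical(dim(land_cover), dim(burns)[1:2]))
    stop("'land_cover' must be a matrix on the same grid as 'burns'")
  years <- as.integer(years)
  if (length(years) != dim(burns)[3] || length(years) < 2L ||
      !all(diff(years) == 1L))
    stop("'years' must be contiguous and match the third dimension of 'burns'")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("'cell_size' must be a positive number of meters")
  structure(list(burns = burns,
                 land_cover = matrix(as.character(land_cover),
                                     nrow(land_cover), ncol(land_cover)),
                 years = years, cell_size = cell_size),
            class = "fire_history")
}

#' @export
print.fire_history <- function(x, ...) {
  d <- dim(x$burns)
  cat("Fire history grid: ", d[1], " x ", d[2], " cells of ",
      x$cell_size, " m, years ", min(x$years), "-", max(x$years), "\n",
      sep = "")
  cat("Land cover:", paste(names(table(x$land_cover)), collapse = ", "), "\n")
  cat("Fraction of cell-years burned:",
      round(mean(x$burns), 4), "\n")
  invisible(x)
}

#' Censored interval observations from one point's fire years
#'
#' Converts the fire years observed at a single point within a record window
#' into interval observations. With fire years y1 < ... < yk inside the record
#' \[Y0, Y1\]: the k-1 differences of successive fire years are complete
#' intervals; the open period before the first fire is a left-censored
#' observation of length y1 - Y0 + 1 (the true interval is at least that
#' long); the open period after the last fire is a right-censored observation
#' of length Y1 - yk. A point with no fires yields a single right-censored
#' observation of length N, the number of record years. Censored lengths of 0
#' (and left-censored lengths of 1) are retained but carry no likelihood
#' information.
#'
#' @param fire_years integer vector of years in which the point burned (may be
#'   empty).
#' @param years the record years (contiguous).
#' @return A data frame with columns `length` and `status`.
#' @examples
#' point_intervals(c(1998, 2000, 2003), 1997:2008)
#' @export
point_intervals <- function(fire_years, years) {
  years <- as.integer(years)
  y0 <- min(years); y1 <- max(years)
  fy <- sort(unique(as.integer(fire_years)))
  if (length(fy) && (min(fy) < y0 || max(fy) > y1))
    stop("fire years outside the record window")
  if (length(fy) == 0L)
    return(data.frame(length = length(years), status = "right_censored",
                      stringsAsFactors = FALSE))
  lens <- c(fy[1] - y0 + 1L, diff(fy), y1 - fy[length(fy)])
  status <- c("left_censored", rep("complete", length(fy) - 1L),
              "right_censored")
  data.frame(length = as.integer(lens), status = status,
             stringsAsFactors = FALSE)
}

#' Sample censored fire intervals on a regular point grid
#'
#' Lays a regular point grid of the given spacing over a [fire_history()]
#' record and converts each sampled point's fire-year sequence into complete
#' and single-censored interval observations (see [point_intervals()] for the
#' rule). Points on unburnable land-cover classes are excluded.
#'
#' @param grid a [fire_history()] object.
#' @param spacing_m point spacing in meters; must be at least the cell size.
#'   Points are taken every `round(spacing_m / cell_size)` cells, starting at
#'   the center of the first block.
#' @param exclude_classes land-cover labels not susceptible to burning;
#'   points on them are dropped.
#' @param drop_uninformative drop censored observations that carry no
#'   likelihood information (right-censored length 0, left-censored length
#'   <= 1)?
#' @return A data frame with columns `point_id`, `row`, `col`, `class`,
#'   `length`, `status`, with the record length in attribute `record_years`.
#' @export
extract_intervals <- function(grid, spacing_m = 500,
                              exclude_classes = c("sand", "water"),
                              drop_uninformative = FALSE) {
  stopifnot(inherits(grid, "fire_history"))
  if (spacing_m < grid$cell_size)
    stop("'spacing_m' must be at least the cell size (", grid$cell_size,
         " m)")
  step <- max(1L, as.integer(round(spacing_m / grid$cell_size)))
  d <- dim(grid$burns)
  if (step > d[1] || step > d[2])
    stop("point spacing exceeds the landscape extent")
  off <- (step + 1L) %/% 2L
  rows <- seq.int(off, d[1], by = step)
  cols <- seq.int(off, d[2], by = step)

  out <- vector("list", length(rows) * length(cols))
  id <- 0L
  for (cc in cols) {
    for (rr in rows) {
      lab <- grid$land_cover[rr, cc]
      if (lab %in% exclude_classes || is.na(lab)) next
      id <- id + 1L
      fy <- grid$years[grid$burns[rr, cc, ]]
      pi <- point_intervals(fy, grid$years)
      out[[id]] <- data.frame(point_id = id, row = rr, col = cc,
                              class = lab, pi, stringsAsFactors = FALSE)
    }
  }
  if (id == 0L) stop("no sampled points on burnable land cover")
  res <- do.call(rbind, out[seq_len(id)])
  if (drop_uninformative) {
    keep <- .is_informative(res)
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "record_years") <- length(grid$years)
  res
}

#' Read point fire histories from a tabular file
#'
#' Tabular alternative to gridded input: a CSV with columns `point_id`, `x`,
#' `y`, `class`, and `fire_years` (semicolon-separated calendar years; empty
#' for never-burned points), converted to censored interval observations for
#' the given record window.
#'
#' @param file path to the CSV file.
#' @param years the record years (contiguous), e.g. `1997:2008`.
#' @inheritParams extract_intervals
#' @return A data frame with columns `point_id`, `class`, `length`, `status`.
#' @export
read_fire_points <- function(file, years,
                             exclude_classes = c("sand", "water"),
                             drop_uninformative = FALSE) {
  pts <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("point_id", "class", "fire_years")
  if (!all(need %in% names(pts)))
    stop("file must have columns: ", paste(need, collapse = ", "))
  pts <- pts[!pts$class %in% exclude_classes, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no points on burnable land cover")
  out <- lapply(seq_len(nrow(pts)), function(i) {
    fy <- pts$fire_years[i]
    fy <- if (is.na(fy) || !nzchar(fy)) integer(0) else
      as.integer(strsplit(fy, ";", fixed = TRUE)[[1]])
    data.frame(point_id = pts$point_id[i], class = pts$class[i],
               point_intervals(fy, years), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (drop_uninformative) res <- res[.is_informative(res), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "record_years") <- length(years)
  res
}
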